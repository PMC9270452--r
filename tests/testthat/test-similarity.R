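# Independent set-based oracles, deliberately naive.
oracle_jaccard <- function(s1, s2)
  length(intersect(s1, s2)) / length(union(s1, s2))
oracle_forbes <- function(s1, s2) {
  a <- length(intersect(s1, s2))
  b <- length(setdiff(s1, s2)); cc <- length(setdiff(s2, s1))
  n <- a + b + cc
  if (a == 0) return(0)
  a * (n + sqrt(n)) / (a * (n + sqrt(n)) + 1.5 * b * cc)
}
oracle_partition <- function(s1, s2) {
  a <- length(intersect(s1, s2))
  b <- length(setdiff(s1, s2)); cc <- length(setdiff(s2, s1))
  bsor <- if (2 * a + b + cc == 0) 0 else (b + cc) / (2 * a + b + cc)
  bsim <- if (a + min(b, cc) == 0) 0 else min(b, cc) / (a + min(b, cc))
  c(total = bsor, turnover = bsim, nestedness = bsor - bsim)
}

test_that("pair counts are plain set arithmetic", {
  expect_equal(pair_counts(c("s1", "s2", "s3"), c("s2", "s3", "s4", "s5")),
               c(a = 2, b = 1, c = 2, n = 5))
  expect_equal(pair_counts(letters[1:5], letters[1:5]),
               c(a = 5, b = 0, c = 0, n = 5))
  expect_equal(pair_counts(letters[1:3], letters[4:7]),
               c(a = 0, b = 3, c = 4, n = 7))
  expect_error(pair_counts(character(0), "a"), "non-empty")
})

test_that("worked metric values match hand evaluation", {
  expect_equal(jaccard(c(a = 2, b = 1, c = 1, n = 4)), 0.5, tolerance = 1e-12)
  expect_equal(jaccard(c(a = 4, b = 0, c = 0, n = 4)), 1)
  expect_equal(jaccard(c(a = 0, b = 2, c = 3, n = 5)), 0)

  # 2(5 + sqrt 5) / (2(5 + sqrt 5) + 1.5 * 1 * 2) = 0.8282975...
  forbes_212 <- 2 * (5 + sqrt(5)) / (2 * (5 + sqrt(5)) + 3)
  expect_equal(corrected_forbes(c(a = 2, b = 1, c = 2, n = 5)), forbes_212,
               tolerance = 1e-12)
  expect_equal(forbes_212, 0.82830, tolerance = 1e-5)
  expect_equal(corrected_forbes(c(a = 3, b = 0, c = 0, n = 3)), 1)
  expect_equal(corrected_forbes(c(a = 0, b = 3, c = 4, n = 7)), 0)

  p <- sorensen_simpson_partition(c(a = 2, b = 1, c = 2, n = 5))
  expect_equal(unname(p), c(3 / 7, 1 / 3, 3 / 7 - 1 / 3), tolerance = 1e-12)

  nested <- sorensen_simpson_partition(c(a = 3, b = 2, c = 0, n = 5))
  expect_equal(unname(nested), c(0.25, 0, 0.25), tolerance = 1e-12)

  ident <- sorensen_simpson_partition(c(a = 4, b = 0, c = 0, n = 4))
  expect_equal(unname(ident), c(0, 0, 0))
})

test_that("metrics are symmetric, bounded, label-invariant, and agree at endpoints", {
  set.seed(7)
  reg <- similarity_metrics()
  for (i in 1:500) {
    a <- sample(0:8, 1); b <- sample(0:8, 1); cc <- sample(0:8, 1)
    if (a + b == 0 || a + cc == 0) next   # empty site, excluded by vetting
    for (nm in names(reg)) {
      v <- reg[[nm]](a, b, cc)
      expect_gte(v, 0); expect_lte(v, 1)
      expect_equal(v, reg[[nm]](a, cc, b), tolerance = 1e-12)  # site swap
    }
    jac <- reg$jaccard(a, b, cc); forb <- reg$forbes_corrected(a, b, cc)
    # Jaccard is 1 only for identical sets; corrected Forbes saturates at 1
    # for any fully nested pair (b * c = 0), by construction of the formula
    expect_equal(jac == 1, b == 0 && cc == 0)
    expect_equal(forb == 1, a > 0 && b * cc == 0)
    expect_equal(jac == 0, forb == 0)
    # partition identity
    p <- sorensen_simpson_partition(c(a = a, b = b, c = cc, n = a + b + cc))
    expect_equal(p[["total"]], p[["turnover"]] + p[["nestedness"]],
                 tolerance = 1e-12)
    # adding a shared species never decreases Jaccard
    expect_gte(reg$jaccard(a + 1, b, cc), jac)
  }
})

test_that("matrix metric implementations equal set-operation oracles exactly", {
  set.seed(11)
  for (rep in 1:50) {
    sets <- random_sets(6, 10)
    m <- matrix_from_sets(sets)
    S <- pairwise_similarity(m, "jaccard")
    Fm <- pairwise_similarity(m, "forbes_corrected")
    for (i in 1:5) for (j in (i + 1):6) {
      expect_identical(S[i, j], oracle_jaccard(sets[[i]], sets[[j]]))
      expect_equal(Fm[i, j], oracle_forbes(sets[[i]], sets[[j]]),
                   tolerance = 1e-14)
    }
  }
})

test_that("multisite partition reduces to pairwise and matches vegan", {
  f <- fauna_from_sets(list(A = c("s1", "s2", "s3"),
                            B = c("s2", "s3", "s4", "s5")))
  m <- build_incidence_matrix(f)
  expect_equal(multisite_partition(m),
               sorensen_simpson_partition(pair_counts(c("s1", "s2", "s3"),
                                                      c("s2", "s3", "s4", "s5"))),
               tolerance = 1e-12)

  same <- matrix(TRUE, 4, 5, dimnames = list(paste0("s", 1:4), letters[1:5]))
  expect_equal(unname(multisite_partition(same)), c(0, 0, 0))

  set.seed(3)
  for (rep in 1:20) {
    m <- matrix_from_sets(random_sets(5, 8))
    ours <- multisite_partition(m)
    v <- vegan::nestedbetasor(m * 1)
    expect_equal(unname(ours[c("turnover", "nestedness", "total")]),
                 unname(v[c("turnover", "nestedness", "sorensen")]),
                 tolerance = 1e-10)
    # pairwise Jaccard against vegan's binary Jaccard distance
    d <- as.matrix(vegan::vegdist(m * 1, method = "jaccard", binary = TRUE))
    S <- pairwise_similarity(m, "jaccard")
    expect_equal(S[lower.tri(S)], 1 - d[lower.tri(d)], tolerance = 1e-10)
  }
})

test_that("mean pairwise similarity averages the unordered pairs", {
  f <- fauna_from_sets(list(A = c("x", "y"), B = c("y", "z"),
                            C = c("x", "y", "z")))
  r <- mean_pairwise_similarity(build_incidence_matrix(f))
  expect_equal(r$mean, mean(c(1 / 3, 2 / 3, 2 / 3)))  # = 5/9
  expect_equal(r$n_pairs, 3)

  ident <- matrix(TRUE, 3, 4, dimnames = list(paste0("s", 1:3), letters[1:4]))
  ri <- mean_pairwise_similarity(ident)
  expect_equal(ri$mean, 1); expect_equal(ri$sem, 0)

  disj <- matrix_from_sets(list(A = "a", B = "b", C = "c"))
  rd <- mean_pairwise_similarity(disj)
  expect_equal(rd$mean, 0); expect_equal(rd$sem, 0)

  expect_error(mean_pairwise_similarity(ident[1, , drop = FALSE]), "two sites")
})
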