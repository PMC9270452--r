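#' Shared/unique species counts for a site pair
#'
#' The atom of every incidence-based similarity metric: `a` species shared,
#' `b` unique to the first site, `c` unique to the second, `n = a + b + c`.
#' Joint absences are deliberately not represented.
#'
#' @param site1,site2 Character vectors (species sets); must be non-empty.
#' @return Named integer vector `c(a, b, c, n)`.
#' @export
pair_counts <- function(site1, site2) {
  if (length(site1) == 0 || length(site2) == 0)
    stop("pair_counts requires non-empty species sets")
  site1 <- unique(site1); site2 <- unique(site2)
  a <- length(intersect(site1, site2))
  b <- length(site1) - a
  cc <- length(site2) - a
  c(a = a, b = b, c = cc, n = a + b + cc)
}

# Vectorized metric kernels on (a, b, c). All return SIMILARITY in [0, 1].
.sim_jaccard <- function(a, b, c) a / (a + b + c)

.sim_forbes_corrected <- function(a, b, c) {
  n <- a + b + c
  num <- a * (n + sqrt(n))
  den <- num + 1.5 * b * c
  out <- ifelse(a == 0, 0, num / den)
  out[den == 0 & a > 0] <- 1
  out
}

.beta_sor <- function(a, b, c) ifelse(2 * a + b + c == 0, 0, (b + c) / (2 * a + b + c))

.beta_sim <- function(a, b, c) {
  m <- pmin(b, c)
  ifelse(a + m == 0, 0, m / (a + m))   # a = 0 & min(b,c) = 0: nested limit
}

#' Jaccard similarity of a site pair
#'
#' Shared species over the total distinct species of the pair,
#' `a / (a + b + c)`; 1 for identical, 0 for disjoint assemblages.
#'
#' @param pc A [pair_counts()] vector.
#' @return Similarity in \[0, 1\].
#' @export
jaccard <- function(pc) unname(.sim_jaccard(pc[["a"]], pc[["b"]], pc[["c"]]))

#' Corrected Forbes similarity of a site pair
#'
#' Alroy's corrected Forbes coefficient,
#' `a (n + sqrt(n)) / (a (n + sqrt(n)) + 3/2 b c)`, which like Jaccard
#' excludes joint absences but compensates for the dependence of
#' Jaccard/Sorensen/Simpson values on site richness.
#'
#' @param pc A [pair_counts()] vector.
#' @return Similarity in \[0, 1\]; 1 when `b = c = 0`, 0 when `a = 0`.
#' @export
corrected_forbes <- function(pc)
  unname(.sim_forbes_corrected(pc[["a"]], pc[["b"]], pc[["c"]]))

#' Pairwise Sorensen/Simpson beta-diversity partition
#'
#' Partitions total pairwise dissimilarity (Sorensen, `beta_sor`) into
#' species turnover (Simpson, `beta_sim`) and nestedness
#' (`beta_sne = beta_sor - beta_sim`), after Baselga. When nothing is shared
#' and one site's complement is empty (`a = 0`, `min(b, c) = 0`) turnover is
#' defined as 0, the nested limit.
#'
#' @param pc A [pair_counts()] vector.
#' @return Named numeric vector `c(total, turnover, nestedness)`; the
#'   identity `total = turnover + nestedness` holds exactly.
#' @export
sorensen_simpson_partition <- function(pc) {
  a <- pc[["a"]]; b <- pc[["b"]]; cc <- pc[["c"]]
  total <- .beta_sor(a, b, cc)
  turnover <- .beta_sim(a, b, cc)
  c(total = total, turnover = turnover, nestedness = total - turnover)
}

#' Registry of pairwise similarity metrics
#'
#' All metrics are reported on the similarity orientation
#' (1 - dissimilarity): `"sorensen"` is `1 - beta_sor`, `"simpson_turnover"`
#' is the Simpson similarity `1 - beta_sim`, and `"nestedness"` is
#' `beta_sne`, i.e. the difference between the Sorensen and Simpson
#' similarities.
#'
#' @return Named list of vectorized kernels `f(a, b, c)`.
#' @export
similarity_metrics <- function() {
  list(
    jaccard = .sim_jaccard,
    forbes_corrected = .sim_forbes_corrected,
    sorensen = function(a, b, c) 1 - .beta_sor(a, b, c),
    simpson_turnover = function(a, b, c) 1 - .beta_sim(a, b, c),
    nestedness = function(a, b, c) .beta_sor(a, b, c) - .beta_sim(a, b, c)
  )
}

.metric_fun <- function(metric) {
  reg <- similarity_metrics()
  if (!metric %in% names(reg))
    stop("unknown metric '", metric, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[metric]]
}

#' All pairwise similarities of an incidence matrix
#'
#' @param m Logical/0-1 incidence matrix (sites x species).
#' @param metric Metric name from [similarity_metrics()].
#' @return Symmetric numeric matrix of pairwise values (diagonal `NA`).
#' @export
pairwise_similarity <- function(m, metric = "jaccard") {
  f <- .metric_fun(metric)
  m <- matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m))
  A <- tcrossprod(m)
  r <- rowSums(m)
  b <- matrix(r, nrow(m), nrow(m)) - A        # unique to row site
  cc <- t(b)                                  # unique to column site
  out <- f(A, b, cc)
  diag(out) <- NA_real_
  out
}

#' Mean pairwise similarity among sites
#'
#' Mean and naive standard error over all `s (s - 1) / 2` unordered site
#' pairs (no self-pairs). The SEM treats pairs as independent, matching how
#' the statistic is conventionally plotted; pairwise values sharing a site
#' are of course not independent.
#'
#' @param m Incidence matrix with at least two sites.
#' @param metric Metric name from [similarity_metrics()].
#' @param bin Optional bin label carried into the result.
#' @return data.frame with columns `bin`, `metric`, `mean`, `sem`, `n_pairs`.
#' @export
mean_pairwise_similarity <- function(m, metric = "jaccard", bin = NA_character_) {
  if (nrow(m) < 2) stop("mean pairwise similarity needs at least two sites")
  v <- pairwise_similarity(m, metric)[lower.tri(diag(nrow(m)))]
  data.frame(bin = bin, metric = metric, mean = mean(v),
             sem = stats::sd(v) / sqrt(length(v)), n_pairs = length(v),
             stringsAsFactors = FALSE)
}

#' Multisite Sorensen/Simpson beta-diversity partition
#'
#' Baselga's multiple-site generalization. With `b_ij` the number of species
#' present in site i but not j, `S_i` site richness and `S_T` the pooled
#' richness:
#' `beta_SIM = Smin / (Sa + Smin)` and
#' `beta_SOR = (Smin + Smax) / (2 Sa + Smin + Smax)`,
#' where `Sa = sum(S_i) - S_T`, `Smin = sum over i<j of min(b_ij, b_ji)` and
#' `Smax` the corresponding sum of maxima; nestedness is their difference.
#' With exactly two sites this reduces to the pairwise partition.
#'
#' @param m Incidence matrix with at least two sites.
#' @return Named numeric vector `c(total, turnover, nestedness)`.
#' @export
multisite_partition <- function(m) {
  if (nrow(m) < 2) stop("multisite partition needs at least two sites")
  mm <- matrix(as.numeric(m), nrow = nrow(m))
  A <- tcrossprod(mm)
  r <- rowSums(mm)
  b <- matrix(r, nrow(mm), nrow(mm)) - A
  lt <- lower.tri(b)
  bmin <- pmin(b, t(b))[lt]
  bmax <- pmax(b, t(b))[lt]
  Sa <- sum(r) - sum(colSums(mm) > 0)
  turnover <- if (Sa + sum(bmin) == 0) 0 else sum(bmin) / (Sa + sum(bmin))
  total <- if (2 * Sa + sum(bmin) + sum(bmax) == 0) 0 else
    (sum(bmin) + sum(bmax)) / (2 * Sa + sum(bmin) + sum(bmax))
  c(total = total, turnover = turnover, nestedness = total - turnover)
}

#' Per-bin mean pairwise similarity of a binned dataset
#'
#' @param fauna A binned `fauna` object.
#' @param metric Metric name from [similarity_metrics()].
#' @return data.frame, one row per non-empty bin with >= 2 sites, columns as
#'   in [mean_pairwise_similarity()].
#' @export
binned_similarity <- function(fauna, metric = "jaccard") {
  pools <- bin_sites(fauna)
  pools <- pools[vapply(pools, length, integer(1)) >= 2]
  out <- do.call(rbind, lapply(names(pools), function(bn) {
    mean_pairwise_similarity(build_incidence_matrix(fauna, pools[[bn]]),
                             metric = metric, bin = bn)
  }))
  rownames(out) <- NULL
  out
}
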