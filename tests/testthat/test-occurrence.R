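test_that("CSV readback preserves a toy dataset and collapses duplicates", {
  dir <- withr::local_tempdir()
  writeLines(c("site_id,species_id", "A,x", "A,y", "B,y", "B,y"),
             file.path(dir, "occ.csv"))
  writeLines(c("site_id,lon,lat,age_bp,modern", "A,-100,40,1000,0",
               "B,-99,41,2000,0"), file.path(dir, "sites.csv"))
  writeLines(c("species_id,order_name,mass_kg,extinct", "x,Rodentia,0.1,0",
               "y,Carnivora,5,0"), file.path(dir, "traits.csv"))
  f <- read_fauna(file.path(dir, "occ.csv"), file.path(dir, "sites.csv"),
                  file.path(dir, "traits.csv"))
  expect_equal(nrow(f$sites), 2)
  expect_equal(nrow(f$traits), 2)
  expect_equal(nrow(f$occurrences), 3)   # duplicate (B, y) collapsed
  expect_setequal(site_species(f)$A, c("x", "y"))
})

test_that("schema and integrity violations fail with named offenders", {
  sites <- data.frame(site_id = "A", lon = -100, lat = 40, age_bp = 1000,
                      modern = FALSE)
  traits <- data.frame(species_id = "x", order_name = "Rodentia",
                       mass_kg = 1, extinct = FALSE)
  expect_error(fauna_dataset(sites[, -2], traits,
                             data.frame(site_id = "A", species_id = "x")),
               "lon")
  expect_error(fauna_dataset(sites, traits,
                             data.frame(site_id = "X", species_id = "x")),
               "X")
  expect_error(fauna_dataset(sites, traits,
                             data.frame(site_id = "A", species_id = "zz")),
               "zz")
})

test_that("contemporaneous layers merge by mean age and species union", {
  f <- fauna_from_sets(list(L1 = c("x", "y"), L2 = c("y", "z")),
                       lon = c(-100, -100), lat = c(40, 40),
                       age = c(10000, 10300))
  m <- merge_contemporaneous_layers(f)
  expect_equal(nrow(m$sites), 1)
  expect_equal(m$sites$age_bp, 10150)
  expect_setequal(site_species(m)[[1]], c("x", "y", "z"))
})

test_that("layers beyond the threshold, or at different coordinates, stay separate", {
  apart <- merge_contemporaneous_layers(
    fauna_from_sets(list(L1 = "x", L2 = "y"), lon = c(-100, -100),
                    lat = c(40, 40), age = c(10000, 10600)))
  expect_equal(nrow(apart$sites), 2)
  moved <- merge_contemporaneous_layers(
    fauna_from_sets(list(L1 = "x", L2 = "y"), lon = c(-100, -99),
                    lat = c(40, 40), age = c(10000, 10000)))
  expect_equal(nrow(moved$sites), 2)
})

test_that("merging is transitive over chains and conserves incidences", {
  f <- fauna_from_sets(list(L1 = "x", L2 = "y", L3 = "z"),
                       lon = rep(-100, 3), lat = rep(40, 3),
                       age = c(10000, 10400, 10800))
  m <- merge_contemporaneous_layers(f)
  expect_equal(nrow(m$sites), 1)    # 400-yr steps chain into one site
  expect_equal(m$sites$age_bp, 10400)

  # conservation: site count never grows, (species, coordinate) multiset kept
  set.seed(1)
  for (i in 1:5) {
    sets <- random_sets(8, 12)
    lon <- sample(c(-100, -100, -99), 8, replace = TRUE)
    g <- fauna_from_sets(sets, lon = lon, lat = rep(40, 8),
                         age = sample(seq(9000, 12000, by = 250), 8))
    mg <- merge_contemporaneous_layers(g)
    expect_lte(nrow(mg$sites), nrow(g$sites))
    key_in <- sort(paste(g$occurrences$species_id,
                         round(g$sites$lon[match(g$occurrences$site_id,
                                                 g$sites$site_id)], 4)))
    key_out <- sort(paste(mg$occurrences$species_id,
                          round(mg$sites$lon[match(mg$occurrences$site_id,
                                                   mg$sites$site_id)], 4)))
    expect_equal(unique(key_out), unique(key_in))
  }
})

test_that("vetting enforces richness and required orders, and is idempotent", {
  sp19 <- sprintf("r%02d", 1:19)
  sp25 <- sprintf("q%02d", 1:25)
  sp20 <- c(sprintf("p%02d", 1:18), "art1", "car1")
  traits <- data.frame(
    species_id = c(sp19, sp25, sp20),
    order_name = c(rep("Rodentia", 19 + 25 + 18), "Artiodactyla", "Carnivora"),
    mass_kg = 1, extinct = FALSE)
  traits$order_name[1:2] <- c("Artiodactyla", "Carnivora")  # give sp19 coverage
  f <- fauna_from_sets(list(poor = sp19, rodents = sp25, good = sp20),
                       traits = traits)
  v <- vet_sites(f)
  expect_equal(v$sites$site_id, "good")
  expect_identical(vet_sites(v)$sites$site_id, v$sites$site_id)

  traits$order_name[3] <- NA
  f2 <- fauna_from_sets(list(poor = sp19, rodents = sp25, good = sp20),
                        traits = traits)
  expect_error(vet_sites(f2), "missing order")
})

test_that("time binning follows the closed-old-edge convention and conserves sites", {
  f <- fauna_from_sets(list(a = "x", b = "x", c = "x", d = "x", e = "x",
                            f = "x"),
                       age = c(12345, 30000, 600, NA, 35000, 200),
                       modern = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  # dropped: age 35000 (older than the oldest edge) and the un-flagged 200
  expect_message(b <- assign_time_bins(f), "2 site")
  expect_equal(as.character(b$sites$bin[b$sites$site_id == "a"]), "15000-10000")
  expect_equal(as.character(b$sites$bin[b$sites$site_id == "b"]), "30000-25000")
  expect_equal(as.character(b$sites$bin[b$sites$site_id == "c"]), "5000-500")
  expect_equal(as.character(b$sites$bin[b$sites$site_id == "d"]), "modern")
  expect_equal(attr(b, "n_dropped") + nrow(b$sites), nrow(f$sites))
})

test_that("site filters drop sites; species filters drop species everywhere", {
  traits <- data.frame(species_id = c("x", "y", "z"),
                       order_name = "Rodentia",
                       mass_kg = c(0.02, 2, 50), extinct = c(FALSE, FALSE, TRUE))
  f <- fauna_from_sets(list(n = c("x", "y", "z"), s = c("x", "y")),
                       lat = c(50.2, 45), traits = traits)

  south <- apply_subset(f, "south_of_49")
  expect_equal(south$sites$site_id, "s")

  noext <- apply_subset(f, "exclude_extinct")
  expect_equal(nrow(noext$sites), 2)             # site kept, species removed
  expect_false("z" %in% noext$occurrences$species_id)

  big <- apply_subset(f, "min_mass", mass_kg = 1)
  expect_false("x" %in% big$occurrences$species_id)
  expect_true(all(c("y", "z") %in% big$occurrences$species_id))

  # strict inequality: a species at exactly the threshold is dropped
  at_thr <- apply_subset(f, "min_mass", mass_kg = 2)
  expect_false("y" %in% at_thr$occurrences$species_id)

  traits$mass_kg[2] <- NA
  f2 <- fauna_from_sets(list(n = c("x", "y")), traits = traits)
  expect_error(apply_subset(f2, "min_mass", mass_kg = 1), "y")
})

test_that("incidence matrix matches the species sets exactly and round-trips", {
  f <- fauna_from_sets(list(A = c("x", "y"), B = c("y", "z")))
  m <- build_incidence_matrix(f)
  expect_equal(dim(m), c(2, 3))
  expect_equal(unname(rowSums(m)), c(2, 2))
  expect_equal(colnames(m), c("x", "y", "z"))

  one <- build_incidence_matrix(fauna_from_sets(list(A = c("x", "y"))))
  expect_true(all(one))

  disjoint <- build_incidence_matrix(
    fauna_from_sets(list(A = c("a1", "a2"), B = c("b1", "b2"))))
  expect_equal(unname(colSums(disjoint)), rep(1, 4))

  set.seed(2)
  sets <- random_sets(6, 10)
  g <- fauna_from_sets(sets)
  mm <- build_incidence_matrix(g)
  rebuilt <- lapply(rownames(mm), function(s) colnames(mm)[mm[s, ]])
  names(rebuilt) <- rownames(mm)
  for (s in names(sets))
    expect_setequal(rebuilt[[s]], sets[[s]])
})
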