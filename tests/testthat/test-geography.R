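test_that("great-circle distances reproduce worked values and geosphere", {
  expect_equal(great_circle_km(10, 20, 10, 20), 0)
  expect_equal(great_circle_km(0, 0, 180, 0), pi * 6371, tolerance = 1e-6)
  expect_equal(great_circle_km(0, 0, 1, 0), 6371 * pi / 180, tolerance = 1e-6)

  skip_if_not_installed("geosphere")
  set.seed(4)
  p1 <- cbind(runif(20, -180, 180), runif(20, -85, 85))
  p2 <- cbind(runif(20, -180, 180), runif(20, -85, 85))
  ref <- geosphere::distHaversine(p1, p2, r = 6371000) / 1000
  expect_equal(great_circle_km(p1[, 1], p1[, 2], p2[, 1], p2[, 2]), ref,
               tolerance = 1e-9)
})

test_that("the Behrmann projection hits worked values and preserves area", {
  expect_equal(as.numeric(behrmann_project(0, 0)), c(0, 0))
  expect_equal(unname(behrmann_project(1, 0)[1]),
               6371 * pi / 180 * cos(30 * pi / 180), tolerance = 1e-6)
  # 111.195 * cos(30 deg) = 96.298
  expect_equal(unname(behrmann_project(1, 0)[1]), 96.298, tolerance = 1e-3)

  # area of 1x1 degree cells vs the spherical-excess oracle, 0 to 70 N
  for (lat0 in seq(0, 69, by = 7)) {
    ll <- behrmann_project(0, lat0); ur <- behrmann_project(1, lat0 + 1)
    proj_area <- (ur[1] - ll[1]) * (ur[2] - ll[2])
    sphere_area <- 6371^2 * (pi / 180) *
      (sin((lat0 + 1) * pi / 180) - sin(lat0 * pi / 180))
    expect_equal(proj_area, sphere_area, tolerance = 1e-3)
  }

  # round trip
  g <- behrmann_unproject(behrmann_project(-101.5, 43.2)[1],
                          behrmann_project(-101.5, 43.2)[2])
  expect_equal(as.numeric(g), c(-101.5, 43.2), tolerance = 1e-9)
})

test_that("cell assignment collapses clustered sites and breaks ties low", {
  grid <- grid_spec(cell_km = 100, lon_range = c(-110, -90),
                    lat_range = c(35, 45))
  # two sites ~10 km apart fall in one cell
  c1 <- assign_to_cells(-100, 40, grid)
  c2 <- assign_to_cells(-100.05, 40.05, grid)
  expect_equal(c1, c2)

  # a point exactly on the south-west grid origin goes to cell 1
  expect_equal(assign_to_cells(-110, 35, grid), 1L)
  # a point exactly one cell width east sits on a boundary: lower index wins
  bx <- behrmann_unproject(behrmann_project(-110, 35)[1] + 100,
                           behrmann_project(-110, 35)[2])
  expect_equal(assign_to_cells(bx[1], bx[2], grid), 1L)

  expect_error(assign_to_cells(-120, 40, grid, ids = "far_site"), "far_site")

  # occupancy is a plain fraction of the grid and ignores site clustering
  f <- fauna_from_sets(list(A = "x", B = "x", C = "x"),
                       lon = c(-100, -100.05, -95), lat = c(40, 40.05, 41))
  occ <- species_occupancy(f, grid)
  expect_equal(length(occ$x), 2)   # two distinct cells, not three sites
  expect_equal(length(occ$x) / grid$n_cells, 2 / grid$n_cells)
})

test_that("cluster hulls match the shoelace oracle and split distant clusters", {
  # five coincident points
  pts0 <- matrix(rep(c(500, 500), 5), ncol = 2, byrow = TRUE)
  expect_equal(as.numeric(cluster_hull_range(pts0)), 0)

  # right triangle with 100 km legs plus two interior points: area 5000
  tri <- rbind(c(0, 0), c(100, 0), c(0, 100), c(20, 20), c(30, 10))
  expect_equal(as.numeric(cluster_hull_range(tri)), 5000, tolerance = 1e-9)

  # two tight 10-point clusters 2000 km apart: sum of two small hulls
  set.seed(8)
  cl1 <- cbind(runif(10, 0, 50), runif(10, 0, 50))
  cl2 <- cbind(runif(10, 2000, 2050), runif(10, 0, 50))
  shoelace <- function(p) {
    h <- grDevices::chull(p); x <- p[h, 1]; y <- p[h, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  got <- as.numeric(cluster_hull_range(rbind(cl1, cl2), level = 0.95))
  expect_equal(got, shoelace(cl1) + shoelace(cl2), tolerance = 1e-9)
  expect_lt(got, shoelace(rbind(cl1, cl2)) / 10)  # no giant spanning hull

  # invariance to point order and to rigid rotation
  set.seed(9)
  pts <- cbind(runif(12, 0, 300), runif(12, 0, 300))
  a1 <- as.numeric(cluster_hull_range(pts))
  a2 <- as.numeric(cluster_hull_range(pts[sample(12), ]))
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  a3 <- as.numeric(cluster_hull_range(pts %*% R))
  expect_equal(a1, a2, tolerance = 1e-9)
  expect_equal(a1, a3, tolerance = 1e-6)

  # planar scaling: doubling the spread quadruples the area
  ctr <- colMeans(pts)
  scaled <- sweep(sweep(pts, 2, ctr), 2, c(1, 1), "*") * 2
  expect_equal(as.numeric(cluster_hull_range(scaled)), 4 * a1, tolerance = 1e-6)

  expect_error(cluster_hull_range(tri[1:4, ]), "at least 5")
})

test_that("per-bin range summaries average species-level estimates", {
  # two bins; all species share the same five sites in each bin
  sites <- paste0("s", 1:10)
  lon <- c(-100, -99, -98, -99.5, -98.5, -100, -99, -98, -99.5, -98.5)
  lat <- c(40, 40, 40, 41, 39, 40, 40, 40, 41, 39)
  sets <- stats::setNames(rep(list(c("x", "y")), 10), sites)
  f <- fauna_from_sets(sets, lon = lon, lat = lat,
                       age = c(rep(27000, 5), rep(7000, 5)))
  f <- suppressMessages(assign_time_bins(f))
  rs <- mean_range_size(f)
  ok <- !is.na(rs$bins$mean_area)
  expect_equal(sum(ok), 2)
  expect_equal(rs$bins$sem_area[ok], c(0, 0))      # both species identical
  expect_equal(rs$bins$mean_area[ok][1], rs$bins$mean_area[ok][2],
               tolerance = 1e-9)                   # same site geometry per bin
  expect_true(all(rs$species$n_points == 5))
})

test_that("distance decay recovers a known exponential slope", {
  d <- seq(100, 2000, length.out = 10)
  sim <- exp(-d / 1000)
  fit <- distance_decay(sim, d)
  expect_equal(fit$slope, -0.001, tolerance = 1e-5)

  flat <- distance_decay(rep(0.4, 10), d)
  expect_equal(flat$slope, 0, tolerance = 1e-8)

  steeper <- distance_decay(exp(-d / 500), d)
  expect_lt(steeper$slope, fit$slope)

  ols <- distance_decay(sim, d, method = "ols")
  expect_lt(ols$slope, 0)
  expect_error(distance_decay(c(1, NA, 1), c(1, 2, 3)), "non-finite")
})

test_that("multivariate dispersion equals plane geometry for Euclidean input", {
  pts <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2),
               c(10, 10), c(11, 10), c(10, 11), c(11, 11))
  groups <- rep(c("g1", "g2"), each = 4)
  d <- as.matrix(dist(pts))
  disp <- multivariate_dispersion(d, groups)
  oracle <- sapply(split(1:8, groups), function(i) {
    ctr <- colMeans(pts[i, ])
    mean(sqrt(colSums((t(pts[i, ]) - ctr)^2)))
  })
  expect_equal(unname(disp), unname(oracle), tolerance = 1e-9)

  zero <- multivariate_dispersion(matrix(0, 4, 4), rep(c("a", "b"), 2))
  expect_equal(unname(zero), c(0, 0), tolerance = 1e-9)

  expect_error(multivariate_dispersion(matrix(1:9, 3), rep("a", 3)),
               "symmetric")
})

test_that("the space-for-time map is constant under uniform composition and
           dips at composition boundaries", {
  grid <- grid_spec(cell_km = 100, lon_range = c(-110, -90),
                    lat_range = c(35, 45))
  lon <- rep(seq(-108, -92, by = 2), times = 4)
  lat <- rep(seq(36, 42, by = 2), each = 9)
  cells <- assign_to_cells(lon, lat, grid)

  uniform <- list(x = sort(unique(cells)), y = sort(unique(cells)))
  m1 <- space_for_time_map(uniform, grid, window_km = 1000)
  expect_true(all(m1$value[!is.na(m1$value)] == 1))

  west <- sort(unique(cells[lon < -100]))
  east <- sort(unique(cells[lon >= -100]))
  halves <- list(w1 = west, w2 = west, e1 = east, e2 = east)
  m2 <- space_for_time_map(halves, grid, window_km = 300)
  interior <- m2$lon < -104.5 | m2$lon > -95.5
  boundary <- abs(m2$lon + 100) < 1.5
  expect_true(all(m2$value[interior & !is.na(m2$value)] == 1))
  expect_lt(min(m2$value[boundary], na.rm = TRUE), 1)

  # subsampling is reproducible under a seed
  m3 <- space_for_time_map(halves, grid, window_km = 300, n_sample = 4, seed = 1)
  m4 <- space_for_time_map(halves, grid, window_km = 300, n_sample = 4, seed = 1)
  expect_identical(m3, m4)
})

test_that("a latitudinal range-size gradient maps to similarity increasing
           with latitude", {
  grid <- grid_spec(cell_km = 100, lon_range = c(-110, -90),
                    lat_range = c(30, 50))
  lons <- seq(-108, -92, by = 2)
  band_cells <- function(lat) sort(unique(assign_to_cells(lons, rep(lat, 9),
                                                          grid)))
  south <- band_cells(32); mid <- band_cells(40); north <- band_cells(48)
  occupancy <- c(
    # south: every cell its own endemic species (narrow ranges)
    stats::setNames(as.list(south), paste0("endemic", seq_along(south))),
    # mid: two species each covering half the band
    list(mid_a = mid[1:5], mid_b = mid[4:9]),
    # north: two species spanning the whole band (wide ranges)
    list(north_a = north, north_b = north))
  m <- space_for_time_map(occupancy, grid, window_km = 300)
  band_mean <- sapply(list(south, mid, north), function(cells)
    mean(m$value[m$cell %in% cells], na.rm = TRUE))
  expect_true(all(diff(band_mean) > 0))
  expect_equal(band_mean[3], 1)
})
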