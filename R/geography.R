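EARTH_RADIUS_KM <- 6371

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorized over
#' coordinates; recycles as usual.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  h <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(h)))
}

#' Behrmann equal-area projection
#'
#' Cylindrical equal-area projection with standard parallel 30 degrees on a
#' sphere of radius 6371 km: `x = R lambda cos(30)`,
#' `y = R sin(phi) / cos(30)`. Exactly area-preserving.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @return Two-column matrix of projected coordinates in km.
#' @export
behrmann_project <- function(lon, lat) {
  k <- cos(30 * pi / 180)
  cbind(x_km = EARTH_RADIUS_KM * (lon * pi / 180) * k,
        y_km = EARTH_RADIUS_KM * sin(lat * pi / 180) / k)
}

#' Inverse Behrmann projection
#'
#' @param x_km,y_km Projected coordinates in km.
#' @return Two-column matrix of `lon`, `lat` in degrees.
#' @export
behrmann_unproject <- function(x_km, y_km) {
  k <- cos(30 * pi / 180)
  cbind(lon = (x_km / (EARTH_RADIUS_KM * k)) * 180 / pi,
        lat = asin(pmax(-1, pmin(1, y_km * k / EARTH_RADIUS_KM))) * 180 / pi)
}

#' Equal-area analysis grid
#'
#' A regular grid of square cells in the Behrmann projection. Every cell has
#' area `cell_km^2`; the default extent is a continental window covering
#' North America (the cell count depends entirely on this bounding box,
#' which is a choice of the analyst, not of the projection).
#'
#' @param cell_km Cell side length in km.
#' @param lon_range,lat_range Geographic extent in degrees.
#' @return Object of class `grid_spec` with the projected extent, numbers of
#'   columns/rows, and `n_cells`.
#' @export
grid_spec <- function(cell_km = 100, lon_range = c(-170, -50),
                      lat_range = c(5, 75)) {
  stopifnot(cell_km > 0)
  ll <- behrmann_project(lon_range[1], lat_range[1])
  ur <- behrmann_project(lon_range[2], lat_range[2])
  nx <- ceiling((ur[1] - ll[1]) / cell_km)
  ny <- ceiling((ur[2] - ll[2]) / cell_km)
  structure(list(cell_km = cell_km, xmin = unname(ll[1]), ymin = unname(ll[2]),
                 nx = as.integer(nx), ny = as.integer(ny),
                 n_cells = as.integer(nx * ny),
                 lon_range = lon_range, lat_range = lat_range),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d = %d cells of %g km\n",
              x$nx, x$ny, x$n_cells, x$cell_km))
  invisible(x)
}

#' Assign points to grid cells
#'
#' Maps each point to the cell whose center is nearest (for a regular grid,
#' the containing cell). Points exactly on a cell boundary are equidistant
#' from two centers and break ties toward the lower cell index. Cells are
#' numbered 1..n row-major from the south-west corner.
#'
#' @param lon,lat Coordinates in degrees.
#' @param grid A [grid_spec()].
#' @param ids Optional point labels used in error messages.
#' @return Integer vector of cell indices.
#' @export
assign_to_cells <- function(lon, lat, grid, ids = NULL) {
  p <- behrmann_project(lon, lat)
  ux <- (p[, 1] - grid$xmin) / grid$cell_km
  uy <- (p[, 2] - grid$ymin) / grid$cell_km
  col <- ifelse(ux <= 0, 0L, ceiling(ux) - 1L)   # boundary -> lower index
  row <- ifelse(uy <= 0, 0L, ceiling(uy) - 1L)
  bad <- ux < 0 | uy < 0 | col >= grid$nx | row >= grid$ny
  if (any(bad)) {
    who <- if (!is.null(ids)) paste(ids[bad], collapse = ", ") else
      paste(which(bad), collapse = ", ")
    stop("point(s) outside grid extent: ", who)
  }
  as.integer(row * grid$nx + col + 1L)
}

#' Cell centers of a grid
#'
#' @param grid A [grid_spec()].
#' @param cells Optional integer vector of cell indices (default all).
#' @return data.frame with `cell`, projected `x_km`/`y_km` and geographic
#'   `lon`/`lat` of each cell center.
#' @export
cell_centers <- function(grid, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(grid$n_cells)
  col <- (cells - 1L) %% grid$nx
  row <- (cells - 1L) %/% grid$nx
  x <- grid$xmin + (col + 0.5) * grid$cell_km
  y <- grid$ymin + (row + 0.5) * grid$cell_km
  g <- behrmann_unproject(x, y)
  data.frame(cell = cells, x_km = x, y_km = y, lon = g[, 1], lat = g[, 2])
}

#' Grid occupancy per species
#'
#' Collapses sites to grid cells (so spatially clustered sites occupy one
#' cell and do not inflate occupancy) and returns the set of occupied cells
#' per species.
#'
#' @param fauna A `fauna` object (typically one bin's sites).
#' @param grid A [grid_spec()].
#' @param sites Optional character vector restricting the sites used.
#' @return Named list of sorted integer cell-index vectors, one per species;
#'   attribute `n_cells` carries the grid size. Occupancy proportion is
#'   `lengths(x) / attr(x, "n_cells")`.
#' @export
species_occupancy <- function(fauna, grid, sites = NULL) {
  stopifnot(inherits(fauna, "fauna"))
  if (is.null(sites)) sites <- fauna$sites$site_id
  s <- fauna$sites[match(sites, fauna$sites$site_id), , drop = FALSE]
  cells <- assign_to_cells(s$lon, s$lat, grid, ids = s$site_id)
  cell_of <- stats::setNames(cells, s$site_id)
  occ <- fauna$occurrences[fauna$occurrences$site_id %in% sites, , drop = FALSE]
  out <- lapply(split(unname(cell_of[occ$site_id]), occ$species_id),
                function(x) sort(unique(x)))
  attr(out, "n_cells") <- grid$n_cells
  out
}

# Shoelace area of the convex hull of projected points (km^2); 0 for fewer
# than 3 distinct points or a degenerate (collinear) hull.
.hull_area <- function(pts) {
  pts <- unique(round(pts, 9))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  if (length(h) < 3) return(0)
  x <- pts[h, 1]; y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Single-linkage clustering of projected points with a bridge cut.
# Single-linkage merge heights stay near the typical nearest-neighbour
# distance while linking points of one population center and jump sharply
# when bridging distinct centers; merges higher than `gap_factor` times the
# median positive height are treated as bridges and undone. No bridge means
# one cluster. Deterministic; returns a list of integer index vectors.
.cluster_points <- function(pts, gap_factor = 3) {
  n <- nrow(pts)
  if (n <= 3) return(list(seq_len(n)))
  hc <- stats::hclust(stats::dist(pts), method = "single")
  h <- hc$height
  pos <- h[h > 0]
  k <- 1L
  if (length(pos) > 1) {
    bridges <- sum(h > gap_factor * stats::median(pos))
    k <- bridges + 1L
  }
  if (k == 1) return(list(seq_len(n)))
  memb <- stats::cutree(hc, k = k)
  unname(split(seq_len(n), memb))
}

#' Cluster-hull geographic range size
#'
#' Estimates range area as the summed convex-hull areas of single-linkage
#' point clusters: points are clustered by a Kenward-style nearest-neighbour
#' rule, clusters are ranked by compactness (mean within-cluster pairwise
#' distance, singletons first), and clusters are retained in that order
#' until at least `level` of the points are enclosed. This keeps a species
#' occupying two distant population centers from being credited with one
#' giant hull spanning the gap.
#'
#' @param points Two-column matrix of projected coordinates in km (e.g. from
#'   [behrmann_project()]); at least `min_points` rows.
#' @param level Fraction of points the retained clusters must enclose.
#' @param min_points Minimum number of points required.
#' @return Area in km^2 (0 when all retained clusters are degenerate), with
#'   the cluster index sets attached as attribute `clusters`.
#' @export
cluster_hull_range <- function(points, level = 0.95, min_points = 5) {
  points <- as.matrix(points)
  if (nrow(points) < min_points)
    stop("cluster_hull_range needs at least ", min_points, " points")
  clusters <- .cluster_points(points)
  if (length(clusters) == 1) {
    out <- .hull_area(points[clusters[[1]], , drop = FALSE])
    attr(out, "clusters") <- clusters
    return(out)
  }
  compact <- vapply(clusters, function(idx) {
    if (length(idx) < 2) return(Inf)   # lone outliers are retained last
    mean(stats::dist(points[idx, , drop = FALSE]))
  }, numeric(1))
  ord <- order(compact, vapply(clusters, min, numeric(1)))
  n <- nrow(points)
  covered <- 0L
  keep <- integer(0)
  for (ci in ord) {
    keep <- c(keep, ci)
    covered <- covered + length(clusters[[ci]])
    if (covered / n >= level) break
  }
  out <- sum(vapply(clusters[keep], function(idx)
    .hull_area(points[idx, , drop = FALSE]), numeric(1)))
  attr(out, "clusters") <- clusters[keep]
  out
}

#' Per-bin mean geographic range size and occupancy
#'
#' For every species occurring at `min_points` or more distinct sites in a
#' bin, estimates range area by [cluster_hull_range()] on Behrmann-projected
#' site coordinates; occupancy (fraction of grid cells occupied) is computed
#' for every species present in the bin. Species-level values are then
#' averaged within bins.
#'
#' Convex-hull area grows with the number of points sampled from a range, so
#' bins with more sites are credited with larger hulls at equal true range
#' size. For comparisons of range size *between* bins with unequal sampling,
#' `equalize_points` subsamples every qualifying species' point set down to a
#' fixed number of sites (without replacement, using the current random
#' stream) before hulling, standardizing effort the same way the equal-site
#' resampling of the similarity analysis does.
#'
#' @param fauna A binned `fauna` object.
#' @param grid A [grid_spec()] for occupancy, or `NULL` to skip occupancy.
#' @param level Hull coverage level.
#' @param min_points Minimum distinct sites for a range estimate.
#' @param equalize_points Integer >= `min_points`, or `NULL` (use all points).
#' @return List with `species` (one row per species x bin estimate) and
#'   `bins` (per-bin means: `mean_area`/`sem_area` over qualifying species,
#'   `mean_occupancy`/`sd_occupancy` over all species present). Bins with no
#'   qualifying species get `NA` means with a warning.
#' @export
mean_range_size <- function(fauna, grid = NULL, level = 0.95, min_points = 5,
                            equalize_points = NULL) {
  if (!is.null(equalize_points) && equalize_points < min_points)
    stop("equalize_points must be at least min_points")
  pools <- bin_sites(fauna)
  sets <- site_species(fauna)
  species_rows <- list()
  bin_rows <- list()
  for (bn in names(pools)) {
    ids <- pools[[bn]]
    s <- fauna$sites[match(ids, fauna$sites$site_id), , drop = FALSE]
    proj <- behrmann_project(s$lon, s$lat)
    occ_cells <- if (!is.null(grid)) species_occupancy(fauna, grid, sites = ids)
    by_sp <- split(rep(seq_along(ids), lengths(sets[ids])), unlist(sets[ids]))
    rows <- lapply(names(by_sp), function(sp) {
      pts <- unique(round(proj[by_sp[[sp]], , drop = FALSE], 6))
      if (!is.null(equalize_points) && nrow(pts) > equalize_points)
        pts <- pts[sample.int(nrow(pts), equalize_points), , drop = FALSE]
      area <- if (nrow(pts) >= min_points)
        as.numeric(cluster_hull_range(pts, level = level, min_points = min_points))
      else NA_real_
      occp <- if (!is.null(grid))
        length(occ_cells[[sp]]) / grid$n_cells else NA_real_
      data.frame(species_id = sp, bin = bn, n_points = nrow(pts),
                 area_km2 = area, occupancy = occp, stringsAsFactors = FALSE)
    })
    sp_df <- do.call(rbind, rows)
    species_rows[[bn]] <- sp_df
    ok <- !is.na(sp_df$area_km2)
    if (!any(ok))
      warning("bin '", bn, "' has no species at >= ", min_points, " sites")
    bin_rows[[bn]] <- data.frame(
      bin = bn, n_species_range = sum(ok),
      mean_area = if (any(ok)) mean(sp_df$area_km2[ok]) else NA_real_,
      sem_area = if (sum(ok) > 1)
        stats::sd(sp_df$area_km2[ok]) / sqrt(sum(ok)) else NA_real_,
      mean_occupancy = if (!is.null(grid)) mean(sp_df$occupancy) else NA_real_,
      sd_occupancy = if (!is.null(grid)) stats::sd(sp_df$occupancy) else NA_real_,
      stringsAsFactors = FALSE)
  }
  species <- do.call(rbind, species_rows)
  bins <- do.call(rbind, bin_rows)
  rownames(species) <- rownames(bins) <- NULL
  list(species = species, bins = bins)
}

#' Distance decay of similarity
#'
#' Regression of pairwise similarity on pairwise geographic distance. The
#' default is a generalized linear model with binomial variance and log
#' link (the classical exponential decay form for a metric bounded in
#' \[0, 1\]), fitted by quasi-likelihood so non-integer similarities are
#' legitimate; `method = "ols"` gives a plain linear fit.
#'
#' @param similarity Numeric vector of pairwise similarities.
#' @param distance_km Numeric vector of matching pairwise distances.
#' @param method `"glm"` (binomial-variance log link) or `"ols"`.
#' @return List with `slope`, `intercept` (on the link scale for `"glm"`),
#'   `deviance`, `method`, and the fitted model object.
#' @export
distance_decay <- function(similarity, distance_km, method = c("glm", "ols")) {
  method <- match.arg(method)
  if (length(similarity) != length(distance_km))
    stop("similarity and distance_km must have equal length")
  if (length(similarity) < 3) stop("need at least three pairs")
  if (any(!is.finite(similarity)) || any(!is.finite(distance_km)))
    stop("non-finite inputs")
  df <- data.frame(sim = similarity, d = distance_km)
  if (method == "ols") {
    fit <- stats::lm(sim ~ d, data = df)
    return(list(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                deviance = stats::deviance(fit), method = method, fit = fit))
  }
  start <- c(log(max(mean(df$sim), 1e-6)), 0)
  fit <- stats::glm(sim ~ d, data = df,
                    family = stats::quasibinomial(link = "log"), start = start)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       deviance = stats::deviance(fit), method = method, fit = fit)
}

#' Multivariate dispersion per group
#'
#' Mean distance of group members to their group centroid in a
#' principal-coordinates embedding of a dissimilarity matrix, with
#' Anderson's correction for negative eigenvalues (delegated to
#' [vegan::betadisper()]).
#'
#' @param d Square symmetric dissimilarity matrix (zero diagonal) or `dist`.
#' @param groups Group labels, one per object.
#' @return Named numeric vector of per-group mean distances to centroid.
#' @export
multivariate_dispersion <- function(d, groups) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-10))
      stop("dissimilarity matrix must be square and symmetric")
    d <- stats::as.dist(d)
  }
  groups <- factor(groups)
  if (all(d == 0))   # degenerate: every object identical, dispersion is zero
    return(stats::setNames(rep(0, nlevels(groups)), levels(groups)))
  bd <- vegan::betadisper(d, group = groups, type = "centroid")
  v <- tapply(bd$distances, bd$group, mean)
  stats::setNames(as.numeric(v), names(v))
}

#' Space-for-time similarity map
#'
#' For each occupied grid cell, subsamples surrounding occupied cells within
#' `window_km` (great-circle distance between cell centers) with selection
#' probability proportional to inverse distance, and records the mean
#' pairwise Jaccard similarity of the sampled cell assemblages. With
#' `n_sample = NULL` all neighbours inside the window are used
#' (deterministic).
#'
#' @param occupancy Named list of occupied cell indices per species (as from
#'   [species_occupancy()]), or a logical species x cells matrix.
#' @param grid The [grid_spec()] the occupancy refers to.
#' @param window_km Window radius in km.
#' @param n_sample Number of neighbour cells to subsample, or `NULL` for all.
#' @param seed Optional integer seed.
#' @return data.frame with `cell`, `lon`, `lat`, `n_neighbours`, `value`
#'   (mean pairwise Jaccard; `NA` when fewer than two neighbours).
#' @export
space_for_time_map <- function(occupancy, grid, window_km = 1000,
                               n_sample = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(occupancy)) {
    occupancy <- apply(occupancy, 1, function(r) which(as.logical(r)),
                       simplify = FALSE)
  }
  cells <- sort(unique(unlist(occupancy)))
  if (!length(cells)) stop("empty occupancy")
  # cell -> species assemblage
  assemb <- lapply(cells, function(cl)
    names(occupancy)[vapply(occupancy, function(x) cl %in% x, logical(1))])
  names(assemb) <- cells
  centers <- cell_centers(grid, cells)
  n <- length(cells)
  value <- rep(NA_real_, n)
  n_neigh <- integer(n)
  for (i in seq_len(n)) {
    d <- great_circle_km(centers$lon[i], centers$lat[i], centers$lon, centers$lat)
    nb <- which(d > 0 & d <= window_km)
    n_neigh[i] <- length(nb)
    if (length(nb) < 2) next
    take <- nb
    if (!is.null(n_sample) && n_sample < length(nb))
      take <- sample(nb, n_sample, prob = 1 / d[nb])
    sets <- assemb[take]
    pr <- utils::combn(length(sets), 2)
    sims <- vapply(seq_len(ncol(pr)), function(j) {
      jaccard(pair_counts(sets[[pr[1, j]]], sets[[pr[2, j]]]))
    }, numeric(1))
    value[i] <- mean(sims)
  }
  data.frame(cell = cells, lon = centers$lon, lat = centers$lat,
             n_neighbours = n_neigh, value = value)
}
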