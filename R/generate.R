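#' Configuration for the synthetic fossil-record generator
#'
#' Defines the study conditions a generated dataset emulates: a species pool
#' with log-uniform body masses spread over the orders carrying most
#' non-volant mammal diversity, geodesic-disc latent ranges, spatially
#' clustered sites in seven time bins (six 5,000-year fossil bins plus a
#' modern bin), an optional extinction pulse of large-bodied species at a
#' bin boundary, and optional per-bin range inflation.
#'
#' `range_inflation` multiplies range *area* (radius scales by its square
#' root), so an inflation of 1.5 emulates a 50% increase in mean geographic
#' range size. `extinction = list(boundary, mass_kg, fraction)` removes
#' `fraction` of the species heavier than `mass_kg` from every bin whose old
#' edge is at or below `boundary`; `extinction = NULL` disables the pulse,
#' which together with unit inflation yields a record with no temporal
#' structure.
#'
#' @param n_species Number of species in the pool.
#' @param n_sites_per_bin Integer vector, one entry per bin (oldest first,
#'   modern last).
#' @param bins A [time_bins()] configuration.
#' @param domain List with `lon` and `lat` ranges (degrees).
#' @param mass_range Log-uniform body-mass bounds (kg).
#' @param order_mix Named proportions over
#'   Rodentia/Artiodactyla/Carnivora/other; must sum to 1.
#' @param range_radius `c(meanlog, sdlog)` of the log-normal base range
#'   radius (km).
#' @param range_inflation Per-bin range-area multipliers (> 0).
#' @param extinction `list(boundary, mass_kg, fraction)` or `NULL`.
#' @param detection Per-species per-site detection probability inside the
#'   species' range.
#' @param clustering `list(n_clusters, sd_km)` for the two-level site
#'   placement process, or `NULL` for uniform placement.
#' @param min_richness,required_orders Vetting rules generated sites must
#'   satisfy (sites failing them are regenerated).
#' @param retry_cap Maximum regeneration attempts per site.
#' @param seed Integer seed making the dataset reproducible.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_species = 350,
                             n_sites_per_bin = c(25, 15, 30, 45, 60, 88, 67),
                             bins = time_bins(),
                             domain = list(lon = c(-125, -70), lat = c(25, 55)),
                             mass_range = c(0.005, 3000),
                             order_mix = c(Rodentia = 0.40, Artiodactyla = 0.15,
                                           Carnivora = 0.15, other = 0.30),
                             range_radius = c(meanlog = log(1000), sdlog = 0.5),
                             range_inflation = rep(1, length(bins$labels)),
                             extinction = NULL,
                             detection = 0.5,
                             clustering = list(n_clusters = 12, sd_km = 150),
                             min_richness = 20,
                             required_orders = c("Rodentia", "Artiodactyla",
                                                 "Carnivora"),
                             retry_cap = 100,
                             seed = NULL) {
  nb <- length(bins$labels)
  if (length(n_sites_per_bin) != nb)
    stop("n_sites_per_bin must have one entry per bin (", nb, ")")
  if (abs(sum(order_mix) - 1) > 1e-8) stop("order_mix must sum to 1")
  if (length(range_inflation) != nb || any(range_inflation <= 0))
    stop("range_inflation must be ", nb, " positive multipliers")
  if (!is.null(extinction)) {
    stopifnot(all(c("boundary", "mass_kg", "fraction") %in% names(extinction)),
              extinction$fraction >= 0, extinction$fraction <= 1)
  }
  structure(list(n_species = n_species, n_sites_per_bin = n_sites_per_bin,
                 bins = bins, domain = domain, mass_range = mass_range,
                 order_mix = order_mix, range_radius = range_radius,
                 range_inflation = range_inflation, extinction = extinction,
                 detection = detection, clustering = clustering,
                 min_richness = min_richness, required_orders = required_orders,
                 retry_cap = retry_cap, seed = seed),
            class = "generator_config")
}

#' Generate the species pool and latent ranges
#'
#' Draws traits (order, body mass, extinct flag) and the latent geodesic-disc
#' range of every species: a fixed center plus a per-bin radius equal to the
#' base radius times the square root of the bin's range-area multiplier.
#' Extinct species have no range in bins at or after the extinction boundary.
#'
#' @param cfg A [generator_config()].
#' @param seed Optional seed (defaults to `cfg$seed`).
#' @return List with `traits` (data.frame), `centers` (n x 2 lon/lat) and
#'   `radius_km` (species x bins matrix, `NA` where a species is absent).
#' @export
generate_species_pool <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_species
  ids <- sprintf("sp%03d", seq_len(n))
  mass <- exp(stats::runif(n, log(cfg$mass_range[1]), log(cfg$mass_range[2])))
  ord <- sample(names(cfg$order_mix), n, replace = TRUE, prob = cfg$order_mix)
  extinct <- rep(FALSE, n)
  if (!is.null(cfg$extinction) && cfg$extinction$fraction > 0) {
    big <- which(mass > cfg$extinction$mass_kg)
    k <- round(cfg$extinction$fraction * length(big))
    if (k > 0) extinct[sample(big, k)] <- TRUE
  }
  traits <- data.frame(species_id = ids, order_name = ord, mass_kg = mass,
                       extinct = extinct, stringsAsFactors = FALSE)
  centers <- cbind(lon = stats::runif(n, cfg$domain$lon[1], cfg$domain$lon[2]),
                   lat = stats::runif(n, cfg$domain$lat[1], cfg$domain$lat[2]))
  base_r <- stats::rlnorm(n, cfg$range_radius[["meanlog"]],
                          cfg$range_radius[["sdlog"]])
  nb <- length(cfg$bins$labels)
  radius <- outer(base_r, sqrt(cfg$range_inflation))
  colnames(radius) <- cfg$bins$labels
  rownames(radius) <- ids
  if (!is.null(cfg$extinction)) {
    old_edges <- c(cfg$bins$edges[-length(cfg$bins$edges)],
                   if (cfg$bins$modern) 0)
    gone <- old_edges <= cfg$extinction$boundary
    radius[extinct, gone] <- NA_real_
  }
  list(traits = traits, centers = centers, radius_km = radius)
}

# One site's location (lon, lat) under the two-level clustering process.
.place_site <- function(cfg, cluster_centers) {
  if (is.null(cfg$clustering)) {
    return(c(stats::runif(1, cfg$domain$lon[1], cfg$domain$lon[2]),
             stats::runif(1, cfg$domain$lat[1], cfg$domain$lat[2])))
  }
  ctr <- cluster_centers[sample.int(nrow(cluster_centers), 1), ]
  sd_deg_lat <- cfg$clustering$sd_km / 111.195
  lat <- ctr[2] + stats::rnorm(1, 0, sd_deg_lat)
  lon <- ctr[1] + stats::rnorm(1, 0, sd_deg_lat / cos(ctr[2] * pi / 180))
  c(min(max(lon, cfg$domain$lon[1]), cfg$domain$lon[2]),
    min(max(lat, cfg$domain$lat[1]), cfg$domain$lat[2]))
}

#' Generate a synthetic fossil record
#'
#' Places spatially clustered sites in every time bin and assembles each
#' site's species list: a species occurs with probability `detection` when
#' the site lies inside its latent range for that bin, and never otherwise.
#' Sites failing the vetting rules (minimum richness, required orders) are
#' regenerated up to `retry_cap` times, so the emitted dataset passes
#' [vet_sites()] unchanged.
#'
#' @param pool Output of [generate_species_pool()].
#' @param cfg The same [generator_config()].
#' @param seed Optional seed for the site-placement stage (`NULL` continues
#'   the current stream, which is what [generate_dataset()] relies on).
#' @return A `fauna` object (unbinned; fossil site ages are uniform within
#'   their bin). The generator configuration is attached as the `manifest`
#'   attribute.
#' @export
generate_fossil_record <- function(pool, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  sp_order <- pool$traits$order_name
  labels <- cfg$bins$labels
  edges <- cfg$bins$edges
  cluster_centers <- if (!is.null(cfg$clustering))
    cbind(stats::runif(cfg$clustering$n_clusters, cfg$domain$lon[1], cfg$domain$lon[2]),
          stats::runif(cfg$clustering$n_clusters, cfg$domain$lat[1], cfg$domain$lat[2]))

  site_rows <- list()
  occ_rows <- list()
  for (b in seq_along(labels)) {
    is_modern <- labels[b] == "modern"
    alive <- which(!is.na(pool$radius_km[, b]))
    for (s in seq_len(cfg$n_sites_per_bin[b])) {
      ok <- FALSE
      for (try in seq_len(cfg$retry_cap)) {
        loc <- .place_site(cfg, cluster_centers)
        d <- great_circle_km(loc[1], loc[2],
                             pool$centers[alive, 1], pool$centers[alive, 2])
        inside <- alive[d <= pool$radius_km[alive, b]]
        present <- inside[stats::runif(length(inside)) <= cfg$detection]
        if (length(present) >= cfg$min_richness &&
            all(cfg$required_orders %in% sp_order[present])) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not generate a vettable site in bin '", labels[b],
             "' within ", cfg$retry_cap, " attempts; enrich the configuration ",
             "(larger ranges, higher detection, or more species)")
      age <- if (is_modern) NA_real_ else stats::runif(1, edges[b + 1], edges[b])
      id <- sprintf("b%ds%03d", b, s)
      site_rows[[length(site_rows) + 1L]] <-
        data.frame(site_id = id, lon = loc[1], lat = loc[2], age_bp = age,
                   modern = is_modern, stringsAsFactors = FALSE)
      occ_rows[[length(occ_rows) + 1L]] <-
        data.frame(site_id = id, species_id = pool$traits$species_id[present],
                   stringsAsFactors = FALSE)
    }
  }
  fauna <- fauna_dataset(do.call(rbind, site_rows), pool$traits,
                         do.call(rbind, occ_rows))
  attr(fauna, "manifest") <- list(
    generator = cfg[setdiff(names(cfg), "bins")],
    bin_edges = cfg$bins$edges, modern_bin = cfg$bins$modern, seed = cfg$seed)
  fauna
}

#' Generate, vet and bin a synthetic dataset in one call
#'
#' @param cfg A [generator_config()]; its `seed` (or the `seed` argument)
#'   makes the result reproducible.
#' @param seed Optional override of `cfg$seed`.
#' @return A vetted, binned `fauna` object.
#' @export
generate_dataset <- function(cfg = generator_config(), seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  pool <- generate_species_pool(cfg, seed = NULL)
  fauna <- generate_fossil_record(pool, cfg, seed = NULL)
  fauna <- vet_sites(fauna, min_richness = cfg$min_richness,
                     required_orders = cfg$required_orders)
  suppressMessages(assign_time_bins(fauna, cfg$bins))
}

#' Generate a synthetic gridded climate record
#'
#' Four climate variables over a fixed set of locations and a ladder of time
#' slices: smooth latitudinal gradients plus slice-specific spatial noise.
#' The `deglaciation` knob multiplies the noise standard deviation by
#' `factor` in every slice younger than `slice`, shrinking between-site
#' climate variance the way deglaciation flattens climate gradients.
#'
#' @param n_locations Number of sample locations (shared by all slices).
#' @param slices Numeric vector of slice ages (years BP).
#' @param domain List with `lon` and `lat` ranges.
#' @param gradient_scale Multiplier on the latitudinal gradients (0 = flat).
#' @param noise_sd Multiplier on the per-variable spatial noise (0 = none).
#' @param deglaciation `list(slice, factor)` or `NULL`.
#' @param seed Optional integer seed.
#' @return data.frame of climate samples: `location_id`, `lon`, `lat`,
#'   `slice`, `tmin`, `tmax`, `aet`, `precip`.
#' @export
generate_climate_grid <- function(n_locations = 150,
                                  slices = seq(30000, 500, by = -500),
                                  domain = list(lon = c(-125, -70),
                                                lat = c(25, 55)),
                                  gradient_scale = 1, noise_sd = 1,
                                  deglaciation = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lon <- stats::runif(n_locations, domain$lon[1], domain$lon[2])
  lat <- stats::runif(n_locations, domain$lat[1], domain$lat[2])
  base_sd <- c(tmin = 4, tmax = 4, aet = 150, precip = 250)
  out <- lapply(slices, function(sl) {
    f <- if (!is.null(deglaciation) && sl < deglaciation$slice)
      deglaciation$factor else 1
    data.frame(
      location_id = sprintf("loc%03d", seq_len(n_locations)),
      lon = lon, lat = lat, slice = sl,
      tmin = gradient_scale * (20 - 0.9 * lat) +
        stats::rnorm(n_locations, 0, noise_sd * f * base_sd["tmin"]),
      tmax = gradient_scale * (38 - 0.6 * lat) +
        stats::rnorm(n_locations, 0, noise_sd * f * base_sd["tmax"]),
      aet = gradient_scale * (1100 - 9 * lat) +
        stats::rnorm(n_locations, 0, noise_sd * f * base_sd["aet"]),
      precip = gradient_scale * (1600 - 14 * lat) +
        stats::rnorm(n_locations, 0, noise_sd * f * base_sd["precip"]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
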