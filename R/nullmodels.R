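# Internal: full pairwise-similarity matrix across all sites of a binned
# dataset, rows/cols in site-table order.
.pair_sim_matrix <- function(fauna, metric = "jaccard") {
  pairwise_similarity(build_incidence_matrix(fauna), metric)
}

# Internal: per-bin mean of within-bin pairwise values given index pools.
.bin_means <- function(S, pools_idx) {
  vapply(pools_idx, function(idx) {
    if (length(idx) < 2) return(NA_real_)
    v <- S[idx, idx]
    mean(v[lower.tri(v)])
  }, numeric(1))
}

#' Shuffle sites among time bins
#'
#' One replicate of the site-shuffling null model: every site, with its
#' observed complement of species, is drawn without replacement from the
#' pool of all sites across all bins until each bin's observed site count is
#' reached. Within-site species sets and per-bin site counts are preserved;
#' only the site-to-bin assignment changes.
#'
#' @param fauna A binned `fauna` object.
#' @return A binned `fauna` object with permuted bin assignments.
#' @export
shuffle_bins <- function(fauna) {
  stopifnot(inherits(fauna, "fauna"), !is.null(fauna$sites$bin))
  fauna$sites$bin <- fauna$sites$bin[sample.int(nrow(fauna$sites))]
  fauna
}

#' Null distributions of a per-bin statistic under site shuffling
#'
#' Repeatedly shuffles sites among bins and evaluates `statistic` on every
#' bin of every shuffled dataset.
#'
#' @param fauna A binned `fauna` object.
#' @param statistic Function of one argument, a list with elements `sites`
#'   (the bin's rows of the site table) and `species` (list of the bin's
#'   species sets), returning a single number. Defaults to mean pairwise
#'   Jaccard similarity.
#' @param reps Number of shuffle replicates.
#' @param seed Optional integer seed for reproducibility.
#' @return A `reps` x bins numeric matrix of class `null_distribution`
#'   (columns named by bin, oldest first).
#' @export
null_distribution <- function(fauna, statistic = NULL, reps = 1000, seed = NULL) {
  stopifnot(inherits(fauna, "fauna"), !is.null(fauna$sites$bin), reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(statistic)) {
    sets <- site_species(fauna)
    statistic <- function(bin) {
      m <- do.call(rbind, lapply(bin$species, function(sp)
        as.numeric(sort(unique(unlist(bin$species))) %in% sp)))
      v <- pairwise_similarity(m, "jaccard")
      mean(v[lower.tri(v)])
    }
  }
  sets <- site_species(fauna)
  bins <- levels(fauna$sites$bin)
  bins <- bins[bins %in% fauna$sites$bin]
  n <- nrow(fauna$sites)
  sizes <- table(factor(fauna$sites$bin, levels = bins))
  out <- matrix(NA_real_, nrow = reps, ncol = length(bins),
                dimnames = list(NULL, bins))
  for (r in seq_len(reps)) {
    perm <- sample.int(n)
    pools <- split(perm, rep(bins, sizes))
    for (bn in bins) {
      idx <- pools[[bn]]
      val <- tryCatch(
        statistic(list(sites = fauna$sites[idx, , drop = FALSE],
                       species = sets[idx])),
        error = function(e) stop(sprintf(
          "statistic failed in bin '%s', replicate %d: %s",
          bn, r, conditionMessage(e)), call. = FALSE))
      out[r, bn] <- val
    }
  }
  class(out) <- c("null_distribution", class(out))
  out
}

#' Fast null distribution of per-bin mean pairwise similarity
#'
#' Equivalent to [null_distribution()] with a mean-pairwise-similarity
#' statistic, but precomputes the all-sites pairwise similarity matrix once,
#' so each shuffle replicate is pure indexing. The observed per-bin means
#' are attached as the `"observed"` attribute.
#'
#' @param fauna A binned `fauna` object.
#' @param metric Metric name from [similarity_metrics()].
#' @param reps Number of shuffle replicates.
#' @param seed Optional integer seed.
#' @return A `reps` x bins matrix of class `null_distribution` with an
#'   `observed` attribute (named numeric vector of per-bin observed means).
#' @export
null_similarity <- function(fauna, metric = "jaccard", reps = 1000, seed = NULL) {
  stopifnot(inherits(fauna, "fauna"), !is.null(fauna$sites$bin))
  if (!is.null(seed)) set.seed(seed)
  S <- .pair_sim_matrix(fauna, metric)
  bins <- levels(fauna$sites$bin)
  bins <- bins[bins %in% fauna$sites$bin]
  sizes <- table(factor(fauna$sites$bin, levels = bins))
  n <- nrow(fauna$sites)
  obs_pools <- split(seq_len(n), factor(fauna$sites$bin, levels = bins))[bins]
  observed <- .bin_means(S, obs_pools)
  names(observed) <- bins
  out <- matrix(NA_real_, nrow = reps, ncol = length(bins),
                dimnames = list(NULL, bins))
  grp <- rep(seq_along(bins), sizes)
  for (r in seq_len(reps)) {
    pools <- split(sample.int(n), grp)
    out[r, ] <- .bin_means(S, pools)
  }
  attr(out, "observed") <- observed
  class(out) <- c("null_distribution", class(out))
  out
}

#' Standardized effect sizes against a null distribution
#'
#' For each bin: `effect_size = (observed - null_mean) / null_sd`, with a
#' 95% band taken either as the 2.5th/97.5th percentiles of the null
#' replicates (default, distribution-free) or as a normal-theory
#' `null_mean +/- 1.96 null_sd`. An observation outside the band is flagged
#' significant; positive effect sizes indicate assemblages more similar than
#' the null, i.e. biotic homogenization.
#'
#' @param observed Named numeric vector of per-bin observed values, or a
#'   `null_distribution` carrying an `observed` attribute.
#' @param nulls A `null_distribution` matrix (ignored when `observed` is one).
#' @param band Two probabilities for the percentile band.
#' @param band_type `"percentile"` or `"normal"`.
#' @return data.frame with columns `bin`, `observed`, `null_mean`,
#'   `null_sd`, `lo95`, `hi95`, `effect_size`, `significant`. When
#'   `null_sd = 0` the effect size is `NA` and significance is judged by the
#'   band alone.
#' @export
effect_sizes <- function(observed, nulls = NULL, band = c(0.025, 0.975),
                         band_type = c("percentile", "normal")) {
  band_type <- match.arg(band_type)
  if (inherits(observed, "null_distribution") && is.null(nulls)) {
    nulls <- observed
    observed <- attr(nulls, "observed")
    if (is.null(observed)) stop("null distribution carries no observed values")
  }
  bins <- colnames(nulls)
  if (!all(bins %in% names(observed)))
    stop("observed values and null distribution bins do not align")
  observed <- observed[bins]
  nm <- colMeans(nulls)
  nsd <- apply(nulls, 2, stats::sd)
  if (band_type == "percentile") {
    lo <- apply(nulls, 2, stats::quantile, probs = band[1], na.rm = TRUE)
    hi <- apply(nulls, 2, stats::quantile, probs = band[2], na.rm = TRUE)
  } else {
    z <- stats::qnorm(band[2])
    lo <- nm - z * nsd
    hi <- nm + z * nsd
  }
  es <- ifelse(nsd > 0, (observed - nm) / nsd, NA_real_)
  data.frame(bin = bins, observed = unname(observed), null_mean = unname(nm),
             null_sd = unname(nsd), lo95 = unname(lo), hi95 = unname(hi),
             effect_size = unname(es),
             significant = unname(observed < lo | observed > hi),
             stringsAsFactors = FALSE)
}

#' Age-error randomization of per-bin mean similarity
#'
#' Propagates radiocarbon dating uncertainty: each replicate adds
#' independent normal noise (`sd_years`) to every fossil site's age,
#' re-bins, and recomputes per-bin mean pairwise similarity. Modern sites
#' are exempt; sites perturbed outside the bin configuration (including to
#' negative ages) are dropped for that replicate.
#'
#' @param fauna A binned `fauna` object (its `bins` attribute supplies the
#'   bin configuration).
#' @param sd_years Standard deviation (years) of the zero-mean age error.
#' @param reps Number of replicates.
#' @param metric Metric name from [similarity_metrics()].
#' @param seed Optional integer seed.
#' @return A `reps` x bins matrix of per-bin mean similarity (`NA` where a
#'   bin held fewer than two sites in a replicate), class
#'   `null_distribution`, with the observed per-bin means attached.
#' @export
age_error_randomization <- function(fauna, sd_years = 2000, reps = 1000,
                                    metric = "jaccard", seed = NULL) {
  stopifnot(inherits(fauna, "fauna"), !is.null(fauna$sites$bin))
  bins_cfg <- attr(fauna, "bins")
  if (is.null(bins_cfg)) stop("fauna carries no time-bin configuration")
  if (!is.null(seed)) set.seed(seed)
  S <- .pair_sim_matrix(fauna, metric)
  bins <- bins_cfg$labels
  s <- fauna$sites
  fossil <- which(!s$modern)
  out <- matrix(NA_real_, nrow = reps, ncol = length(bins),
                dimnames = list(NULL, bins))
  for (r in seq_len(reps)) {
    lab <- as.character(s$bin)
    if (sd_years > 0 && length(fossil)) {
      ages <- s$age_bp[fossil] + stats::rnorm(length(fossil), 0, sd_years)
      lab[fossil] <- .bin_of_age(ages, bins_cfg)
    }
    pools <- split(seq_len(nrow(s)), factor(lab, levels = bins))
    out[r, ] <- .bin_means(S, pools)
  }
  obs_pools <- split(seq_len(nrow(s)), factor(as.character(s$bin), levels = bins))
  attr(out, "observed") <- stats::setNames(.bin_means(S, obs_pools), bins)
  class(out) <- c("null_distribution", class(out))
  out
}

#' Smallest per-bin longitudinal extent
#'
#' The maximum pairwise longitudinal distance (degrees) between sites,
#' minimized over bins -- the window width used by the extent-limited
#' resampling design.
#'
#' @param fauna A binned `fauna` object.
#' @return Width in degrees of longitude.
#' @export
min_longitudinal_extent <- function(fauna) {
  pools <- bin_sites(fauna)
  min(vapply(pools, function(ids) {
    lon <- fauna$sites$lon[match(ids, fauna$sites$site_id)]
    diff(range(lon))
  }, numeric(1)))
}

#' Equal-effort resampling of per-bin mean similarity
#'
#' Controls for uneven sampling intensity: each replicate draws `n_sites`
#' sites without replacement from every bin and recomputes per-bin mean
#' pairwise similarity. With `extent_limit_deg` set, the draw is further
#' restricted to sites inside a longitudinal window of that width placed
#' uniformly at random over the bin's longitudinal span; a window holding
#' fewer than `n_sites` sites is redrawn up to 100 times, after which the
#' replicate is skipped for that bin (skips are counted in the `n_skipped`
#' attribute).
#'
#' @param fauna A binned `fauna` object; every bin must hold at least
#'   `n_sites` sites.
#' @param n_sites Number of sites drawn per bin (conventionally the size of
#'   the poorest-sampled bin).
#' @param reps Number of replicates.
#' @param metric Metric name from [similarity_metrics()].
#' @param extent_limit_deg Optional longitudinal window width in degrees.
#' @param seed Optional integer seed.
#' @return A `reps` x bins matrix of class `null_distribution` with
#'   attributes `observed` (full-data per-bin means) and `n_skipped`.
#' @export
resample_equal_sites <- function(fauna, n_sites = 15, reps = 1000,
                                 metric = "jaccard", extent_limit_deg = NULL,
                                 seed = NULL) {
  stopifnot(inherits(fauna, "fauna"), !is.null(fauna$sites$bin))
  if (!is.null(seed)) set.seed(seed)
  S <- .pair_sim_matrix(fauna, metric)
  pools <- split(seq_len(nrow(fauna$sites)), fauna$sites$bin)
  pools <- pools[vapply(pools, length, integer(1)) > 0]
  short <- names(pools)[vapply(pools, length, integer(1)) < n_sites]
  if (length(short))
    stop("bin(s) with fewer than ", n_sites, " sites: ",
         paste(short, collapse = ", "))
  bins <- names(pools)
  lon <- fauna$sites$lon
  out <- matrix(NA_real_, nrow = reps, ncol = length(bins),
                dimnames = list(NULL, bins))
  n_skipped <- 0L
  for (r in seq_len(reps)) {
    for (bn in bins) {
      idx <- pools[[bn]]
      if (!is.null(extent_limit_deg)) {
        span <- range(lon[idx])
        found <- FALSE
        for (try in seq_len(100)) {
          x0 <- if (diff(span) <= extent_limit_deg) span[1] else
            stats::runif(1, span[1], span[2] - extent_limit_deg)
          inside <- idx[lon[idx] >= x0 & lon[idx] <= x0 + extent_limit_deg]
          if (length(inside) >= n_sites) { idx <- inside; found <- TRUE; break }
        }
        if (!found) { n_skipped <- n_skipped + 1L; next }
      }
      take <- if (length(idx) == n_sites) idx else sample(idx, n_sites)
      v <- S[take, take]
      out[r, bn] <- mean(v[lower.tri(v)])
    }
  }
  attr(out, "observed") <- stats::setNames(.bin_means(S, pools), bins)
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("null_distribution", class(out))
  out
}

#' Regression control of similarity on species-pool size
#'
#' Ordinary least-squares fit of per-bin mean similarity on per-bin pooled
#' species richness, used to check that temporal trends in similarity are
#' not driven by the size of the regional species pool.
#'
#' @param mean_similarity Numeric vector of per-bin mean similarities.
#' @param pooled_richness Numeric vector of per-bin pooled species richness.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, and the
#'   underlying `lm` fit.
#' @export
similarity_richness_control <- function(mean_similarity, pooled_richness) {
  if (length(mean_similarity) != length(pooled_richness))
    stop("inputs must have equal length")
  if (length(mean_similarity) < 3)
    stop("need at least three bins for the control regression")
  fit <- stats::lm(mean_similarity ~ pooled_richness)
  sm <- summary(fit)
  if (is.nan(sm$r.squared)) sm$r.squared <- 0   # constant response
  slope <- unname(stats::coef(fit)[2])
  if (is.na(slope)) slope <- 0
  p <- if (nrow(sm$coefficients) >= 2 && ncol(sm$coefficients) >= 4)
    sm$coefficients[2, 4] else NA_real_
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p_value = p, fit = fit)
}

#' Pooled species richness per bin
#'
#' @param fauna A binned `fauna` object.
#' @return Named integer vector: number of distinct species per bin.
#' @export
binned_richness <- function(fauna) {
  pools <- bin_sites(fauna)
  vapply(pools, function(ids) {
    length(unique(fauna$occurrences$species_id[fauna$occurrences$site_id %in% ids]))
  }, integer(1))
}
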