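#' Principal components of climate samples
#'
#' Correlation-matrix PCA (variables standardized to zero mean and unit
#' variance, since temperatures and water fluxes are on different scales) of
#' the four climate variables, pooled across all time slices so that scores
#' are comparable between slices. A per-slice mode is available for
#' sensitivity checks.
#'
#' @param samples data.frame with columns `location_id`, `slice` and the
#'   four climate variables.
#' @param variables Names of the climate variable columns.
#' @param pooled Pool all slices into one decomposition (default) or run a
#'   separate PCA per slice.
#' @return List with `scores` (data.frame: `location_id`, `slice`, `PC1`,
#'   `PC2`), `loadings` (variables x components), `variance_fraction`
#'   (length 4, sums to 1), and the underlying `prcomp` object (pooled mode
#'   only).
#' @export
climate_pca <- function(samples,
                        variables = c("tmin", "tmax", "aet", "precip"),
                        pooled = TRUE) {
  .require_columns(samples, c("location_id", "slice", variables), "climate")
  X <- as.matrix(samples[, variables])
  if (nrow(X) < 3) stop("need at least three climate samples")
  if (any(!is.finite(X))) stop("non-finite climate values")
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance climate variable(s): ",
         paste(variables[sdv == 0], collapse = ", "))
  if (pooled) {
    pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
    scores <- data.frame(location_id = samples$location_id,
                         slice = samples$slice,
                         PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                         stringsAsFactors = FALSE)
    vf <- pc$sdev^2 / sum(pc$sdev^2)
    return(list(scores = scores, loadings = pc$rotation,
                variance_fraction = vf, prcomp = pc))
  }
  parts <- lapply(split(seq_len(nrow(samples)), samples$slice), function(idx) {
    sub <- samples[idx, , drop = FALSE]
    climate_pca(sub, variables = variables, pooled = TRUE)$scores
  })
  scores <- do.call(rbind, parts)
  rownames(scores) <- NULL
  list(scores = scores, loadings = NULL, variance_fraction = NULL, prcomp = NULL)
}

#' Climate turnover per time slice
#'
#' Mean pairwise Euclidean distance between samples in (PC1, PC2) space
#' within each slice, with a naive SEM over the unordered pairs. A slice
#' with a single sample yields `NA` with a warning.
#'
#' @param scores data.frame with columns `slice`, `PC1`, `PC2` (as returned
#'   by [climate_pca()]).
#' @return data.frame with `slice`, `mean_dissimilarity`, `sem`, `n_samples`.
#' @export
climate_turnover <- function(scores) {
  .require_columns(scores, c("slice", "PC1", "PC2"), "scores")
  out <- lapply(split(seq_len(nrow(scores)), scores$slice), function(idx) {
    sl <- scores$slice[idx[1]]
    if (length(idx) < 2) {
      warning("slice '", sl, "' has a single sample; turnover is NA")
      return(data.frame(slice = sl, mean_dissimilarity = NA_real_,
                        sem = NA_real_, n_samples = length(idx)))
    }
    d <- stats::dist(scores[idx, c("PC1", "PC2")])
    data.frame(slice = sl, mean_dissimilarity = mean(d),
               sem = if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else 0,
               n_samples = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Average slice-level turnover into time bins
#'
#' Unweighted mean of per-slice turnover values within each bin of a
#' [time_bins()] configuration; slices are mapped to bins by their age with
#' the same boundary convention as sites.
#'
#' @param turnover data.frame from [climate_turnover()] whose `slice` column
#'   is a numeric age in years BP (0 maps to the modern bin when present).
#' @param bins A [time_bins()] configuration.
#' @return data.frame with `bin`, `mean_turnover`, `n_slices` (empty bins
#'   yield `NA`).
#' @export
average_slices_to_bins <- function(turnover, bins = time_bins()) {
  age <- as.numeric(turnover$slice)
  lab <- .bin_of_age(age, bins)
  if (bins$modern) lab[age == 0] <- "modern"
  out <- data.frame(bin = bins$labels, mean_turnover = NA_real_, n_slices = 0L,
                    stringsAsFactors = FALSE)
  for (bn in bins$labels) {
    sel <- !is.na(lab) & lab == bn & !is.na(turnover$mean_dissimilarity)
    out$n_slices[out$bin == bn] <- sum(sel)
    if (any(sel)) out$mean_turnover[out$bin == bn] <-
        mean(turnover$mean_dissimilarity[sel])
  }
  out
}
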