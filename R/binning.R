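#' Time-bin configuration
#'
#' Defines ordered time bins from strictly decreasing bin edges in calibrated
#' years before present, optionally followed by a modern bin. Bins are
#' half-open `[old_edge, young_edge)` on the age axis, with the oldest edge
#' closed, so e.g. edges `c(30000, 25000)` place age 30000 in the
#' `30000-25000` bin and age 25000 in the next bin down.
#'
#' The default edges give six 5,000-year intervals from 30,000 to 500 yr BP;
#' ages in `(500, 0]` that are not flagged modern fall in no bin.
#'
#' @param edges Strictly decreasing numeric vector of bin edges (years BP).
#' @param modern Logical; append a modern bin for sites flagged modern.
#' @return An object of class `time_bins` with elements `edges`, `modern`,
#'   and `labels` (oldest first, `"modern"` last when present).
#' @export
time_bins <- function(edges = c(30000, 25000, 20000, 15000, 10000, 5000, 500),
                      modern = TRUE) {
  edges <- as.numeric(edges)
  if (length(edges) < 2 || any(diff(edges) >= 0))
    stop("edges must be strictly decreasing and of length >= 2")
  labels <- paste0(edges[-length(edges)], "-", edges[-1])
  if (modern) labels <- c(labels, "modern")
  structure(list(edges = edges, modern = modern, labels = labels),
            class = "time_bins")
}

#' @export
print.time_bins <- function(x, ...) {
  cat("<time_bins>", paste(x$labels, collapse = " | "), "\n")
  invisible(x)
}

# Bin label for a vector of ages (NA where out of range). Bin j holds ages in
# (edges[j+1], edges[j]]: every old edge is closed, so the oldest edge is too.
.bin_of_age <- function(age, bins) {
  edges <- bins$edges
  out <- rep(NA_character_, length(age))
  for (j in seq_len(length(edges) - 1L))
    out[!is.na(age) & age > edges[j + 1L] & age <= edges[j]] <- bins$labels[j]
  out
}

#' Merge contemporaneous stratigraphic layers
#'
#' Layers of the same deposit (identical coordinates after rounding to four
#' decimal places, roughly 11 m) whose ages fall within `threshold_years` of
#' each other are combined into one site: species are unioned and the merged
#' age is the mean of the layer ages. Merging is transitive (a chain of
#' layers each within the threshold of the next becomes one site). Layers at
#' the same coordinates separated by more than the threshold, or at different
#' coordinates, remain separate; modern sites pass through untouched.
#'
#' @param fauna A `fauna` object.
#' @param threshold_years Maximum age difference (years) for combining layers.
#' @return A `fauna` object with merged sites. Merged sites keep the id of
#'   their oldest layer.
#' @export
merge_contemporaneous_layers <- function(fauna, threshold_years = 500) {
  stopifnot(inherits(fauna, "fauna"))
  s <- fauna$sites
  fossil <- !s$modern
  key <- paste(sprintf("%.4f", s$lon), sprintf("%.4f", s$lat))
  group <- rep(NA_character_, nrow(s))

  for (k in unique(key[fossil])) {
    idx <- which(fossil & key == k)
    idx <- idx[order(s$age_bp[idx], decreasing = TRUE)]
    if (length(idx) == 1) { group[idx] <- s$site_id[idx]; next }
    ages <- s$age_bp[idx]
    # consecutive gaps > threshold cut the chain; within-threshold chains merge
    comp <- cumsum(c(0, abs(diff(ages)) > threshold_years))
    for (cc in unique(comp)) {
      members <- idx[comp == cc]
      group[members] <- s$site_id[members[1]]
    }
  }
  group[!fossil | is.na(group)] <- s$site_id[!fossil | is.na(group)]

  id_map <- stats::setNames(group, s$site_id)
  merged_sites <- do.call(rbind, lapply(split(seq_len(nrow(s)), group), function(i) {
    data.frame(site_id = group[i[1]],
               lon = s$lon[i[1]], lat = s$lat[i[1]],
               age_bp = if (all(s$modern[i])) NA_real_ else mean(s$age_bp[i]),
               modern = all(s$modern[i]),
               stringsAsFactors = FALSE)
  }))
  # preserve first-appearance order of merged ids
  ord <- match(unique(group), merged_sites$site_id)
  merged_sites <- merged_sites[ord, , drop = FALSE]
  rownames(merged_sites) <- NULL

  occ <- fauna$occurrences
  occ$site_id <- unname(id_map[occ$site_id])
  fauna$sites <- merged_sites
  fauna$occurrences <- unique(occ)
  rownames(fauna$occurrences) <- NULL
  fauna
}

#' Vet sites for minimum richness and taxonomic coverage
#'
#' Retains only sites with at least `min_richness` species and at least one
#' occurrence from every order in `required_orders`. This mirrors standard
#' practice for comparing fossil to modern assemblages: it removes sparse
#' accumulations and guarantees representation of the clades carrying most
#' non-volant mammal diversity.
#'
#' @param fauna A `fauna` object.
#' @param min_richness Minimum number of species per retained site.
#' @param required_orders Character vector of taxonomic orders each retained
#'   site must include.
#' @return A `fauna` object containing only the surviving sites, in their
#'   original order.
#' @export
vet_sites <- function(fauna, min_richness = 20,
                      required_orders = c("Rodentia", "Artiodactyla", "Carnivora")) {
  stopifnot(inherits(fauna, "fauna"))
  sp_order <- stats::setNames(fauna$traits$order_name, fauna$traits$species_id)
  present <- unique(fauna$occurrences$species_id)
  no_order <- present[is.na(sp_order[present]) | sp_order[present] == ""]
  if (length(no_order))
    stop("species with missing order_name: ", paste(sort(no_order), collapse = ", "))

  sets <- site_species(fauna)
  keep <- vapply(sets, function(sp) {
    length(sp) >= min_richness &&
      all(required_orders %in% unique(sp_order[sp]))
  }, logical(1))
  .subset_sites(fauna, names(sets)[keep])
}

#' Assign sites to time bins
#'
#' Places every site into exactly one bin by its median age (modern sites go
#' to the modern bin); sites older than the oldest edge or younger than the
#' youngest edge without a modern flag are dropped, and the number dropped is
#' recorded in the `n_dropped` attribute and messaged.
#'
#' @param fauna A `fauna` object.
#' @param bins A [time_bins()] configuration.
#' @return A `fauna` object whose site table gains a `bin` factor column with
#'   levels ordered oldest to modern.
#' @export
assign_time_bins <- function(fauna, bins = time_bins()) {
  stopifnot(inherits(fauna, "fauna"), inherits(bins, "time_bins"))
  s <- fauna$sites
  lab <- rep(NA_character_, nrow(s))
  lab[s$modern] <- if (bins$modern) "modern" else NA_character_
  fossil <- !s$modern
  lab[fossil] <- .bin_of_age(s$age_bp[fossil], bins)

  n_dropped <- sum(is.na(lab))
  if (n_dropped > 0)
    message(n_dropped, " site(s) fell outside the bin configuration and were dropped")
  out <- .subset_sites(fauna, s$site_id[!is.na(lab)])
  out$sites$bin <- factor(lab[!is.na(lab)][match(out$sites$site_id, s$site_id[!is.na(lab)])],
                          levels = bins$labels)
  attr(out, "bins") <- bins
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Subset a binned dataset the way the sensitivity analyses do
#'
#' Site filters (`east_of_rockies`, `south_of_49`) drop whole sites; species
#' filters (`exclude_extinct`, `min_mass`) drop species from every site.
#' Sites are deliberately not re-vetted after a species filter, which keeps
#' the site list identical across subset variants. The trait table is never
#' modified.
#'
#' @param fauna A `fauna` object (binned or not).
#' @param filter One of `"east_of_rockies"`, `"south_of_49"`,
#'   `"exclude_extinct"`, `"min_mass"`.
#' @param mass_kg Mass threshold in kg for `"min_mass"` (strict inequality:
#'   species with mass greater than the threshold are kept).
#' @param rockies_lon Longitude (degrees east) operationalizing "east of the
#'   Rocky Mountains"; sites with `lon >= rockies_lon` are kept.
#' @param border_lat Latitude of the Canada/USA border; sites with
#'   `lat <= border_lat` are kept.
#' @return The filtered `fauna` object. Sites left with no species after a
#'   species filter are removed.
#' @export
apply_subset <- function(fauna,
                         filter = c("east_of_rockies", "south_of_49",
                                    "exclude_extinct", "min_mass"),
                         mass_kg = NULL, rockies_lon = -105, border_lat = 49) {
  stopifnot(inherits(fauna, "fauna"))
  filter <- match.arg(filter)
  s <- fauna$sites
  if (filter == "east_of_rockies")
    return(.subset_sites(fauna, s$site_id[s$lon >= rockies_lon]))
  if (filter == "south_of_49")
    return(.subset_sites(fauna, s$site_id[s$lat <= border_lat]))

  tr <- fauna$traits
  if (filter == "exclude_extinct") {
    drop_sp <- tr$species_id[tr$extinct]
  } else {
    if (is.null(mass_kg) || !is.finite(mass_kg) || mass_kg < 0)
      stop("min_mass requires a non-negative mass_kg threshold")
    present <- unique(fauna$occurrences$species_id)
    mass <- stats::setNames(tr$mass_kg, tr$species_id)[present]
    if (anyNA(mass))
      stop("species lacking mass_kg: ",
           paste(sort(present[is.na(mass)]), collapse = ", "))
    drop_sp <- present[mass <= mass_kg]
  }
  fauna$occurrences <-
    fauna$occurrences[!(fauna$occurrences$species_id %in% drop_sp), , drop = FALSE]
  rownames(fauna$occurrences) <- NULL
  nonempty <- unique(fauna$occurrences$site_id)
  if (length(nonempty) < nrow(fauna$sites))
    message(nrow(fauna$sites) - length(nonempty),
            " site(s) left empty by the species filter were removed")
  .subset_sites(fauna, nonempty)
}

#' Build a site-by-species incidence matrix
#'
#' @param fauna A `fauna` object with at least one site.
#' @param sites Optional character vector restricting (and ordering) the
#'   rows; defaults to all sites in site-table order.
#' @return Logical matrix, rows = sites, columns = species (the union over
#'   the chosen sites, sorted lexicographically in the C locale).
#' @export
build_incidence_matrix <- function(fauna, sites = NULL) {
  stopifnot(inherits(fauna, "fauna"))
  if (is.null(sites)) sites <- fauna$sites$site_id
  if (length(sites) < 1) stop("need at least one site")
  occ <- fauna$occurrences[fauna$occurrences$site_id %in% sites, , drop = FALSE]
  species <- sort(unique(occ$species_id), method = "radix")
  m <- matrix(FALSE, nrow = length(sites), ncol = length(species),
              dimnames = list(sites, species))
  m[cbind(match(occ$site_id, sites), match(occ$species_id, species))] <- TRUE
  if (any(rowSums(m) < 1)) stop("incidence matrix has empty site row(s)")
  m
}

#' Per-bin site pools of a binned dataset
#'
#' @param fauna A binned `fauna` object (see [assign_time_bins()]).
#' @return Named list (one element per non-empty bin, oldest first) of
#'   character vectors of site ids.
#' @export
bin_sites <- function(fauna) {
  stopifnot(inherits(fauna, "fauna"), !is.null(fauna$sites$bin))
  pools <- split(fauna$sites$site_id, fauna$sites$bin)
  pools[vapply(pools, length, integer(1)) > 0]
}
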