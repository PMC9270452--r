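#' Assemble an occurrence dataset
#'
#' Bundles the three tables of an incidence study -- site metadata, species
#' traits, and (site, species) occurrence records -- into a single validated
#' object. Duplicate occurrence rows collapse to one incidence; referential
#' integrity between the tables is enforced.
#'
#' @param sites data.frame with columns `site_id`, `lon`, `lat`, `age_bp`
#'   (years before present; `NA` allowed for modern sites) and `modern`
#'   (logical or 0/1).
#' @param traits data.frame with columns `species_id`, `order_name`,
#'   `mass_kg` (`NA` allowed) and `extinct` (logical or 0/1).
#' @param occurrences data.frame with columns `site_id`, `species_id`.
#' @return An object of class `fauna`: a list with elements `sites`,
#'   `traits` and `occurrences` (deduplicated).
#' @export
fauna_dataset <- function(sites, traits, occurrences) {
  .require_columns(sites, c("site_id", "lon", "lat", "age_bp", "modern"), "site")
  .require_columns(traits, c("species_id", "order_name", "mass_kg", "extinct"), "trait")
  .require_columns(occurrences, c("site_id", "species_id"), "occurrence")

  sites <- as.data.frame(sites)
  traits <- as.data.frame(traits)
  occurrences <- as.data.frame(occurrences)

  sites$site_id <- as.character(sites$site_id)
  sites$lon <- as.numeric(sites$lon)
  sites$lat <- as.numeric(sites$lat)
  sites$age_bp <- as.numeric(sites$age_bp)
  sites$modern <- as.logical(sites$modern)
  traits$species_id <- as.character(traits$species_id)
  traits$order_name <- as.character(traits$order_name)
  traits$mass_kg <- as.numeric(traits$mass_kg)
  traits$extinct <- as.logical(traits$extinct)
  occurrences$site_id <- as.character(occurrences$site_id)
  occurrences$species_id <- as.character(occurrences$species_id)

  if (anyDuplicated(sites$site_id))
    stop("duplicated site_id in site table: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]), collapse = ", "))
  if (anyDuplicated(traits$species_id))
    stop("duplicated species_id in trait table: ",
         paste(unique(traits$species_id[duplicated(traits$species_id)]), collapse = ", "))
  if (any(!is.finite(sites$lon)) || any(!is.finite(sites$lat)))
    stop("non-finite site coordinates")
  if (any(sites$lon < -180 | sites$lon > 180) || any(sites$lat < -90 | sites$lat > 90))
    stop("site coordinates out of range")
  if (any(!sites$modern & (is.na(sites$age_bp) | sites$age_bp < 0)))
    stop("fossil sites must have a non-negative age_bp")
  bad_mass <- !is.na(traits$mass_kg) & traits$mass_kg <= 0
  if (any(bad_mass))
    stop("non-positive mass_kg for: ",
         paste(traits$species_id[bad_mass], collapse = ", "))

  unknown_sites <- setdiff(occurrences$site_id, sites$site_id)
  if (length(unknown_sites))
    stop("occurrences reference unknown sites: ",
         paste(sort(unknown_sites), collapse = ", "))
  unknown_sp <- setdiff(occurrences$species_id, traits$species_id)
  if (length(unknown_sp))
    stop("occurrences reference unknown species: ",
         paste(sort(unknown_sp), collapse = ", "))

  occurrences <- unique(occurrences[, c("site_id", "species_id")])
  rownames(sites) <- rownames(traits) <- rownames(occurrences) <- NULL

  structure(list(sites = sites, traits = traits, occurrences = occurrences),
            class = "fauna")
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
  invisible(df)
}

#' Read an occurrence dataset from CSV files
#'
#' Reads the three-table CSV layout (occurrences, sites, traits), tolerating
#' extra columns, and returns a validated [fauna_dataset()].
#'
#' @param occurrence_path CSV with columns `site_id,species_id`.
#' @param site_path CSV with columns `site_id,lon,lat,age_bp,modern` (0/1);
#'   `age_bp` may be empty for modern sites.
#' @param trait_path CSV with columns `species_id,order_name,mass_kg,extinct`.
#' @return A `fauna` object.
#' @export
read_fauna <- function(occurrence_path, site_path, trait_path) {
  for (p in c(occurrence_path, site_path, trait_path))
    if (!file.exists(p)) stop("file not found: ", p)
  occ <- utils::read.csv(occurrence_path, stringsAsFactors = FALSE)
  sites <- utils::read.csv(site_path, stringsAsFactors = FALSE)
  traits <- utils::read.csv(trait_path, stringsAsFactors = FALSE)
  fauna_dataset(sites, traits, occ)
}

#' Write an occurrence dataset to CSV files
#'
#' Emits `occurrences.csv`, `sites.csv` and `traits.csv` under `dir`, plus a
#' `manifest.json` recording any generator configuration attached to the
#' object (see [generate_fossil_record()]).
#'
#' @param fauna A `fauna` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_fauna <- function(fauna, dir) {
  stopifnot(inherits(fauna, "fauna"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("occurrences.csv", "sites.csv", "traits.csv"))
  utils::write.csv(fauna$occurrences, paths[1], row.names = FALSE, quote = TRUE)
  sites <- fauna$sites
  sites$modern <- as.integer(sites$modern)
  utils::write.csv(sites[, c("site_id", "lon", "lat", "age_bp", "modern")],
                   paths[2], row.names = FALSE, quote = TRUE)
  traits <- fauna$traits
  traits$extinct <- as.integer(traits$extinct)
  utils::write.csv(traits[, c("species_id", "order_name", "mass_kg", "extinct")],
                   paths[3], row.names = FALSE, quote = TRUE)
  manifest <- attr(fauna, "manifest")
  if (!is.null(manifest)) {
    mp <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, null = "null")
    paths <- c(paths, mp)
  }
  invisible(paths)
}

#' Species sets per site
#'
#' @param fauna A `fauna` object.
#' @return Named list (one element per site, in site-table order) of character
#'   vectors of species ids.
#' @export
site_species <- function(fauna) {
  stopifnot(inherits(fauna, "fauna"))
  sets <- split(fauna$occurrences$species_id, fauna$occurrences$site_id)
  out <- sets[fauna$sites$site_id]
  names(out) <- fauna$sites$site_id
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  out
}

# Keep only the given sites (occurrences trimmed to match); traits untouched.
.subset_sites <- function(fauna, keep_ids) {
  fauna$sites <- fauna$sites[fauna$sites$site_id %in% keep_ids, , drop = FALSE]
  fauna$occurrences <-
    fauna$occurrences[fauna$occurrences$site_id %in% keep_ids, , drop = FALSE]
  rownames(fauna$sites) <- rownames(fauna$occurrences) <- NULL
  fauna
}

#' @export
print.fauna <- function(x, ...) {
  cat(sprintf("<fauna> %d sites, %d species, %d occurrences\n",
              nrow(x$sites), length(unique(x$occurrences$species_id)),
              nrow(x$occurrences)))
  if (!is.null(x$sites$bin))
    cat("  bins:", paste(levels(x$sites$bin), collapse = " | "), "\n")
  invisible(x)
}
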