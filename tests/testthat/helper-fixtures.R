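# Build a small fauna object from named species sets. Coordinates, ages and
# traits default to innocuous values; any can be overridden.
fauna_from_sets <- function(sets, lon = NULL, lat = NULL, age = NULL,
                            modern = NULL, traits = NULL) {
  n <- length(sets)
  ids <- names(sets)
  if (is.null(lon)) lon <- seq(-100, -90, length.out = n)
  if (is.null(lat)) lat <- rep(40, n)
  if (is.null(age)) age <- rep(1000, n)
  if (is.null(modern)) modern <- rep(FALSE, n)
  sp <- sort(unique(unlist(sets)))
  if (is.null(traits))
    traits <- data.frame(species_id = sp, order_name = "Rodentia",
                         mass_kg = 1, extinct = FALSE, stringsAsFactors = FALSE)
  occ <- data.frame(site_id = rep(ids, lengths(sets)),
                    species_id = unlist(sets, use.names = FALSE),
                    stringsAsFactors = FALSE)
  fauna_dataset(data.frame(site_id = ids, lon = lon, lat = lat, age_bp = age,
                           modern = modern, stringsAsFactors = FALSE),
                traits, occ)
}

# Random species sets over an alphabet, guaranteed non-empty.
random_sets <- function(n_sites, n_species, p = 0.5) {
  alphabet <- sprintf("s%02d", seq_len(n_species))
  sets <- lapply(seq_len(n_sites), function(i) {
    s <- alphabet[stats::runif(n_species) < p]
    if (!length(s)) s <- sample(alphabet, 1)
    s
  })
  names(sets) <- sprintf("site%02d", seq_len(n_sites))
  sets
}

# Incidence matrix straight from species sets (independent of the package's
# builder) for oracle computations.
matrix_from_sets <- function(sets) {
  sp <- sort(unique(unlist(sets)))
  m <- t(vapply(sets, function(s) sp %in% s, logical(length(sp))))
  colnames(m) <- sp
  m
}

# Scaled-down generator configuration used across stochastic tests: the same
# seven-bin design as the default conditions, shrunk to run in milliseconds.
small_config <- function(seed, range_inflation = rep(1, 7), extinction = NULL,
                         n_sites_per_bin = rep(18, 7), n_species = 240) {
  generator_config(n_species = n_species, n_sites_per_bin = n_sites_per_bin,
                   range_inflation = range_inflation, extinction = extinction,
                   seed = seed)
}

# A small binned dataset shared by tests that just need plausible structure.
small_binned <- function(seed = 42) generate_dataset(small_config(seed))
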