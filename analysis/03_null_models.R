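#!/usr/bin/env Rscript
# The core inference: site-shuffling null model and standardized effect
# sizes for the six subset variants (all sites; east of the Rockies; south
# of the 49th parallel; excluding extinct species; species > 1 kg; > 5 kg),
# plus the two sensitivity designs (radiocarbon age error, equal-site
# resampling with and without a longitudinal-extent limit).

library(faunabeta)

data_dir <- file.path("results", "data")
fauna <- assign_time_bins(read_fauna(
  file.path(data_dir, "occurrences.csv"),
  file.path(data_dir, "sites.csv"),
  file.path(data_dir, "traits.csv")))

bundle <- run_pipeline(fauna = fauna, reps = 1000, seed = 2,
                       output_dir = "results")
report(bundle)

# Radiocarbon age error: 2,000-yr noise on every fossil age, re-binned.
ae <- age_error_randomization(fauna, sd_years = 2000, reps = 1000, seed = 3)
ae_sum <- data.frame(bin = colnames(ae),
                     observed = attr(ae, "observed"),
                     median = apply(ae, 2, median, na.rm = TRUE),
                     lo = apply(ae, 2, quantile, 0.025, na.rm = TRUE),
                     hi = apply(ae, 2, quantile, 0.975, na.rm = TRUE))
write.csv(ae_sum, file.path("results", "age_error.csv"), row.names = FALSE)
cat("\nAge-error randomization: observed bin means against the 2.5-97.5%\n",
    "band of 1,000 noisy re-binnings:\n")
print(ae_sum, row.names = FALSE)

# Equal-effort resampling at the poorest bin's site count.
n_min <- min(table(fauna$sites$bin))
rs <- resample_equal_sites(fauna, n_sites = n_min, reps = 1000, seed = 4)
w <- min_longitudinal_extent(fauna)
rs_ext <- resample_equal_sites(fauna, n_sites = n_min, reps = 1000,
                               extent_limit_deg = w, seed = 5)
rs_sum <- data.frame(bin = colnames(rs),
                     observed = attr(rs, "observed"),
                     resampled_median = apply(rs, 2, median, na.rm = TRUE),
                     extent_limited_median = apply(rs_ext, 2, median,
                                                   na.rm = TRUE))
write.csv(rs_sum, file.path("results", "resampling.csv"), row.names = FALSE)
cat(sprintf("\nEqual-effort resampling (%d sites/bin; extent window %.1f deg):\n",
            n_min, w))
print(rs_sum, row.names = FALSE)
cat("A temporal trend surviving equal effort and a fixed spatial window is\n",
    "not a sampling-intensity artefact.\n")
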