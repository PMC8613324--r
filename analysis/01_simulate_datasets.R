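#!/usr/bin/env Rscript
# Generate the synthetic dataset battery used by the downstream analyses:
# radiomics-like tables spanning the dimensionality range of published
# feature tables (samples-per-feature from 0.05 to 5), with imbalanced
# prevalences, correlated feature blocks and sparse missing cells.
# Writes one CSV per dataset plus a summary table under results/data/.

library(foldleak)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

specs <- list(
  null_wide = dataset_spec(100, 2000, prevalence = 0.5, seed = 101),
  null_high = dataset_spec(100, 1000, prevalence = 0.5, seed = 102),
  null_mid = dataset_spec(100, 200, prevalence = 0.4, seed = 103),
  null_low = dataset_spec(100, 20, prevalence = 0.5, seed = 104),
  imbalanced = dataset_spec(120, 400, prevalence = 0.28, seed = 105,
                            block_size = 10, within_block_correlation = 0.6),
  signal = dataset_spec(200, 200, prevalence = 0.5, n_informative = 8,
                        effect_size = 1, seed = 106),
  missing = dataset_spec(150, 300, prevalence = 0.6, missing_rate = 0.005,
                         seed = 107)
)

summary_rows <- lapply(names(specs), function(nm) {
  ds <- generate_dataset(specs[[nm]])
  path <- file.path(out_dir, paste0(nm, ".csv"))
  write_dataset(ds, path)
  data.frame(dataset = nm,
             n_samples = nrow(ds$features), n_features = ncol(ds$features),
             samples_per_feature = round(samples_per_feature(ds), 3),
             prevalence = round(mean(ds$outcome), 3),
             n_informative = length(ds$informative),
             missing_cells = sum(is.na(ds$features)))
})
summary_df <- do.call(rbind, summary_rows)
write.csv(summary_df, file.path("results", "dataset_summary.csv"),
          row.names = FALSE)
print(summary_df, row.names = FALSE)
cat(sprintf("\nwrote %d datasets to %s\n", length(specs), out_dir))
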