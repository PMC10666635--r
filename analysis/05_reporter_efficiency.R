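#!/usr/bin/env Rscript
# Reporter-gene arithmetic on a synthetic measurement table shaped like the
# two-reporter coupling experiments: an empty-vector control, a wildtype
# gene-pair fusion, and mutants with increasing intergenic distances whose
# downstream-reporter efficiency collapses with distance. Values are
# illustrative inputs for the pipeline, not measured data.

suppressPackageStartupMessages(library(overlapscan))
dir.create("results", showWarnings = FALSE)

set.seed(42)
constructs <- tibble::tibble(
  construct_id = c("empty_vector", "wt_minus4", "d13", "d22", "d34"),
  true_eff = c(0, 1.00, 0.40, 0.05, 0.02)  # relative coupling efficiency
)
meas <- dplyr::bind_rows(lapply(seq_len(nrow(constructs)), function(i) {
  tibble::tibble(
    construct_id = constructs$construct_id[i],
    replicate = 1:3,
    specific_activity = 0.2 + 5 * constructs$true_eff[i] *
      (1 + rnorm(3, 0, 0.05)),
    transcript_level = 1 + rnorm(3, 0, 0.05)
  )
}))

out <- reporter_efficiency_table(meas, control_id = "empty_vector",
                                 wildtype_id = "wt_minus4")
readr::write_tsv(out, "results/reporter_efficiencies.tsv")
print(as.data.frame(out), digits = 3)
cat("downstream-reporter efficiency collapses once the intergenic distance\n")
cat("exceeds ~20 nt, the signature of distance-limited reinitiation\n")
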