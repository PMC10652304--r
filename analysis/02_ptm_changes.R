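#!/usr/bin/env Rscript
# Stage 2: percent change in PTM per modified site.
#
# Condition means are compared treated vs vehicle at each modified site,
# averaged per protein and per modification, then totalled. The interesting
# readouts are the signs: the grand sum should be negative in the old arm
# (planted loss-dominated) and positive in the young arm, and the
# young-vs-old per-protein changes should show the planted asymmetry.

library(oxsens)

evidence <- utils::read.csv("results/synthetic/ptm_evidence.csv",
                            stringsAsFactors = FALSE)
pairs <- list(young = c(vehicle = "young-vehicle", treated = "young-treated"),
              old = c(vehicle = "old-vehicle", treated = "old-treated"))

dir.create("results/ptm", recursive = TRUE, showWarnings = FALSE)
changes <- list()
for (age in names(pairs)) {
  by_protein <- ptm_change_table(evidence, pairs[[age]], by = "protein")
  by_mod <- ptm_change_table(evidence, pairs[[age]], by = "modification")
  utils::write.table(by_protein,
                     file.path("results/ptm", paste0("protein_", age, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(by_mod,
                     file.path("results/ptm", paste0("modification_", age, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  census <- sign_census(by_protein)
  cat(sprintf("%s arm: grand sum %+.1f (per protein), %+.1f (per modification); %d down / %d up\n",
              age, grand_sum(by_protein), grand_sum(by_mod),
              census[["decreasing"]], census[["increasing"]]))
  changes[[age]] <- stats::setNames(by_protein$pct_change_per_site, by_protein$id)
}

shared <- intersect(names(changes$young), names(changes$old))
corr <- correlate(changes$young[shared], changes$old[shared],
                  n_boot = 1000, seed = 20)
cat(sprintf("young vs old %%-change correlation: r = %+.3f, slope %+.3f [%+.3f, %+.3f]\n",
            corr$pearson_r, corr$slope, corr$ci_low, corr$ci_high))
jsonlite::write_json(unclass(corr), "results/ptm/young_vs_old_correlation.json",
                     auto_unbox = TRUE, digits = NA)
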