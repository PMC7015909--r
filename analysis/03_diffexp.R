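#!/usr/bin/env Rscript
# Stage 3 — label-swap reconciliation and protein-level differential
# expression: orient heavy/light ratios to metastatic/primary, check
# forward/reverse consistency and correlation, aggregate to protein fold
# changes with RSD and 1.5-fold calls, and assemble the common-kinome
# matrix with kinase-class counts.
#
# Reads:  results/analysis/{sim,quant}/
# Writes: results/analysis/diffexp/

suppressPackageStartupMessages(library(prmkinome))

sim_dir <- "results/analysis/sim"
quant_dir <- "results/analysis/quant"
out <- "results/analysis/diffexp"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

manifest <- utils::read.csv(file.path(sim_dir, "manifest.csv"))
qc <- list()
pair_tables <- list()
for (pair_id in unique(manifest$pair_id)) {
  runs <- manifest[manifest$pair_id == pair_id, ]
  recs <- lapply(seq_len(nrow(runs)), function(i) {
    q <- utils::read.csv(file.path(quant_dir,
                                   sprintf("quant_%s.csv", runs$run_id[i])))
    orient_ratios(q, runs$design[i], runs$replicate_id[i])
  })
  records <- do.call(rbind, recs)
  fwd <- records[records$design == "forward", ]
  rev_ <- records[records$design == "reverse", ]
  tab <- aggregate_protein(records, cutoff = 1.5)
  pair_tables[[pair_id]] <- tab
  utils::write.csv(tab, file.path(out, sprintf("proteins_%s.csv", pair_id)),
                   row.names = FALSE, quote = FALSE)
  qc[[pair_id]] <- list(
    n_proteins = nrow(tab),
    n_up = sum(tab$call == "up"), n_down = sum(tab$call == "down"),
    consistency_fraction = consistency_fraction(fwd, rev_),
    forward_reverse_r2 = forward_reverse_r2(fwd, rev_),
    median_rsd_percent = stats::median(tab$rsd_percent, na.rm = TRUE)
  )
  message(sprintf(
    "%s: %d proteins (%d up / %d down at 1.5-fold), consistency %.1f%%, R2 %.2f",
    pair_id, nrow(tab), qc[[pair_id]]$n_up, qc[[pair_id]]$n_down,
    100 * qc[[pair_id]]$consistency_fraction,
    qc[[pair_id]]$forward_reverse_r2))
}
jsonlite::write_json(qc, file.path(out, "qc.json"), auto_unbox = TRUE,
                     digits = 6, pretty = TRUE)

km <- build_kinome_matrix(pair_tables)
utils::write.csv(data.frame(protein_id = rownames(km$matrix), km$matrix),
                 file.path(out, "kinome_matrix.csv"), row.names = FALSE,
                 quote = FALSE)
utils::write.csv(km$class_counts, file.path(out, "class_counts.csv"),
                 row.names = FALSE, quote = FALSE)
message(sprintf("common kinome across all pairs: %d proteins",
                nrow(km$matrix)))
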