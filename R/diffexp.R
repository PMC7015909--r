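# Label-swap reconciliation and protein-level differential expression:
# orientation of heavy/light ratios to metastatic/primary, forward/reverse
# QC (consistency, R^2), RSD, 1.5-fold regulation calls, dynamic range, and
# the cross-pair kinome matrix with kinase-class counts.

#' Orient per-run peptide ratios to the metastatic/primary axis
#'
#' Under forward labeling (heavy = metastatic) the measured heavy/light
#' ratio already is metastatic/primary, so `oriented_log2 = log2(ratio)`;
#' under reverse labeling the ratio is inverted, so
#' `oriented_log2 = -log2(ratio)`. Peptides that failed the quantification
#' filters are excluded.
#'
#' @param quant Per-run peptide table from [quantify_run()].
#' @param design `"forward"` or `"reverse"`.
#' @param replicate_id Replicate label attached to every record.
#' @return Data frame of replicate ratio records: `peptide_sequence`,
#'   `protein_id`, `kinase_class`, `design`, `replicate_id`,
#'   `measured_ratio`, `oriented_log2`.
#' @export
orient_ratios <- function(quant, design, replicate_id = 1L) {
  if (!design %in% c("forward", "reverse")) {
    stop("unknown design label '", design, "'", call. = FALSE)
  }
  keep <- quant[quant$passed_filters & is.finite(quant$ratio) &
                  quant$ratio > 0, ]
  sign_ <- if (design == "forward") 1 else -1
  data.frame(
    peptide_sequence = keep$peptide_sequence,
    protein_id = keep$protein_id,
    kinase_class = keep$kinase_class,
    design = design,
    replicate_id = replicate_id,
    measured_ratio = keep$ratio,
    oriented_log2 = sign_ * log2(keep$ratio),
    stringsAsFactors = FALSE
  )
}

.per_peptide_mean <- function(records) {
  agg <- stats::aggregate(oriented_log2 ~ peptide_sequence, data = records,
                          FUN = mean)
  stats::setNames(agg$oriented_log2, agg$peptide_sequence)
}

#' Fraction of peptides with consistent forward/reverse trends
#'
#' Over peptides quantified in both labeling schemes, the fraction whose
#' oriented log2 ratios have the same sign (an exact zero is consistent
#' with either sign). `NA` when no peptide is shared.
#'
#' @param forward_records,reverse_records Records from [orient_ratios()].
#' @return Fraction in \[0, 1\], or `NA`.
#' @export
consistency_fraction <- function(forward_records, reverse_records) {
  f <- .per_peptide_mean(forward_records)
  r <- .per_peptide_mean(reverse_records)
  shared <- intersect(names(f), names(r))
  if (length(shared) == 0) return(NA_real_)
  sf <- sign(f[shared])
  sr <- sign(r[shared])
  mean(sf == sr | sf == 0 | sr == 0)
}

#' Forward vs reverse correlation (R^2)
#'
#' Squared Pearson correlation of oriented log2 ratios of peptides shared
#' between forward and reverse labeling experiments.
#'
#' @inheritParams consistency_fraction
#' @return R^2, or `NA` when fewer than 3 peptides are shared or either
#'   vector has zero variance.
#' @export
forward_reverse_r2 <- function(forward_records, reverse_records) {
  f <- .per_peptide_mean(forward_records)
  r <- .per_peptide_mean(reverse_records)
  shared <- intersect(names(f), names(r))
  if (length(shared) < 3) return(NA_real_)
  x <- f[shared]
  y <- r[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Aggregate oriented peptide ratios to protein-level fold changes
#'
#' Within each replicate, the protein log2 ratio is the mean of its
#' peptides' oriented log2 ratios; `mean_log2` is the mean of those
#' replicate values. The RSD is computed on the linear-scale replicate
#' protein ratios (sample SD over mean, in percent; `NA` with a single
#' replicate). A protein is called `up` when `mean_log2 >= log2(cutoff)`,
#' `down` when `<= -log2(cutoff)`, else `unchanged`.
#'
#' @param records Replicate ratio records from [orient_ratios()], possibly
#'   several replicates row-bound together.
#' @param cutoff Fold-change cutoff (default 1.5, motivated by replicate
#'   RSDs of kinase protein quantification).
#' @return Data frame with one row per protein: `protein_id`,
#'   `kinase_class`, `mean_log2`, `rsd_percent`, `n_peptides`,
#'   `n_replicates`, `call`.
#' @export
aggregate_protein <- function(records, cutoff = 1.5) {
  stopifnot(cutoff > 1, nrow(records) > 0)
  out <- lapply(split(records, records$protein_id), function(rec) {
    rep_log2 <- tapply(rec$oriented_log2,
                       paste(rec$design, rec$replicate_id), mean)
    mean_log2 <- mean(rep_log2)
    lin <- 2^rep_log2
    rsd <- if (length(lin) >= 2) 100 * stats::sd(lin) / mean(lin)
           else NA_real_
    data.frame(
      protein_id = rec$protein_id[1],
      kinase_class = rec$kinase_class[1],
      mean_log2 = mean_log2,
      rsd_percent = rsd,
      n_peptides = length(unique(rec$peptide_sequence)),
      n_replicates = length(rep_log2),
      call = if (mean_log2 >= log2(cutoff)) "up"
             else if (mean_log2 <= -log2(cutoff)) "down"
             else "unchanged",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$protein_id), , drop = FALSE]
}

#' Dynamic range of quantified peptide signals
#'
#' Orders of magnitude between the largest and smallest summed peptide
#' signal: `log10(max / min)`.
#'
#' @param areas Positive peptide summed areas (typically light + heavy of
#'   passing peptides).
#' @return Orders of magnitude (>= 0).
#' @export
dynamic_range <- function(areas) {
  if (length(areas) == 0 || any(!is.finite(areas) | areas <= 0)) {
    stop("all areas must be positive and finite", call. = FALSE)
  }
  log10(max(areas) / min(areas))
}

#' Kinome summary matrix and kinase-class counts across cell-line pairs
#'
#' Restricts to proteins quantified in every pair (the common kinome) and
#' returns their `mean_log2` values as a proteins x pairs matrix, together
#' with per-pair counts of all quantified proteins by kinase class.
#'
#' @param pair_tables Named list of protein tables from
#'   [aggregate_protein()], one per cell-line pair.
#' @return List with `matrix` (proteins x pairs, no missing cells) and
#'   `class_counts` (data frame `pair_id`, `kinase_class`, `n`).
#' @export
build_kinome_matrix <- function(pair_tables) {
  stopifnot(length(pair_tables) >= 1)
  if (is.null(names(pair_tables))) {
    names(pair_tables) <- paste0("pair", seq_along(pair_tables))
  }
  common <- Reduce(intersect, lapply(pair_tables, `[[`, "protein_id"))
  common <- sort(common)
  mat <- sapply(pair_tables, function(tab) {
    stats::setNames(tab$mean_log2, tab$protein_id)[common]
  })
  mat <- matrix(mat, nrow = length(common),
                dimnames = list(common, names(pair_tables)))
  counts <- do.call(rbind, lapply(names(pair_tables), function(p) {
    tab <- pair_tables[[p]]
    cnt <- table(factor(tab$kinase_class, levels = KINASE_CLASSES))
    data.frame(pair_id = p, kinase_class = names(cnt),
               n = as.integer(cnt), stringsAsFactors = FALSE)
  }))
  list(matrix = mat, class_counts = counts)
}
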