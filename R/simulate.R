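# Synthetic PRM experiment generator: a spectral library, per-protein ground
# truth ratios, and light/heavy Gaussian transition chromatograms with known
# truth, emulating the structure of scheduled SILAC-PRM acquisitions.

#' Simulation configuration
#'
#' Study conditions for the synthetic PRM experiment. Defaults describe a
#' scheduled PRM run on a nano-LC gradient: 2 s cycle time, 5 s peak sigma
#' (>= 10 points per peak), peptide abundances spanning 4 orders of
#' magnitude, and true protein log2 ratios drawn from N(0, 1) so roughly
#' half the proteins exceed a 1.5-fold change.
#'
#' @param n_proteins Number of kinase proteins.
#' @param peptides_per_protein Integer range `c(min, max)` of peptides per
#'   protein (1-4, mirroring up-to-four-peptides-per-kinase libraries).
#' @param transitions_per_peptide Integer range of y transitions (4-6).
#' @param rt_range Gradient window (seconds) over which apexes are placed.
#' @param peak_sigma Gaussian elution peak sigma, seconds.
#' @param cycle_time Sampling interval of the scheduled acquisition, seconds.
#' @param window_halfwidth Half-width of the scheduled acquisition window
#'   around each peptide apex, seconds.
#' @param abundance_log10_min log10 of the lowest peptide-level abundance.
#' @param abundance_log10_range Orders of magnitude spanned by abundances.
#' @param ratio_log2_sd Scale of the N(0, sd) distribution of true
#'   log2(metastatic/primary) protein ratios.
#' @param noise_relative_sd Coefficient of variation of the per-point
#'   multiplicative log-normal noise (0 = noiseless).
#' @param baseline_level Constant baseline intensity added to every trace.
#' @param interference_fraction Fraction of peptides receiving an interfering
#'   co-isolated peak (see [inject_interference()]).
#' @param interference_amplitude Interference peak height as a multiple of
#'   the affected channel's summed apex intensity.
#' @param interference_offset_sigma Range (in peak sigmas) of the RT offset
#'   of the interfering peak from the true apex.
#' @param missed_cleavage_rate Fraction of library peptides carrying one
#'   internal tryptic site.
#' @param seed Integer seed; every random draw in the generator flows from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 50,
                       peptides_per_protein = c(1, 4),
                       transitions_per_peptide = c(4, 6),
                       rt_range = c(300, 1500),
                       peak_sigma = 5,
                       cycle_time = 2,
                       window_halfwidth = 60,
                       abundance_log10_min = 3,
                       abundance_log10_range = 4,
                       ratio_log2_sd = 1,
                       noise_relative_sd = 0.25,
                       baseline_level = 1,
                       interference_fraction = 0.1,
                       interference_amplitude = 5,
                       interference_offset_sigma = c(3, 6),
                       missed_cleavage_rate = 0.25,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_proteins >= 1,
    all(peptides_per_protein >= 1), all(peptides_per_protein <= 4),
    all(transitions_per_peptide >= 4), all(transitions_per_peptide <= 6),
    diff(rt_range) >= 0, peak_sigma > 0, cycle_time > 0,
    window_halfwidth > 0, abundance_log10_range >= 0, ratio_log2_sd >= 0,
    noise_relative_sd >= 0, baseline_level >= 0,
    interference_fraction >= 0, interference_fraction <= 1,
    interference_amplitude > 0,
    missed_cleavage_rate >= 0, missed_cleavage_rate <= 1
  )
  if (window_halfwidth < max(interference_offset_sigma) * peak_sigma) {
    stop("window_halfwidth must cover the interference offset range",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Class mix loosely follows the composition of a quantified kinome
# (predominantly protein kinases, plus lipid/nucleotide/carbohydrate/other).
.KINASE_CLASS_PROB <- c(protein = 0.80, lipid = 0.04, nucleotide = 0.09,
                        carbohydrate = 0.05, other = 0.02)

.random_tryptic_sequence <- function(missed_cleavage) {
  len <- sample(7:16, 1)
  internal_alphabet <- setdiff(names(AA_MONO), c("K", "R"))
  body <- sample(internal_alphabet, len - 1L, replace = TRUE)
  if (missed_cleavage) {
    pos <- sample(seq_len(len - 2L), 1)  # not last body slot: avoid KP/RP
    body[pos] <- sample(c("K", "R"), 1)
    if (body[pos + 1L] == "P") body[pos + 1L] <- "A"
  }
  paste(c(body, sample(c("K", "R"), 1)), collapse = "")
}

#' Generate a synthetic PRM kinome spectral library
#'
#' Random tryptic peptides (7-16 residues, ending in K/R, at most one
#' internal missed-cleavage site), 1-4 peptides per protein, 4-6 y
#' transitions per peptide with relative intensities drawn from a Dirichlet
#' simplex. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return A validated `prm_library`.
#' @export
generate_library <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  rows <- list()
  used_sequences <- character(0)
  for (p in seq_len(config$n_proteins)) {
    protein_id <- sprintf("KIN%03d", p)
    kclass <- sample(names(.KINASE_CLASS_PROB), 1, prob = .KINASE_CLASS_PROB)
    n_pep <- sample(seq(config$peptides_per_protein[1],
                        config$peptides_per_protein[2]), 1)
    for (q in seq_len(n_pep)) {
      repeat {
        mc <- stats::runif(1) < config$missed_cleavage_rate
        seq_q <- .random_tryptic_sequence(mc)
        if (!seq_q %in% used_sequences) break
      }
      used_sequences <- c(used_sequences, seq_q)
      k <- sample(seq(config$transitions_per_peptide[1],
                      config$transitions_per_peptide[2]), 1)
      k <- min(k, nchar(seq_q) - 2L)  # y ordinals available: 2..len-1
      ordinals <- sort(sample(2:(nchar(seq_q) - 1L), k))
      rel <- stats::rgamma(k, shape = 2)
      rel <- rel / sum(rel)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = protein_id,
        kinase_class = kclass,
        peptide_sequence = seq_q,
        precursor_charge = sample(2:3, 1),
        missed_cleavages = as.integer(mc),
        fragment = paste0("y", ordinals),
        fragment_charge = 1L,
        library_relative_intensity = rel,
        stringsAsFactors = FALSE
      )
    }
  }
  prm_library(do.call(rbind, rows))
}

#' Draw ground truth for a library
#'
#' One true log2(metastatic/primary) ratio per protein (shared by all its
#' peptides), a log-uniform peptide abundance spanning the configured
#' dynamic range, and an apex retention time per peptide. Per-transition
#' true fractional intensities equal the library's relative intensities
#' (the library is assumed to be built from the same spectra).
#'
#' @param library A `prm_library`.
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return List with data frames `proteins` (`protein_id`,
#'   `true_log2_ratio`) and `peptides` (`peptide_sequence`, `protein_id`,
#'   `abundance`, `apex_rt`).
#' @export
generate_ground_truth <- function(library, config, seed = config$seed) {
  stopifnot(inherits(library, "prm_library"), inherits(config, "sim_config"))
  set.seed(seed)
  protein_ids <- unique(library$protein_id)
  proteins <- data.frame(
    protein_id = protein_ids,
    true_log2_ratio = stats::rnorm(length(protein_ids), 0,
                                   config$ratio_log2_sd),
    stringsAsFactors = FALSE
  )
  pep <- unique(library[, c("peptide_sequence", "protein_id")])
  rownames(pep) <- NULL
  pep$abundance <- 10^stats::runif(nrow(pep), config$abundance_log10_min,
                                   config$abundance_log10_min +
                                     config$abundance_log10_range)
  pep$apex_rt <- stats::runif(nrow(pep), config$rt_range[1],
                              config$rt_range[2])
  list(proteins = proteins, peptides = pep)
}

#' Label-swap experiment design
#'
#' @param label_scheme `"forward"` (heavy channel = metastatic state) or
#'   `"reverse"` (heavy = primary). The realized heavy/light ratio of a
#'   peptide is the true metastatic/primary ratio under forward labeling and
#'   its reciprocal under reverse labeling.
#' @return List with `label_scheme` and the channel-to-state map.
#' @export
experiment_design <- function(label_scheme = c("forward", "reverse")) {
  label_scheme <- match.arg(label_scheme)
  channel_state <- if (label_scheme == "forward") {
    c(light = "primary", heavy = "metastatic")
  } else {
    c(light = "metastatic", heavy = "primary")
  }
  list(label_scheme = label_scheme, channel_state = channel_state)
}

#' Simulate transition chromatograms for one PRM run
#'
#' For each library peptide and SILAC channel, every transition trace is a
#' Gaussian sharing the peptide's apex RT and sigma (co-elution is physical
#' for PRM), with amplitude = abundance x channel factor x transition
#' fraction, sampled on the cycle-time grid over the scheduled window, plus
#' a constant baseline, all scaled by multiplicative log-normal noise of
#' unit mean. The channel factors split the peptide abundance so that
#' heavy/light realizes the true ratio under the design's channel map.
#'
#' @param library A `prm_library`.
#' @param truth Output of [generate_ground_truth()]; must cover every
#'   library peptide.
#' @param design An [experiment_design()] (or its `label_scheme` string).
#' @param config A [sim_config()].
#' @param seed Seed for the noise draws (defaults to `config$seed`).
#' @return Long-form chromatogram data frame with columns
#'   `peptide_sequence`, `channel`, `fragment`, `rt_sec`, `intensity`.
#' @export
simulate_experiment <- function(library, truth, design, config,
                                seed = config$seed) {
  stopifnot(inherits(library, "prm_library"), inherits(config, "sim_config"))
  if (is.character(design)) design <- experiment_design(design)
  set.seed(seed)
  sigma <- config$peak_sigma
  truth_pep <- truth$peptides
  missing <- setdiff(unique(library$peptide_sequence),
                     truth_pep$peptide_sequence)
  if (length(missing) > 0) {
    stop("ground truth missing for peptide(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ratio_by_protein <- stats::setNames(truth$proteins$true_log2_ratio,
                                      truth$proteins$protein_id)
  out <- vector("list", 0L)
  for (entry in library_entries(library)) {
    pep_row <- truth_pep[truth_pep$peptide_sequence ==
                           entry$peptide_sequence, ][1, ]
    r_ms_over_prim <- 2^ratio_by_protein[[entry$protein_id]]
    hl <- if (design$label_scheme == "forward") r_ms_over_prim
          else 1 / r_ms_over_prim
    light_amp <- pep_row$abundance / (1 + hl)
    heavy_amp <- pep_row$abundance * hl / (1 + hl)
    grid <- seq(pep_row$apex_rt - config$window_halfwidth,
                pep_row$apex_rt + config$window_halfwidth,
                by = config$cycle_time)
    shape <- exp(-(grid - pep_row$apex_rt)^2 / (2 * sigma^2))
    frac <- entry$transitions$library_relative_intensity
    frac <- frac / sum(frac)
    k <- length(frac)
    for (channel in c("light", "heavy")) {
      amp <- if (channel == "light") light_amp else heavy_amp
      signal <- outer(shape, amp * frac) + config$baseline_level
      if (config$noise_relative_sd > 0) {
        s <- sqrt(log(1 + config$noise_relative_sd^2))
        noise <- matrix(stats::rlnorm(length(signal), meanlog = -s^2 / 2,
                                      sdlog = s),
                        nrow = nrow(signal))
        signal <- signal * noise
      }
      out[[length(out) + 1L]] <- data.frame(
        peptide_sequence = entry$peptide_sequence,
        channel = channel,
        fragment = rep(entry$transitions$fragment, each = length(grid)),
        rt_sec = rep(grid, times = k),
        intensity = as.vector(signal),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Inject interfering peaks into simulated chromatograms
#'
#' Emulates co-isolated matrix interference: a fraction of peptides gains an
#' extra Gaussian peak on a random subset of transitions of one channel, at
#' an RT offset of several peak sigmas, with height a configured multiple of
#' that channel's summed apex intensity. Such peaks distort the transition
#' intensity pattern and retention-time agreement, so affected peptides are
#' expected to fail the dotp / co-elution gates downstream.
#'
#' @param chromatograms Long-form chromatogram data frame.
#' @param config A [sim_config()] with `interference_fraction > 0` (a value
#'   of 0 returns the input unchanged).
#' @param seed Seed (defaults to `config$seed`).
#' @return List with `chromatograms` (modified data frame) and `corrupted`
#'   (character vector of affected peptide sequences).
#' @export
inject_interference <- function(chromatograms, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  peptides <- unique(chromatograms$peptide_sequence)
  n_corrupt <- round(config$interference_fraction * length(peptides))
  if (n_corrupt == 0) {
    return(list(chromatograms = chromatograms, corrupted = character(0)))
  }
  set.seed(seed)
  corrupted <- sort(sample(peptides, n_corrupt))
  sigma <- config$peak_sigma
  for (pep in corrupted) {
    channel <- sample(c("light", "heavy"), 1)
    sel <- chromatograms$peptide_sequence == pep &
      chromatograms$channel == channel
    sub <- chromatograms[sel, ]
    fragments <- unique(sub$fragment)
    targets <- sample(fragments, sample(seq_len(max(1, length(fragments) - 2L)), 1))
    summed <- tapply(sub$intensity, sub$rt_sec, sum)
    apex_rt <- as.numeric(names(summed))[which.max(summed)]
    height <- config$interference_amplitude * max(summed)
    offset <- sample(c(-1, 1), 1) *
      stats::runif(1, config$interference_offset_sigma[1],
                   config$interference_offset_sigma[2]) * sigma
    center <- apex_rt + offset
    hit <- sel & chromatograms$fragment %in% targets
    extra <- height / length(targets) *
      exp(-(chromatograms$rt_sec[hit] - center)^2 / (2 * sigma^2))
    chromatograms$intensity[hit] <- chromatograms$intensity[hit] + extra
  }
  list(chromatograms = chromatograms, corrupted = corrupted)
}

#' Read / write long-form chromatogram CSV
#'
#' Columns: `peptide_sequence`, `channel` (light|heavy), `fragment`
#' (e.g. y7), `rt_sec`, `intensity`.
#'
#' @param chromatograms Long-form chromatogram data frame.
#' @param path File path.
#' @export
write_chromatograms <- function(chromatograms, path) {
  utils::write.csv(chromatograms, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chromatograms
#' @export
read_chromatograms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("peptide_sequence", "channel", "fragment", "rt_sec", "intensity")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("chromatogram file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Simulate an expression matrix with survival outcomes
#'
#' Test-bed for the quartile logrank screen: null genes have expression
#' independent of survival; each effect gene splits samples at its median
#' expression and scales the exponential event rate by the given rate ratio
#' (low-expression half has `rate_ratio`-fold the hazard of the
#' high-expression half, i.e. high expression is protective). Censoring is
#' uniform on (0, `censor_max`). A sample has a single hazard, so only the
#' first effect gene drives survival; any additional effect genes are
#' noisy correlates of the driver.
#'
#' @param n_samples Number of samples.
#' @param n_null_genes Number of null genes.
#' @param effect_rate_ratio Hazard ratio between low- and high-expression
#'   halves for the driver gene; `NULL` for a fully null dataset.
#' @param n_effect_genes Number of genes correlated with the driver (>= 1
#'   when `effect_rate_ratio` is given); gene 1 is the driver itself.
#' @param base_rate Baseline exponential event rate (per day).
#' @param censor_max Upper limit of the uniform censoring time (days).
#' @param seed Integer seed.
#' @return List with `expression` (genes x samples matrix) and `survival`
#'   (data frame `sample_id`, `time`, `event`) plus `effect_genes`.
#' @export
simulate_survival_dataset <- function(n_samples = 200, n_null_genes = 100,
                                      effect_rate_ratio = NULL,
                                      n_effect_genes = 1,
                                      base_rate = 1 / 1000,
                                      censor_max = 3000,
                                      seed = 1L) {
  set.seed(seed)
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  expr <- matrix(stats::rnorm(n_null_genes * n_samples),
                 nrow = n_null_genes,
                 dimnames = list(sprintf("NULL%04d", seq_len(n_null_genes)),
                                 sample_ids))
  rate <- rep(base_rate, n_samples)
  effect_genes <- character(0)
  if (!is.null(effect_rate_ratio)) {
    stopifnot(effect_rate_ratio > 0, n_effect_genes >= 1)
    driver <- stats::rnorm(n_samples)
    high <- driver > stats::median(driver)
    rate <- ifelse(high, base_rate / sqrt(effect_rate_ratio),
                   base_rate * sqrt(effect_rate_ratio))
    eff <- matrix(rep(driver, n_effect_genes), nrow = n_effect_genes,
                  byrow = TRUE)
    if (n_effect_genes > 1) {
      eff[-1, ] <- 0.8 * eff[-1, ] +
        0.6 * matrix(stats::rnorm((n_effect_genes - 1) * n_samples),
                     nrow = n_effect_genes - 1)
    }
    effect_genes <- sprintf("EFF%03d", seq_len(n_effect_genes))
    rownames(eff) <- effect_genes
    colnames(eff) <- sample_ids
    expr <- rbind(eff, expr)
  }
  event_time <- stats::rexp(n_samples, rate)
  censor_time <- stats::runif(n_samples, 0, censor_max)
  survival <- data.frame(
    sample_id = sample_ids,
    time = pmin(event_time, censor_time),
    event = as.integer(event_time <= censor_time),
    stringsAsFactors = FALSE
  )
  # exact zero times are not meaningful survival records
  survival$time <- pmax(survival$time, 1e-6)
  list(expression = expr, survival = survival, effect_genes = effect_genes)
}
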