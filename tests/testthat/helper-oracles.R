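# Independent oracles, deliberately built from first principles so they do
# not share code paths with the implementation under test.

# Elemental-composition mass oracle: residue masses assembled from atomic
# monoisotopic masses and residue elemental formulas, not from the
# package's residue table.
.ELEMENT_MONO <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069)
.RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)
# label increments from isotope mass differences
.C13_MINUS_C12 <- 13.0033548378 - 12.0
.N15_MINUS_N14 <- 15.0001088984 - 14.0030740052
.ORACLE_K_SHIFT <- 6 * .C13_MINUS_C12 + 2 * .N15_MINUS_N14
.ORACLE_R_SHIFT <- 6 * .C13_MINUS_C12
.ORACLE_CAM <- 2 * 12 + 3 * .ELEMENT_MONO["H"] + .ELEMENT_MONO["N"] +
  .ELEMENT_MONO["O"]  # carbamidomethyl C2H3NO

oracle_residue_mass <- function(aa, heavy = FALSE, cam_c = TRUE) {
  f <- .RESIDUE_FORMULA[[aa]]
  m <- sum(.ELEMENT_MONO[names(f)] * f)
  if (cam_c && aa == "C") m <- m + .ORACLE_CAM
  if (heavy && aa == "K") m <- m + .ORACLE_K_SHIFT
  if (heavy && aa == "R") m <- m + .ORACLE_R_SHIFT
  unname(m)
}

oracle_peptide_mass <- function(sequence, heavy = FALSE) {
  residues <- strsplit(sequence, "")[[1]]
  water <- 2 * .ELEMENT_MONO["H"] + .ELEMENT_MONO["O"]
  unname(sum(vapply(residues, oracle_residue_mass, numeric(1),
                    heavy = heavy)) + water)
}

oracle_y_mz <- function(sequence, ordinal, charge = 1, heavy = FALSE) {
  n <- nchar(sequence)
  frag <- substring(sequence, n - ordinal + 1, n)
  proton <- 1.00727646688
  (oracle_peptide_mass(frag, heavy) + charge * proton) / charge
}

random_tryptic <- function(len = sample(6:20, 1)) {
  body <- sample(names(.RESIDUE_FORMULA), len - 1, replace = TRUE)
  paste(c(body, sample(c("K", "R"), 1)), collapse = "")
}

# Direct-formula relative standard deviation (percent)
oracle_rsd <- function(x) 100 * stats::sd(x) / mean(x)

# Brute-force two-group logrank via explicit hypergeometric sums over the
# pooled distinct event times.
oracle_logrank <- function(time1, event1, time2, event2) {
  time <- c(time1, time2)
  event <- c(event1, event2)
  grp1 <- c(rep(TRUE, length(time1)), rep(FALSE, length(time2)))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & grp1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) o_minus_e^2 / v else 0
  list(statistic = stat,
       p_value = if (v > 0) stats::pchisq(stat, 1, lower.tail = FALSE) else 1)
}

# Trapezoid on an arbitrary sampled function, independent of the package's
# integration routine
oracle_trapz <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

# small default simulation for tests
quick_config <- function(...) {
  do.call(sim_config,
          utils::modifyList(list(n_proteins = 15, seed = 42), list(...)))
}

quick_experiment <- function(config, design = "forward", seed = config$seed) {
  lib <- generate_library(config)
  truth <- generate_ground_truth(lib, config)
  chrom <- simulate_experiment(lib, truth, design, config, seed = seed)
  list(library = lib, truth = truth, chromatograms = chrom)
}
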