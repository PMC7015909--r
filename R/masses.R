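# Monoisotopic residue masses (Da), water and proton, and SILAC label shifts.
# All arithmetic is monoisotopic: PRM isolates monoisotopic precursors.

#' Monoisotopic residue masses of the 20 canonical amino acids
#'
#' Named numeric vector of residue (not free amino acid) monoisotopic masses
#' in Da, indexed by one-letter code.
#'
#' @export
AA_MONO <- c(
  G = 57.02146373, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694304, Q = 128.05857751,
  K = 128.09496301, E = 129.04259310, M = 131.04048461, H = 137.05891186,
  F = 147.06841392, R = 156.10111102, Y = 163.06332854, W = 186.07931295
)

#' @rdname AA_MONO
#' @export
WATER_MONO <- 18.01056469

#' @rdname AA_MONO
#' @export
PROTON_MASS <- 1.007276

# Heavy-label mass increments: [13C6,15N2]-lysine and [13C6]-arginine.
SILAC_K_SHIFT <- 8.014199
SILAC_R_SHIFT <- 6.020129

#' SILAC channel descriptor
#'
#' @param label `"light"` or `"heavy"`. The light channel carries no label
#'   shift; the heavy channel adds the \[13C6,15N2\]-lysine (+8.014199 Da per
#'   K) and \[13C6\]-arginine (+6.020129 Da per R) increments.
#' @return A list with `label`, `lysine_shift`, `arginine_shift` (Da).
#' @export
silac_channel <- function(label = c("light", "heavy")) {
  label <- match.arg(label)
  if (label == "light") {
    list(label = "light", lysine_shift = 0, arginine_shift = 0)
  } else {
    list(label = "heavy", lysine_shift = SILAC_K_SHIFT,
         arginine_shift = SILAC_R_SHIFT)
  }
}

#' Default fixed modifications
#'
#' Named vector of fixed modification masses (Da) applied per matching
#' residue. Default is carbamidomethylation of cysteine (+57.02146 Da), the
#' usual consequence of alkylation during filter-aided sample preparation.
#' Pass `numeric(0)` (or `NULL`) for unmodified masses.
#'
#' @export
default_fixed_mods <- function() c(C = 57.02146373)

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("peptide sequence must be a single non-empty string", call. = FALSE)
  }
  residues <- strsplit(sequence, "")[[1]]
  bad <- setdiff(residues, names(AA_MONO))
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue '%s' in sequence '%s'", bad[1], sequence),
         call. = FALSE)
  }
  residues
}

.residue_masses <- function(residues, channel, fixed_mods) {
  m <- AA_MONO[residues]
  if (length(fixed_mods) > 0) {
    extra <- unname(fixed_mods[residues])
    extra[is.na(extra)] <- 0
    m <- m + extra
  }
  m + ifelse(residues == "K", channel$lysine_shift, 0) +
    ifelse(residues == "R", channel$arginine_shift, 0)
}

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass of a peptide: sum of residue masses plus one
#' water, plus the SILAC label increment for every K/R when the channel is
#' heavy, plus any fixed modification masses.
#'
#' @param sequence Uppercase one-letter amino-acid string.
#' @param channel `"light"`, `"heavy"`, or a [silac_channel()] list.
#' @param fixed_mods Named vector of per-residue fixed modification masses
#'   (Da); see [default_fixed_mods()].
#' @return Mass in Da.
#' @examples
#' peptide_mass("GK")                    # 203.12699
#' peptide_mass("GK", "heavy")           # 211.14119 (+8.014199 for K)
#' @export
peptide_mass <- function(sequence, channel = "light",
                         fixed_mods = default_fixed_mods()) {
  if (is.character(channel)) channel <- silac_channel(channel)
  residues <- .check_sequence(sequence)
  sum(.residue_masses(residues, channel, fixed_mods)) + WATER_MONO
}

#' y-ion fragment m/z
#'
#' m/z of the C-terminal fragment retaining `ordinal` residues (the y series):
#' (residue-mass sum + water + charge * proton) / charge. The heavy label
#' shift is included whenever the fragment contains a labeled K or R, which
#' for tryptic peptides is every y ion.
#'
#' @param sequence Peptide sequence.
#' @param ordinal y-ion index, `1 <= ordinal < nchar(sequence)`.
#' @param fragment_charge Positive integer charge.
#' @param channel `"light"`, `"heavy"`, or a [silac_channel()] list.
#' @param series Ion series; only `"y"` is supported.
#' @inheritParams peptide_mass
#' @return m/z in Th.
#' @examples
#' fragment_mz("GK", 1)            # y1 of GK, 147.11280
#' @export
fragment_mz <- function(sequence, ordinal, fragment_charge = 1L,
                        channel = "light", series = "y",
                        fixed_mods = default_fixed_mods()) {
  if (!identical(series, "y")) {
    stop("only the y ion series is supported", call. = FALSE)
  }
  if (is.character(channel)) channel <- silac_channel(channel)
  residues <- .check_sequence(sequence)
  n <- length(residues)
  if (!(is.numeric(ordinal) && length(ordinal) == 1L && ordinal >= 1 &&
        ordinal < n && ordinal == round(ordinal))) {
    stop(sprintf("y-ion ordinal must be an integer in [1, %d) for '%s'",
                 n, sequence), call. = FALSE)
  }
  if (!(is.numeric(fragment_charge) && fragment_charge >= 1)) {
    stop("fragment_charge must be a positive integer", call. = FALSE)
  }
  frag <- residues[(n - ordinal + 1L):n]
  neutral <- sum(.residue_masses(frag, channel, fixed_mods)) + WATER_MONO
  (neutral + fragment_charge * PROTON_MASS) / fragment_charge
}

#' Precursor m/z of a peptide
#'
#' @inheritParams peptide_mass
#' @param precursor_charge Positive integer charge.
#' @export
precursor_mz <- function(sequence, precursor_charge = 2L, channel = "light",
                         fixed_mods = default_fixed_mods()) {
  (peptide_mass(sequence, channel, fixed_mods) +
     precursor_charge * PROTON_MASS) / precursor_charge
}

#' Symmetric ppm mass-accuracy window
#'
#' The extraction window used for fragment-ion matching: the interval
#' `mz_center * (1 +/- tolerance_ppm * 1e-6)`.
#'
#' @param mz_center Positive m/z.
#' @param tolerance_ppm Non-negative tolerance in parts per million
#'   (default 20, the gate imposed during peptide identification).
#' @return Numeric vector `c(low, high)`.
#' @examples
#' ppm_window(500, 20)   # c(499.99, 500.01)
#' @export
ppm_window <- function(mz_center, tolerance_ppm = 20) {
  if (!is.numeric(mz_center) || length(mz_center) != 1L || mz_center <= 0) {
    stop("mz_center must be a positive number", call. = FALSE)
  }
  if (!is.numeric(tolerance_ppm) || tolerance_ppm < 0) {
    stop("tolerance_ppm must be non-negative", call. = FALSE)
  }
  half <- mz_center * tolerance_ppm * 1e-6
  c(low = mz_center - half, high = mz_center + half)
}
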