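# XIC quantification core: peak detection on the summed transition trace,
# shared-bounds trapezoidal integration, library dot-product (dotp) scoring,
# co-elution checking, and heavy/light ratio computation per peptide.

#' Quantification parameters
#'
#' @param dotp_min Minimum spectral-library dot product required in both
#'   channels (default 0.7).
#' @param rt_tolerance Maximum pairwise apex RT difference (seconds) allowed
#'   across all transitions of both channels (inclusive; default 5 s, one
#'   peak sigma under the default chromatographic conditions).
#' @param boundary_fraction Peak boundaries are set where the summed trace
#'   first falls to this fraction of the apex height (default 0.05).
#' @param max_width_sigmas Boundaries are capped at this many estimated peak
#'   sigmas from the apex (default 4).
#' @param min_points Minimum number of time points required per trace.
#' @param coelution_min_share Transitions contributing less than this
#'   fraction of their channel's largest transition area are too weak to
#'   carry RT information and are excluded from the co-elution test.
#' @return List of class `quant_params`.
#' @export
quant_params <- function(dotp_min = 0.7, rt_tolerance = 5,
                         boundary_fraction = 0.05, max_width_sigmas = 4,
                         min_points = 5, coelution_min_share = 0.05) {
  stopifnot(dotp_min >= 0, dotp_min <= 1, rt_tolerance >= 0,
            boundary_fraction > 0, boundary_fraction < 1,
            max_width_sigmas > 0, min_points >= 3,
            coelution_min_share >= 0, coelution_min_share < 1)
  structure(as.list(environment()), class = "quant_params")
}

#' Detect the elution peak of a summed transition trace
#'
#' The apex is the maximum of the baseline-subtracted summed-across-
#' transitions trace (baseline = median of the trace, valid because the
#' peak occupies a small fraction of the scheduled window). Boundaries are
#' placed where the trace first falls to `boundary_fraction` of the apex
#' height or reaches a local minimum, whichever comes first, and are capped
#' at `max_width_sigmas` estimated sigmas from the apex (sigma estimated
#' from the full width at half maximum).
#'
#' @param times Strictly increasing retention times (seconds).
#' @param summed Summed intensity across transitions, same length.
#' @param params A [quant_params()].
#' @return List with `apex_rt`, `left_rt`, `right_rt`, `apex_height`
#'   (baseline-subtracted), `baseline`, `sigma_est`; or `NULL` when the
#'   trace carries no signal (flat or all-zero).
#' @export
detect_peak <- function(times, summed, params = quant_params()) {
  stopifnot(length(times) == length(summed))
  if (length(times) < params$min_points) {
    stop("need at least ", params$min_points, " time points", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("retention times must be strictly increasing", call. = FALSE)
  }
  baseline <- stats::median(summed)
  y <- summed - baseline
  apex_idx <- which.max(y)
  apex_height <- y[apex_idx]
  if (!is.finite(apex_height) || apex_height <= 0) return(NULL)

  # sigma from full width at half maximum: contiguous run around the apex
  half <- apex_height / 2
  left_hm <- apex_idx
  while (left_hm > 1 && y[left_hm - 1L] >= half) left_hm <- left_hm - 1L
  right_hm <- apex_idx
  while (right_hm < length(y) && y[right_hm + 1L] >= half)
    right_hm <- right_hm + 1L
  fwhm <- times[right_hm] - times[left_hm]
  dt <- stats::median(diff(times))
  sigma_est <- max(fwhm / (2 * sqrt(2 * log(2))), dt / 2)

  thresh <- params$boundary_fraction * apex_height
  cap <- params$max_width_sigmas * sigma_est

  walk <- function(step) {
    i <- apex_idx
    repeat {
      nxt <- i + step
      if (nxt < 1 || nxt > length(y)) return(i)
      if (abs(times[nxt] - times[apex_idx]) > cap) return(i)
      if (y[nxt] <= thresh) return(nxt)
      if (y[nxt] > y[i] && i != apex_idx) return(i)  # local minimum at i
      i <- nxt
    }
  }
  left_idx <- walk(-1L)
  right_idx <- walk(1L)
  list(apex_rt = times[apex_idx], left_rt = times[left_idx],
       right_rt = times[right_idx], apex_height = apex_height,
       baseline = baseline, sigma_est = sigma_est)
}

#' Trapezoidal integration of a transition trace over a peak window
#'
#' @param times Retention times (seconds).
#' @param intensities Intensities, same length.
#' @param left_rt,right_rt Integration bounds (seconds, inclusive).
#' @param baseline Constant baseline subtracted before integration
#'   (intensities are clamped at zero afterwards).
#' @return Non-negative area in intensity x seconds; 0 for an empty window.
#' @export
integrate_transition <- function(times, intensities, left_rt, right_rt,
                                 baseline = 0) {
  stopifnot(length(times) == length(intensities), left_rt <= right_rt)
  idx <- which(times >= left_rt & times <= right_rt)
  if (length(idx) < 2) return(0)
  t <- times[idx]
  y <- pmax(intensities[idx] - baseline, 0)
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

#' Spectral-library dot product (dotp)
#'
#' Cosine similarity between the observed per-transition areas and the
#' library's relative intensities, after unit normalization of both: 1 for
#' proportional vectors, 0 for orthogonal ones; scale-invariant in both
#' arguments. An all-zero observation scores 0.
#'
#' @param observed Non-negative observed per-transition areas (length >= 2).
#' @param library_intensities Library relative intensities, same length,
#'   not all zero.
#' @return dotp in \[0, 1\].
#' @export
compute_dotp <- function(observed, library_intensities) {
  stopifnot(length(observed) == length(library_intensities),
            length(observed) >= 2)
  if (all(library_intensities == 0)) {
    stop("library intensity vector must be non-zero", call. = FALSE)
  }
  if (all(observed == 0)) return(0)
  d <- sum(observed * library_intensities) /
    (sqrt(sum(observed^2)) * sqrt(sum(library_intensities^2)))
  min(max(d, 0), 1)
}

#' Co-elution check
#'
#' Pass if and only if the maximum pairwise apex RT difference across all
#' supplied transitions (typically both channels pooled) is at most the
#' tolerance (inclusive). Requires at least two detected apexes; `NA`
#' apexes are dropped.
#'
#' @param apex_rts Per-transition apex retention times (seconds).
#' @param tolerance Tolerance in seconds.
#' @return Logical.
#' @export
check_coelution <- function(apex_rts, tolerance) {
  rts <- apex_rts[!is.na(apex_rts)]
  if (length(rts) < 2) return(FALSE)
  (max(rts) - min(rts)) <= tolerance
}

# per-transition intensity matrix (time x fragment) for one channel
.channel_matrix <- function(chrom_channel, fragments) {
  present <- unique(chrom_channel$fragment)
  if (!setequal(present, fragments)) {
    stop("chromatogram transitions do not match the library entry (",
         paste(sort(present), collapse = ","), " vs ",
         paste(sort(fragments), collapse = ","), ")", call. = FALSE)
  }
  first <- chrom_channel[chrom_channel$fragment == fragments[1], ]
  times <- sort(first$rt_sec)
  mat <- sapply(fragments, function(fr) {
    tr <- chrom_channel[chrom_channel$fragment == fr, ]
    if (nrow(tr) != length(times)) {
      stop("transitions of one channel must share the time grid",
           call. = FALSE)
    }
    tr$intensity[order(tr$rt_sec)]
  })
  list(times = times, mat = matrix(mat, ncol = length(fragments),
                                   dimnames = list(NULL, fragments)))
}

.empty_channel <- function(k) {
  list(areas = rep(NA_real_, k), area_sum = NA_real_, dotp = NA_real_,
       apex_rt = NA_real_, centroids = rep(NA_real_, k))
}

#' Quantify one peptide from its light/heavy transition chromatograms
#'
#' Implements the shared-bounds SILAC quantification rule: the elution peak
#' is detected on the summed trace of each channel, the integration window
#' is taken from the channel with the larger (baseline-subtracted) apex and
#' applied to both channels, every transition is integrated over that
#' window above a per-trace baseline (median intensity outside the window),
#' per-channel dotp is computed from the integrated areas against the
#' library relative intensities, and the ratio is the heavy summed area
#' over the light summed area. A peptide passes the filters when both
#' channel dotps reach `dotp_min` and all informative transitions of both
#' channels co-elute within `rt_tolerance` (per-transition apex estimated
#' as the intensity-weighted RT centroid inside the window).
#'
#' @param chromatograms Long-form chromatogram rows for one peptide.
#' @param entry A [library_entries()] element for the same peptide.
#' @param params A [quant_params()].
#' @return List of class `peptide_quant` with per-channel areas, dotp and
#'   apex, the heavy/light `ratio`, `passed_filters` and `failure_reason`
#'   (`none`, `low_dotp`, `no_coelution` or `missing_channel`).
#' @export
quantify_peptide <- function(chromatograms, entry, params = quant_params()) {
  fragments <- entry$transitions$fragment
  lib_int <- entry$transitions$library_relative_intensity
  k <- length(fragments)

  channels <- list()
  peaks <- list()
  for (ch in c("light", "heavy")) {
    sub <- chromatograms[chromatograms$channel == ch, ]
    if (nrow(sub) == 0 || all(sub$intensity == 0)) {
      channels[[ch]] <- NULL
      next
    }
    cm <- .channel_matrix(sub, fragments)
    channels[[ch]] <- cm
    peaks[[ch]] <- detect_peak(cm$times, rowSums(cm$mat), params)
  }

  result <- list(peptide_sequence = entry$peptide_sequence,
                 protein_id = entry$protein_id,
                 kinase_class = entry$kinase_class,
                 light = .empty_channel(k), heavy = .empty_channel(k),
                 ratio = NA_real_, apex_rt = NA_real_,
                 passed_filters = FALSE, failure_reason = "missing_channel")
  class(result) <- "peptide_quant"
  if (is.null(channels$light) || is.null(channels$heavy) ||
      is.null(peaks$light) || is.null(peaks$heavy)) {
    return(result)
  }

  bounds_ch <- if (peaks$heavy$apex_height > peaks$light$apex_height)
    "heavy" else "light"
  pk <- peaks[[bounds_ch]]
  left <- pk$left_rt
  right <- pk$right_rt

  for (ch in c("light", "heavy")) {
    cm <- channels[[ch]]
    inside <- cm$times >= left & cm$times <= right
    areas <- numeric(k)
    centroids <- rep(NA_real_, k)
    for (j in seq_len(k)) {
      trace <- cm$mat[, j]
      outside <- trace[!inside]
      bl <- if (length(outside) >= 3) stats::median(outside) else min(trace)
      areas[j] <- integrate_transition(cm$times, trace, left, right, bl)
      w <- pmax(trace[inside] - bl, 0)
      if (sum(w) > 0) centroids[j] <- sum(cm$times[inside] * w) / sum(w)
    }
    result[[ch]] <- list(
      areas = areas, area_sum = sum(areas),
      dotp = compute_dotp(areas, lib_int),
      apex_rt = peaks[[ch]]$apex_rt, centroids = centroids
    )
  }

  result$apex_rt <- pk$apex_rt
  if (result$light$area_sum <= 0 || result$heavy$area_sum <= 0) {
    result$failure_reason <- "missing_channel"
    return(result)
  }
  result$ratio <- result$heavy$area_sum / result$light$area_sum

  dotp_ok <- result$light$dotp >= params$dotp_min &&
    result$heavy$dotp >= params$dotp_min
  # pool informative transitions of both channels for the co-elution test
  rts <- c()
  for (ch in c("light", "heavy")) {
    a <- result[[ch]]$areas
    keep <- a >= params$coelution_min_share * max(a)
    rts <- c(rts, result[[ch]]$centroids[keep])
  }
  coelute <- check_coelution(rts, params$rt_tolerance)

  if (!dotp_ok) {
    result$failure_reason <- "low_dotp"
  } else if (!coelute) {
    result$failure_reason <- "no_coelution"
  } else {
    result$failure_reason <- "none"
    result$passed_filters <- TRUE
  }
  result
}

#' Quantify every library peptide found in a run's chromatograms
#'
#' @param chromatograms Long-form chromatogram data frame for one run.
#' @param library A `prm_library`.
#' @param params A [quant_params()].
#' @return Data frame with one row per peptide: `peptide_sequence`,
#'   `protein_id`, `kinase_class`, `area_light`, `area_heavy`, `dotp_light`,
#'   `dotp_heavy`, `apex_rt`, `ratio`, `passed_filters`, `failure_reason`.
#' @export
quantify_run <- function(chromatograms, library, params = quant_params()) {
  entries <- library_entries(library)
  present <- unique(chromatograms$peptide_sequence)
  chrom_split <- split(chromatograms, chromatograms$peptide_sequence)
  rows <- list()
  for (entry in entries) {
    pep <- entry$peptide_sequence
    if (!pep %in% present) next
    q <- quantify_peptide(chrom_split[[pep]], entry, params)
    rows[[length(rows) + 1L]] <- data.frame(
      peptide_sequence = pep,
      protein_id = q$protein_id,
      kinase_class = q$kinase_class,
      area_light = q$light$area_sum,
      area_heavy = q$heavy$area_sum,
      dotp_light = q$light$dotp,
      dotp_heavy = q$heavy$dotp,
      apex_rt = q$apex_rt,
      ratio = q$ratio,
      passed_filters = q$passed_filters,
      failure_reason = q$failure_reason,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
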