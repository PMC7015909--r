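# Skyline-style PRM spectral library: one row per transition, entry-level
# fields repeated. Tab-separated on disk; validated data.frame in memory.

KINASE_CLASSES <- c("protein", "lipid", "nucleotide", "carbohydrate", "other")

LIBRARY_COLUMNS <- c(
  "protein_id", "kinase_class", "peptide_sequence", "precursor_charge",
  "missed_cleavages", "fragment", "fragment_charge",
  "library_relative_intensity"
)

#' Construct a validated PRM spectral library
#'
#' @param df Data frame with one row per transition and the columns
#'   `protein_id`, `kinase_class`, `peptide_sequence`, `precursor_charge`,
#'   `missed_cleavages`, `fragment` (e.g. `"y7"`), `fragment_charge`,
#'   `library_relative_intensity`.
#' @return The data frame with class `prm_library`, validated against the
#'   library invariants (4-6 y transitions per precursor, at most 4 peptides
#'   per protein, at most one missed cleavage, tryptic C-terminus, unique
#'   transitions).
#' @export
prm_library <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  validate_library(df)
  class(df) <- c("prm_library", "data.frame")
  df
}

.count_internal_kr <- function(sequence) {
  body <- substr(sequence, 1L, nchar(sequence) - 1L)
  # KP/RP are not tryptic cleavage sites
  sites <- gregexpr("[KR](?!P)", body, perl = TRUE)[[1]]
  if (sites[1] == -1L) 0L else length(sites)
}

#' Validate a spectral-library data frame
#'
#' Checks every library invariant and stops with a message naming the first
#' offending row. Called by [prm_library()] and [read_library()].
#'
#' @param df Library data frame (one row per transition).
#' @return Invisibly `TRUE`.
#' @export
validate_library <- function(df) {
  missing_cols <- setdiff(LIBRARY_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("library is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("library has no transitions", call. = FALSE)
  fail <- function(rows, msg) {
    stop(sprintf("library row %s: %s", rows[1], msg), call. = FALSE)
  }

  bad_class <- which(!df$kinase_class %in% KINASE_CLASSES)
  if (length(bad_class)) {
    fail(bad_class, sprintf("unknown kinase_class '%s'",
                            df$kinase_class[bad_class[1]]))
  }
  bad_frag <- which(!grepl("^y[0-9]+$", df$fragment))
  if (length(bad_frag)) {
    fail(bad_frag, sprintf("fragment '%s' is not a y ion label",
                           df$fragment[bad_frag[1]]))
  }
  bad_int <- which(!is.finite(df$library_relative_intensity) |
                     df$library_relative_intensity < 0)
  if (length(bad_int)) fail(bad_int, "library_relative_intensity must be finite and >= 0")
  bad_z <- which(df$precursor_charge < 1 | df$fragment_charge < 1)
  if (length(bad_z)) fail(bad_z, "charges must be positive integers")
  bad_mc <- which(!df$missed_cleavages %in% c(0L, 1L))
  if (length(bad_mc)) fail(bad_mc, "missed_cleavages must be 0 or 1")

  for (i in seq_len(nrow(df))) {
    seq_i <- df$peptide_sequence[i]
    residues <- strsplit(seq_i, "")[[1]]
    if (length(residues) == 0 || any(!residues %in% names(AA_MONO))) {
      fail(i, sprintf("sequence '%s' contains non-canonical residues", seq_i))
    }
    if (!substring(seq_i, nchar(seq_i)) %in% c("K", "R")) {
      fail(i, sprintf("sequence '%s' is not tryptic (must end in K or R)", seq_i))
    }
    ordinal <- as.integer(sub("^y", "", df$fragment[i]))
    if (ordinal < 1 || ordinal >= nchar(seq_i)) {
      fail(i, sprintf("y%d out of range for sequence '%s'", ordinal, seq_i))
    }
  }

  key <- paste(df$peptide_sequence, df$precursor_charge)
  for (k in unique(key)) {
    rows <- which(key == k)
    n_tr <- length(rows)
    if (n_tr < 4 || n_tr > 6) {
      fail(rows, sprintf("precursor %s has %d transitions (4-6 required)",
                         k, n_tr))
    }
    tkey <- paste(df$fragment[rows], df$fragment_charge[rows])
    if (anyDuplicated(tkey)) {
      fail(rows, sprintf("precursor %s has duplicate transitions", k))
    }
    if (length(unique(df$protein_id[rows])) != 1 ||
        length(unique(df$missed_cleavages[rows])) != 1 ||
        length(unique(df$kinase_class[rows])) != 1) {
      fail(rows, sprintf("precursor %s has inconsistent entry-level fields", k))
    }
    mc_obs <- .count_internal_kr(df$peptide_sequence[rows[1]])
    if (mc_obs > 1) {
      fail(rows, sprintf("sequence '%s' has %d missed cleavage sites (max 1)",
                         df$peptide_sequence[rows[1]], mc_obs))
    }
  }

  per_protein <- tapply(df$peptide_sequence, df$protein_id,
                        function(x) length(unique(x)))
  if (any(per_protein > 4)) {
    bad <- names(per_protein)[which(per_protein > 4)[1]]
    stop(sprintf("protein %s has %d peptides (max 4 per protein)",
                 bad, per_protein[[bad]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write a spectral library TSV
#'
#' One row per transition, tab-separated with a header; entry-level fields
#' are repeated on each transition row. `write_library` followed by
#' `read_library` is the identity on the canonical (row-sorted) form.
#'
#' @param path File path.
#' @return `read_library` returns a validated `prm_library`.
#' @export
read_library <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(
                            protein_id = "character",
                            kinase_class = "character",
                            peptide_sequence = "character",
                            precursor_charge = "integer",
                            missed_cleavages = "integer",
                            fragment = "character",
                            fragment_charge = "integer",
                            library_relative_intensity = "numeric"
                          ))
  prm_library(df)
}

#' @rdname read_library
#' @param library A `prm_library`.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "prm_library"))
  utils::write.table(library[, LIBRARY_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-precursor view of a library
#'
#' Splits a transition-level library into a list of entries, one per
#' (peptide, precursor charge), each carrying its transition table.
#'
#' @param library A `prm_library`.
#' @return Named list of lists with `peptide_sequence`, `protein_id`,
#'   `kinase_class`, `precursor_charge`, `missed_cleavages`, and a
#'   `transitions` data frame (`fragment`, `ordinal`, `fragment_charge`,
#'   `library_relative_intensity`).
#' @export
library_entries <- function(library) {
  stopifnot(inherits(library, "prm_library"))
  key <- paste(library$peptide_sequence, library$precursor_charge, sep = "/")
  lapply(split(seq_len(nrow(library)), key)[unique(key)], function(rows) {
    tr <- library[rows, c("fragment", "fragment_charge",
                          "library_relative_intensity")]
    tr$ordinal <- as.integer(sub("^y", "", tr$fragment))
    rownames(tr) <- NULL
    list(
      peptide_sequence = library$peptide_sequence[rows[1]],
      protein_id = library$protein_id[rows[1]],
      kinase_class = library$kinase_class[rows[1]],
      precursor_charge = library$precursor_charge[rows[1]],
      missed_cleavages = library$missed_cleavages[rows[1]],
      transitions = tr
    )
  })
}
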