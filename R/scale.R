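#' Construct a residue hydrophobicity scale
#'
#' A `residue_scale` maps each of the 20 canonical one-letter amino-acid codes
#' to a signed, dimensionless hydrophobicity value. The sign convention used
#' throughout the package is that hydrophobic residues carry positive values
#' while polar and charged residues carry negative values, so that summing
#' values over a sequence window rewards hydrophobic stretches and penalizes
#' polar ones.
#'
#' @param values named numeric vector; names are the 20 canonical one-letter
#'   codes, each present exactly once.
#' @param name short identifier for the scale.
#' @param reference free-text citation for the scale's provenance.
#' @return an object of class `residue_scale`.
#' @export
residue_scale <- function(values, name = "custom", reference = "") {
  if (is.null(names(values))) {
    stop("`values` must be a named numeric vector", call. = FALSE)
  }
  letters_in <- names(values)
  dup <- unique(letters_in[duplicated(letters_in)])
  if (length(dup)) {
    stop("duplicate residue letter(s) in scale: ", paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  missing <- setdiff(AA_CANONICAL, letters_in)
  if (length(missing)) {
    stop("incomplete scale: missing canonical residue(s) ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(letters_in, AA_CANONICAL)
  if (length(extra)) {
    stop("non-canonical letter(s) in scale: ", paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(!is.finite(values))) {
    bad <- letters_in[!is.finite(values)]
    stop("non-finite scale value(s) for: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      name = name,
      reference = reference,
      values = values[AA_CANONICAL]
    ),
    class = "residue_scale"
  )
}

#' @export
print.residue_scale <- function(x, ...) {
  cat("residue_scale:", x$name, "\n")
  if (nzchar(x$reference)) cat("  reference:", x$reference, "\n")
  cat("  range: [", min(x$values), ",", max(x$values), "]\n")
  print(round(x$values, 3))
  invisible(x)
}

#' Load a hydrophobicity scale from a plain-text table
#'
#' The file format is two whitespace-separated columns, `LETTER VALUE`, one
#' record per canonical residue; lines starting with `#` are comments.
#'
#' @param path path to the scale file.
#' @inheritParams residue_scale
#' @return a validated [residue_scale()].
#' @export
load_scale <- function(path, name = basename(path), reference = "") {
  if (!file.exists(path)) stop("scale file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("incomplete scale: empty file ", path, call. = FALSE)
  fields <- strsplit(lines, "[[:space:]]+")
  bad_shape <- vapply(fields, length, 1L) != 2L
  if (any(bad_shape)) {
    stop("malformed scale row(s): ",
      paste(lines[bad_shape], collapse = "; "),
      call. = FALSE
    )
  }
  letter <- toupper(vapply(fields, `[[`, "", 1L))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(value)) {
    bad <- which(is.na(value))
    stop("unparseable scale value in row(s): ",
      paste(lines[bad], collapse = "; "),
      call. = FALSE
    )
  }
  names(value) <- letter
  residue_scale(value, name = name, reference = reference)
}

#' The packaged hydrophobicity scale
#'
#' Signed fragmental-constant hydrophobicity values attributed to Abraham and
#' Leo (1987), packaged as a plain-text resource. The transcription conforms
#' to the sign convention required by the cap-scoring method (see
#' [validate_sign_convention()]); the methods vignette discusses the
#' provenance caveats of the exact numeric variant.
#'
#' @return a [residue_scale()].
#' @export
default_scale <- function() {
  path <- system.file("extdata", "abraham_leo_scale.txt",
    package = "acylscreen", mustWork = TRUE
  )
  load_scale(path,
    name = "abraham_leo",
    reference = "Abraham & Leo (1987) fragmental constants, ProtScale variant"
  )
}

#' Check the sign convention of a hydrophobicity scale
#'
#' The cap-scoring method assumes hydrophobic residues score positive and
#' charged residues negative. This diagnostic checks that the six strongly
#' hydrophobic residues (L, I, V, F, W, M) are strictly positive and the four
#' charged residues (D, E, K, R) strictly negative. Histidine, whose
#' protonation state is ambiguous at assay pH, is deliberately unconstrained.
#' A value of exactly zero fails either test.
#'
#' @param scale a [residue_scale()].
#' @return list with elements `pass` (logical) and `offending` (character
#'   vector of residues violating the convention, empty when `pass`).
#' @export
validate_sign_convention <- function(scale) {
  stopifnot(inherits(scale, "residue_scale"))
  v <- scale$values
  bad_pos <- AA_HYDROPHOBIC[v[AA_HYDROPHOBIC] <= 0]
  bad_neg <- AA_CHARGED[v[AA_CHARGED] >= 0]
  offending <- sort(c(bad_pos, bad_neg))
  list(pass = length(offending) == 0L, offending = offending)
}

#' Calibrate a scale against reference sequences with known scores
#'
#' Scores each reference sequence over the N-terminal window and compares the
#' result with its expected score. Used to confirm that a particular numeric
#' variant of a hydrophobicity scale (and a window/Met-stripping convention)
#' reproduces a set of trusted reference scores before the scale is used for
#' screening.
#'
#' @param scale a [residue_scale()].
#' @param references data frame with columns `id`, `sequence`, `expected`
#'   (the trusted score for each sequence).
#' @param window cap window length in residues.
#' @param tolerance maximum absolute deviation tolerated per reference;
#'   default 0.1, the printed precision of typical reference scores.
#' @param strip_initiator_met drop a leading methionine before extracting the
#'   window (see [extract_cap()]).
#' @return an object of class `calibration_report`: a data frame with one row
#'   per reference (`id`, `expected`, `computed`, `deviation`) plus
#'   attributes `max_deviation`, `tolerance` and `pass`.
#' @export
calibrate <- function(scale, references, window = 45L, tolerance = 0.1,
                      strip_initiator_met = FALSE) {
  stopifnot(inherits(scale, "residue_scale"))
  req <- c("id", "sequence", "expected")
  if (!is.data.frame(references) || !all(req %in% names(references))) {
    stop("`references` must be a data frame with columns id, sequence, expected",
      call. = FALSE
    )
  }
  computed <- vapply(seq_len(nrow(references)), function(i) {
    seq_i <- protein_sequence(references$id[i], references$sequence[i])
    score_sequence(seq_i, scale,
      window = window,
      unknown_policy = "error",
      strip_initiator_met = strip_initiator_met
    )$H
  }, numeric(1))
  report <- data.frame(
    id = references$id,
    expected = references$expected,
    computed = computed,
    deviation = abs(computed - references$expected),
    stringsAsFactors = FALSE
  )
  structure(report,
    class = c("calibration_report", "data.frame"),
    max_deviation = max(report$deviation),
    tolerance = tolerance,
    pass = max(report$deviation) <= tolerance
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(
    "calibration_report: max deviation",
    format(attr(x, "max_deviation"), digits = 4),
    if (attr(x, "pass")) "(PASS" else "(FAIL",
    "at tolerance", attr(x, "tolerance"), ")\n"
  )
  print.data.frame(x, ...)
  invisible(x)
}
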