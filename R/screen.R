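#' Configuration for a library screen
#'
#' Defaults follow the screening workflow for bHSL homologue libraries:
#' sequences are kept if their full length lies in `[length_min, length_max]`
#' (default 250-400 residues, the typical catalytic-domain-plus-cap size of
#' the family), exact duplicates are removed, caps are scored over a
#' 45-residue window, and candidates are selected with scores strictly above
#' the library mean and at or below the upper quartile. Very high scores are
#' deliberately excluded: strongly hydrophobic caps predict aggregation-prone,
#' unstable proteins.
#'
#' @param length_min,length_max inclusive full-sequence length bounds.
#' @param dedup_mode `"exact-sequence"` keys redundancy on the full residue
#'   string; `"exact-cap"` keys on the cap window only.
#' @param window cap window length.
#' @param unknown_policy passed to [score_batch()].
#' @param strip_initiator_met passed to [score_batch()].
#' @return an object of class `screen_config`.
#' @export
screen_config <- function(length_min = 250L, length_max = 400L,
                          dedup_mode = c("exact-sequence", "exact-cap"),
                          window = 45L,
                          unknown_policy = c("zero", "error"),
                          strip_initiator_met = FALSE) {
  dedup_mode <- match.arg(dedup_mode)
  unknown_policy <- match.arg(unknown_policy)
  if (length_min > length_max) {
    stop("length_min must be <= length_max", call. = FALSE)
  }
  if (window > length_min) {
    stop("cap window (", window, ") exceeds length_min (", length_min, ")",
      call. = FALSE
    )
  }
  structure(
    list(
      length_min = as.integer(length_min),
      length_max = as.integer(length_max),
      dedup_mode = dedup_mode,
      window = as.integer(window),
      unknown_policy = unknown_policy,
      strip_initiator_met = strip_initiator_met
    ),
    class = "screen_config"
  )
}

#' Filter sequences by full length
#'
#' @param seqs list of [protein_sequence()] objects.
#' @param length_min,length_max inclusive bounds.
#' @return list with `kept` (surviving sequences), `n_dropped`, and
#'   `dropped_ids`.
#' @export
filter_length <- function(seqs, length_min, length_max = Inf) {
  lens <- vapply(seqs, function(s) nchar(s$residues), 1L)
  keep <- lens >= length_min & lens <= length_max
  list(
    kept = seqs[keep],
    n_dropped = sum(!keep),
    dropped_ids = vapply(seqs[!keep], function(s) s$id, "")
  )
}

#' Remove redundant sequences
#'
#' Keeps the first occurrence of each distinct key (full residue string, or
#' the cap window under `"exact-cap"`) and records what was merged.
#'
#' @param seqs list of [protein_sequence()] objects.
#' @param mode `"exact-sequence"` or `"exact-cap"`.
#' @param window cap window length, used only for `"exact-cap"`.
#' @return list with `kept`, `n_dropped`, and `duplicate_map`: a data frame
#'   mapping each removed id to the id it duplicated.
#' @export
deduplicate <- function(seqs, mode = c("exact-sequence", "exact-cap"),
                        window = 45L) {
  mode <- match.arg(mode)
  keys <- vapply(seqs, function(s) {
    if (mode == "exact-sequence") s$residues else substring(s$residues, 1L, window)
  }, "")
  first <- !duplicated(keys)
  kept_ids <- vapply(seqs[first], function(s) s$id, "")
  names(kept_ids) <- keys[first]
  dup_idx <- which(!first)
  duplicate_map <- data.frame(
    removed_id = vapply(seqs[dup_idx], function(s) s$id, ""),
    kept_id = unname(kept_ids[keys[dup_idx]]),
    stringsAsFactors = FALSE
  )
  list(kept = seqs[first], n_dropped = length(dup_idx), duplicate_map = duplicate_map)
}

#' Summarize a score distribution
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), the package's fixed convention; the candidate
#' selection rule uses the same convention.
#'
#' @param scores numeric vector of hydrophobicity scores, length >= 1.
#' @param breaks histogram bin specification passed to [graphics::hist()]
#'   semantics via [base::cut()]; default "Sturges"-style count from
#'   `grDevices::nclass.Sturges`.
#' @return an object of class `score_distribution`: list with `n`, `mean`,
#'   `min`, `max`, `q1`, `median`, `q3`, and `histogram` (list of `breaks`,
#'   `counts`).
#' @export
summarize_distribution <- function(scores, breaks = NULL) {
  if (!length(scores)) stop("cannot summarize an empty score list", call. = FALSE)
  if (any(!is.finite(scores))) stop("non-finite score(s)", call. = FALSE)
  qs <- stats::quantile(scores, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (is.null(breaks)) breaks <- grDevices::nclass.Sturges(scores)
  h <- graphics::hist(scores, breaks = breaks, plot = FALSE)
  structure(
    list(
      n = length(scores),
      mean = mean(scores),
      min = min(scores),
      max = max(scores),
      q1 = qs[1], median = qs[2], q3 = qs[3],
      histogram = list(breaks = h$breaks, counts = h$counts)
    ),
    class = "score_distribution"
  )
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf(
    "score_distribution: n=%d mean=%.3f range=[%.3f, %.3f] Q1=%.3f Q2=%.3f Q3=%.3f\n",
    x$n, x$mean, x$min, x$max, x$q1, x$median, x$q3
  ))
  invisible(x)
}

#' Select acyltransferase candidates from a scored library
#'
#' The selection rule encodes the screening heuristic that good promiscuous
#' acyltransferases score above the library average but at or below the upper
#' quartile: the lower bound is open (a score equal to the mean is excluded),
#' the upper bound closed (ties at Q3 are included).
#'
#' @param scored data frame with at least columns `id` and `H`.
#' @param distribution a [summarize_distribution()] result computed from
#'   exactly these scores.
#' @return the subset of `scored` rows satisfying `mean < H <= Q3`.
#' @export
select_candidates <- function(scored, distribution) {
  stopifnot(inherits(distribution, "score_distribution"))
  if (nrow(scored) != distribution$n) {
    stop("distribution was not computed from these scores (n mismatch)",
      call. = FALSE
    )
  }
  keep <- scored$H > distribution$mean & scored$H <= distribution$q3
  scored[keep, , drop = FALSE]
}

#' Run the full library screen
#'
#' End-to-end pipeline: length filter, deduplication, cap scoring,
#' distribution summary, candidate selection. Per-stage counts are conserved
#' (`n_input = n_kept + n_dropped` at every stage) and returned for
#' provenance.
#'
#' @param seqs list of [protein_sequence()] objects, or a path to a FASTA
#'   file.
#' @param scale a [residue_scale()].
#' @param config a [screen_config()].
#' @return an object of class `screen_result`: list with `scores` (all scored
#'   records), `distribution`, `selected`, `counts`, `config`, `input_md5`
#'   (when the input was a file) and `diagnostics`.
#' @export
run_screen <- function(seqs, scale, config = screen_config()) {
  stopifnot(inherits(scale, "residue_scale"), inherits(config, "screen_config"))
  md5 <- NA_character_
  if (is.character(seqs) && length(seqs) == 1L) {
    md5 <- input_md5(seqs)
    seqs <- read_protein_fasta(seqs)
  }
  n_input <- length(seqs)
  fl <- filter_length(seqs, config$length_min, config$length_max)
  dd <- deduplicate(fl$kept, mode = config$dedup_mode, window = config$window)
  scores <- score_batch(dd$kept, scale,
    window = config$window,
    unknown_policy = config$unknown_policy,
    strip_initiator_met = config$strip_initiator_met
  )
  diagnostics <- attr(scores, "diagnostics")
  counts <- list(
    n_input = n_input,
    n_length_dropped = fl$n_dropped,
    n_duplicates_removed = dd$n_dropped,
    n_unscoreable = nrow(diagnostics),
    n_scored = nrow(scores)
  )
  if (nrow(scores) == 0L) {
    return(structure(
      list(
        scores = scores, distribution = NULL,
        selected = scores[0, , drop = FALSE],
        counts = c(counts, list(n_selected = 0L)),
        config = config, input_md5 = md5, diagnostics = diagnostics
      ),
      class = "screen_result"
    ))
  }
  distribution <- summarize_distribution(scores$H)
  selected <- select_candidates(scores, distribution)
  structure(
    list(
      scores = scores,
      distribution = distribution,
      selected = selected,
      counts = c(counts, list(n_selected = nrow(selected))),
      config = config,
      input_md5 = md5,
      diagnostics = diagnostics
    ),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result\n")
  cat(
    "  input:", x$counts$n_input,
    "| length-dropped:", x$counts$n_length_dropped,
    "| duplicates:", x$counts$n_duplicates_removed,
    "| unscoreable:", x$counts$n_unscoreable,
    "| scored:", x$counts$n_scored,
    "| selected:", x$counts$n_selected, "\n"
  )
  if (!is.null(x$distribution)) print(x$distribution)
  invisible(x)
}

#' Write screen outputs to a directory
#'
#' Writes `screen_scores.tsv` (all scored records), `screen_selected.tsv`
#' (candidates) and `screen_summary.json` (distribution, config echo, stage
#' counts, input hash).
#'
#' @param result a [run_screen()] result.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_screen_result <- function(result, dir) {
  stopifnot(inherits(result, "screen_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(
    input_md5 = result$input_md5,
    window = result$config$window,
    length_min = result$config$length_min,
    length_max = result$config$length_max,
    dedup_mode = result$config$dedup_mode
  )
  write_scores_tsv(result$scores, file.path(dir, "screen_scores.tsv"), prov)
  write_scores_tsv(result$selected, file.path(dir, "screen_selected.tsv"), prov)
  jsonlite::write_json(
    list(
      tool = pkg_version_string(),
      config = unclass(result$config),
      input_md5 = result$input_md5,
      counts = result$counts,
      distribution = if (is.null(result$distribution)) NULL else unclass(result$distribution)
    ),
    file.path(dir, "screen_summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}
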