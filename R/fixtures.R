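#' Generate a protein sequence with a prescribed cap score
#'
#' Builds a random sequence whose N-terminal cap scores within `tol` of a
#' target hydrophobicity H under the given scale, by seeded coordinate
#' descent: cap positions are revisited in random order and each is replaced
#' by the residue that brings the running score closest to the target. The
#' tail beyond the window is uniform random over the canonical alphabet.
#'
#' @param target_H target cap score (dimensionless).
#' @param scale a [residue_scale()].
#' @param tol acceptable absolute deviation from `target_H` (default 0.1).
#' @param window cap window length.
#' @param total_length full sequence length (>= `window`).
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @param id record identifier.
#' @return a [protein_sequence()] whose cap score is within `tol` of
#'   `target_H`.
#' @export
gen_sequence_with_score <- function(target_H, scale = default_scale(),
                                    tol = 0.1, window = 45L,
                                    total_length = 300L, seed = 1L,
                                    id = sprintf("synthH%.1f", target_H)) {
  stopifnot(inherits(scale, "residue_scale"), total_length >= window)
  v <- scale$values
  lo <- window * min(v)
  hi <- window * max(v)
  if (target_H < lo - tol || target_H > hi + tol) {
    stop(sprintf(
      "unreachable target score %.2f: achievable range is [%.2f, %.2f] for window %d",
      target_H, lo, hi, window
    ), call. = FALSE)
  }
  with_seed(seed, {
    cap <- sample(names(v), window, replace = TRUE)
    H <- sum(v[cap])
    for (sweep in 1:50) {
      if (abs(H - target_H) <= tol) break
      for (pos in sample.int(window)) {
        need <- target_H - (H - v[[cap[pos]]])
        best <- names(v)[which.min(abs(v - need))]
        H <- H - v[[cap[pos]]] + v[[best]]
        cap[pos] <- best
        if (abs(H - target_H) <= tol) break
      }
    }
    if (abs(H - target_H) > tol) {
      stop(sprintf(
        "could not reach target score %.2f within tol %.3f (best %.3f)",
        target_H, tol, H
      ), call. = FALSE)
    }
    tail_len <- total_length - window
    tail <- if (tail_len > 0) {
      paste(sample(AA_CANONICAL, tail_len, replace = TRUE), collapse = "")
    } else {
      ""
    }
    protein_sequence(id, paste0(paste(cap, collapse = ""), tail),
      description = "synthetic sequence with planted cap score"
    )
  })
}

#' Generate a synthetic bHSL-like sequence library
#'
#' Emulates a homologue library for screening tests: per-sequence cap-score
#' targets are drawn from a normal distribution (defaulting to the mean
#' observed in large bHSL libraries, 13.65), lengths are uniform over
#' `length_range`, and known fractions of exact duplicates and too-short
#' records are planted so that filtering and deduplication can be verified
#' against ground truth.
#'
#' @param n total number of records.
#' @param score_mean,score_sd parameters of the target score distribution.
#' @param length_range full-length range (residues) for normal records.
#' @param duplicate_fraction fraction of `n` that are exact copies of earlier
#'   records (ids prefixed `dup`).
#' @param short_fraction fraction of `n` that are too short for the default
#'   length filter (ids prefixed `short`).
#' @param short_length length of planted short records.
#' @param scale a [residue_scale()].
#' @param window cap window length.
#' @param tol per-sequence score tolerance passed to
#'   [gen_sequence_with_score()].
#' @param seed RNG seed.
#' @return list of [protein_sequence()] objects with attribute `truth`:
#'   list of `targets` (per-base-record target scores), `duplicate_ids`,
#'   `short_ids`.
#' @export
gen_library <- function(n, score_mean = 13.65, score_sd = 8,
                        length_range = c(260L, 380L),
                        duplicate_fraction = 0, short_fraction = 0,
                        short_length = 100L,
                        scale = default_scale(), window = 45L,
                        tol = 0.25, seed = 42L) {
  stopifnot(n >= 1)
  n_dup <- round(duplicate_fraction * n)
  n_short <- round(short_fraction * n)
  n_base <- n - n_dup - n_short
  if (n_base < 1) stop("duplicate/short fractions leave no base records", call. = FALSE)
  v <- scale$values
  feasible <- c(window * min(v) + tol, window * max(v) - tol)
  with_seed(seed, {
    targets <- pmin(pmax(stats::rnorm(n_base, score_mean, score_sd), feasible[1]), feasible[2])
    lens <- sample(seq(length_range[1], length_range[2]), n_base, replace = TRUE)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_base + n_short)
    base <- lapply(seq_len(n_base), function(i) {
      gen_sequence_with_score(targets[i],
        scale = scale, tol = tol, window = window,
        total_length = lens[i], seed = sub_seeds[i],
        id = sprintf("lib%04d", i)
      )
    })
    shorts <- lapply(seq_len(n_short), function(i) {
      s <- gen_sequence_with_score(0,
        scale = scale, tol = window * max(abs(v)), # any score: unconstrained
        window = min(window, short_length), total_length = short_length,
        seed = sub_seeds[n_base + i], id = sprintf("short%04d", i)
      )
      s
    })
    dup_src <- if (n_dup > 0) sample.int(n_base, n_dup, replace = TRUE) else integer()
    dups <- lapply(seq_len(n_dup), function(i) {
      src <- base[[dup_src[i]]]
      protein_sequence(
        sprintf("dup%04d_of_%s", i, src$id), src$residues,
        description = "planted exact duplicate"
      )
    })
    lib <- c(base, shorts, dups)
    lib <- lib[sample.int(length(lib))]
    names(lib) <- vapply(lib, function(s) s$id, "")
    attr(lib, "truth") <- list(
      targets = targets,
      duplicate_ids = vapply(dups, function(s) s$id, character(1)),
      short_ids = vapply(shorts, function(s) s$id, character(1))
    )
    lib
  })
}

# One fixed-width PDB ATOM line.
format_pdb_atom <- function(serial, name, resname, chain, resno,
                            x, y, z, occ = 1, b = 0, element) {
  name_field <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, name_field, resname, chain, resno, x, y, z, occ, b, element
  )
}

#' Generate a toy structure in PDB format
#'
#' Three kinds of synthetic atom clusters, written as standards-conformant
#' ATOM records with exact requested coordinates:
#' \itemize{
#'   \item `"single-atom"` - one atom at `center` (surface-area closed-form
#'     tests);
#'   \item `"two-sphere"` - two atoms separated by `separation` along x
#'     (overlap tests against an independent integration oracle);
#'   \item `"helix"` - an idealized helical trace of `n_res` residues with a
#'     planted fraction of hydrophobic side chains (LEU, four apolar
#'     side-chain atoms) among polar ones (SER, one oxygen side-chain atom),
#'     plus a catalytic serine at `ser_resno` carrying the O-gamma reference
#'     atom used for pocket definition.
#' }
#'
#' @param kind one of `"single-atom"`, `"two-sphere"`, `"helix"`.
#' @param element,center element symbol and position for `"single-atom"`.
#' @param elements,separation two element symbols and their distance for
#'   `"two-sphere"`.
#' @param n_res,hydrophobic_fraction,ser_resno helix parameters; the
#'   hydrophobic residues are chosen by seeded sampling (the catalytic
#'   serine is always polar).
#' @param seed RNG seed (helix residue assignment only).
#' @return single character string of PDB-format text.
#' @export
gen_toy_structure <- function(kind = c("single-atom", "two-sphere", "helix"),
                              element = "C", center = c(0, 0, 0),
                              elements = c("C", "C"), separation = 4,
                              n_res = 45L, hydrophobic_fraction = 0.5,
                              ser_resno = NULL, seed = 1L) {
  kind <- match.arg(kind)
  lines <- switch(kind,
    "single-atom" = format_pdb_atom(
      1L, paste0(element, "1"), "UNK", "A", 1L,
      center[1], center[2], center[3],
      element = element
    ),
    "two-sphere" = {
      if (separation < 0) stop("separation must be non-negative", call. = FALSE)
      c(
        format_pdb_atom(1L, paste0(elements[1], "1"), "UNK", "A", 1L,
          0, 0, 0,
          element = elements[1]
        ),
        format_pdb_atom(2L, paste0(elements[2], "2"), "UNK", "A", 2L,
          separation, 0, 0,
          element = elements[2]
        )
      )
    },
    "helix" = {
      if (is.null(ser_resno)) ser_resno <- ceiling(n_res / 2)
      if (ser_resno < 1 || ser_resno > n_res) {
        stop("ser_resno out of range", call. = FALSE)
      }
      n_hyd <- round(hydrophobic_fraction * (n_res - 1L))
      hyd_pool <- setdiff(seq_len(n_res), ser_resno)
      hyd_res <- with_seed(seed, sort(sample(hyd_pool, n_hyd)))
      out <- character()
      serial <- 0L
      add <- function(name, resname, resno, x, y, z, el) {
        serial <<- serial + 1L
        out[length(out) + 1L] <<- format_pdb_atom(
          serial, name, resname, "A", resno, x, y, z,
          element = el
        )
      }
      for (i in seq_len(n_res)) {
        ang <- i * 100 * pi / 180
        zc <- i * 1.5
        ca <- c(2.3 * cos(ang), 2.3 * sin(ang), zc)
        u <- c(cos(ang), sin(ang), 0) # outward radial unit vector
        is_ser <- i == ser_resno
        is_hyd <- i %in% hyd_res
        resname <- if (is_ser) "SER" else if (is_hyd) "LEU" else "SER"
        add("N", resname, i, ca[1] - 0.8 * u[1], ca[2] - 0.8 * u[2], zc - 0.9, "N")
        add("CA", resname, i, ca[1], ca[2], ca[3], "C")
        add("C", resname, i, ca[1] - 0.6 * u[1], ca[2] - 0.6 * u[2], zc + 1.0, "C")
        add("O", resname, i, ca[1] - 1.3 * u[1], ca[2] - 1.3 * u[2], zc + 1.4, "O")
        add("CB", resname, i, 3.4 * u[1], 3.4 * u[2], zc, "C")
        if (is_hyd && !is_ser) {
          add("CG", resname, i, 4.7 * u[1], 4.7 * u[2], zc, "C")
          add("CD1", resname, i, 5.6 * u[1], 5.6 * u[2], zc + 0.8, "C")
          add("CD2", resname, i, 5.6 * u[1], 5.6 * u[2], zc - 0.8, "C")
        } else {
          add("OG", resname, i, 4.5 * u[1], 4.5 * u[2], zc, "O")
        }
      }
      out
    }
  )
  paste(c(lines, "END"), collapse = "\n")
}

#' Generate a synthetic pNPA assay curve
#'
#' Samples the relative-activity model at the requested acceptor
#' concentrations and applies multiplicative lognormal noise. The A = 0
#' reference point is exactly 1 by construction (the assay normalizes every
#' rate to the no-acceptor rate).
#'
#' @param r_t,K_i true model parameters (see [relative_activity_model()]).
#' @param concentrations acceptor concentrations in mM; must include 0 and be
#'   non-negative.
#' @param noise_sd standard deviation of the multiplicative log-normal noise
#'   (0 = noiseless).
#' @param seed RNG seed.
#' @return data frame with columns `A`, `rel` and attribute `truth` (list of
#'   `r_t`, `K_i`).
#' @export
gen_assay_curve <- function(r_t, K_i = Inf,
                            concentrations = c(0, 5, 10, 20, 40, 60, 80, 100),
                            noise_sd = 0, seed = 1L) {
  if (any(concentrations < 0)) {
    stop("negative acceptor concentration in `concentrations`", call. = FALSE)
  }
  if (!any(concentrations == 0)) {
    stop("`concentrations` must include the A = 0 reference", call. = FALSE)
  }
  rel <- relative_activity_model(concentrations, r_t, K_i)
  if (noise_sd > 0) {
    rel <- with_seed(
      seed,
      rel * exp(stats::rnorm(length(rel), 0, noise_sd))
    )
  }
  rel[concentrations == 0] <- 1
  out <- data.frame(A = concentrations, rel = rel)
  attr(out, "truth") <- list(r_t = r_t, K_i = K_i)
  out
}

#' Printed cap scores of the six reference bHSLs
#'
#' The six reference enzymes with solved crystal structures, their published
#' 45-residue cap hydrophobicity scores, and their experimentally observed
#' acyltransferase-activity tier in water (high: near-complete acceptor
#' conversion; mid: ~27% transient conversion; low: <5%, conventional
#' hydrolase behaviour).
#'
#' @return data frame with columns `id`, `pdb`, `score`, `activity_tier`.
#' @export
reference_scores <- function() {
  data.frame(
    id = c("4XVC", "3K6K", "Est8", "3FAK", "1EVQ", "3ZWQ"),
    pdb = c("4XVC", "3K6K", "6Y9K", "3FAK", "1EVQ", "3ZWQ"),
    score = c(4.4, 4.6, 11.2, 12.4, 18.2, 21.4),
    activity_tier = c("low", "low", "mid", "mid", "high", "high"),
    stringsAsFactors = FALSE
  )
}

#' Synthetic stand-in cap sequences for the six reference enzymes
#'
#' The real cap sequences of the six reference structures are not bundled
#' with the package; these are SYNTHETIC stand-ins generated by
#' [gen_sequence_with_score()] so that each stand-in's cap score matches the
#' corresponding published score. They exercise the scoring pipeline
#' end-to-end but are not the real enzyme sequences and carry no structural
#' information.
#'
#' @param scale a [residue_scale()].
#' @param tol per-sequence score tolerance.
#' @param seed RNG seed.
#' @return named list of [protein_sequence()] objects (one per reference
#'   id), each flagged as synthetic in its description.
#' @export
synthetic_reference_caps <- function(scale = default_scale(), tol = 0.05,
                                     seed = 101L) {
  refs <- reference_scores()
  seqs <- lapply(seq_len(nrow(refs)), function(i) {
    s <- gen_sequence_with_score(refs$score[i],
      scale = scale, tol = tol,
      total_length = 300L, seed = seed + i,
      id = paste0("synth_", refs$id[i])
    )
    s$description <- sprintf(
      "SYNTHETIC stand-in for %s cap (planted score %.1f); not the real sequence",
      refs$id[i], refs$score[i]
    )
    s
  })
  names(seqs) <- refs$id
  seqs
}

#' Synthetic stand-in structures with a planted pocket-hydrophobicity gradient
#'
#' The real crystal structures of the six reference enzymes are not bundled;
#' these are SYNTHETIC helical toy structures whose planted hydrophobic
#' side-chain fraction increases linearly with the corresponding published
#' cap score. They exercise the pocket-area pipeline (parsing, SASA, pocket
#' definition, correlation) as a planted-truth recovery problem.
#'
#' @param n_res residues per toy structure.
#' @param seed RNG seed.
#' @return named list of PDB-format strings (one per reference id).
#' @export
synthetic_reference_structures <- function(n_res = 45L, seed = 202L) {
  refs <- reference_scores()
  lo <- min(refs$score)
  hi <- max(refs$score)
  frac <- 0.15 + 0.7 * (refs$score - lo) / (hi - lo)
  out <- lapply(seq_len(nrow(refs)), function(i) {
    gen_toy_structure("helix",
      n_res = n_res,
      hydrophobic_fraction = frac[i],
      seed = seed + i
    )
  })
  names(out) <- refs$id
  out
}
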