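#' @keywords internal
"_PACKAGE"

# Canonical one-letter amino-acid alphabet, alphabetical by letter.
AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Residues whose sign the scoring convention constrains: the six strongly
# hydrophobic side chains must score positive, the four charged ones negative.
# Histidine is deliberately unconstrained.
AA_HYDROPHOBIC <- c("L", "I", "V", "F", "W", "M")
AA_CHARGED <- c("D", "E", "K", "R")

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards, so generators are pure functions of their seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# MD5 of a file, used to stamp outputs with input provenance.
input_md5 <- function(path) {
  unname(tools::md5sum(path.expand(path)))
}

pkg_version_string <- function() {
  paste0("acylscreen ", as.character(utils::packageVersion("acylscreen")))
}
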