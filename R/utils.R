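#' @importFrom tibble tibble as_tibble
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Map ASCII codes to base indices (A=1, C=2, G=3, T=4); other characters 0.
.base_code_map <- local({
  m <- integer(128L)
  m[utf8ToInt("A")] <- 1L; m[utf8ToInt("a")] <- 1L
  m[utf8ToInt("C")] <- 2L; m[utf8ToInt("c")] <- 2L
  m[utf8ToInt("G")] <- 3L; m[utf8ToInt("g")] <- 3L
  m[utf8ToInt("T")] <- 4L; m[utf8ToInt("t")] <- 4L
  m
})

#' Encode a DNA string as base indices
#'
#' @param seq single character string over the DNA alphabet.
#' @return integer vector with A=1, C=2, G=3, T=4 and NA for any other
#'   character (N included).
#' @keywords internal
encode_dna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  v <- utf8ToInt(seq)
  if (any(v > 127L)) stop("non-ASCII character in sequence", call. = FALSE)
  code <- .base_code_map[v]
  code[code == 0L] <- NA_integer_
  code
}

decode_dna <- function(code) {
  paste(DNA_BASES[code], collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Keeps N and case as-is apart from complementation; used on plain
#' character windows where constructing a Biostrings object per call
#' would dominate runtime.
#' @param seq character string.
#' @return character string.
#' @keywords internal
revcomp <- function(seq) {
  chartr("ACGTacgtNn", "TGCAtgcaNn", vapply(strsplit(seq, NULL), function(x) {
    paste(rev(x), collapse = "")
  }, character(1)))
}

#' Derive a reproducible child seed from a master seed and an identifier
#'
#' Streams for per-sequence randomness are keyed on (id, seed) so results
#' do not depend on processing order.
#' @param seed master integer seed.
#' @param id character identifier (may be NULL for the unkeyed stream).
#' @return integer in \[1, 2^31 - 2\].
#' @keywords internal
derive_seed <- function(seed, id = NULL) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  if (!is.null(id)) {
    for (c in utf8ToInt(as.character(id))) h <- (h * 31 + c) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Run code under a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
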