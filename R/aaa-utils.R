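#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino acids in the fixed order used everywhere in this
#' package: alphabetical by one-letter code. Potts tables, logits and
#' serialized models all index residues in this order.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Convert an amino-acid string to integer indices
#'
#' @param seq Character scalar (e.g. `"ACDE"`) or character vector of
#'   single letters.
#' @return Integer vector of 1-based indices into [aa_alphabet()].
#' @export
aa_to_int <- function(seq) {
  if (length(seq) == 1L && nchar(seq) > 1L) seq <- strsplit(seq, "")[[1]]
  idx <- match(seq, .AA)
  if (anyNA(idx)) {
    bad <- unique(seq[is.na(idx)])
    stop("unknown amino-acid letter(s): ", paste(bad, collapse = ", "))
  }
  idx
}

#' Convert integer indices to an amino-acid string
#'
#' @param idx Integer vector of 1-based alphabet indices.
#' @return Character scalar.
#' @export
int_to_aa <- function(idx) {
  stopifnot(all(idx >= 1L & idx <= 20L))
  paste(.AA[idx], collapse = "")
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically combine a base seed with extra keys (integers or strings)
# into a 32-bit-safe positive integer. Used to key per-protein decoding
# orders, per-step noise draws, etc. off one global seed.
derive_seed <- function(seed, ...) {
  m <- 2147483629
  acc <- as.numeric(seed) %% m
  for (key in list(...)) {
    if (is.character(key)) key <- utf8ToInt(key)
    for (v in as.numeric(key)) {
      acc <- (acc * 48271 + (v %% m) + 1) %% m
    }
  }
  as.integer(acc)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
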