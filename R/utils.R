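## Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All randomness in the package flows from one integer seed through named
#' substreams (\code{"data"}, \code{"init"}, \code{"folds"}, \code{"dropout"},
#' ...), so that e.g. re-drawing fold assignments never perturbs weight
#' initialisation. The stream name is hashed with FNV-1a and folded into the
#' seed modulo 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param stream character stream name.
#' @return an integer seed < 2^31.
#' @export
deriveSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- fnv1a(charToRaw(stream))
  as.integer((abs(seed) %% 2147483647 + h) %% 2147483647)
}

## FNV-1a on raw bytes, 31-bit result (kept in double arithmetic: all
## intermediates stay below 2^53 because we reduce mod 2^31-1 each step).
fnv1a <- function(bytes) {
  h <- 216613626  # FNV offset basis folded into 31 bits
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h), b)
    h <- (h * 16777619) %% 2147483647
  }
  h
}

#' Hash an R object for provenance stamping
#'
#' FNV-1a over the canonical serialization; used to stamp every artifact a
#' run writes so that two runs with the same configuration are
#' byte-comparable.
#'
#' @param x any serializable R object.
#' @return hex string.
#' @export
configHash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  ## skip the serialization header (R version stamp varies across builds)
  sprintf("%08x", fnv1a(raw[-seq_len(14)]))
}

## Evaluate `expr` under a seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Row-major flatten: rows of `m` concatenated.
flattenRowMajor <- function(m) as.vector(t(m))

## Inverse of flattenRowMajor for an nr x nc matrix.
unflattenRowMajor <- function(v, nr, nc) {
  stopifnot(length(v) == nr * nc)
  matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
}

## Symmetrize by averaging with the transpose; zero the diagonal.
symmetrizeZeroDiag <- function(m) {
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

isSymmetricTol <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

## Stop with a labelled message unless a condition holds.
assertThat <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
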