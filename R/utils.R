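# Internal helpers shared across modules.

DNA_CODES <- c(A = 65L, C = 67L, G = 71L, T = 84L)

#' Evaluate code under a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded package operations do not perturb the user's random stream.
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Deterministic 31-bit seed from a character id
#'
#' Used to give every sample its own reproducible subsampling seed derived
#' from its identifier (overridable everywhere it is applied).
#' @noRd
id_seed <- function(id, offset = 0L) {
  stopifnot(is.character(id), length(id) == 1L)
  s <- as.double(offset) %% 2147483647
  for (v in utf8ToInt(id)) s <- (s * 31 + v) %% 2147483647
  as.integer(s)
}

#' n random DNA sequences of a fixed length
#' @noRd
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  codes <- matrix(sample(DNA_CODES, n * len, replace = TRUE), nrow = len)
  vapply(seq_len(n), function(i) intToUtf8(codes[, i]), character(1))
}

#' Character vector of equal-length sequences -> integer code matrix (len x n)
#' @noRd
seq_code_matrix <- function(x) {
  len <- unique(nchar(x))
  if (length(len) != 1L) stop("sequences must have equal length")
  matrix(utf8ToInt(paste(x, collapse = "")), nrow = len)
}

#' Integer code matrix (len x n) -> character vector
#' @noRd
code_matrix_to_seq <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
  vapply(seq_len(ncol(m)), function(i) intToUtf8(m[, i]), character(1))
}

#' Flip each base independently with probability `rate` to a different base
#'
#' Vectorised over a character vector of sequences (lengths may differ).
#' Returns the mutated sequences; uses the current RNG stream.
#' @noRd
inject_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  codes <- utf8ToInt(paste(seqs, collapse = ""))
  hit <- which(stats::runif(length(codes)) < rate)
  if (length(hit)) {
    idx <- match(codes[hit], DNA_CODES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    codes[hit] <- DNA_CODES[((idx - 1L + shift) %% 4L) + 1L]
  }
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  vapply(seq_along(seqs), function(i) intToUtf8(codes[starts[i]:ends[i]]),
         character(1))
}

#' Per-position mismatch count between two equal-length string vectors
#' @noRd
string_mismatches <- function(x, y) {
  lx <- nchar(x)
  if (!all(lx == nchar(y))) stop("string lengths differ")
  if (length(x) == 0L) return(integer(0))
  if (length(unique(lx)) == 1L) {
    a <- charToRaw(paste(x, collapse = ""))
    b <- charToRaw(paste(y, collapse = ""))
    colSums(matrix(a != b, nrow = lx[1]))
  } else {
    mapply(function(p, q) sum(charToRaw(p) != charToRaw(q)), x, y,
           USE.NAMES = FALSE)
  }
}

#' Draw from a zipf law on 1..max_count truncated at max_count
#' P(k) proportional to k^(-exponent)
#' @noRd
rzipf_trunc <- function(n, exponent, max_count) {
  if (n == 0L) return(integer(0))
  k <- seq_len(max_count)
  sample(k, n, replace = TRUE, prob = k^(-exponent))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
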