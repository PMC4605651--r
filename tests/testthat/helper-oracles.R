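# Independent oracles used to cross-check package implementations.
# These are deliberately written as direct transcriptions of first
# principles (dynamic programming, enumeration, root finding) and share no
# code with the package.

# Smith-Waterman local alignment score with affine gaps (Gotoh), where a
# gap of length k costs gap_open + k * gap_ext. Plain O(nm) loops.
sw_oracle_score <- function(s1, s2, match = 1, mismatch = -1,
                            gap_open = 2, gap_ext = 1) {
  a <- utf8ToInt(s1)
  b <- utf8ToInt(s2)
  n <- length(a)
  m <- length(b)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, F[i - 1, j] - gap_ext)
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# One-sided Mann-Whitney p-value (group a stochastically larger) by full
# enumeration of all C(n, na) group assignments, midranks under ties.
mw_enumeration_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  rk <- rank(pooled)
  obs <- sum(rk[seq_len(na)])
  sets <- utils::combn(length(pooled), na)
  sums <- apply(sets, 2, function(ix) sum(rk[ix]))
  mean(sums >= obs - 1e-9)
}

# AUC by brute force over all positive x negative pairs, half credit for
# ties.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Continuity-corrected Wilson bounds by root finding on the defining
# equations |phat - p| - 1/(2n) = z * sqrt(p(1-p)/n).
wilson_cc_oracle <- function(k, n, alpha = 0.05) {
  z <- qnorm(1 - alpha / 2)
  phat <- k / n
  lo <- if (k == 0) 0 else {
    g <- function(p) (phat - p - 1 / (2 * n)) - z * sqrt(p * (1 - p) / n)
    uniroot(g, c(1e-12, phat), tol = 1e-12)$root
  }
  hi <- if (k == n) 1 else {
    h <- function(p) (p - phat - 1 / (2 * n)) - z * sqrt(p * (1 - p) / n)
    uniroot(h, c(phat, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lo = max(0, lo), hi = min(1, hi))
}

# Tiny deterministic annotated-molecule table builder for metrics tests.
make_molecules <- function(sequence_key, isotype, mutated,
                           v_segment = "V01") {
  n <- length(sequence_key)
  data.frame(uid = sprintf("UID%03d", seq_len(n)), coverage = 1L,
             v_segment = rep_len(v_segment, n), mutation_count = 0L,
             mutation_rate = ifelse(mutated, 0.05, 0),
             mutated = mutated, isotype = isotype,
             sequence_key = sequence_key, stringsAsFactors = FALSE)
}

# Clone table builder: one row per clone.
make_clones <- function(isotype, molecule_count, mutated,
                        sequence_key = NULL) {
  n <- length(isotype)
  data.frame(sequence_key = sequence_key %||%
               sprintf("SEQ%05d", seq_len(n)),
             isotype = isotype, v_segment = "V01", mutated = mutated,
             molecule_count = as.integer(molecule_count),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small shared simulation fixtures (built once per test run).
tiny_refs <- function(n_v = 4, seed = 11) {
  make_germline_refs(n_v = n_v, v_len = 80, seed = seed)
}
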