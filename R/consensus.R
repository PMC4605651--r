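# UID extraction, grouping by molecular barcode, and consensus calling.
# Each group of read pairs sharing a 16-nt UID is treated as one original
# IGH transcript molecule; per-position majority vote across the group
# corrects sequencing errors whenever coverage >= 2.

#' Extract the 16-nt UID and trim primers from read pairs
#'
#' The UID is the first `uid_len_each` bases of mate 1 concatenated with the
#' first `uid_len_each` bases of mate 2. The bases immediately following the
#' UID on each mate must match one of the supplied primers within
#' `max_primer_mismatches`; UID and primer are then removed, leaving the
#' payloads. Vectorised over read pairs.
#'
#' @param seq1,seq2 Character vectors of mate-1 / mate-2 sequences.
#' @param qual1,qual2 Matching quality strings (trimmed alongside).
#' @param primers List with `v_fr3` (mate 1) and `c_region` (mate 2) primer
#'   sequences; each may be a vector of alternative primers of equal length.
#' @param uid_len_each UID bases contributed by each mate (default 8).
#' @param max_primer_mismatches Tolerated mismatches against the best
#'   matching primer.
#' @return data.frame with columns uid, payload1, payload2, pqual1, pqual2
#'   and status ("ok", "short" or "primer"); the attribute
#'   `rejection_tally` holds the counts of rejected pairs by reason.
#' @export
extract_uid_and_trim <- function(seq1, seq2, qual1 = strrep("I", nchar(seq1)),
                                 qual2 = strrep("I", nchar(seq2)),
                                 primers, uid_len_each = 8L,
                                 max_primer_mismatches = 2L) {
  stopifnot(length(seq1) == length(seq2))
  n <- length(seq1)
  p1 <- primers$v_fr3
  p2 <- primers$c_region
  pl1 <- unique(nchar(p1)); pl2 <- unique(nchar(p2))
  stopifnot(length(pl1) == 1L, length(pl2) == 1L)
  min1 <- uid_len_each + pl1 + 1L
  min2 <- uid_len_each + pl2 + 1L
  status <- rep("ok", n)
  status[nchar(seq1) < min1 | nchar(seq2) < min2] <- "short"
  ok <- status == "ok"
  mm_best <- function(seqs, prims, plen) {
    region <- substr(seqs, uid_len_each + 1L, uid_len_each + plen)
    best <- rep(Inf, length(seqs))
    for (p in prims) {
      best <- pmin(best, string_mismatches(region, rep(p, length(seqs))))
    }
    best
  }
  if (any(ok)) {
    bad <- (mm_best(seq1[ok], p1, pl1) > max_primer_mismatches) |
      (mm_best(seq2[ok], p2, pl2) > max_primer_mismatches)
    status[which(ok)[bad]] <- "primer"
  }
  out <- data.frame(
    uid = paste0(substr(seq1, 1L, uid_len_each),
                 substr(seq2, 1L, uid_len_each)),
    payload1 = substr(seq1, uid_len_each + pl1 + 1L, nchar(seq1)),
    payload2 = substr(seq2, uid_len_each + pl2 + 1L, nchar(seq2)),
    pqual1 = substr(qual1, uid_len_each + pl1 + 1L, nchar(qual1)),
    pqual2 = substr(qual2, uid_len_each + pl2 + 1L, nchar(qual2)),
    status = status, stringsAsFactors = FALSE)
  out$uid[status != "ok"] <- NA_character_
  attr(out, "rejection_tally") <- c(short = sum(status == "short"),
                                    primer = sum(status == "primer"))
  out
}

#' Group extracted read pairs by UID
#'
#' @param extracted A data.frame from [extract_uid_and_trim()] (rows with
#'   status != "ok" are ignored).
#' @return A named list of `uid_group` objects (sorted by UID), each a list
#'   with uid, forward_reads, reverse_reads, forward_quals, reverse_quals
#'   and coverage.
#' @export
group_by_uid <- function(extracted) {
  keep <- extracted[extracted$status == "ok", , drop = FALSE]
  if (nrow(keep) == 0L) return(structure(list(), names = character(0)))
  idx <- split(seq_len(nrow(keep)), keep$uid)
  groups <- lapply(idx, function(i) {
    g <- list(uid = keep$uid[i[1]],
              forward_reads = keep$payload1[i],
              reverse_reads = keep$payload2[i],
              forward_quals = keep$pqual1[i],
              reverse_quals = keep$pqual2[i],
              coverage = length(i))
    class(g) <- "uid_group"
    g
  })
  groups[order(names(groups))]
}

# Majority vote over a set of equal-length reads; ties broken by highest
# summed quality at the position, then by the lexicographically smallest
# base. Returns a single consensus string.
consensus_vote <- function(reads, quals) {
  if (length(reads) == 1L) return(reads)
  m <- seq_code_matrix(reads)
  q <- seq_code_matrix(quals) - 33L
  len <- nrow(m)
  best_score <- rep(-Inf, len)
  best_base <- integer(len)
  for (b in seq_along(DNA_CODES)) {
    is_b <- m == DNA_CODES[b]
    cnt <- rowSums(is_b)
    qs <- rowSums(q * is_b)
    score <- cnt * 1e7 + qs * 4 + (4 - b)
    better <- score > best_score
    best_score[better] <- score[better]
    best_base[better] <- DNA_CODES[b]
  }
  intToUtf8(best_base)
}

#' Build the consensus pair of one UID group
#'
#' Coverage-1 groups are passed through unchanged (uncorrected but still
#' counted as one molecule); groups with coverage >= 2 get an independent
#' per-position majority vote for the forward and reverse reads. Ties are
#' broken by the highest summed base quality at the position, then by the
#' lexicographically smallest base, so the result is deterministic.
#'
#' @param group A `uid_group` from [group_by_uid()].
#' @return An object of class `consensus_pair`: list with uid,
#'   forward_consensus, reverse_consensus, coverage and corrected
#'   (`TRUE` iff coverage >= 2).
#' @export
build_consensus <- function(group) {
  stopifnot(inherits(group, "uid_group"))
  if (length(unique(nchar(group$forward_reads))) != 1L ||
      length(unique(nchar(group$reverse_reads))) != 1L) {
    stop("length-discordant reads within UID group ", group$uid,
         "; group discarded")
  }
  out <- list(uid = group$uid,
              forward_consensus = consensus_vote(group$forward_reads,
                                                 group$forward_quals),
              reverse_consensus = consensus_vote(group$reverse_reads,
                                                 group$reverse_quals),
              coverage = group$coverage,
              corrected = group$coverage >= 2L)
  class(out) <- "consensus_pair"
  out
}

#' Consensus pairs for a whole sample (vectorised)
#'
#' Equivalent to applying [group_by_uid()] and [build_consensus()] to every
#' group, but implemented with matrix operations over all groups at once.
#' Length-discordant groups are dropped and tallied.
#'
#' @param extracted A data.frame from [extract_uid_and_trim()].
#' @return data.frame (one row per UID, sorted by UID) with columns uid,
#'   coverage, corrected, forward_consensus, reverse_consensus; attribute
#'   `tally` holds counts of input pairs, rejected pairs and discarded
#'   groups.
#' @export
build_consensus_table <- function(extracted) {
  tally <- attr(extracted, "rejection_tally") %||% c(short = 0L, primer = 0L)
  keep <- extracted[extracted$status == "ok", , drop = FALSE]
  empty <- data.frame(uid = character(0), coverage = integer(0),
                      corrected = logical(0),
                      forward_consensus = character(0),
                      reverse_consensus = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(keep) == 0L) {
    attr(empty, "tally") <- c(tally, length_discordant_groups = 0L,
                              input_pairs = nrow(extracted))
    return(empty)
  }
  keep <- keep[order(keep$uid), , drop = FALSE]
  gid <- cumsum(!duplicated(keep$uid))
  n_groups <- gid[length(gid)]
  coverage <- tabulate(gid, n_groups)
  uids <- keep$uid[!duplicated(keep$uid)]

  len_ok <- function(x) {
    lens <- nchar(x)
    if (length(unique(lens)) == 1L) return(rep(TRUE, n_groups))
    rng_min <- tapply(lens, gid, min)
    rng_max <- tapply(lens, gid, max)
    as.vector(rng_min == rng_max)
  }
  good <- len_ok(keep$payload1) & len_ok(keep$payload2)
  discarded <- sum(!good)
  sel <- good[gid]
  keep <- keep[sel, , drop = FALSE]
  gid <- gid[sel]
  if (nrow(keep) == 0L) {
    attr(empty, "tally") <- c(tally, length_discordant_groups = discarded,
                              input_pairs = nrow(extracted))
    return(empty)
  }
  gid <- match(gid, unique(gid))
  coverage <- tabulate(gid, max(gid))
  uids <- keep$uid[!duplicated(keep$uid)]

  vote_all <- function(reads, quals) {
    single <- coverage == 1L
    cons <- character(length(coverage))
    if (any(single)) {
      cons[single] <- reads[match(which(single), gid)]
    }
    multi <- which(!single)
    if (length(multi)) {
      # groups whose reads all agree need no vote
      first_row <- which(!duplicated(gid))
      disagree_g <- unique(gid[reads != reads[first_row[gid]]])
      uniform <- setdiff(multi, disagree_g)
      cons[uniform] <- reads[first_row[uniform]]
      multi <- intersect(multi, disagree_g)
    }
    if (length(multi)) {
      rows <- gid %in% multi
      sub_reads <- reads[rows]
      sub_gid <- match(gid[rows], multi)
      sub_q <- quals[rows]
      for (L in unique(nchar(sub_reads))) {
        pick <- nchar(sub_reads) == L
        m <- t(seq_code_matrix(sub_reads[pick]))        # reads x positions
        q <- t(seq_code_matrix(sub_q[pick])) - 33L
        g <- sub_gid[pick]
        gi <- match(g, unique(g))
        best_score <- NULL
        best_base <- NULL
        for (b in seq_along(DNA_CODES)) {
          is_b <- m == DNA_CODES[b]
          cnt <- rowsum(is_b + 0, gi)
          qs <- rowsum(q * is_b, gi)
          score <- cnt * 1e7 + qs * 4 + (4 - b)
          if (is.null(best_score)) {
            best_score <- score
            best_base <- matrix(DNA_CODES[b], nrow(score), ncol(score))
          } else {
            better <- score > best_score
            best_score[better] <- score[better]
            best_base[better] <- DNA_CODES[b]
          }
        }
        cons[multi[unique(g)]] <- vapply(seq_len(nrow(best_base)),
                                         function(i) intToUtf8(best_base[i, ]),
                                         character(1))
      }
    }
    cons
  }
  out <- data.frame(uid = uids, coverage = coverage,
                    corrected = coverage >= 2L,
                    forward_consensus = vote_all(keep$payload1, keep$pqual1),
                    reverse_consensus = vote_all(keep$payload2, keep$pqual2),
                    stringsAsFactors = FALSE)
  attr(out, "tally") <- c(tally, length_discordant_groups = discarded,
                          input_pairs = nrow(extracted))
  out
}
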