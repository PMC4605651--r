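# V-segment / isotype annotation of consensus pairs by local alignment.
# The forward consensus is aligned to the germline V references (mutation
# rate = mismatches per aligned base), the reverse consensus to the five
# constant-region references (isotype).

#' Alignment parameters
#'
#' Scoring and acceptance cutoffs for the local aligner: match +1,
#' mismatch -1, and affine gaps where a gap of length k costs
#' `gap_open + k * gap_extend`. A hit is accepted when the best local
#' alignment reaches at least `min_identity` over at least `min_len`
#' aligned columns (gap columns included and counted as mismatches).
#'
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Positive gap penalties.
#' @param min_identity Minimum identity (1 - mismatches/aligned_length).
#' @param min_len Minimum aligned length in columns.
#' @return List of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -1, gap_open = 2,
                         gap_extend = 1, min_identity = 0.80, min_len = 40) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            min_identity >= 0, min_identity <= 1, min_len >= 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity = min_identity,
                 min_len = min_len), class = "align_params")
}

# Vectorised best-hit alignment: every sequence against every reference.
# Returns a data.frame (one row per sequence) with the best reference by
# score, ties broken by reference order.
align_many <- function(seqs, refs, params = align_params()) {
  stopifnot(length(seqs) >= 1L, length(refs) >= 1L)
  if (any(nchar(seqs) == 0L)) stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                                  mismatch = params$mismatch,
                                                  baseOnly = TRUE)
  n <- length(seqs)
  ref_names <- names(refs) %||% as.character(seq_along(refs))
  ref_str <- as.character(refs)
  best <- data.frame(ref = NA_character_, score = NA_real_,
                     mismatches = NA_integer_, aligned_length = NA_integer_,
                     identity = NA_real_, stringsAsFactors = FALSE)[rep(1, n), ]
  rownames(best) <- NULL
  # Exact screen: a sequence containing exactly one full reference verbatim
  # has that perfect match as its best local alignment (no other reference
  # can reach a full-length perfect score against a distinct reference set).
  contains <- vapply(ref_str, function(r) grepl(r, seqs, fixed = TRUE),
                     logical(n))
  contains <- matrix(contains, nrow = n)
  direct <- rowSums(contains) == 1L
  if (any(direct)) {
    j <- max.col(contains[direct, , drop = FALSE], ties.method = "first")
    best$ref[direct] <- ref_names[j]
    best$score[direct] <- params$match * nchar(ref_str)[j]
    best$mismatches[direct] <- 0L
    best$aligned_length[direct] <- nchar(ref_str)[j]
  }
  todo <- which(!direct)
  if (length(todo)) {
    pats <- Biostrings::DNAStringSet(seqs[todo])
    # pass 1: scores only (no traceback) against every reference
    scores <- vapply(seq_along(refs), function(j) {
      Biostrings::pairwiseAlignment(pats, refs[[j]], type = "local",
                                    substitutionMatrix = mat,
                                    gapOpening = params$gap_open,
                                    gapExtension = params$gap_extend,
                                    scoreOnly = TRUE)
    }, numeric(length(todo)))
    scores <- matrix(scores, nrow = length(todo))
    pick <- max.col(scores, ties.method = "first")  # tie -> reference order
    best$ref[todo] <- ref_names[pick]
    best$score[todo] <- scores[cbind(seq_along(todo), pick)]
    # pass 2: full alignment against the winning reference only
    for (j in unique(pick)) {
      rows <- todo[pick == j]
      aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(seqs[rows]),
                                           refs[[j]], type = "local",
                                           substitutionMatrix = mat,
                                           gapOpening = params$gap_open,
                                           gapExtension = params$gap_extend)
      ind <- Biostrings::nindel(aln)
      gaps <- ind@insertion[, "WidthSum"] + ind@deletion[, "WidthSum"]
      mm <- Biostrings::nmismatch(aln) + gaps
      best$mismatches[rows] <- mm
      best$aligned_length[rows] <- Biostrings::nmatch(aln) + mm
    }
  }
  best$identity <- 1 - best$mismatches / best$aligned_length
  best$hit <- best$identity >= params$min_identity &
    best$aligned_length >= params$min_len
  best
}

#' Best local alignment of one sequence against a reference set
#'
#' @param seq A DNA sequence (character or `DNAString`).
#' @param refs A named `DNAStringSet` of references.
#' @param params An [align_params()].
#' @return A list of class `alignment_hit` (ref, score, mismatches,
#'   aligned_length, identity), or an object of class `no_hit` when the
#'   best alignment fails the identity/length cutoffs.
#' @export
align_to_references <- function(seq, refs, params = align_params()) {
  seq <- as.character(seq)
  if (length(refs) == 0L) stop("empty reference set")
  b <- align_many(seq, refs, params)
  if (!b$hit[1]) {
    return(structure(list(best_identity = b$identity[1]), class = "no_hit"))
  }
  structure(list(ref = b$ref[1], score = b$score[1],
                 mismatches = b$mismatches[1],
                 aligned_length = b$aligned_length[1],
                 identity = b$identity[1]), class = "alignment_hit")
}

#' Classify a molecule as somatically mutated
#'
#' A molecule counts as mutated when its V mutation rate reaches
#' `mutated_igm_min_rate` (closed lower bound: a rate exactly equal to the
#' threshold is mutated). The flag is computed for every isotype but only
#' enters the ABS definition for IgM.
#'
#' @param mutation_rate Mutation rate(s) in [0, 1].
#' @param mutated_igm_min_rate Threshold (default 0.01).
#' @return Logical vector.
#' @export
classify_mutated <- function(mutation_rate, mutated_igm_min_rate = 0.01) {
  mutation_rate >= mutated_igm_min_rate
}

#' Annotate consensus pairs with V segment, mutation rate and isotype
#'
#' Aligns every distinct forward consensus to the V references and every
#' distinct reverse consensus to the constant-region references; a molecule
#' is "aligned" only when both mates hit. Unaligned molecules are excluded
#' from the returned table and tallied in the `tally` attribute.
#'
#' @param consensus A data.frame from [build_consensus_table()] (or one
#'   consensus pair coerced to the same columns).
#' @param refs A [make_germline_refs()] result (or any list with `v` and
#'   `c` `DNAStringSet`s).
#' @param params An [align_params()].
#' @param mutated_igm_min_rate Threshold passed to [classify_mutated()].
#' @return data.frame of annotated molecules: uid, coverage, v_segment,
#'   mutation_count, mutation_rate, mutated, isotype, sequence_key (the
#'   forward consensus, carrying the CDR3).
#' @export
annotate_molecules <- function(consensus, refs, params = align_params(),
                               mutated_igm_min_rate = 0.01) {
  stopifnot(nrow(consensus) >= 0L)
  if (nrow(consensus) == 0L) {
    out <- data.frame(uid = character(0), coverage = integer(0),
                      v_segment = character(0), mutation_count = integer(0),
                      mutation_rate = numeric(0), mutated = logical(0),
                      isotype = character(0), sequence_key = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "tally") <- c(aligned = 0L, unaligned = 0L)
    return(out)
  }
  ufwd <- unique(consensus$forward_consensus)
  urev <- unique(consensus$reverse_consensus)
  vhit <- align_many(ufwd, refs$v, params)
  chit <- align_many(urev, refs$c, params)
  fi <- match(consensus$forward_consensus, ufwd)
  ri <- match(consensus$reverse_consensus, urev)
  ok <- vhit$hit[fi] & chit$hit[ri]
  out <- data.frame(uid = consensus$uid[ok],
                    coverage = consensus$coverage[ok],
                    v_segment = vhit$ref[fi][ok],
                    mutation_count = as.integer(vhit$mismatches[fi][ok]),
                    mutation_rate = (vhit$mismatches / vhit$aligned_length)[fi][ok],
                    isotype = chit$ref[ri][ok],
                    sequence_key = consensus$forward_consensus[ok],
                    stringsAsFactors = FALSE)
  out$mutated <- classify_mutated(out$mutation_rate, mutated_igm_min_rate)
  attr(out, "tally") <- c(aligned = sum(ok), unaligned = sum(!ok))
  out
}
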