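# Repertoire simulator: germline references, ground-truth repertoires and
# paired reads with molecular barcodes and sequencing error, so that every
# downstream stage can be validated against known truth.

ISOTYPES <- c("IgM", "IgD", "IgG", "IgA", "IgE")

#' Simulation configuration
#'
#' Parameters of the synthetic B-cell repertoire generator. A repertoire is a
#' set of clones; each clone has an isotype, an activation flag, a V-segment
#' derived sequence (possibly carrying somatic hypermutation) followed by a
#' random CDR3, and a molecule count drawn from a heavy-tailed (truncated
#' zipf) law whose exponent depends on activation. Each molecule carries a
#' unique 16-nt molecular barcode (UID) and is sequenced by one or more read
#' pairs with independent per-base substitution error.
#'
#' Defaults describe a plausible peripheral-blood IGH repertoire under
#' partial immunosuppression: mostly IgM with a class-switched minority, a
#' small activated fraction whose clones are expressed at higher levels,
#' somatic mutation rates of 2--8\% in mutated clones, and Illumina-grade
#' (about Q30) per-base error.
#'
#' @param n_clones Number of clones (>= 1).
#' @param isotype_probs Named probabilities over IgM, IgD, IgG, IgA, IgE;
#'   must sum to 1.
#' @param p_activated Probability that a clone is activated (activated
#'   clones use the heavier-tailed molecule-count law).
#' @param molecule_count_law List with `exponent_naive`,
#'   `exponent_activated` and `max_count`: molecule counts are drawn from
#'   P(k) proportional to k^-exponent on 1..max_count.
#' @param igm_mutated_prob Probability that an IgM clone carries V-segment
#'   hypermutation (class-switched clones always do).
#' @param mutation_rate_range Length-2 vector: per-base V mutation
#'   probability of a mutated clone is drawn uniformly from this range.
#' @param reads_per_molecule_law List with `model` ("one_plus_poisson" or
#'   "fixed") and either `mean_extra` (Poisson mean of extra reads) or
#'   `coverage` (fixed reads per molecule).
#' @param per_base_error Independent per-base substitution probability
#'   applied to every read base (UID and primer included).
#' @param cdr3_len Length of the random CDR3 region appended to the V
#'   payload.
#' @param read_len Optional fixed read length; when set, each read is
#'   truncated to `read_len` and construction fails if the payload is too
#'   short to fill it. `NULL` (default) emits the full construct.
#' @param seed RNG seed; all generator stages are deterministic given the
#'   seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_clones = 5400,
                       isotype_probs = c(IgM = 0.52, IgD = 0.03, IgG = 0.25,
                                         IgA = 0.17, IgE = 0.03),
                       p_activated = 0.05,
                       molecule_count_law = list(exponent_naive = 5,
                                                 exponent_activated = 2,
                                                 max_count = 30),
                       igm_mutated_prob = 0.15,
                       mutation_rate_range = c(0.02, 0.08),
                       reads_per_molecule_law = list(model = "one_plus_poisson",
                                                     mean_extra = 4),
                       per_base_error = 0.001,
                       cdr3_len = 40,
                       read_len = NULL,
                       seed = 1L) {
  stopifnot(length(n_clones) == 1L, n_clones >= 1)
  if (!setequal(names(isotype_probs), ISOTYPES)) {
    stop("isotype_probs must be named with exactly: ",
         paste(ISOTYPES, collapse = ", "))
  }
  isotype_probs <- isotype_probs[ISOTYPES]
  if (any(isotype_probs < 0) || abs(sum(isotype_probs) - 1) > 1e-8) {
    stop("isotype_probs must be non-negative and sum to 1")
  }
  for (p in list(p_activated, igm_mutated_prob, per_base_error)) {
    if (length(p) != 1L || p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  stopifnot(length(mutation_rate_range) == 2L,
            all(mutation_rate_range >= 0), all(mutation_rate_range <= 1),
            mutation_rate_range[1] <= mutation_rate_range[2])
  law <- molecule_count_law
  stopifnot(is.list(law), law$exponent_naive > 0, law$exponent_activated > 0,
            law$max_count >= 1)
  rl <- reads_per_molecule_law
  if (!rl$model %in% c("one_plus_poisson", "fixed")) {
    stop("reads_per_molecule_law$model must be 'one_plus_poisson' or 'fixed'")
  }
  if (rl$model == "one_plus_poisson") stopifnot(rl$mean_extra >= 0)
  if (rl$model == "fixed") stopifnot(rl$coverage >= 1)
  cfg <- list(n_clones = as.integer(n_clones), isotype_probs = isotype_probs,
              p_activated = p_activated, molecule_count_law = law,
              igm_mutated_prob = igm_mutated_prob,
              mutation_rate_range = mutation_rate_range,
              reads_per_molecule_law = rl, per_base_error = per_base_error,
              cdr3_len = as.integer(cdr3_len), read_len = read_len,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Repertoire simulation config:\n")
  cat("  clones:", x$n_clones, " activated fraction:", x$p_activated, "\n")
  cat("  isotype probs:",
      paste(sprintf("%s=%.2f", names(x$isotype_probs), x$isotype_probs),
            collapse = " "), "\n")
  cat("  per-base error:", x$per_base_error, " seed:", x$seed, "\n")
  invisible(x)
}

#' Generate germline V-segment and constant-region references
#'
#' Draws `n_v` random V-segment references of `v_len` bases and exactly five
#' constant-region references (one per isotype), plus the two fixed primer
#' sequences of the library construct. All references are required to be
#' mutually distinguishable: no pair may reach a local alignment with
#' identity >= `max_identity` over at least `min_len` aligned bases (the
#' same cutoffs the annotation stage uses). Offending sequences are redrawn;
#' if distinctness cannot be achieved the function fails.
#'
#' @param n_v Number of V references (>= 1).
#' @param v_len V reference length in bases (>= 60).
#' @param seed RNG seed; output is deterministic given the seed.
#' @param c_len Constant-region reference length.
#' @param primer_len Length of each primer.
#' @param max_identity,min_len Distinctness cutoffs (see Description).
#' @param max_tries Redraw attempts per sequence before failing.
#' @return An object of class `germline_refs`: list with `v` and `c`
#'   (named `DNAStringSet`s), `primers` (list of `v_fr3` and `c_region`
#'   sequences), and the lengths used.
#' @export
make_germline_refs <- function(n_v, v_len = 80, seed = 1L, c_len = 80,
                               primer_len = 20, max_identity = 0.80,
                               min_len = 40, max_tries = 50) {
  stopifnot(n_v >= 1, v_len >= 60, c_len >= 40, primer_len >= 10)
  with_seed(seed, {
    v <- random_dna(n_v, v_len)
    names(v) <- sprintf("V%02d", seq_len(n_v))
    cseq <- random_dna(5L, c_len)
    names(cseq) <- ISOTYPES
    all_refs <- c(v, cseq)
    params <- align_params(min_identity = max_identity, min_len = min_len)
    for (i in seq_along(all_refs)) {
      tries <- 0L
      repeat {
        others <- Biostrings::DNAStringSet(all_refs[-i])
        hit <- align_to_references(all_refs[[i]], others, params)
        if (inherits(hit, "no_hit")) break
        tries <- tries + 1L
        if (tries > max_tries) {
          stop("could not generate ", length(all_refs),
               " mutually distinct references of the requested lengths")
        }
        len_i <- if (i <= n_v) v_len else c_len
        all_refs[i] <- random_dna(1L, len_i)
      }
    }
    v <- all_refs[seq_len(n_v)]
    cseq <- all_refs[n_v + seq_len(5L)]
    primers <- list(v_fr3 = random_dna(1L, primer_len),
                    c_region = random_dna(1L, primer_len))
    refs <- list(v = Biostrings::DNAStringSet(v),
                 c = Biostrings::DNAStringSet(cseq),
                 primers = primers, v_len = as.integer(v_len),
                 c_len = as.integer(c_len),
                 primer_len = as.integer(primer_len))
    class(refs) <- "germline_refs"
    refs
  })
}

#' @export
print.germline_refs <- function(x, ...) {
  cat("Germline references:", length(x$v), "V segments (", x$v_len,
      "nt ),", length(x$c), "constant regions (", x$c_len, "nt )\n")
  invisible(x)
}

#' Sample a ground-truth repertoire
#'
#' Draws clones (isotype, activation, hypermutation, molecule count) and the
#' per-molecule 16-nt UIDs. Hypermutation is planted as substitutions at
#' interior V positions (positions 4 to v_len-3) so that local alignment
#' against the germline recovers the exact planted count. UID collisions
#' (two molecules sharing a barcode) are permitted and recorded.
#'
#' @param cfg A [sim_config()].
#' @param refs A [make_germline_refs()] result.
#' @return An object of class `true_repertoire`: list with `clones`
#'   (data.frame: clone_id, v_segment, isotype, activated, n_mutations,
#'   mutation_rate, sequence, molecule_count and a list column
#'   mut_positions), `molecules` (data.frame: clone_id, uid),
#'   `n_uid_collisions`, plus the `refs` and `cfg` used.
#' @export
sample_true_repertoire <- function(cfg, refs) {
  stopifnot(inherits(cfg, "sim_config"), inherits(refs, "germline_refs"))
  with_seed(cfg$seed, {
    n <- cfg$n_clones
    isotype <- sample(ISOTYPES, n, replace = TRUE, prob = cfg$isotype_probs)
    activated <- stats::runif(n) < cfg$p_activated
    law <- cfg$molecule_count_law
    counts <- integer(n)
    counts[activated] <- rzipf_trunc(sum(activated), law$exponent_activated,
                                     law$max_count)
    counts[!activated] <- rzipf_trunc(sum(!activated), law$exponent_naive,
                                      law$max_count)
    switched <- isotype != "IgM"
    mut_capable <- switched | (stats::runif(n) < cfg$igm_mutated_prob)
    rate <- ifelse(mut_capable,
                   stats::runif(n, cfg$mutation_rate_range[1],
                                cfg$mutation_rate_range[2]), 0)
    v_len <- refs$v_len
    v_idx <- sample(length(refs$v), n, replace = TRUE)
    ref_codes <- lapply(as.character(refs$v), function(s) utf8ToInt(s))
    eligible <- 4:(v_len - 3)  # keep alignment ends intact
    seq_codes <- matrix(0L, nrow = v_len, ncol = n)
    for (i in seq_len(n)) seq_codes[, i] <- ref_codes[[v_idx[i]]]
    mut_positions <- vector("list", n)
    hit_rows <- which(matrix(stats::runif(length(eligible) * n),
                             nrow = length(eligible)) <
                        rep(rate, each = length(eligible)), arr.ind = TRUE)
    if (nrow(hit_rows)) {
      pos <- eligible[hit_rows[, 1]]
      col <- hit_rows[, 2]
      cur <- seq_codes[cbind(pos, col)]
      idx <- match(cur, DNA_CODES)
      shift <- sample.int(3L, length(idx), replace = TRUE)
      seq_codes[cbind(pos, col)] <- DNA_CODES[((idx - 1L + shift) %% 4L) + 1L]
      mut_positions <- split(pos, factor(col, levels = seq_len(n)))
    } else {
      mut_positions <- rep(list(integer(0)), n)
    }
    n_mut <- lengths(mut_positions)
    cdr3 <- random_dna(n, cfg$cdr3_len)
    sequence <- paste0(code_matrix_to_seq(seq_codes), cdr3)
    clones <- data.frame(clone_id = seq_len(n),
                         v_segment = names(refs$v)[v_idx],
                         isotype = isotype, activated = activated,
                         n_mutations = as.integer(n_mut),
                         mutation_rate = n_mut / v_len,
                         sequence = sequence,
                         molecule_count = counts,
                         stringsAsFactors = FALSE)
    clones$mut_positions <- unname(mut_positions)
    total <- sum(counts)
    molecules <- data.frame(clone_id = rep(seq_len(n), counts),
                            uid = random_dna(total, 16L),
                            stringsAsFactors = FALSE)
    rep_out <- list(clones = clones, molecules = molecules,
                    n_uid_collisions = total - length(unique(molecules$uid)),
                    refs = refs, cfg = cfg)
    class(rep_out) <- "true_repertoire"
    rep_out
  })
}

#' @export
print.true_repertoire <- function(x, ...) {
  cat("True repertoire:", nrow(x$clones), "clones,",
      nrow(x$molecules), "molecules,",
      x$n_uid_collisions, "UID collision(s)\n")
  invisible(x)
}

#' Synthesize paired reads from a true repertoire
#'
#' For each molecule, draws a number of read pairs from the configured
#' coverage law (always >= 1) and emits the library construct: read 1 is the
#' first 8 nt of the UID, the V-FR3 primer, then the V+CDR3 payload; read 2
#' is the last 8 nt of the UID, the constant-region primer, then the
#' constant-region payload of the clone's isotype. Every base (UID and
#' primer included) is flipped independently with `per_base_error`.
#' Qualities are constant ("I", Phred+33 Q40). Deterministic given the
#' config seed.
#'
#' @param rep A [sample_true_repertoire()] result.
#' @param cfg A [sim_config()]; defaults to the one stored in `rep`.
#' @return data.frame with columns id, molecule (row in `rep$molecules`),
#'   seq1, qual1, seq2, qual2.
#' @export
synthesize_reads <- function(rep, cfg = rep$cfg) {
  stopifnot(inherits(rep, "true_repertoire"))
  refs <- rep$refs
  with_seed(cfg$seed + 1L, {
    mol <- rep$molecules
    n_mol <- nrow(mol)
    rl <- cfg$reads_per_molecule_law
    coverage <- switch(rl$model,
                       one_plus_poisson = 1L + stats::rpois(n_mol, rl$mean_extra),
                       fixed = rep(as.integer(rl$coverage), n_mol))
    ridx <- rep(seq_len(n_mol), coverage)
    clone <- rep$clones[mol$clone_id[ridx], ]
    uid <- mol$uid[ridx]
    c_payload <- as.character(refs$c)[clone$isotype]
    seq1 <- paste0(substr(uid, 1L, 8L), refs$primers$v_fr3, clone$sequence)
    seq2 <- paste0(substr(uid, 9L, 16L), refs$primers$c_region, c_payload)
    if (!is.null(cfg$read_len)) {
      need <- cfg$read_len
      if (any(nchar(seq1) < need) || any(nchar(seq2) < need)) {
        stop("payload shorter than the requested read length (", need, ")")
      }
      seq1 <- substr(seq1, 1L, need)
      seq2 <- substr(seq2, 1L, need)
    }
    seq1 <- inject_errors(seq1, cfg$per_base_error)
    seq2 <- inject_errors(seq2, cfg$per_base_error)
    data.frame(id = sprintf("M%06d_R%02d", ridx,
                            sequence(tabulate(ridx, n_mol))),
               molecule = ridx,
               seq1 = seq1, qual1 = strrep("I", nchar(seq1)),
               seq2 = seq2, qual2 = strrep("I", nchar(seq2)),
               stringsAsFactors = FALSE)
  })
}

#' Ground-truth ABS level of a simulated repertoire
#'
#' Applies the activated-B-cell-sequence definition to the truth table:
#' clones expressed by at least `highly_expressed_min` molecules whose
#' isotype is class-switched (IgA/IgD/IgE/IgG) or that are mutated IgM
#' (realised mutation rate >= `mutated_igm_min_rate`), counted and divided
#' by the total number of molecules. With `depth` set, the truth table is
#' first subsampled to that many molecules (without replacement) so that the
#' value is comparable to a pipeline estimate at fixed sequencing depth.
#'
#' @param rep A [sample_true_repertoire()] result.
#' @param highly_expressed_min Minimum molecule count of a highly expressed
#'   clone.
#' @param mutated_igm_min_rate Mutation-rate threshold for "mutated IgM".
#' @param depth Optional subsampling depth (molecules).
#' @param seed Seed for the optional subsampling.
#' @return ABS level as a single fraction.
#' @export
true_abs_level <- function(rep, highly_expressed_min = 2,
                           mutated_igm_min_rate = 0.01, depth = NULL,
                           seed = 1L) {
  stopifnot(inherits(rep, "true_repertoire"))
  cl <- rep$clones
  counts <- cl$molecule_count
  total <- sum(counts)
  if (total < 1) stop("repertoire has no molecules; ABS level undefined")
  if (!is.null(depth)) {
    if (depth > total) stop("depth exceeds the number of molecules")
    ids <- rep(seq_len(nrow(cl)), counts)
    keep <- with_seed(seed, sample(ids, depth))
    counts <- tabulate(keep, nbins = nrow(cl))
    total <- depth
  }
  qualifies <- cl$isotype != "IgM" | cl$mutation_rate >= mutated_igm_min_rate
  sum(counts >= highly_expressed_min & qualifies) / total
}

#' Write the ground-truth clone table as TSV
#'
#' @param rep A [sample_true_repertoire()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(rep, path) {
  stopifnot(inherits(rep, "true_repertoire"))
  cl <- rep$clones
  uid_by_clone <- split(rep$molecules$uid, rep$molecules$clone_id)
  out <- data.frame(clone_id = cl$clone_id, v_segment = cl$v_segment,
                    isotype = cl$isotype, activated = cl$activated,
                    n_mutations = cl$n_mutations,
                    mutation_rate = cl$mutation_rate,
                    molecule_count = cl$molecule_count,
                    sequence = cl$sequence,
                    uids = vapply(as.character(cl$clone_id), function(k)
                      paste(uid_by_clone[[k]] %||% character(0),
                            collapse = ","), character(1)),
                    stringsAsFactors = FALSE)
  write_tsv_commented(out, path,
                      comment = "ground-truth clone table (counts in molecules)")
  invisible(path)
}
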