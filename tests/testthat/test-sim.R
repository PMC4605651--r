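# Simulator: reference generation, repertoire sampling, read synthesis and
# the ground-truth ABS definition.

test_that("germline references are reproducible and mutually distinct", {
  r1 <- make_germline_refs(n_v = 4, v_len = 120, seed = 1)
  r2 <- make_germline_refs(n_v = 4, v_len = 120, seed = 1)
  expect_identical(as.character(r1$v), as.character(r2$v))
  expect_identical(as.character(r1$c), as.character(r2$c))
  expect_identical(r1$primers, r2$primers)
  expect_length(r1$v, 4)
  expect_named(r1$c, c("IgM", "IgD", "IgG", "IgA", "IgE"))
  # brute-force pairwise check: no cross-reference local alignment reaches
  # 80% identity over >= 40 columns; verify via the exhaustive
  # Smith-Waterman oracle that no pair scores as high as a 40-column 80%
  # identity alignment would (0.8*40 matches - 0.2*40 mismatches = 24)
  all_refs <- c(as.character(r1$v), as.character(r1$c))
  for (i in seq_along(all_refs)) {
    for (j in seq_along(all_refs)) {
      if (i < j) {
        expect_lt(sw_oracle_score(all_refs[i], all_refs[j]), 24)
      }
    }
  }
})

test_that("single-reference case annotates error-free reads to it", {
  refs <- make_germline_refs(n_v = 1, v_len = 120, seed = 7)
  cfg <- sim_config(n_clones = 30, per_base_error = 0,
                    reads_per_molecule_law = list(model = "fixed",
                                                  coverage = 1), seed = 7)
  rep <- sample_true_repertoire(cfg, refs)
  reads <- synthesize_reads(rep, cfg)
  ex <- extract_uid_and_trim(reads$seq1, reads$seq2, reads$qual1,
                             reads$qual2, primers = refs$primers)
  mol <- annotate_molecules(build_consensus_table(ex), refs)
  expect_true(all(mol$v_segment == names(refs$v)[1]))
})

test_that("impossible distinctness request fails explicitly", {
  # an identity ceiling of zero can never be met: any shared base is a hit
  expect_error(make_germline_refs(n_v = 3, v_len = 60, seed = 1,
                                  max_identity = 0, min_len = 1,
                                  max_tries = 3),
               "distinct")
})

test_that("repertoire sampling is seeded and honours degenerate configs", {
  refs <- tiny_refs()
  cfg <- sim_config(n_clones = 100, seed = 5)
  r1 <- sample_true_repertoire(cfg, refs)
  r2 <- sample_true_repertoire(cfg, refs)
  expect_identical(r1$clones, r2$clones)
  expect_identical(r1$molecules, r2$molecules)
  expect_equal(sum(r1$clones$molecule_count), nrow(r1$molecules))

  # all-naive limit: IgM only, no activation, no IgM mutation -> true ABS 0
  cfg0 <- sim_config(n_clones = 50, p_activated = 0, igm_mutated_prob = 0,
                     isotype_probs = c(IgM = 1, IgD = 0, IgG = 0, IgA = 0,
                                       IgE = 0), seed = 3)
  r0 <- sample_true_repertoire(cfg0, refs)
  expect_true(all(r0$clones$isotype == "IgM"))
  expect_true(all(r0$clones$n_mutations == 0))
  expect_equal(true_abs_level(r0), 0)

  # singleton limit: every clone has one molecule -> no highly expressed
  cfg1 <- sim_config(n_clones = 50,
                     molecule_count_law = list(exponent_naive = 5,
                                               exponent_activated = 5,
                                               max_count = 1), seed = 4)
  rs <- sample_true_repertoire(cfg1, refs)
  expect_true(all(rs$clones$molecule_count == 1))
  expect_equal(true_abs_level(rs), 0)
})

test_that("read synthesis conserves molecules and is byte-deterministic", {
  refs <- tiny_refs()
  cfg <- sim_config(n_clones = 60, per_base_error = 0,
                    reads_per_molecule_law = list(model = "fixed",
                                                  coverage = 1), seed = 9)
  rep <- sample_true_repertoire(cfg, refs)
  reads <- synthesize_reads(rep, cfg)
  expect_equal(nrow(reads), nrow(rep$molecules))
  # noiseless identity: payloads equal the true sequences
  cl <- rep$clones[rep$molecules$clone_id[reads$molecule], ]
  expect_identical(substring(reads$seq1, 8 + 20 + 1),
                   cl$sequence)
  expect_identical(substring(reads$seq1, 1, 8),
                   substr(rep$molecules$uid[reads$molecule], 1, 8))
  # conservation under variable coverage
  cfgv <- sim_config(n_clones = 60, seed = 9)
  repv <- sample_true_repertoire(cfgv, refs)
  rv1 <- synthesize_reads(repv, cfgv)
  rv2 <- synthesize_reads(repv, cfgv)
  expect_identical(rv1, rv2)
  expect_true(all(tabulate(rv1$molecule, nrow(repv$molecules)) >= 1))

  # payload shorter than a requested fixed read length fails
  cfg_short <- cfg
  cfg_short$read_len <- 500L
  expect_error(synthesize_reads(rep, cfg_short), "shorter")
})

test_that("injected error rate matches the binomial expectation", {
  refs <- tiny_refs()
  cfg <- sim_config(n_clones = 400, per_base_error = 0.01,
                    reads_per_molecule_law = list(model = "fixed",
                                                  coverage = 1), seed = 21)
  rep <- sample_true_repertoire(cfg, refs)
  clean_cfg <- cfg
  clean_cfg$per_base_error <- 0
  clean <- synthesize_reads(rep, clean_cfg)
  noisy <- synthesize_reads(rep, cfg)
  bases <- sum(nchar(clean$seq1)) + sum(nchar(clean$seq2))
  expect_gt(bases, 1e5)
  mism <- sum(mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)),
                     c(clean$seq1, clean$seq2), c(noisy$seq1, noisy$seq2)))
  expected <- bases * 0.01
  sd3 <- 3 * sqrt(bases * 0.01 * 0.99)
  expect_lt(abs(mism - expected), sd3)
})

test_that("true ABS level implements the definition", {
  refs <- tiny_refs()
  cfg <- sim_config(n_clones = 4, seed = 2)
  rep <- sample_true_repertoire(cfg, refs)
  # hand-built truth: 1 IgG clone with 3 molecules + 3 unmutated IgM
  # singletons -> 1 qualifying highly expressed clone / 6 molecules
  rep$clones <- data.frame(clone_id = 1:4, v_segment = "V01",
                           isotype = c("IgG", "IgM", "IgM", "IgM"),
                           activated = FALSE, n_mutations = 0L,
                           mutation_rate = 0,
                           sequence = sprintf("S%d", 1:4),
                           molecule_count = c(3L, 1L, 1L, 1L),
                           stringsAsFactors = FALSE)
  rep$molecules <- data.frame(clone_id = rep(1:4, c(3, 1, 1, 1)),
                              uid = sprintf("U%02d", 1:6))
  expect_equal(true_abs_level(rep), 1 / 6)
  # all unmutated IgM regardless of count -> 0
  rep$clones$isotype <- "IgM"
  expect_equal(true_abs_level(rep), 0)
})
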