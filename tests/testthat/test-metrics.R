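# Depth subsampling, clone collapsing, ABS level, histogram, pooling.

test_that("subsampling is exact at the boundary and seeded above it", {
  mol <- make_molecules(sprintf("S%04d", 1:4000), rep("IgM", 4000),
                        rep(FALSE, 4000))
  expect_identical(subsample_molecules(mol, depth = 4000), mol)
  # below depth -> discarded with count
  d <- subsample_molecules(mol[1:3999, ], depth = 4000, sample_id = "X")
  expect_s3_class(d, "sample_discarded")
  expect_equal(d$n_aligned, 3999)
  # above depth -> deterministic subset per seed
  big <- make_molecules(sprintf("S%05d", 1:10000), rep("IgM", 10000),
                        rep(FALSE, 10000))
  s1 <- subsample_molecules(big, depth = 4000, seed = 7)
  s2 <- subsample_molecules(big, depth = 4000, seed = 7)
  s3 <- subsample_molecules(big, depth = 4000, seed = 8)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 4000)
  expect_false(identical(s1, s3))
  expect_error(subsample_molecules(big, depth = 0), "depth")
})

test_that("clone collapsing combines identical sequence+isotype", {
  mol <- make_molecules(c("AAA", "AAA", "AAA", "CCC"),
                        c("IgG", "IgG", "IgG", "IgM"),
                        c(FALSE, TRUE, FALSE, FALSE))
  cl <- collapse_clones(mol)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$molecule_count[cl$sequence_key == "AAA"], 3)
  expect_true(cl$mutated[cl$sequence_key == "AAA"])  # OR over members
  # same sequence, different isotype -> distinct clones
  mol2 <- make_molecules(c("AAA", "AAA"), c("IgG", "IgA"), c(FALSE, FALSE))
  expect_equal(nrow(collapse_clones(mol2)), 2)
  # majority V segment with name-order tie-break
  mol3 <- make_molecules(rep("AAA", 4), rep("IgG", 4), rep(FALSE, 4),
                         v_segment = c("V02", "V02", "V01", "V03"))
  expect_equal(collapse_clones(mol3)$v_segment, "V02")
  mol4 <- make_molecules(rep("AAA", 2), rep("IgG", 2), rep(FALSE, 2),
                         v_segment = c("V03", "V01"))
  expect_equal(collapse_clones(mol4)$v_segment, "V01")
})

test_that("ABS level implements the published definition", {
  # printed pooled ratio: 1,296 qualifying highly expressed clones over
  # 19,845 molecules
  n_he_qual <- 1296
  cl <- make_clones(isotype = c(rep("IgG", n_he_qual),
                                rep("IgM", 19845 - 2 * n_he_qual)),
                    molecule_count = c(rep(2, n_he_qual),
                                       rep(1, 19845 - 2 * n_he_qual)),
                    mutated = FALSE)
  expect_equal(round(abs_level(cl), 3), 0.065)
  # singletons only -> 0
  cl0 <- make_clones(rep("IgG", 5), rep(1, 5), rep(FALSE, 5))
  expect_equal(abs_level(cl0), 0)
  # hand enumeration: IgG x3 + mutated IgM x2 + unmutated IgM x2 +
  # 3 unmutated IgM singletons = 2 qualifying / 10 molecules
  cl1 <- make_clones(isotype = c("IgG", "IgM", "IgM", "IgM", "IgM", "IgM"),
                     molecule_count = c(3, 2, 2, 1, 1, 1),
                     mutated = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(abs_level(cl1), 0.2)
  expect_error(abs_level(cl1[0, ]), "empty")
  # order invariance
  perm <- cl1[c(4, 2, 6, 1, 3, 5), ]
  expect_equal(abs_level(perm), abs_level(cl1))
})

test_that("expression histogram partitions the clone table", {
  cl <- make_clones(isotype = c("IgG", "IgM", "IgM", "IgA"),
                    molecule_count = c(1, 3, 3, 1),
                    mutated = c(FALSE, TRUE, FALSE, FALSE))
  h <- expression_histogram(cl)
  expect_equal(sum(h$n_clones), nrow(cl))
  expect_setequal(h$isotype_class[h$molecule_count == 3],
                  c("IgM_mutated", "IgM_unmutated"))
  expect_equal(h$n_clones[h$molecule_count == 1 & h$isotype_class == "IgG"], 1)
})

test_that("pooling sums molecules without merging clones", {
  cl <- make_clones(isotype = c("IgG", "IgM"), molecule_count = c(3, 1),
                    mutated = c(FALSE, FALSE))
  pooled <- pool_samples(list(cl, cl), c("A", "B"))
  p <- attr(pooled, "pooled")
  expect_equal(p$total_molecules, 8)
  expect_equal(p$abs_numerator, 2)
  expect_equal(nrow(pooled), 4)  # identical clones kept distinct per sample
  # pooled ABS equals the molecule-weighted combination of samples
  cl2 <- make_clones(isotype = c("IgA", "IgM"), molecule_count = c(2, 4),
                     mutated = c(FALSE, FALSE))
  p2 <- attr(pool_samples(list(cl, cl2), c("A", "B")), "pooled")
  expect_equal(p2$abs_numerator / p2$total_molecules,
               (1 + 1) / (4 + 6))
})

test_that("repertoire summaries assert their invariants", {
  cl <- make_clones(isotype = c("IgG", "IgM", "IgM"),
                    molecule_count = c(2, 1, 1),
                    mutated = c(FALSE, FALSE, FALSE))
  s <- repertoire_summary(cl, "S1")
  expect_equal(s$total_molecules, 4)
  expect_equal(s$n_sequences, 3)
  expect_equal(s$n_highly_expressed, 1)
  expect_equal(s$abs_numerator, 1)
  expect_equal(s$abs_level, 0.25)
  expect_output(print(s), "ABS level")
})

test_that("noiseless full-depth pipeline reproduces the truth table", {
  refs <- tiny_refs()
  cfg <- sim_config(n_clones = 500, per_base_error = 0, seed = 37)
  rep <- sample_true_repertoire(cfg, refs)
  expect_equal(rep$n_uid_collisions, 0)
  reads <- synthesize_reads(rep, cfg)
  ex <- extract_uid_and_trim(reads$seq1, reads$seq2, reads$qual1,
                             reads$qual2, primers = refs$primers)
  mol <- annotate_molecules(build_consensus_table(ex), refs)
  cl <- collapse_clones(mol)   # full depth, no subsampling
  truth <- rep$clones
  truth_key <- paste(truth$sequence, truth$isotype)
  cl_key <- paste(cl$sequence_key, cl$isotype)
  expect_setequal(cl_key, truth_key)
  idx <- match(cl_key, truth_key)
  expect_equal(cl$molecule_count, truth$molecule_count[idx])
  expect_equal(cl$v_segment, truth$v_segment[idx])
  expect_equal(cl$mutated, truth$n_mutations[idx] >= 1)
  # and the pipeline ABS equals the ground-truth ABS exactly
  expect_equal(abs_level(cl), true_abs_level(rep))
})
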