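test_that("generation is deterministic in the seed", {
  a <- generate_pair(seed = 11, length = 25)
  b <- generate_pair(seed = 11, length = 25)
  expect_identical(a$msa_q$seqs, b$msa_q$seqs)
  expect_identical(a$msa_t$seqs, b$msa_t$seqs)
  expect_identical(a$true_alignment, b$true_alignment)
  expect_identical(a$ann_t$phi, b$ann_t$phi)
  c_ <- generate_pair(seed = 12, length = 25)
  expect_false(identical(a$msa_q$seqs, c_$msa_q$seqs))
})

test_that("zero divergence and indels give the identity alignment", {
  sp <- generate_pair(seed = 2, length = 20, divergence = 0,
                      indel_rate = 0, mutation_rate = 0)
  expect_identical(unname(aligned_pairs(sp$true_alignment)),
                   unname(cbind(1:20, 1:20)))
  expect_identical(sp$msa_q$seqs[1, ], sp$msa_t$seqs[1, ])
  # consensus rows of the reference FASTA are equal too
  f <- tempfile(); dir.create(f)
  write_synthetic_pair(sp, f)
  ref <- read_reference_alignment(file.path(f, "reference.fasta"))
  expect_identical(nrow(ref$pairs), 20L)
})

test_that("true alignments always satisfy the pairwise invariants", {
  for (seed in 1:10) {
    sp <- generate_pair(seed = seed, length = 30, indel_rate = 0.15)
    expect_s3_class(validate_alignment(sp$true_alignment),
                    "pairwise_alignment")
    expect_true(all(sp$true_alignment$state == "MM"))
  }
})

test_that("planted coupling dominates the MI matrix of the family", {
  sp <- generate_pair(seed = 5, length = 20, n_seq = 64, divergence = 0,
                      indel_rate = 0, mutation_rate = 0.5,
                      coupled_pairs = cbind(4, 12), coupling_strength = 1)
  mi <- mutual_information_matrix(sp$msa_q, pseudocount = 0)
  top <- which(mi == max(mi), arr.ind = TRUE)[1, ]
  expect_identical(sort(unname(top)), c(4L, 12L))
  expect_identical(unclass(sp$partners_q)[c(4, 12)], c(12L, 4L))
})

test_that("degenerate indel parameters raise a generation error", {
  expect_error(generate_pair(seed = 1, length = 5, indel_rate = 1),
               "degenerate")
  expect_error(generate_pair(seed = 1, length = 3), "length")
  expect_error(generate_pair(seed = 1, divergence = 1.5), "rates")
})

test_that("fixture files round-trip through the package readers", {
  sp <- generate_pair(seed = 9, length = 25,
                      coupled_pairs = cbind(c(3, 8), c(15, 20)))
  d <- tempfile(); dir.create(d)
  write_synthetic_pair(sp, d)
  m <- read_msa(file.path(d, "query.fasta"))
  expect_identical(m$seqs, sp$msa_q$seqs)
  ann <- read_annotation_table(file.path(d, "query.ann"))
  expect_identical(ann$ss, sp$ann_q$ss)
  k <- read_partner_map(file.path(d, "query.partners"),
                        length = sp$msa_q$n_col)
  expect_identical(unclass(k), unclass(sp$partners_q))
  ref <- read_reference_alignment(file.path(d, "reference.fasta"))
  expect_identical(unname(ref$pairs), unname(sp$reference$pairs))
})

test_that("structural weights recover planted homology (directional)", {
  # scaled-down version of the acceptance criterion: annotations agree on
  # truly aligned columns, so structural terms should not hurt mean SP
  sp_with <- numeric(10); sp_without <- numeric(10)
  w_str <- scoring_weights(w_sa = 0.72, w_tors = 0.4, w_ec = 0)
  w_null <- scoring_weights(w_sa = 0, w_tors = 0, w_ec = 0)
  for (s in 1:10) {
    sp <- generate_pair(seed = 1000 + s, length = 40, divergence = 0.45,
                        indel_rate = 0.08, annotation_agreement = 0.95)
    qp <- build_profile(sp$msa_q, name = "q", annotation = sp$ann_q)
    tp <- build_profile(sp$msa_t, name = "t", annotation = sp$ann_t)
    a1 <- mac_align(forward_backward(qp, tp, w_str))$alignment
    a0 <- mac_align(forward_backward(qp, tp, w_null))$alignment
    sp_with[s] <- sp_score(a1, sp$reference)
    sp_without[s] <- sp_score(a0, sp$reference)
  }
  expect_gte(mean(sp_with), mean(sp_without))
})
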