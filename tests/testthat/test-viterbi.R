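test_that("single matchable column aligns with the Eq.-style score", {
  ubg <- uniform_bg()
  q <- one_hot_profile("A", name = "q")
  t <- one_hot_profile("A", name = "t")
  w <- scoring_weights(w_ss = 0, w_sa = 0, w_tors = 0, w_ec = 0, s_shift = 0)
  v <- viterbi_align(q, t, w, ubg)
  expect_equal(v$score, log2(20), tolerance = 1e-12)
  expect_identical(unname(aligned_pairs(v$alignment)), matrix(c(1L, 1L), 1))
  expect_identical(v$alignment$state, "MM")
})

test_that("uniformly negative match scores give the empty local alignment", {
  set.seed(14)
  q <- random_profile(5); t <- random_profile(5)
  w <- scoring_weights(s_shift = -50, mode = "local")
  v <- suppressWarnings(viterbi_align(q, t, w))
  expect_identical(nrow(v$alignment), 0L)
  expect_identical(v$score, 0)
})

test_that("viterbi matches the exhaustive chain oracle (property)", {
  set.seed(1234)
  bg <- default_background()
  for (k in 1:30) {
    for (mode in c("local", "global")) {
      lo <- if (mode == "global") 2L else 1L
      q <- random_profile(sample(lo:6, 1))
      t <- random_profile(sample(lo:6, 1))
      w <- scoring_weights(mode = mode)
      v <- suppressWarnings(viterbi_align(q, t, w, bg))
      expect_equal(v$score, oracle_viterbi_score(q, t, w, bg),
                   tolerance = 1e-9)
    }
  }
})

test_that("reported S_LSO equals the recomputed score of the path", {
  set.seed(77)
  bg <- default_background()
  for (k in 1:10) {
    q <- random_profile(sample(3:8, 1))
    t <- random_profile(sample(3:8, 1))
    for (mode in c("local", "global")) {
      w <- scoring_weights(mode = mode)
      v <- suppressWarnings(viterbi_align(q, t, w, bg))
      if (nrow(v$alignment) > 0)
        expect_equal(v$score,
                     score_alignment_path(v$alignment, q, t, w, bg),
                     tolerance = 1e-9)
    }
  }
})

test_that("score is invariant under swapping query and template", {
  set.seed(31)
  bg <- default_background()
  for (k in 1:8) {
    q <- random_profile(sample(2:7, 1))
    t <- random_profile(sample(2:7, 1))
    for (mode in c("local", "global")) {
      w <- scoring_weights(mode = mode)
      a <- suppressWarnings(viterbi_align(q, t, w, bg))
      b <- suppressWarnings(viterbi_align(t, q, w, bg))
      expect_equal(a$score, b$score, tolerance = 1e-9)
      # paths agree after exchanging roles (MI <-> IM, DG <-> GD)
      swap <- c(MM = "MM", MI = "IM", IM = "MI", DG = "GD", GD = "DG")
      expect_identical(unname(swap[a$alignment$state]), b$alignment$state)
      expect_identical(a$alignment$qpos, b$alignment$tpos)
    }
  }
})

test_that("global self-alignment with a dominant diagonal is the identity", {
  q <- one_hot_profile(c("A", "C", "D", "E", "F", "G"), name = "self")
  w <- scoring_weights(w_ss = 0, w_sa = 0, w_tors = 0, mode = "global",
                       s_shift = 0)
  v <- viterbi_align(q, q, w, uniform_bg())
  expect_identical(unname(aligned_pairs(v$alignment)),
                   unname(cbind(1:6, 1:6)))
  expect_equal(v$score, 6 * log2(20) + 10 * log2(0.97), tolerance = 1e-9)
})

test_that("structural weights reduce to the baselines when zeroed", {
  set.seed(99)
  bg <- default_background()
  q <- random_profile(6); t <- random_profile(6)
  w_base <- scoring_weights(w_ss = 0, w_sa = 0, w_tors = 0, w_ec = 0)
  v_base <- viterbi_align(q, t, w_base, bg)
  # strip annotations: pure-profile run must be bit-identical
  q2 <- q; q2$annotation <- NULL
  t2 <- t; t2$annotation <- NULL
  v_plain <- viterbi_align(q2, t2, w_base, bg)
  expect_identical(v_base$score, v_plain$score)
  expect_identical(v_base$alignment$state, v_plain$alignment$state)
})
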