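test_that("single-column pair in global mode has posterior 1", {
  q <- one_hot_profile("A"); t <- one_hot_profile("A")
  w <- scoring_weights(w_ss = 0, w_sa = 0, w_tors = 0, mode = "global")
  fb <- forward_backward(q, t, w, uniform_bg())
  expect_equal(fb$posterior[1, 1], 1, tolerance = 1e-12)
})

test_that("posteriors match the exhaustive partition oracle (property)", {
  set.seed(4321)
  bg <- default_background()
  for (k in 1:15) {
    for (mode in c("local", "global")) {
      lo <- if (mode == "global") 2L else 1L
      q <- random_profile(sample(lo:5, 1))
      t <- random_profile(sample(lo:5, 1))
      w <- scoring_weights(mode = mode)
      p_min <- if (mode == "local") 1 else 0
      fb <- suppressWarnings(forward_backward(q, t, w, bg))
      o <- oracle_posteriors(q, t, w, bg, p_min)
      expect_equal(fb$posterior, o$posterior, tolerance = 1e-9)
      expect_equal(2^fb$logZ_forward, o$Z, tolerance = 1e-9 * o$Z)
    }
  }
})

test_that("forward and backward partition functions agree", {
  set.seed(55)
  bg <- default_background()
  for (k in 1:10) {
    q <- random_profile(sample(2:20, 1))
    t <- random_profile(sample(2:20, 1))
    for (mode in c("local", "global")) {
      fb <- suppressWarnings(forward_backward(q, t, scoring_weights(mode = mode), bg))
      expect_equal(fb$logZ_forward, fb$logZ_backward,
                   tolerance = 1e-9 * max(1, abs(fb$logZ_forward)))
    }
  }
})

test_that("posterior rows and columns are subnormalized", {
  set.seed(66)
  bg <- default_background()
  for (k in 1:20) {
    q <- random_profile(sample(2:30, 1))
    t <- random_profile(sample(2:30, 1))
    fb <- suppressWarnings(forward_backward(q, t, scoring_weights(), bg))
    expect_true(all(fb$posterior >= 0 & fb$posterior <= 1))
    expect_true(all(rowSums(fb$posterior) <= 1 + 1e-6))
    expect_true(all(colSums(fb$posterior) <= 1 + 1e-6))
  }
})

test_that("MAC recursion reproduces the hand-computed 2x2 case", {
  P <- matrix(c(0.9, 0.05, 0.05, 0.9), 2, 2)
  m <- mac_align(P, mact = 0.3501)
  expect_equal(m$best_score, 2 * (0.9 - 0.3501), tolerance = 1e-12)
  expect_identical(unname(aligned_pairs(m$alignment)),
                   unname(cbind(1:2, 1:2)))
})

test_that("MAC with all posteriors below mact gives an empty alignment", {
  P <- matrix(0.1, 3, 4)
  m <- mac_align(P, mact = 0.3501)
  expect_identical(nrow(m$alignment), 0L)
  expect_equal(m$best_score, 0)
})

test_that("path posterior sum minus penalties equals the best AS value", {
  set.seed(88)
  bg <- default_background()
  for (k in 1:10) {
    q <- random_profile(sample(4:15, 1))
    t <- random_profile(sample(4:15, 1))
    fb <- suppressWarnings(forward_backward(q, t, scoring_weights(), bg))
    for (mact in c(0.1, 0.3501, 0.7)) {
      m <- mac_align(fb, mact = mact)
      aln <- m$alignment
      n_mm <- sum(aln$state == "MM")
      n_gap <- sum(aln$state != "MM")
      expect_equal(sum(aln$score[aln$state == "MM"]) -
                     mact * n_mm - (mact / 2) * n_gap,
                   m$best_score, tolerance = 1e-9)
    }
  }
})

test_that("aligned-pair count is non-increasing in mact", {
  set.seed(101)
  bg <- default_background()
  for (k in 1:10) {
    q <- random_profile(sample(5:20, 1))
    t <- random_profile(sample(5:20, 1))
    fb <- suppressWarnings(forward_backward(q, t, scoring_weights(), bg))
    counts <- vapply(c(0, 0.1, 0.3501, 0.7, 0.9), function(mact) {
      sum(mac_align(fb, mact = mact)$alignment$state == "MM")
    }, numeric(1))
    expect_false(is.unsorted(rev(counts)))
  }
})

test_that("AS matrices are elementwise monotone decreasing in mact", {
  set.seed(77)
  P <- matrix(runif(30), 5, 6)
  as_lo <- mac_align(P, mact = 0.1)$AS
  as_hi <- mac_align(P, mact = 0.5)$AS
  expect_true(all(as_hi <= as_lo + 1e-12))
  expect_true(all(as_lo >= 0))
})
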