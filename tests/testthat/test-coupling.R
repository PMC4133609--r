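test_that("MI analytics: independence gives 0, perfect covariation ln 2", {
  # all four symbol combinations equally frequent -> independent columns
  m_ind <- msa(c("AA", "AC", "CA", "CC"))
  mi <- mutual_information_matrix(m_ind, pseudocount = 0)
  expect_lt(abs(mi[1, 2]), 1e-12)
  # half A/A, half C/C -> MI = ln 2 (natural log)
  m_cov <- msa(c("AA", "AA", "CC", "CC"))
  mi <- mutual_information_matrix(m_cov, pseudocount = 0)
  expect_equal(mi[1, 2], log(2), tolerance = 1e-12)
})

test_that("MI matrices are symmetric and non-negative (property)", {
  set.seed(24)
  for (k in 1:8) {
    m <- random_msa(sample(3:10, 1), sample(4:9, 1))
    for (pc in c(0, NULL)) {
      mi <- mutual_information_matrix(m, pseudocount = pc)
      expect_equal(mi, t(mi), tolerance = 1e-12)
      expect_true(all(mi >= -1e-12))
    }
    mi_pc <- mutual_information_matrix(m)  # default pseudocount
    expect_true(all(mi_pc >= -1e-12))
  }
})

test_that("gaps count as the 21st symbol", {
  m <- msa(c("A-", "A-", "CA", "CA"))
  mi <- mutual_information_matrix(m, pseudocount = 0)
  expect_equal(mi[1, 2], log(2), tolerance = 1e-12)
})

test_that("single-sequence MSA warns and returns zeros", {
  expect_warning(mi <- mutual_information_matrix(msa("ACD")), "single")
  expect_true(all(mi == 0))
})

test_that("select_partners ranks, separates and deduplicates", {
  L <- 12
  mi <- matrix(0, L, L)
  expect_true(all(is.na(select_partners(mi, n_pairs = 0))))

  mi[3, 9] <- mi[9, 3] <- 5
  k <- select_partners(mi, n_pairs = 3, min_separation = 5)
  expect_identical(unclass(k)[c(3, 9)], c(9L, 3L))
  expect_identical(sum(!is.na(k)), 2L)

  # equal values: lexicographically smaller pair wins; columns used once
  mi2 <- matrix(0, L, L)
  mi2[2, 8] <- mi2[8, 2] <- 1
  mi2[2, 9] <- mi2[9, 2] <- 1
  k2 <- select_partners(mi2, n_pairs = 1, min_separation = 5)
  expect_identical(unclass(k2)[2], 8L)
  expect_true(is.na(k2[9]))

  # separation filter removes near-diagonal pairs
  mi3 <- matrix(0, L, L)
  mi3[4, 5] <- mi3[5, 4] <- 10
  mi3[1, 7] <- mi3[7, 1] <- 1
  k3 <- select_partners(mi3, n_pairs = 2, min_separation = 5)
  expect_true(is.na(k3[4]))
  expect_identical(unclass(k3)[1], 7L)
})

test_that("partner maps round-trip through the two-column text format", {
  k <- structure(c(9L, NA, NA, 11L, rep(NA, 4), 1L, NA, 4L, NA),
                 class = "partner_map")
  f <- tempfile()
  write_partner_map(k, f)
  expect_identical(unclass(read_partner_map(f, 12)), unclass(k))
})

test_that("EC traceback reduces to MAC when unarmed", {
  set.seed(47)
  bg <- default_background()
  q <- random_profile(8); t <- random_profile(8)
  fb <- suppressWarnings(forward_backward(q, t, scoring_weights(), bg))
  m <- mac_align(fb, mact = 0.3501)
  # w_ec = 0 and empty maps both give the bitwise-identical alignment
  expect_identical(ec_traceback(m, NULL, NULL, w_ec = 0.1), m$alignment)
  k_empty <- rep(NA_integer_, 8)
  expect_identical(ec_traceback(m, k_empty, k_empty, w_ec = 0.1),
                   m$alignment)
  k_any <- c(6L, NA, NA, NA, NA, 1L, NA, NA)
  expect_identical(ec_traceback(m, k_any, k_any, w_ec = 0), m$alignment)
})

test_that("EC bonus flips exactly one traceback decision on the tie fixture", {
  # pass 1: best cell is (1,1), alignment = {(1,1)}; the planted coupling
  # (1 <-> 2 on both profiles) fires at cell (2,2), whose augmented value
  # then dominates and the re-trace gains exactly the pair (2,2)
  P <- matrix(c(0.5, 0, 0, 0.15), 2, 2)
  m <- mac_align(P, mact = 0.2)
  expect_identical(unname(aligned_pairs(m$alignment)),
                   matrix(c(1L, 1L), 1))
  k <- c(2L, 1L)
  aln2 <- ec_traceback(m, k, k, w_ec = 0.1)
  expect_identical(unname(aligned_pairs(aln2)), unname(cbind(1:2, 1:2)))
  # and stays put without the bonus
  expect_identical(aligned_pairs(ec_traceback(m, k, k, w_ec = 0)),
                   aligned_pairs(m$alignment))
})

test_that("EC traceback output satisfies alignment invariants (property)", {
  set.seed(58)
  bg <- default_background()
  sym <- function(x) (x + t(x)) / 2
  for (rep in 1:5) {
    L <- sample(8:14, 1)
    qp <- random_profile(L); tp <- random_profile(L)
    fb <- suppressWarnings(forward_backward(qp, tp, scoring_weights(), bg))
    m <- mac_align(fb, mact = 0.3501)
    k_q <- select_partners(sym(matrix(runif(L * L), L, L)),
                           n_pairs = 3, min_separation = 2)
    k_t <- select_partners(sym(matrix(runif(L * L), L, L)),
                           n_pairs = 3, min_separation = 2)
    aln <- ec_traceback(m, k_q, k_t, w_ec = 0.5)
    expect_s3_class(validate_alignment(aln), "pairwise_alignment")
  }
})
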