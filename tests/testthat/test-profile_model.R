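test_that("read_msa handles fasta, a3m and malformed input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", ">b", "ACD", ">c", "ACD"), fa)
  m <- read_msa(fa)
  expect_identical(c(m$n_seq, m$n_col), c(3L, 3L))
  expect_true(all(m$seqs == matrix(c("A", "C", "D"), 3, 3, byrow = TRUE)))

  a3m <- withr::local_tempfile(fileext = ".a3m")
  writeLines(c(">a", "AcD", ">b", "AD"), a3m)
  m2 <- read_msa(a3m, format = "a3m")
  expect_identical(m2$n_col, 2L)

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_msa(empty), "empty")

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", ">b", "AC"), ragged)
  expect_error(read_msa(ragged), "ragged")
})

test_that("build_profile emission admixture matches hand evaluation", {
  ubg <- uniform_bg()
  # identity: all-A column, no pseudocount (up to the 1e-6 emission floor)
  p <- build_profile(msa(c("A", "A")), ubg, tau = 0)
  expect_equal(unname(p$emissions[1, "A"]), 1, tolerance = 1e-4)
  # symmetry: 50/50 column
  p <- build_profile(msa(c("A", "A", "C", "C")), ubg, tau = 0)
  expect_equal(unname(p$emissions[1, c("A", "C")]), c(0.5, 0.5),
               tolerance = 1e-4)
  # admixture: (1 - 0.5) * 1 + 0.5 * 0.05 = 0.525
  p <- build_profile(msa(c("A", "A")), ubg, tau = 0.5)
  expect_equal(unname(p$emissions[1, "A"]), 0.525, tolerance = 1e-4)
  # tau = 1 reproduces the background exactly
  set.seed(5)
  p <- build_profile(random_msa(4, 6), default_background(), tau = 1)
  for (i in 1:6)
    expect_equal(unname(p$emissions[i, ]), unname(c(default_background())),
                 tolerance = 1e-12)
})

test_that("build_profile output satisfies profile invariants (property)", {
  set.seed(42)
  for (k in 1:20) {
    m <- random_msa(sample(2:8, 1), sample(3:12, 1))
    # sprinkle gaps
    m$seqs[runif(length(m$seqs)) < 0.2] <- "-"
    m <- msa(m$seqs)
    tau <- runif(1)
    wt <- sample(c("uniform", "position-based"), 1)
    p <- suppressWarnings(build_profile(m, tau = tau, weighting = wt))
    expect_s3_class(validate_profile(p), "profile_hmm")
    expect_true(all(p$emissions > 0))
  }
})

test_that("all-gap columns are dropped with a warning", {
  m <- msa(c("A-D", "A-D"))
  expect_warning(p <- build_profile(m, tau = 0), "all-gap")
  expect_identical(p$length, 2L)
})

test_that("native profile dialect round-trips within 1e-12", {
  set.seed(9)
  p <- random_profile(7, name = "rt")
  f <- withr::local_tempfile(fileext = ".prof")
  write_profile(p, f)
  p2 <- read_profile(f)
  expect_equal(p2$emissions, p$emissions, tolerance = 1e-12)
  expect_equal(p2$transitions, p$transitions, tolerance = 1e-12)
  expect_identical(p2$name, p$name)
  expect_equal(p2$annotation$ss, p$annotation$ss)
  expect_equal(p2$annotation$phi, p$annotation$phi, tolerance = 1e-12)
})

test_that("profile reader rejects invariant violations", {
  set.seed(10)
  p <- random_profile(3, annotated = FALSE)
  f <- withr::local_tempfile(fileext = ".prof")
  write_profile(p, f)
  lines <- readLines(f)
  # halve every emission on column 2 -> row sums to 0.5
  i <- grep("^col\t2\t", lines)
  v <- strsplit(lines[i], "\t")[[1]]
  v[3:22] <- sprintf("%.17g", as.numeric(v[3:22]) / 2)
  lines[i] <- paste(v, collapse = "\t")
  writeLines(lines, f)
  expect_error(read_profile(f), "column 2")

  f0 <- withr::local_tempfile(fileext = ".prof")
  writeLines(c("profalign_profile\tv1", "name\tx", "length\t0",
               "background\t0.05"), f0)
  expect_error(read_profile(f0), "length")
})

test_that("transition estimation reflects gap runs and stays normalized", {
  m <- msa(c("AAAA", "AA--", "AAAA", "AA--"))
  p <- build_profile(m, tau = 0)
  # half the rows open a deletion after column 2
  expect_gt(p$transitions[2, "MD"], p$transitions[1, "MD"])
  expect_gt(p$transitions[3, "DD"], 0.5)  # observed D->D runs beat the prior
  expect_equal(rowSums(p$transitions[, c("MM", "MI", "MD")]), rep(1, 4),
               tolerance = 1e-9)
})
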