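# in-code fixtures: random profiles, MSAs and simple deterministic profiles.
# callers control the RNG with set.seed().

uniform_bg <- function() background_model(rep(1 / 20, 20))

# emission row concentrated on one residue (up to the 1e-6 floor used by
# build_profile; here exact one-hot, which validate_profile allows)
one_hot_row <- function(letter) {
  v <- numeric(20)
  v[match(letter, AA_ALPHABET)] <- 1
  v
}

default_transition_rows <- function(L) {
  matrix(rep(c(0.97, 0.015, 0.015, 0.5, 0.5, 0.5, 0.5), each = L), L, 7,
         dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
}

one_hot_profile <- function(seq_letters, name = "onehot", annotation = NULL) {
  L <- length(seq_letters)
  emis <- do.call(rbind, lapply(seq_letters, one_hot_row))
  profile_hmm(name, emis, default_transition_rows(L), annotation = annotation)
}

uniform_profile <- function(L, name = "uniform") {
  profile_hmm(name, matrix(1 / 20, L, 20), default_transition_rows(L))
}

random_annotation <- function(L, na_frac = 0.1) {
  maybe_na <- function(x, na_value) {
    x[runif(L) < na_frac] <- na_value
    x
  }
  structural_annotation(
    ss = maybe_na(sample(c("H", "E", "C"), L, replace = TRUE), NA_character_),
    sa = maybe_na(sample(c("e", "b"), L, replace = TRUE), NA_character_),
    phi = maybe_na(runif(L, -180, 180), NA_real_),
    psi = maybe_na(runif(L, -180, 180), NA_real_))
}

random_profile <- function(L, name = "rand", annotated = TRUE) {
  emis <- matrix(stats::rgamma(L * 20, shape = 0.7), L, 20)
  emis <- emis / rowSums(emis)
  tr <- matrix(0, L, 7)
  for (i in seq_len(L)) {
    m <- c(runif(1, 0.5, 1), runif(2, 0.01, 0.25))
    ii <- runif(2, 0.1, 1)
    dd <- runif(2, 0.1, 1)
    tr[i, ] <- c(m / sum(m), ii / sum(ii), dd / sum(dd))
  }
  colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  profile_hmm(name, emis, tr,
              annotation = if (annotated) random_annotation(L) else NULL)
}

random_msa <- function(n, L) {
  msa(matrix(sample(AA_ALPHABET, n * L, replace = TRUE), n, L))
}
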