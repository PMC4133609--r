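#' Scoring weights and alignment parameters
#'
#' Bundles every tunable parameter of the aligner. The defaults are the
#' optimized values of the method: `w_ss = 0.11`, `w_sa = 0.72`,
#' `w_tors = 0.4`, `s_shift = -0.03`, `w_ec = 0.1` and the MAC greediness
#' penalty `mact = 0.3501`. `mode` selects local (default) or global
#' alignment for both the Viterbi and the Forward-Backward pass.
#'
#' @param w_ss Weight of the secondary-structure score (>= 0).
#' @param w_sa Weight of the solvent-accessibility score (>= 0).
#' @param w_tors Weight of the torsion-angle score (>= 0).
#' @param w_ec Weight of the evolutionary-coupling traceback bonus (>= 0).
#' @param s_shift Constant score offset added to every match-match score.
#' @param mact MAC greediness penalty in \[0, 1): 0 gives nearly global,
#'   long alignments; values near 1 give short, precise local alignments.
#' @param mode `"local"` or `"global"`.
#' @param ss_matrix 3 x 3 secondary-structure score table with dimnames
#'   `H, E, C`; defaults to +1 match / -1 mismatch.
#' @return An object of class `scoring_weights`.
#' @export
scoring_weights <- function(w_ss = 0.11, w_sa = 0.72, w_tors = 0.4,
                            w_ec = 0.1, s_shift = -0.03, mact = 0.3501,
                            mode = c("local", "global"),
                            ss_matrix = default_ss_matrix()) {
  mode <- match.arg(mode)
  for (nm in c("w_ss", "w_sa", "w_tors", "w_ec")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      .stopf("%s must be a single non-negative number", nm)
  }
  if (!is.numeric(mact) || mact < 0 || mact >= 1)
    .stopf("mact must lie in [0, 1)")
  ss_matrix <- as.matrix(ss_matrix)
  if (!identical(dim(ss_matrix), c(3L, 3L)))
    .stopf("ss_matrix must be 3 x 3")
  dimnames(ss_matrix) <- list(c("H", "E", "C"), c("H", "E", "C"))
  structure(list(w_ss = w_ss, w_sa = w_sa, w_tors = w_tors, w_ec = w_ec,
                 s_shift = s_shift, mact = mact, mode = mode,
                 ss_matrix = ss_matrix),
            class = "scoring_weights")
}

#' @rdname scoring_weights
#' @export
default_ss_matrix <- function() {
  m <- matrix(-1, 3, 3, dimnames = list(c("H", "E", "C"), c("H", "E", "C")))
  diag(m) <- 1
  m
}

#' Column amino-acid score (log-sum-of-odds, bits)
#'
#' The profile-profile column score: `log2 sum_a q_i(a) t_j(a) / f(a)`.
#' The inner sum is floored at a small epsilon before the logarithm so
#' zero-overlap columns score a large negative number rather than -Inf.
#'
#' @param q_col,t_col Emission rows (length-20 probability vectors).
#' @param background A [background_model].
#' @return Score in bits; 0 when both columns equal the background.
#' @examples
#' bg <- background_model(rep(1 / 20, 20))
#' one_hot <- c(1, rep(0, 19))
#' column_amino_score(one_hot, one_hot, bg)  # log2(20)
#' @export
column_amino_score <- function(q_col, t_col, background) {
  s <- sum(q_col * t_col / background)
  log2(max(s, 1e-6))
}

#' Secondary-structure score
#'
#' Looks up the pair of 3-state assignments in a 3 x 3 score table;
#' any unknown state scores 0.
#'
#' @param ss_q,ss_t States in `"H"`, `"E"`, `"C"` or `NA`.
#' @param matrix 3 x 3 table with dimnames H, E, C.
#' @return Numeric score (vectorized over pairs).
#' @export
ss_score <- function(ss_q, ss_t, matrix = default_ss_matrix()) {
  out <- numeric(length(ss_q))
  known <- !is.na(ss_q) & !is.na(ss_t)
  out[known] <- matrix[cbind(ss_q[known], ss_t[known])]
  out
}

#' Solvent-accessibility score
#'
#' Kronecker delta on the 2-state exposed/buried assignment: 1 when both
#' states are known and equal, 0 otherwise.
#'
#' @param sa_q,sa_t States in `"e"`, `"b"` or `NA`.
#' @return 0/1 numeric (vectorized).
#' @export
sa_score <- function(sa_q, sa_t) {
  as.numeric(!is.na(sa_q) & !is.na(sa_t) & sa_q == sa_t)
}

#' Torsion-angle score
#'
#' Mean of the cosines of the phi and psi differences:
#' `(cos(phi_q - phi_t) + cos(psi_q - psi_t)) / 2`. Bounded in \[-1, 1\],
#' symmetric, and periodic in 360 degrees in every argument. Any unknown
#' angle makes the score 0.
#'
#' @param phi_q,psi_q,phi_t,psi_t Angles in degrees in \[-180, 180\] or `NA`.
#' @return Numeric score in \[-1, 1\] (vectorized).
#' @export
torsion_score <- function(phi_q, psi_q, phi_t, psi_t) {
  known <- !is.na(phi_q) & !is.na(psi_q) & !is.na(phi_t) & !is.na(psi_t)
  out <- numeric(length(known))
  d2r <- pi / 180
  out[known] <- (cos((phi_q[known] - phi_t[known]) * d2r) +
                 cos((psi_q[known] - psi_t[known]) * d2r)) / 2
  out
}

#' Augmented match-match score of two profile columns
#'
#' The full match-state score combined in the Viterbi and Forward-Backward
#' recursions: amino-acid column score plus the weighted secondary
#' structure, solvent accessibility and torsion terms plus the constant
#' shift:
#' `S_aa + w_ss * S_ss + w_sa * S_sa + w_tors * S_tors + s_shift`.
#' Structural terms are 0 when the corresponding annotation is missing.
#'
#' @param q,t [profile_hmm] objects.
#' @param i,j 1-based column indices.
#' @param w A [scoring_weights].
#' @param background A [background_model].
#' @return Score in bits.
#' @export
match_score <- function(q, i, t, j, w = scoring_weights(),
                        background = default_background()) {
  match_score_matrix(q, t, w, background)[i, j]
}

# Full L_q x L_t matrix of augmented match scores; vectorized, used by the
# DP kernels. Warns once when a structural weight is positive but the
# needed annotation is absent on either side.
match_score_matrix <- function(q, t, w = scoring_weights(),
                               background = default_background(),
                               warn_missing = TRUE) {
  validate_background(background)
  Lq <- q$length; Lt <- t$length
  # amino-acid term: log2 of Q diag(1/f) T'
  S <- log2(pmax(q$emissions %*% (t(t$emissions) / background), 1e-6))

  aq <- q$annotation; at <- t$annotation
  have <- function(field) {
    !is.null(aq) && !is.null(at) &&
      any(!is.na(aq[[field]])) && any(!is.na(at[[field]]))
  }
  miss <- character(0)
  if (w$w_ss > 0) {
    if (have("ss")) {
      iq <- rep(seq_len(Lq), times = Lt); jt <- rep(seq_len(Lt), each = Lq)
      S <- S + w$w_ss * matrix(ss_score(aq$ss[iq], at$ss[jt], w$ss_matrix), Lq, Lt)
    } else miss <- c(miss, "ss")
  }
  if (w$w_sa > 0) {
    if (have("sa")) {
      iq <- rep(seq_len(Lq), times = Lt); jt <- rep(seq_len(Lt), each = Lq)
      S <- S + w$w_sa * matrix(sa_score(aq$sa[iq], at$sa[jt]), Lq, Lt)
    } else miss <- c(miss, "sa")
  }
  if (w$w_tors > 0) {
    if (have("phi")) {
      iq <- rep(seq_len(Lq), times = Lt); jt <- rep(seq_len(Lt), each = Lq)
      S <- S + w$w_tors * matrix(
        torsion_score(aq$phi[iq], aq$psi[iq], at$phi[jt], at$psi[jt]), Lq, Lt)
    } else miss <- c(miss, "tors")
  }
  if (warn_missing && length(miss))
    .warnf("structural weight(s) %s > 0 but annotation missing; term scores 0",
           paste(miss, collapse = ", "))
  S + w$s_shift
}
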