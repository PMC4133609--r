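#' Viterbi alignment of two profile HMMs
#'
#' Five-matrix Viterbi dynamic programming over the pair states
#' `MM, MI, IM, DG, GD`, maximizing the augmented log-sum-of-odds score:
#' the sum over matched columns of the structural match score (amino-acid
#' column score plus weighted secondary-structure, solvent-accessibility
#' and torsion terms plus shift) plus the log2 of all transition
#' probabilities along the path. In local mode a path may start and end at
#' any cell and the empty alignment scores 0; in global mode the path runs
#' from matched pair (1,1) to (L_q, L_t). Ties prefer
#' MM > MI > IM > DG > GD, then the diagonal predecessor, so output is
#' deterministic.
#'
#' @param q,t [profile_hmm] objects (annotations optional; missing
#'   annotations make the corresponding structural term 0 with a warning
#'   when its weight is positive).
#' @param w A [scoring_weights]; `w$mode` selects local/global.
#' @param background A [background_model].
#' @param keep_matrices Keep the five DP matrices in the result (testing).
#' @return List of class `viterbi_result`: `score` (S_LSO), `alignment`
#'   (a [pairwise_alignment] whose `score` column holds per-pair match
#'   scores on MM rows), and optionally `matrices`.
#' @examples
#' set.seed(1)
#' m <- msa(c("ACDEF", "ACDEF", "ACDQF"))
#' p <- build_profile(m, name = "toy")
#' viterbi_align(p, p)$score
#' @export
viterbi_align <- function(q, t, w = scoring_weights(),
                          background = default_background(),
                          keep_matrices = FALSE) {
  validate_profile(q); validate_profile(t)
  stopifnot(inherits(w, "scoring_weights"))
  S <- match_score_matrix(q, t, w, background)
  res <- .viterbi_dp(S, log2(q$transitions), log2(t$transitions),
                     w$mode == "local")
  states <- c("MM", "MI", "IM", "DG", "GD")[res$state]
  qpos <- ifelse(res$qpos == 0L, NA_integer_, res$qpos)
  tpos <- ifelse(res$tpos == 0L, NA_integer_, res$tpos)
  score_col <- rep(NA_real_, length(states))
  is_mm <- states == "MM"
  score_col[is_mm] <- S[cbind(qpos[is_mm], tpos[is_mm])]
  aln <- pairwise_alignment(qpos, tpos, states, score_col,
                            query = q$name, template = t$name)
  out <- list(score = res$score, alignment = aln)
  if (keep_matrices)
    out$matrices <- res[c("S_MM", "S_MI", "S_IM", "S_DG", "S_GD")]
  structure(out, class = "viterbi_result")
}

#' @export
print.viterbi_result <- function(x, ...) {
  cat(sprintf("viterbi_result: S_LSO = %.4f bits, %d alignment columns\n",
              x$score, nrow(x$alignment)))
  invisible(x)
}

#' Recompute the log-sum-of-odds score of an alignment path
#'
#' Independent re-scoring of a `pairwise_alignment` path: sums the
#' augmented match score over MM rows and the log2 transition
#' probabilities implied by the state sequence. Used to check the Viterbi
#' invariant that the reported S_LSO equals the score of the returned path.
#'
#' @param aln A [pairwise_alignment] over the pair states.
#' @param q,t The aligned [profile_hmm] objects.
#' @param w A [scoring_weights].
#' @param background A [background_model].
#' @return The path score in bits (0 for an empty alignment).
#' @export
score_alignment_path <- function(aln, q, t, w = scoring_weights(),
                                 background = default_background()) {
  if (nrow(aln) == 0L) return(0)
  S <- match_score_matrix(q, t, w, background, warn_missing = FALSE)
  total <- 0
  qtr <- log2(q$transitions); ttr <- log2(t$transitions)
  prev_state <- NULL
  prev_i <- 0L; prev_j <- 0L
  cur_i <- 0L; cur_j <- 0L
  for (k in seq_len(nrow(aln))) {
    st <- aln$state[k]
    if (!is.na(aln$qpos[k])) cur_i <- aln$qpos[k]
    if (!is.na(aln$tpos[k])) cur_j <- aln$tpos[k]
    if (st == "MM") total <- total + S[aln$qpos[k], aln$tpos[k]]
    if (!is.null(prev_state)) {
      # transition from the previous pair state into this one
      total <- total + transition_log2(prev_state, st, prev_i, prev_j, qtr, ttr)
    }
    prev_state <- st; prev_i <- cur_i; prev_j <- cur_j
  }
  unname(total)
}

# log2 transition weight for moving from pair state `from` at (i, j) into
# pair state `to`; i/j are the last consumed columns of `from`
transition_log2 <- function(from, to, i, j, qtr, ttr) {
  key <- paste(from, to)
  switch(key,
    "MM MM" = qtr[i, "MM"] + ttr[j, "MM"],
    "MM MI" = qtr[i, "MM"] + ttr[j, "MI"],
    "MI MI" = qtr[i, "MM"] + ttr[j, "II"],
    "MI MM" = qtr[i, "MM"] + ttr[j, "IM"],
    "MM DG" = qtr[i, "MD"],
    "DG DG" = qtr[i, "DD"],
    "DG MM" = qtr[i, "DM"] + ttr[j, "MM"],
    "MM IM" = ttr[j, "MM"] + qtr[i, "MI"],
    "IM IM" = ttr[j, "MM"] + qtr[i, "II"],
    "IM MM" = ttr[j, "MM"] + qtr[i, "IM"],
    "MM GD" = ttr[j, "MD"],
    "GD GD" = ttr[j, "DD"],
    "GD MM" = ttr[j, "DM"] + qtr[i, "MM"],
    .stopf("illegal state transition %s -> %s in alignment path", from, to)
  )
}
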