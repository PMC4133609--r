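#' Forward-Backward posterior match probabilities
#'
#' Computes the Forward and Backward partition functions over the five
#' pair states with the structurally augmented match odds
#' `P_match(i,j) = 2^match_score(i,j)` (the same augmented score used by
#' Viterbi; insert/delete states carry transition factors only), and from
#' them the posterior probability `p(i~j)` that match column `i` of the
#' query aligns to match column `j` of the template:
#' `p(i~j) = F_MM(i,j) * B_MM(i,j) / Z`.
#'
#' `p_min` selects the alignment model: 1 lets paths start and end at any
#' cell (local mode), 0 pins them to (1,1) and (L_q, L_t) (global mode).
#' All recursions run in log2 space, so posteriors are exact up to rounding
#' with no overflow for realistic profile lengths.
#'
#' @param q,t [profile_hmm] objects.
#' @param w A [scoring_weights]; used for the match odds. When `p_min` is
#'   `NULL` it is taken from `w$mode` (local = 1, global = 0).
#' @param background A [background_model].
#' @param p_min 0 (global) or 1 (local), overriding `w$mode`.
#' @return Object of class `posterior_matrix`: list with `posterior`
#'   (L_q x L_t matrix in \[0,1\]), `logZ_forward`, `logZ_backward` (log2
#'   total partition values, equal up to rounding), and `p_min`.
#' @export
forward_backward <- function(q, t, w = scoring_weights(),
                             background = default_background(),
                             p_min = NULL) {
  validate_profile(q); validate_profile(t)
  if (is.null(p_min)) p_min <- if (w$mode == "local") 1 else 0
  if (!p_min %in% c(0, 1)) .stopf("p_min must be 0 (global) or 1 (local)")
  S <- match_score_matrix(q, t, w, background)
  res <- .forward_backward_dp(S, log2(q$transitions), log2(t$transitions),
                              p_min)
  if (!is.finite(res$logZ_forward))
    .stopf(paste0("empty partition function: no admissible %s-mode path ",
                  "for profile lengths %d and %d"),
           if (p_min == 1) "local" else "global", q$length, t$length)
  if (any(!is.finite(res$posterior)))
    .stopf("numeric failure in Forward-Backward at cell (%d, %d)",
           which(!is.finite(res$posterior), arr.ind = TRUE)[1, 1],
           which(!is.finite(res$posterior), arr.ind = TRUE)[1, 2])
  # clip tiny rounding excursions above 1
  res$posterior <- pmin(pmax(res$posterior, 0), 1)
  structure(list(posterior = res$posterior,
                 logZ_forward = res$logZ_forward,
                 logZ_backward = res$logZ_backward,
                 logF_MM = res$logF_MM, logB_MM = res$logB_MM,
                 p_min = p_min, query = q$name, template = t$name),
            class = "posterior_matrix")
}

#' @export
print.posterior_matrix <- function(x, ...) {
  cat(sprintf("posterior_matrix %s ~ %s: %d x %d, log2 Z = %.4f (%s mode)\n",
              x$query, x$template, nrow(x$posterior), ncol(x$posterior),
              x$logZ_forward, if (x$p_min == 1) "local" else "global"))
  invisible(x)
}

#' Maximum-accuracy (MAC) alignment from a posterior matrix
#'
#' Finds the alignment maximizing the sum of posterior probabilities of its
#' matched pairs minus the greediness penalty `mact` per pair (gap moves
#' cost `mact/2`), via the optimal sub-alignment score matrix
#' `AS(i,j) = max(AS(i-1,j-1) + p(i~j) - mact,
#'                AS(i-1,j) - mact/2, AS(i,j-1) - mact/2, 0)`
#' with traceback from the global maximum cell down to a zero cell.
#' `mact = 0` yields nearly global, long alignments; `mact` near 1 yields
#' short, precise local alignments. Ties prefer the diagonal, then the
#' query-advancing move; the best cell is the lowest (i, j) on ties.
#'
#' @param post A [forward_backward] result (or bare posterior matrix).
#' @param mact Penalty in \[0, 1).
#' @param query,template Names for the output alignment (defaults taken
#'   from `post` when available).
#' @return List of class `mac_result`: `AS` matrix, `best` cell and score,
#'   and `alignment` (a [pairwise_alignment] whose `score` column holds the
#'   posterior of each matched pair; query-advancing gap rows are labelled
#'   `MI`, template-advancing rows `IM`).
#' @export
mac_align <- function(post, mact = 0.3501, query = NULL, template = NULL) {
  P <- if (inherits(post, "posterior_matrix")) post$posterior else as.matrix(post)
  if (mact < 0 || mact >= 1) .stopf("mact must lie in [0, 1)")
  query <- query %||% (if (inherits(post, "posterior_matrix")) post$query else "query")
  template <- template %||% (if (inherits(post, "posterior_matrix")) post$template else "template")
  AS <- mac_matrix(P, mact)
  best <- arg_max_cell(AS)
  aln <- mac_traceback(AS, P, mact, best, query, template)
  structure(list(AS = AS, best = best, best_score = AS[best[1], best[2]],
                 mact = mact, alignment = aln),
            class = "mac_result", posterior = P)
}

# AS recursion (R loop; O(Lq * Lt), cheap at the profile lengths in scope)
mac_matrix <- function(P, mact) {
  Lq <- nrow(P); Lt <- ncol(P)
  AS <- matrix(0, Lq + 1L, Lt + 1L)
  g <- mact / 2
  for (i in seq_len(Lq)) {
    for (j in seq_len(Lt)) {
      AS[i + 1L, j + 1L] <- max(AS[i, j] + P[i, j] - mact,
                                AS[i, j + 1L] - g,
                                AS[i + 1L, j] - g,
                                0)
    }
  }
  AS[-1L, -1L, drop = FALSE]
}

# first (row-major lowest i then j) cell attaining the matrix maximum
arg_max_cell <- function(M) {
  hits <- which(M == max(M), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  c(hits[1, 1], hits[1, 2])
}

# traceback of the AS matrix from `cell` until AS hits 0; `bonus`, when
# given, is added to AS values *read during move selection* (EC-augmented
# traceback re-uses this with a nonzero bonus matrix)
mac_traceback <- function(AS, P, mact, cell, query, template, bonus = NULL) {
  at <- function(i, j) {
    if (i < 1L || j < 1L) return(0)
    v <- AS[i, j]
    if (!is.null(bonus)) v <- v + bonus[i, j]
    v
  }
  g <- mact / 2
  i <- cell[1]; j <- cell[2]
  qpos <- integer(0); tpos <- integer(0); st <- character(0); sc <- numeric(0)
  if (AS[i, j] > 0) {
    while (i >= 1L && j >= 1L && AS[i, j] > 0) {
      diag_v <- at(i - 1L, j - 1L) + P[i, j] - mact
      up_v <- at(i - 1L, j) - g
      left_v <- at(i, j - 1L) - g
      best <- max(diag_v, up_v, left_v, 0)
      if (diag_v >= best) {          # ties prefer the matched pair
        qpos <- c(i, qpos); tpos <- c(j, tpos); st <- c("MM", st)
        sc <- c(P[i, j], sc)
        i <- i - 1L; j <- j - 1L
      } else if (up_v >= best) {     # then query-advancing gap
        qpos <- c(i, qpos); tpos <- c(NA_integer_, tpos); st <- c("MI", st)
        sc <- c(NA_real_, sc)
        i <- i - 1L
      } else if (left_v >= best) {
        qpos <- c(NA_integer_, qpos); tpos <- c(j, tpos); st <- c("IM", st)
        sc <- c(NA_real_, sc)
        j <- j - 1L
      } else break                   # a fresh 0 start
    }
  }
  pairwise_alignment(qpos, tpos, st, sc, query = query, template = template)
}

#' @export
print.mac_result <- function(x, ...) {
  cat(sprintf("mac_result: best AS = %.4f (mact = %.4g), %d alignment columns\n",
              x$best_score, x$mact, nrow(x$alignment)))
  invisible(x)
}
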