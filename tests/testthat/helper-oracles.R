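# Independent oracles for the alignment recursions.
#
# An alignment path over the pair states MM/MI/IM/DG/GD is a chain of
# matched cells in which consecutive matches (p,q) -> (i,j) advance one
# side by exactly 1; the intervening columns on the other side are covered
# by a single run of one gap-state type (MI or DG when the query advances,
# IM or GD when the template advances), because the recursions admit no
# direct transitions between gap states. The oracles below therefore
# enumerate match chains with closed-form per-segment weights: an
# exhaustive sum/maximization over all legal state paths, with none of the
# five-matrix machinery of the package kernels.
#
# The match score is recomputed here from first principles on purpose --
# shared code with the package would defeat the dual-route check.

oracle_match_matrix <- function(q, t, w, bg) {
  S <- matrix(0, q$length, t$length)
  aq <- q$annotation; at <- t$annotation
  for (i in seq_len(q$length)) {
    for (j in seq_len(t$length)) {
      s <- log2(max(sum(q$emissions[i, ] * t$emissions[j, ] / bg), 1e-6))
      if (!is.null(aq) && !is.null(at)) {
        if (!is.na(aq$ss[i]) && !is.na(at$ss[j]))
          s <- s + w$w_ss * w$ss_matrix[aq$ss[i], at$ss[j]]
        if (!is.na(aq$sa[i]) && !is.na(at$sa[j]) && aq$sa[i] == at$sa[j])
          s <- s + w$w_sa
        if (!any(is.na(c(aq$phi[i], aq$psi[i], at$phi[j], at$psi[j]))))
          s <- s + w$w_tors *
            (cos((aq$phi[i] - at$phi[j]) * pi / 180) +
             cos((aq$psi[i] - at$psi[j]) * pi / 180)) / 2
      }
      S[i, j] <- s + w$s_shift
    }
  }
  S
}

# linear-domain weights of the two single-gap-state routes for the segment
# between matched cells (p,q) and (i,j); the diagonal step has one route
oracle_segment_weights <- function(p, q_, i, j, qt, tt) {
  if (i == p + 1 && j == q_ + 1) {
    return(qt[p, "MM"] * tt[q_, "MM"])
  }
  if (j == q_ + 1 && i > p + 1) {           # query advances through i-p-1 gaps
    w_mi <- prod(qt[p:(i - 1), "MM"]) *
      tt[q_, "MI"] * tt[q_, "II"]^(i - p - 2) * tt[q_, "IM"]
    w_dg <- qt[p, "MD"] *
      (if (i - p - 2 > 0) prod(qt[(p + 1):(i - 2), "DD"]) else 1) *
      qt[i - 1, "DM"] * tt[q_, "MM"]
    return(c(MI = w_mi, DG = w_dg))
  }
  if (i == p + 1 && j > q_ + 1) {           # template advances
    w_im <- prod(tt[q_:(j - 1), "MM"]) *
      qt[p, "MI"] * qt[p, "II"]^(j - q_ - 2) * qt[p, "IM"]
    w_gd <- tt[q_, "MD"] *
      (if (j - q_ - 2 > 0) prod(tt[(q_ + 1):(j - 2), "DD"]) else 1) *
      tt[j - 1, "DM"] * qt[p, "MM"]
    return(c(IM = w_im, GD = w_gd))
  }
  numeric(0)                                # illegal segment
}

# Exhaustive Viterbi: best chain score, maximizing over gap-state routes
oracle_viterbi_score <- function(q, t, w, bg) {
  local <- w$mode == "local"
  S <- oracle_match_matrix(q, t, w, bg)
  qt <- q$transitions; tt <- t$transitions
  Lq <- q$length; Lt <- t$length
  V <- matrix(-Inf, Lq, Lt)
  for (i in seq_len(Lq)) {
    for (j in seq_len(Lt)) {
      best <- if (local || (i == 1 && j == 1)) 0 else -Inf
      if (i > 1 && j > 1) {
        for (p in seq_len(i - 1)) {
          for (q_ in seq_len(j - 1)) {
            ws <- oracle_segment_weights(p, q_, i, j, qt, tt)
            if (length(ws) && is.finite(V[p, q_]))
              best <- max(best, V[p, q_] + log2(max(ws)))
          }
        }
      }
      V[i, j] <- S[i, j] + best
    }
  }
  if (local) max(0, max(V)) else V[Lq, Lt]
}

# Exhaustive partition sums: posterior that match i aligns to match j
oracle_posteriors <- function(q, t, w, bg, p_min) {
  S <- oracle_match_matrix(q, t, w, bg)
  pm <- 2^S
  qt <- q$transitions; tt <- t$transitions
  Lq <- q$length; Lt <- t$length
  start <- function(i, j) if (i == 1 && j == 1) 1 else p_min
  endw <- function(i, j) if (i == Lq && j == Lt) 1 else p_min
  Zf <- matrix(0, Lq, Lt)
  for (i in seq_len(Lq)) {
    for (j in seq_len(Lt)) {
      acc <- start(i, j)
      if (i > 1 && j > 1) {
        for (p in seq_len(i - 1)) {
          for (q_ in seq_len(j - 1)) {
            ws <- oracle_segment_weights(p, q_, i, j, qt, tt)
            if (length(ws)) acc <- acc + Zf[p, q_] * sum(ws)
          }
        }
      }
      Zf[i, j] <- pm[i, j] * acc
    }
  }
  Zb <- matrix(0, Lq, Lt)
  for (i in rev(seq_len(Lq))) {
    for (j in rev(seq_len(Lt))) {
      acc <- endw(i, j)
      if (i < Lq && j < Lt) {
        for (r in (i + 1):Lq) {
          for (s in (j + 1):Lt) {
            ws <- oracle_segment_weights(i, j, r, s, qt, tt)
            if (length(ws)) acc <- acc + sum(ws) * pm[r, s] * Zb[r, s]
          }
        }
      }
      Zb[i, j] <- acc
    }
  }
  Z <- 0
  for (i in seq_len(Lq)) for (j in seq_len(Lt))
    Z <- Z + Zf[i, j] * endw(i, j)
  list(posterior = Zf * Zb / Z, Z = Z)
}
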