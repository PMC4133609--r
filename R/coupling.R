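#' Mutual-information evolutionary-coupling matrix of an MSA
#'
#' Quantifies the evolutionary coupling between every pair of alignment
#' columns as the mutual information over 21 symbols (20 amino acids plus
#' gap): `EC_ij = sum_{a,b} F_ij(a,b) * ln( F_ij(a,b) / (F_i(a) F_j(b)) )`
#' with `0 * ln 0 = 0`. Joint frequencies receive a small additive
#' pseudocount; the marginals are obtained by summing the (pseudocounted)
#' joint, which keeps every entry a true mutual information and hence
#' non-negative. Unknown residues (`X`) are counted as gap.
#'
#' @param x An [msa] with at least 2 sequences.
#' @param pseudocount Additive count per joint symbol pair; default
#'   `1 / n_seq`. Use 0 for exact plug-in MI.
#' @param weights Optional per-sequence weights (default uniform).
#' @return Symmetric L x L matrix of MI values in nats (diagonal set to 0).
#' @examples
#' m <- msa(c("AA", "AA", "CC", "CC"))
#' mutual_information_matrix(m, pseudocount = 0)[1, 2]  # ln 2
#' @export
mutual_information_matrix <- function(x, pseudocount = NULL, weights = NULL) {
  stopifnot(inherits(x, "msa"))
  L <- x$n_col; n <- x$n_seq
  if (n < 2L) {
    .warnf("MSA has a single sequence; MI matrix is all zero")
    return(matrix(0, L, L))
  }
  pseudocount <- pseudocount %||% (1 / n)
  if (pseudocount < 0) .stopf("pseudocount must be >= 0")
  w <- weights %||% rep(1, n)
  stopifnot(length(w) == n)
  syms <- c(AA_ALPHABET, "-")
  m <- x$seqs
  m[m == "X"] <- "-"
  idx <- matrix(match(m, syms), n, L)  # integer codes 1..21

  # per-column weighted one-hot indicator (n x 21) kept sparse-free; L is
  # modest so an L x 21 count table per column pair is fine
  mi <- matrix(0, L, L)
  counts <- array(0, dim = c(21L, L))
  for (i in seq_len(L))
    counts[, i] <- tabulate2(idx[, i], w, 21L)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      joint <- joint_counts(idx[, i], idx[, j], w, 21L) + pseudocount
      joint <- joint / sum(joint)
      fi <- rowSums(joint); fj <- colSums(joint)
      pr <- outer(fi, fj)
      nz <- joint > 0
      v <- sum(joint[nz] * log(joint[nz] / pr[nz]))
      mi[i, j] <- v; mi[j, i] <- v
    }
  }
  mi
}

tabulate2 <- function(codes, w, nbins) {
  out <- numeric(nbins)
  for (k in seq_along(codes)) out[codes[k]] <- out[codes[k]] + w[k]
  out
}

joint_counts <- function(ci, cj, w, nbins) {
  out <- matrix(0, nbins, nbins)
  for (k in seq_along(ci)) out[ci[k], cj[k]] <- out[ci[k], cj[k]] + w[k]
  out
}

#' Select top coupled column pairs as a partner map
#'
#' Ranks off-diagonal column pairs with separation `|i - j| >=
#' min_separation` by MI and greedily keeps the `n_pairs` best, each column
#' used at most once; equal MI values break ties toward the
#' lexicographically smaller `(i, j)`. The result is a symmetric partial
#' partner map `k(i) = j`, `k(j) = i`.
#'
#' @param mi Symmetric MI matrix.
#' @param n_pairs Number of pairs to keep; default `ceiling(L / 10)`.
#' @param min_separation Minimum column separation (default 5).
#' @return Integer vector of length L: `k[i]` is the partner column of `i`
#'   or `NA`. Class `partner_map`.
#' @export
select_partners <- function(mi, n_pairs = NULL, min_separation = 5L) {
  mi <- as.matrix(mi)
  L <- nrow(mi)
  if (ncol(mi) != L) .stopf("MI matrix must be square")
  if (max(abs(mi - t(mi))) > 1e-12) .stopf("MI matrix must be symmetric")
  n_pairs <- n_pairs %||% ceiling(L / 10)
  if (min_separation < 1L) .stopf("min_separation must be >= 1")
  k <- rep(NA_integer_, L)
  if (n_pairs == 0L || L < 2L) return(structure(k, class = "partner_map"))
  cand <- which(upper.tri(mi), arr.ind = TRUE)
  cand <- cand[abs(cand[, 1] - cand[, 2]) >= min_separation, , drop = FALSE]
  cand <- cand[mi[cand] > 0, , drop = FALSE]  # zero MI is no coupling
  if (nrow(cand) == 0L) return(structure(k, class = "partner_map"))
  vals <- mi[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  taken <- 0L
  for (r in ord) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (is.na(k[i]) && is.na(k[j])) {
      k[i] <- j; k[j] <- i
      taken <- taken + 1L
      if (taken >= n_pairs) break
    }
  }
  structure(k, class = "partner_map")
}

#' Read and write partner maps as two-column text
#'
#' Plain text, one `position partner` pair per line (both directions
#' written once, smaller position first).
#'
#' @param path File path.
#' @param length Profile length (needed on read).
#' @export
read_partner_map <- function(path, length) {
  k <- rep(NA_integer_, length)
  tb <- utils::read.table(path, header = FALSE,
                          col.names = c("position", "partner"))
  for (r in seq_len(nrow(tb))) {
    i <- tb$position[r]; j <- tb$partner[r]
    if (i < 1 || j < 1 || i > length || j > length)
      .stopf("partner pair (%d, %d) outside profile length %d", i, j, length)
    k[i] <- j; k[j] <- i
  }
  structure(k, class = "partner_map")
}

#' @param k A `partner_map`.
#' @rdname read_partner_map
#' @export
write_partner_map <- function(k, path) {
  i <- which(!is.na(k) & seq_along(k) < unclass(k))
  utils::write.table(data.frame(position = i, partner = unclass(k)[i]), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' EC-augmented maximum-accuracy traceback
#'
#' Re-traces the MAC sub-alignment matrix with evolutionary-coupling
#' bonuses. Pass 1 is the standard MAC traceback, giving the matched-column
#' maps `M_q` (query -> template) and `M_t` (template -> query). Pass 2
#' repeats the traceback on the augmented matrix
#' `AS'(i,j) = AS(i,j) + w_ec * d(M_q(k_q(i)), k_t(j))
#'                     + w_ec * d(M_t(k_t(j)), k_q(i))`
#' where `k_q`/`k_t` are the partner maps, and the Kronecker delta `d`
#' fires only when every value involved is defined: the bonus rewards
#' cells whose coupled partners were matched to each other in pass 1.
#' Move selection compares augmented values under the standard MAC tie
#' rules; with `w_ec = 0` or empty partner maps the result is identical to
#' the standard traceback.
#'
#' @param mac A [mac_align] result.
#' @param k_q,k_t Partner maps ([select_partners]) for query and template;
#'   `NULL` means no partners.
#' @param w_ec Bonus weight (default 0.1).
#' @return A [pairwise_alignment] (scores are pass-1 posteriors of the
#'   matched pairs).
#' @export
ec_traceback <- function(mac, k_q = NULL, k_t = NULL, w_ec = 0.1) {
  stopifnot(inherits(mac, "mac_result"))
  if (w_ec < 0) .stopf("w_ec must be >= 0")
  base <- mac$alignment
  if (w_ec == 0 || (is.null(k_q) && is.null(k_t))) return(base)
  Lq <- nrow(mac$AS); Lt <- ncol(mac$AS)
  k_q <- k_q %||% rep(NA_integer_, Lq)
  k_t <- k_t %||% rep(NA_integer_, Lt)
  if (length(k_q) != Lq || length(k_t) != Lt)
    .stopf("partner map length does not match profile length")

  pairs <- aligned_pairs(base)
  M_q <- rep(NA_integer_, Lq); M_t <- rep(NA_integer_, Lt)
  if (nrow(pairs)) {
    M_q[pairs[, "qpos"]] <- pairs[, "tpos"]
    M_t[pairs[, "tpos"]] <- pairs[, "qpos"]
  }

  bonus <- matrix(0, Lq, Lt)
  for (i in which(!is.na(k_q))) {
    mq <- M_q[k_q[i]]
    if (is.na(mq)) next
    js <- which(!is.na(k_t) & k_t == mq)
    bonus[i, js] <- bonus[i, js] + w_ec
  }
  for (j in which(!is.na(k_t))) {
    mt <- M_t[k_t[j]]
    if (is.na(mt)) next
    is_ <- which(!is.na(k_q) & k_q == mt)
    bonus[is_, j] <- bonus[is_, j] + w_ec
  }
  if (all(bonus == 0)) return(base)

  ASp <- mac$AS + bonus
  best <- arg_max_cell(ASp)
  mac_traceback(mac$AS, attr_posterior(mac), mac$mact, best,
                attr(base, "query"), attr(base, "template"), bonus = bonus)
}

# posterior matrix backing a mac_result (stored at creation)
attr_posterior <- function(mac) {
  p <- attr(mac, "posterior")
  if (is.null(p)) .stopf("mac_result lacks its posterior matrix")
  p
}
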