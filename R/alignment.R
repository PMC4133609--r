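#' Pairwise alignments of two profiles
#'
#' A pairwise alignment is a data frame with one row per alignment column:
#' `qpos` / `tpos` are 1-based profile columns (`NA` against a gap),
#' `state` is the pair-state label (`MM`, `MI`, `IM`, `DG`, `GD`), and
#' `score` carries the per-pair match score (Viterbi) or posterior
#' probability (MAC). Non-`NA` positions are strictly increasing and no row
#' is a gap on both sides.
#'
#' @param qpos,tpos Integer columns (`NA` for gap).
#' @param state Character state labels.
#' @param score Per-row numeric score or posterior.
#' @param query,template Profile names.
#' @return An object of classes `pairwise_alignment` and `data.frame`.
#' @export
pairwise_alignment <- function(qpos, tpos, state, score = NA_real_,
                               query = "query", template = "template") {
  df <- data.frame(qpos = as.integer(qpos), tpos = as.integer(tpos),
                   state = as.character(state),
                   score = rep_len(as.numeric(score), length(qpos)))
  attr(df, "query") <- query
  attr(df, "template") <- template
  class(df) <- c("pairwise_alignment", "data.frame")
  validate_alignment(df)
}

#' @rdname pairwise_alignment
#' @param x A `pairwise_alignment`.
#' @export
validate_alignment <- function(x) {
  stopifnot(inherits(x, "pairwise_alignment"))
  if (nrow(x) == 0L) return(x)
  if (!all(x$state %in% c("MM", "MI", "IM", "DG", "GD")))
    .stopf("illegal pair-state label")
  if (any(is.na(x$qpos) & is.na(x$tpos)))
    .stopf("alignment row with gaps on both sides")
  q <- x$qpos[!is.na(x$qpos)]
  t <- x$tpos[!is.na(x$tpos)]
  if (length(q) > 1L && any(diff(q) <= 0L))
    .stopf("query positions not strictly increasing")
  if (length(t) > 1L && any(diff(t) <= 0L))
    .stopf("template positions not strictly increasing")
  x
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  n_mm <- sum(x$state == "MM")
  cat(sprintf("pairwise_alignment %s ~ %s: %d columns, %d matched pairs\n",
              attr(x, "query"), attr(x, "template"), nrow(x), n_mm))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Matched (MM) pairs of an alignment as a two-column matrix
#'
#' @param x A [pairwise_alignment].
#' @return Integer matrix with columns `qpos`, `tpos`.
#' @export
aligned_pairs <- function(x) {
  stopifnot(inherits(x, "pairwise_alignment"))
  mm <- x[x$state == "MM", , drop = FALSE]
  cbind(qpos = mm$qpos, tpos = mm$tpos)
}

#' Render an alignment as two aligned sequence rows
#'
#' Uses the consensus residue (argmax emission) of each profile column;
#' gap-state rows print `-`. Intended for the two-row aligned FASTA output
#' of the command-line interface.
#'
#' @param aln A [pairwise_alignment].
#' @param q,t The aligned [profile_hmm] objects.
#' @return Character vector of two aligned strings, named by profile.
#' @export
alignment_as_strings <- function(aln, q, t) {
  cons <- function(p) AA_ALPHABET[max.col(p$emissions, ties.method = "first")]
  cq <- cons(q); ct <- cons(t)
  qrow <- ifelse(is.na(aln$qpos), "-", cq[aln$qpos])
  trow <- ifelse(is.na(aln$tpos), "-", ct[aln$tpos])
  stats::setNames(c(paste(qrow, collapse = ""), paste(trow, collapse = "")),
                  c(q$name, t$name))
}

#' Write an alignment as a tab-separated report
#'
#' Columns: `qpos`, `tpos`, `state`, `score` (Viterbi match score or MAC
#' posterior, depending on provenance).
#'
#' @param aln A [pairwise_alignment].
#' @param path Output path.
#' @export
write_alignment_tsv <- function(aln, path) {
  utils::write.table(as.data.frame(aln), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
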