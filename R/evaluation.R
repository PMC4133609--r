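#' Reference alignments with core blocks
#'
#' A reference (presumed true) pairwise alignment plus a core-block mask:
#' the subset of its aligned residue pairs determined precisely enough by
#' structural superposition to serve as ground truth for SP/TC scoring.
#'
#' @param pairs Two-column integer matrix (`qpos`, `tpos`) of aligned
#'   residue pairs, strictly increasing in both columns.
#' @param core Logical vector marking core pairs (default: all).
#' @return Object of class `reference_alignment`.
#' @export
reference_alignment <- function(pairs, core = NULL) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) .stopf("reference pairs must be a 2-column matrix")
  colnames(pairs) <- c("qpos", "tpos")
  if (nrow(pairs) > 1L &&
      (any(diff(pairs[, 1]) <= 0) || any(diff(pairs[, 2]) <= 0)))
    .stopf("reference pairs must be strictly increasing in both columns")
  core <- core %||% rep(TRUE, nrow(pairs))
  if (length(core) != nrow(pairs)) .stopf("core mask length mismatch")
  structure(list(pairs = pairs, core = as.logical(core)),
            class = "reference_alignment")
}

#' @export
print.reference_alignment <- function(x, ...) {
  cat(sprintf("reference_alignment: %d pairs, %d in core blocks\n",
              nrow(x$pairs), sum(x$core)))
  invisible(x)
}

#' Read a reference alignment from two-row aligned FASTA
#'
#' The file holds exactly two aligned records (gaps `-`). Aligned columns
#' with residues on both rows become reference pairs, numbered by ungapped
#' position. An optional third record named `core` (or a `mask` argument)
#' marks core-block columns with `*`; without a mask every pair is core.
#'
#' @param path Aligned FASTA path.
#' @param mask Optional core mask string (same length as the alignment,
#'   `*` = core), overriding any `core` record in the file.
#' @return A [reference_alignment].
#' @export
read_reference_alignment <- function(path, mask = NULL) {
  recs <- Biostrings::readBStringSet(path)
  seqs <- as.character(recs)
  is_core_rec <- tolower(names(recs)) == "core"
  if (is.null(mask) && any(is_core_rec)) mask <- seqs[is_core_rec][1]
  seqs <- seqs[!is_core_rec]
  if (length(seqs) != 2L)
    .stopf("reference FASTA must hold exactly two aligned records")
  a <- strsplit(toupper(seqs[1]), "")[[1]]
  b <- strsplit(toupper(seqs[2]), "")[[1]]
  if (length(a) != length(b)) .stopf("reference rows differ in length")
  qpos <- cumsum(a != "-"); tpos <- cumsum(b != "-")
  both <- a != "-" & b != "-"
  core <- NULL
  if (!is.null(mask)) {
    mk <- strsplit(mask, "")[[1]]
    if (length(mk) != length(a)) .stopf("core mask length mismatch")
    core <- mk[both] == "*"
  }
  reference_alignment(cbind(qpos[both], tpos[both]), core)
}

#' Sum-of-pairs (SP) and true-column (TC) alignment scores
#'
#' SP is the percentage of core-block reference residue pairs recovered by
#' the predicted alignment:
#' `100 * |predicted MM pairs intersect core pairs| / |core pairs|`.
#' TC counts correctly aligned core columns; for strictly pairwise
#' alignments a column is one residue pair, so TC uses the same counting
#' and equals SP (kept as a separate function for reporting parity).
#'
#' @param predicted A [pairwise_alignment].
#' @param reference A [reference_alignment] with a nonempty core.
#' @return Percentage in \[0, 100\].
#' @export
sp_score <- function(predicted, reference) {
  stopifnot(inherits(predicted, "pairwise_alignment"),
            inherits(reference, "reference_alignment"))
  core <- reference$pairs[reference$core, , drop = FALSE]
  if (nrow(core) == 0L) .stopf("reference has no core pairs; SP undefined")
  pred <- aligned_pairs(predicted)
  if (nrow(pred) == 0L) return(0)
  hits <- sum(paste(pred[, 1], pred[, 2]) %in% paste(core[, 1], core[, 2]))
  100 * hits / nrow(core)
}

#' @rdname sp_score
#' @export
tc_score <- function(predicted, reference) {
  sp_score(predicted, reference)
}

#' Write a TSV report of SP/TC scores
#'
#' @param scores Data frame with columns `pair`, `sp`, `tc`.
#' @param path Output path.
#' @export
write_evaluation_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
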