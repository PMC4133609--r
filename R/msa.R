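#' Multiple sequence alignments
#'
#' A light container for an aligned protein family: a character matrix of
#' single-letter residues with one row per sequence and one column per
#' alignment column. The alphabet is the 20 amino acids, `-` for a gap and
#' `X` for an unknown residue.
#'
#' @param sequences Character vector of aligned sequences (equal lengths) or
#'   a character matrix of single letters.
#' @param ids Sequence identifiers; defaults to `seq_1 ...`.
#' @return An object of class `msa`: list with `seqs` (character matrix),
#'   `ids`, `n_seq`, `n_col`.
#' @export
msa <- function(sequences, ids = NULL) {
  if (is.matrix(sequences)) {
    m <- sequences
  } else {
    if (length(sequences) == 0L) .stopf("MSA needs at least one sequence")
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      .stopf("ragged alignment: sequence lengths %s", paste(unique(lens), collapse = ", "))
    m <- do.call(rbind, strsplit(toupper(sequences), ""))
  }
  dimnames(m) <- NULL
  if (is.null(ids)) ids <- paste0("seq_", seq_len(nrow(m)))
  if (length(ids) != nrow(m)) .stopf("ids length does not match sequence count")
  ok <- m %in% c(AA_ALPHABET, "-", "X")
  if (!all(ok)) {
    bad <- unique(m[!ok])
    .stopf("illegal alignment symbol(s): %s", paste(bad, collapse = " "))
  }
  structure(list(seqs = m, ids = as.character(ids),
                 n_seq = nrow(m), n_col = ncol(m)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n", x$n_seq, x$n_col))
  invisible(x)
}

#' Read a multiple sequence alignment from FASTA or A3M
#'
#' FASTA input must be rectangular (all records the same length). A3M input
#' follows the usual convention: lower-case letters are insert-state
#' residues relative to the master and are removed, `.` characters are
#' dropped, so only match columns are retained; the result is rectangular by
#' construction for a valid A3M.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"a3m"`.
#' @return An [msa] object.
#' @export
read_msa <- function(path, format = c("fasta", "a3m")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("no such file: %s", path)
  recs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) .stopf("cannot parse %s: %s", path, conditionMessage(e)))
  if (length(recs) == 0L) .stopf("empty alignment file: %s", path)
  seqs <- as.character(recs)
  if (format == "a3m") {
    # strip '.' and lower-case insert residues; keep match columns only
    seqs <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      ch <- ch[ch != "."]
      ch <- ch[!(ch %in% letters)]
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    .stopf("ragged alignment in %s: record lengths %s", path,
           paste(unique(lens), collapse = ", "))
  msa(seqs, ids = names(recs))
}

#' Write an MSA as aligned FASTA
#'
#' @param x An [msa].
#' @param path Output path.
#' @export
write_msa <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  seqs <- apply(x$seqs, 1L, paste, collapse = "")
  writeLines(paste0(">", x$ids, "\n", seqs), path)
  invisible(path)
}
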