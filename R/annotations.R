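#' Per-residue structural annotations
#'
#' Holds three optional structural features per profile column: a 3-state
#' secondary structure (H helix, E strand, C coil), a 2-state relative
#' solvent accessibility (e exposed, b buried; threshold 25% of the maximum
#' exposed area), and backbone torsion angles phi/psi in degrees within
#' \[-180, 180\]. Any value may be unknown (`NA`); unknown values score 0
#' (neutral) in every structural term so missing predictions never bias an
#' alignment.
#'
#' @param ss Character vector of `"H"`, `"E"`, `"C"` or `NA`.
#' @param sa Character vector of `"e"`, `"b"` or `NA`.
#' @param phi,psi Numeric vectors of angles in degrees, `NA` for unknown.
#' @param length Number of columns; inferred from the longest field when
#'   omitted. Fields given as `NULL` become all-`NA`.
#' @return An object of class `structural_annotation`.
#' @export
structural_annotation <- function(ss = NULL, sa = NULL, phi = NULL,
                                  psi = NULL, length = NULL) {
  L <- length %||% max(base::length(ss), base::length(sa),
                       base::length(phi), base::length(psi))
  if (is.null(L) || L < 1L) .stopf("annotation needs at least one column")
  fill <- function(x, what, mode) {
    if (is.null(x)) return(rep(if (mode == "chr") NA_character_ else NA_real_, L))
    if (mode == "num") x <- as.numeric(x)
    if (base::length(x) != L)
      .stopf("%s has %d values but annotation has %d columns",
             what, base::length(x), L)
    x
  }
  ss <- toupper(fill(ss, "ss", "chr"))
  sa <- tolower(fill(sa, "sa", "chr"))
  phi <- fill(phi, "phi", "num")
  psi <- fill(psi, "psi", "num")
  if (!all(ss %in% c("H", "E", "C", NA)))
    .stopf("secondary structure states must be H, E or C")
  if (!all(sa %in% c("e", "b", NA)))
    .stopf("solvent accessibility states must be e or b")
  for (ang in list(phi = phi, psi = psi)) {
    bad <- which(!is.na(ang) & (ang < -180 | ang > 180))
    if (base::length(bad))
      .stopf("torsion angle out of [-180, 180] at column %d", bad[1])
  }
  structure(list(length = as.integer(L), ss = ss, sa = sa,
                 phi = phi, psi = psi),
            class = "structural_annotation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.structural_annotation <- function(x, ...) {
  cat(sprintf("structural_annotation: %d columns (ss %d, sa %d, angles %d known)\n",
              x$length, sum(!is.na(x$ss)), sum(!is.na(x$sa)),
              sum(!is.na(x$phi) & !is.na(x$psi))))
  invisible(x)
}

#' Discretize relative solvent accessibility
#'
#' A residue is exposed (`"e"`) when at least 25% of its maximum surface
#' area is solvent-accessible, buried (`"b"`) below that; the boundary value
#' 0.25 is exposed.
#'
#' @param rsa Numeric vector of relative exposures in \[0, 1\]; `NA` passes
#'   through.
#' @return Character vector of `"e"` / `"b"` (NA preserved).
#' @examples
#' discretize_sa(c(0.30, 0.10, 0.25))  # "e" "b" "e"
#' @export
discretize_sa <- function(rsa) {
  rsa <- as.numeric(rsa)
  bad <- which(!is.na(rsa) & (rsa < 0 | rsa > 1))
  if (length(bad)) .stopf("relative solvent accessibility out of [0, 1]: %g", rsa[bad[1]])
  ifelse(is.na(rsa), NA_character_, ifelse(rsa >= 0.25, "e", "b"))
}

# 8-state DSSP codes -> 3 states
collapse_ss8 <- function(x) {
  x <- toupper(x)
  out <- rep(NA_character_, length(x))
  out[x %in% c("H", "G", "I")] <- "H"
  out[x %in% c("E", "B")] <- "E"
  out[!is.na(x) & !(x %in% c("H", "G", "I", "E", "B"))] <- "C"
  out[is.na(x)] <- NA_character_
  out
}

#' Read and write per-residue annotation tables
#'
#' The canonical exchange format is a tab-separated table with a header row
#' `position  ss  sa  phi  psi` and one row per profile column, positions
#' contiguous from 1. Cells may be empty or `.` for unknown. The `ss` column
#' accepts 8-state DSSP codes (collapsed H,G,I->H; E,B->E; rest->C). The
#' `sa` column accepts the states `e` / `b` or a numeric relative exposure
#' in \[0, 1\], which is discretized at the 25% threshold.
#'
#' @param path File path.
#' @return `read_annotation_table` returns a [structural_annotation];
#'   `write_annotation_table` returns `path` invisibly.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = c("", "."),
                          check.names = FALSE, quote = "")
  need <- c("position", "ss", "sa", "phi", "psi")
  if (!all(need %in% names(df)))
    .stopf("annotation table must have columns: %s", paste(need, collapse = ", "))
  pos <- as.integer(df$position)
  if (any(is.na(pos)) || !identical(pos, seq_along(pos)))
    .stopf("annotation positions must be contiguous from 1")
  sa_raw <- df$sa
  sa_num <- suppressWarnings(as.numeric(sa_raw))
  sa <- ifelse(is.na(sa_raw), NA_character_,
               ifelse(!is.na(sa_num), discretize_sa(sa_num), tolower(sa_raw)))
  ang <- function(col, name) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(v))
    if (length(bad)) .stopf("non-numeric %s at row %d", name, bad[1])
    out <- which(!is.na(v) & (v < -180 | v > 180))
    if (length(out)) .stopf("%s out of [-180, 180] at row %d", name, out[1])
    v
  }
  structural_annotation(ss = collapse_ss8(df$ss), sa = sa,
                        phi = ang(df$phi, "phi"), psi = ang(df$psi, "psi"),
                        length = length(pos))
}

#' @param ann A [structural_annotation].
#' @rdname read_annotation_table
#' @export
write_annotation_table <- function(ann, path) {
  stopifnot(inherits(ann, "structural_annotation"))
  dot <- function(x, fmt = "%s") ifelse(is.na(x), ".", sprintf(fmt, x))
  df <- data.frame(position = seq_len(ann$length),
                   ss = dot(ann$ss), sa = dot(ann$sa),
                   phi = dot(ann$phi, "%.6g"), psi = dot(ann$psi, "%.6g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
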