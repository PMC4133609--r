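#' Background amino-acid frequency model
#'
#' The null model f(a) against which profile emissions are scored. The
#' default table is the Robinson & Robinson survey of database amino-acid
#' composition, renormalized over the 20 standard residues; it can be
#' replaced by any strictly positive vector of 20 frequencies.
#'
#' @param frequencies Numeric vector of 20 relative frequencies, named or in
#'   [AA_ALPHABET] order. Renormalized to sum to 1.
#' @return An object of class `background_model`: a named numeric vector of
#'   20 probabilities summing to 1.
#' @examples
#' bg <- default_background()
#' sum(bg)  # 1
#' @export
background_model <- function(frequencies) {
  if (length(frequencies) != 20L)
    .stopf("background model needs 20 frequencies, got %d", length(frequencies))
  if (!is.null(names(frequencies))) {
    if (!setequal(names(frequencies), AA_ALPHABET))
      .stopf("background frequency names must be the 20 amino acids")
    frequencies <- frequencies[AA_ALPHABET]
  }
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    .stopf("background frequencies must be finite and strictly positive")
  f <- frequencies / sum(frequencies)
  names(f) <- AA_ALPHABET
  structure(f, class = "background_model")
}

#' @rdname background_model
#' @export
default_background <- function() {
  # Robinson & Robinson (1991) database composition, alphabetical order
  f <- c(A = 0.078047, C = 0.019246, D = 0.053640, E = 0.062949,
         F = 0.038556, G = 0.073770, H = 0.021992, I = 0.051420,
         K = 0.057438, L = 0.090191, M = 0.022425, N = 0.044873,
         P = 0.052028, Q = 0.042644, R = 0.051269, S = 0.071198,
         T = 0.058413, V = 0.064409, W = 0.013298, Y = 0.032165)
  background_model(f)
}

validate_background <- function(bg) {
  stopifnot(inherits(bg, "background_model"))
  if (abs(sum(bg) - 1) > 1e-9) .stopf("background frequencies must sum to 1")
  invisible(bg)
}
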