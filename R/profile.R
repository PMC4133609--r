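#' Profile hidden Markov models
#'
#' A profile HMM summarizes a protein family column by column: a match-state
#' emission distribution `q_i(a)` over the 20 amino acids and seven
#' transition probabilities (M->M, M->I, M->D, I->M, I->I, D->M, D->D) per
#' column. Structural annotations (secondary structure, solvent
#' accessibility, torsion angles) can be attached and are then used by the
#' augmented match score.
#'
#' @param name Profile name.
#' @param emissions L x 20 numeric matrix; each row a probability
#'   distribution over [AA_ALPHABET].
#' @param transitions L x 7 numeric matrix with columns
#'   `MM, MI, MD, IM, II, DM, DD`; the three source-state groups
#'   (M, I, D) must each sum to 1 per row.
#' @param annotation Optional [structural_annotation] of matching length.
#' @return An object of class `profile_hmm`.
#' @export
profile_hmm <- function(name, emissions, transitions, annotation = NULL) {
  emissions <- as.matrix(emissions)
  transitions <- as.matrix(transitions)
  colnames(emissions) <- AA_ALPHABET
  colnames(transitions) <- TRANSITION_NAMES
  p <- structure(list(name = as.character(name)[1],
                      length = nrow(emissions),
                      emissions = emissions,
                      transitions = transitions,
                      annotation = annotation),
                 class = "profile_hmm")
  validate_profile(p)
}

#' Validate a profile HMM
#'
#' Checks the probabilistic invariants: emission rows sum to 1 (1e-9),
#' entries non-negative, each transition source-state group sums to 1
#' (1e-9), and an attached annotation matches the profile length.
#'
#' @param p A `profile_hmm`.
#' @return `p`, invisibly usable; errors name the offending column.
#' @export
validate_profile <- function(p) {
  stopifnot(inherits(p, "profile_hmm"))
  L <- p$length
  if (L < 1L) .stopf("profile '%s' has length %d; must be >= 1", p$name, L)
  if (ncol(p$emissions) != 20L) .stopf("emissions must have 20 columns")
  if (nrow(p$transitions) != L || ncol(p$transitions) != 7L)
    .stopf("transitions must be %d x 7", L)
  if (any(p$emissions < 0) || any(!is.finite(p$emissions))) {
    bad <- which(apply(p$emissions, 1L, function(r) any(r < 0 | !is.finite(r))))[1]
    .stopf("negative or non-finite emission in column %d", bad)
  }
  rs <- rowSums(p$emissions)
  if (any(abs(rs - 1) > 1e-9))
    .stopf("emission row does not sum to 1 in column %d (sum %.6g)",
           which(abs(rs - 1) > 1e-9)[1], rs[which(abs(rs - 1) > 1e-9)[1]])
  if (any(p$transitions < 0 | !is.finite(p$transitions)))
    .stopf("negative or non-finite transition probability")
  for (grp in list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))) {
    gs <- rowSums(p$transitions[, grp, drop = FALSE])
    if (any(abs(gs - 1) > 1e-9))
      .stopf("transitions out of state %s do not sum to 1 in column %d",
             substr(grp[1], 1, 1), which(abs(gs - 1) > 1e-9)[1])
  }
  if (!is.null(p$annotation)) {
    stopifnot(inherits(p$annotation, "structural_annotation"))
    if (p$annotation$length != L)
      .stopf("annotation has %d columns but profile has %d",
             p$annotation$length, L)
  }
  p
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s': %d columns%s\n", x$name, x$length,
              if (is.null(x$annotation)) "" else " (annotated)"))
  invisible(x)
}

#' Build a profile HMM from a multiple sequence alignment
#'
#' Emissions are a pseudocount admixture of weighted observed residue
#' frequencies with the background: `q_i = (1 - tau) * obs_i + tau * f`,
#' floored at `emission_floor` and renormalized. Transition probabilities
#' are estimated from the gap-run structure of the alignment (a gap in a row
#' is a delete state) with one pseudo-observation of the default transition
#' table; insert transitions fall back to defaults because A3M insert
#' columns are removed on reading. All-gap columns are dropped with a
#' warning.
#'
#' @param x An [msa].
#' @param background A [background_model].
#' @param tau Pseudocount admixture in \[0, 1\]; `tau = 1` gives the
#'   background exactly.
#' @param weighting `"uniform"` or `"position-based"` (Henikoff) sequence
#'   weights.
#' @param name Profile name.
#' @param emission_floor Minimum emission probability after admixture
#'   (avoids log(0) in column scores).
#' @param annotation Optional [structural_annotation] to attach.
#' @return A [profile_hmm].
#' @examples
#' m <- msa(c("ACD", "ACD", "AMD"))
#' p <- build_profile(m, default_background(), tau = 0.1)
#' @export
build_profile <- function(x, background = default_background(), tau = 0.1,
                          weighting = c("uniform", "position-based"),
                          name = "profile", emission_floor = 1e-6,
                          annotation = NULL) {
  stopifnot(inherits(x, "msa"))
  validate_background(background)
  weighting <- match.arg(weighting)
  if (!is.numeric(tau) || tau < 0 || tau > 1) .stopf("tau must be in [0, 1]")

  keep <- which(colSums(x$seqs != "-") > 0L)
  if (length(keep) < ncol(x$seqs))
    .warnf("dropping %d all-gap column(s)", ncol(x$seqs) - length(keep))
  if (length(keep) == 0L) .stopf("alignment has no non-gap columns")
  m <- x$seqs[, keep, drop = FALSE]
  L <- ncol(m)
  n <- nrow(m)

  w <- if (weighting == "uniform") rep(1 / n, n) else henikoff_weights(m)

  emis <- matrix(0, L, 20L, dimnames = list(NULL, AA_ALPHABET))
  for (i in seq_len(L)) {
    col <- m[, i]
    res <- col %in% AA_ALPHABET
    if (any(res)) {
      cw <- tapply(w[res], factor(col[res], levels = AA_ALPHABET), sum)
      cw[is.na(cw)] <- 0
      obs <- cw / sum(cw)
    } else {
      obs <- background  # column of only X: no residue information
    }
    q <- (1 - tau) * obs + tau * background
    q <- pmax(q, emission_floor)
    emis[i, ] <- q / sum(q)
  }

  trans <- estimate_transitions(m, w)
  profile_hmm(name, emis, trans, annotation = annotation)
}

# Henikoff position-based sequence weights; gaps count as a symbol
henikoff_weights <- function(m) {
  n <- nrow(m)
  w <- numeric(n)
  for (i in seq_len(ncol(m))) {
    col <- m[, i]
    counts <- table(col)
    r <- length(counts)
    w <- w + 1 / (r * as.numeric(counts[col]))
  }
  w / sum(w)
}

# Per-column transitions from the gap structure: residue = M, '-' = D.
# Counts between column i and i+1 are shrunk toward the default table with
# one pseudo-observation; insert states are never observed (A3M inserts are
# stripped) so I-transitions stay at their defaults.
estimate_transitions <- function(m, w) {
  L <- ncol(m)
  trans <- matrix(rep(DEFAULT_TRANSITIONS, each = L), L, 7L,
                  dimnames = list(NULL, TRANSITION_NAMES))
  if (L < 2L) return(trans)
  is_res <- m != "-"
  for (i in seq_len(L - 1L)) {
    cur <- is_res[, i]
    nxt <- is_res[, i + 1L]
    n_mm <- sum(w[cur & nxt]);  n_md <- sum(w[cur & !nxt])
    n_dm <- sum(w[!cur & nxt]); n_dd <- sum(w[!cur & !nxt])
    c0 <- 1  # pseudo-observation weight
    mm <- n_mm + c0 * DEFAULT_TRANSITIONS["MM"]
    mi <- c0 * DEFAULT_TRANSITIONS["MI"]
    md <- n_md + c0 * DEFAULT_TRANSITIONS["MD"]
    sM <- mm + mi + md
    dm <- n_dm + c0 * DEFAULT_TRANSITIONS["DM"]
    dd <- n_dd + c0 * DEFAULT_TRANSITIONS["DD"]
    sD <- dm + dd
    trans[i, c("MM", "MI", "MD")] <- c(mm, mi, md) / sM
    trans[i, c("DM", "DD")] <- c(dm, dd) / sD
  }
  trans
}

#' Read and write profiles in the native text dialect
#'
#' The native dialect is a tab-separated text format: a `profalign_profile`
#' magic line, `name`, `length` and `background` header lines, one line per
#' column carrying the 20 emission and 7 transition probabilities at full
#' double precision (round-trips within 1e-12), and optional `ss`, `sa`,
#' `phi`, `psi` annotation lines.
#'
#' @param path File path.
#' @return `read_profile` returns a validated [profile_hmm];
#'   `write_profile` returns `path` invisibly.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 4L || !startsWith(lines[1], "profalign_profile"))
    .stopf("%s is not a profalign profile file", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- function(key) {
    i <- which(vapply(fields, `[`, "", 1L) == key)
    if (length(i) != 1L) .stopf("profile file missing '%s' header", key)
    fields[[i]][-1L]
  }
  name <- hdr("name")
  L <- as.integer(hdr("length"))
  if (is.na(L) || L < 1L) .stopf("profile of length %s fails validation", hdr("length"))
  bg <- as.numeric(hdr("background"))
  col_lines <- fields[vapply(fields, `[`, "", 1L) == "col"]
  if (length(col_lines) != L)
    .stopf("expected %d column lines, found %d", L, length(col_lines))
  emis <- matrix(NA_real_, L, 20L)
  trans <- matrix(NA_real_, L, 7L)
  for (k in seq_len(L)) {
    v <- as.numeric(col_lines[[k]][-(1:2)])
    if (length(v) != 27L || any(is.na(v)))
      .stopf("malformed column line %d: need 27 numeric values", k)
    emis[k, ] <- v[1:20]
    trans[k, ] <- v[21:27]
  }
  ann <- NULL
  keys <- vapply(fields, `[`, "", 1L)
  if (any(keys %in% c("ss", "sa", "phi", "psi"))) {
    get_opt <- function(key) if (key %in% keys) hdr(key) else NULL
    chr <- function(x) if (is.null(x)) NULL else ifelse(x == ".", NA_character_, x)
    num <- function(x) if (is.null(x)) NULL else
      suppressWarnings(as.numeric(ifelse(x == ".", NA_character_, x)))
    ann <- structural_annotation(ss = chr(get_opt("ss")), sa = chr(get_opt("sa")),
                                 phi = num(get_opt("phi")), psi = num(get_opt("psi")),
                                 length = L)
  }
  profile_hmm(name, emis, trans, annotation = ann)
}

#' @param p A [profile_hmm].
#' @rdname read_profile
#' @export
write_profile <- function(p, path) {
  validate_profile(p)
  num <- function(x) sprintf("%.17g", x)
  out <- c("profalign_profile\tv1",
           paste0("name\t", p$name),
           paste0("length\t", p$length),
           paste("background", paste(num(default_background()), collapse = "\t"),
                 sep = "\t"),
           vapply(seq_len(p$length), function(i) {
             paste(c("col", i, num(p$emissions[i, ]), num(p$transitions[i, ])),
                   collapse = "\t")
           }, character(1)))
  if (!is.null(p$annotation)) {
    a <- p$annotation
    dot <- function(x, f = identity) {
      paste(ifelse(is.na(x), ".", f(x)), collapse = "\t")
    }
    out <- c(out,
             paste0("ss\t", dot(a$ss)), paste0("sa\t", dot(a$sa)),
             paste0("phi\t", dot(a$phi, num)), paste0("psi\t", dot(a$psi, num)))
  }
  writeLines(out, path)
  invisible(path)
}
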