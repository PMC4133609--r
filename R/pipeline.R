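#' End-to-end profile-profile alignment pipeline
#'
#' Runs the full alignment workflow on two profiles: (1) Viterbi alignment
#' for the log-sum-of-odds score; (2) unless `realign = "none"`,
#' Forward-Backward posteriors and maximum-accuracy realignment, which
#' becomes the final alignment; (3) when coupling information is supplied,
#' the MAC traceback is repeated with evolutionary-coupling bonuses and
#' that alignment is returned as final.
#'
#' Each side may be given as a [profile_hmm], an [msa] (a profile is built
#' with default settings), or a file path (`.fasta`/`.fa`/`.a3m` read as an
#' MSA, anything else as a native profile file). Annotations given
#' separately are attached to the profile; coupling inputs may be partner
#' maps ([select_partners]) or MSAs/omitted (partners are then derived from
#' the input MSA via [mutual_information_matrix] when `use_coupling` is
#' `TRUE`).
#'
#' @param query,template Profile inputs (see Details).
#' @param w A [scoring_weights].
#' @param background A [background_model].
#' @param realign `"mac"` (default) or `"none"` (Viterbi alignment is
#'   final).
#' @param query_annotation,template_annotation Optional
#'   [structural_annotation] (or annotation table path) to attach.
#' @param query_partners,template_partners Optional partner maps (or
#'   partner-map file paths) for the EC traceback.
#' @param use_coupling Derive partner maps from the input MSAs when none
#'   are given explicitly (default `FALSE`).
#' @return Object of class `alignment_report`: `viterbi`
#'   ([viterbi_align] result), `posterior`, `mac`, `final`
#'   (a [pairwise_alignment]), `s_lso`, `mac_score`, and the resolved
#'   profiles `query`, `template`.
#' @examples
#' sp <- generate_pair(seed = 3, length = 30)
#' rep <- align_pair(sp$msa_q, sp$msa_t,
#'                   query_annotation = sp$ann_q,
#'                   template_annotation = sp$ann_t)
#' sp_score(rep$final, sp$reference)
#' @export
align_pair <- function(query, template, w = scoring_weights(),
                       background = default_background(),
                       realign = c("mac", "none"),
                       query_annotation = NULL, template_annotation = NULL,
                       query_partners = NULL, template_partners = NULL,
                       use_coupling = FALSE) {
  realign <- match.arg(realign)
  qr <- resolve_profile(query, "query", background)
  tr <- resolve_profile(template, "template", background)
  q <- attach_annotation(qr$profile, query_annotation)
  t <- attach_annotation(tr$profile, template_annotation)

  vit <- viterbi_align(q, t, w, background)
  out <- list(viterbi = vit, s_lso = vit$score, query = q, template = t)
  if (realign == "none") {
    out$final <- vit$alignment
    return(structure(out, class = "alignment_report"))
  }

  post <- forward_backward(q, t, w, background)
  mac <- mac_align(post, mact = w$mact)
  out$posterior <- post
  out$mac <- mac
  out$mac_score <- mac$best_score

  k_q <- resolve_partners(query_partners, q$length)
  k_t <- resolve_partners(template_partners, t$length)
  if (is.null(k_q) && use_coupling && inherits(qr$msa, "msa"))
    k_q <- select_partners(mutual_information_matrix(qr$msa))
  if (is.null(k_t) && use_coupling && inherits(tr$msa, "msa"))
    k_t <- select_partners(mutual_information_matrix(tr$msa))

  out$final <- if ((!is.null(k_q) || !is.null(k_t)) && w$w_ec > 0)
    ec_traceback(mac, k_q, k_t, w_ec = w$w_ec)
  else mac$alignment
  structure(out, class = "alignment_report")
}

resolve_profile <- function(x, side, background) {
  if (inherits(x, "profile_hmm")) return(list(profile = x, msa = NULL))
  if (inherits(x, "msa"))
    return(list(profile = build_profile(x, background, name = side), msa = x))
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) .stopf("missing %s input file: %s", side, x)
    ext <- tolower(tools::file_ext(x))
    if (ext %in% c("fasta", "fa", "mfa", "a3m")) {
      m <- read_msa(x, format = if (ext == "a3m") "a3m" else "fasta")
      return(list(profile = build_profile(m, background, name = side), msa = m))
    }
    return(list(profile = read_profile(x), msa = NULL))
  }
  .stopf("%s input must be a profile_hmm, msa, or file path", side)
}

attach_annotation <- function(p, ann) {
  if (is.null(ann)) return(p)
  if (is.character(ann)) ann <- read_annotation_table(ann)
  stopifnot(inherits(ann, "structural_annotation"))
  if (ann$length != p$length)
    .stopf("annotation length %d does not match profile '%s' length %d",
           ann$length, p$name, p$length)
  p$annotation <- ann
  validate_profile(p)
}

resolve_partners <- function(x, L) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) return(read_partner_map(x, L))
  if (length(x) != L)
    .stopf("partner map length %d does not match profile length %d",
           length(x), L)
  x
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("alignment_report %s ~ %s\n  S_LSO = %.4f bits\n",
              x$query$name, x$template$name, x$s_lso))
  if (!is.null(x$mac_score))
    cat(sprintf("  MAC best AS = %.4f\n", x$mac_score))
  cat(sprintf("  final alignment: %d columns, %d matched pairs\n",
              nrow(x$final), sum(x$final$state == "MM")))
  invisible(x)
}
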