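#' Seeded synthetic homolog-pair generator
#'
#' Emulates a CASP-style query-template pair with a known true alignment:
#' an ancestral sequence is drawn from the background, two descendants
#' diverge from it by background-draw substitutions and indels (the indel
#' history fixes the true alignment), and each descendant seeds a shallow
#' sequence family (its MSA). Per-column structural states drive secondary
#' structure, exposed/buried labels and canonical torsion angles; truly
#' aligned columns agree structurally with probability
#' `annotation_agreement`. Optional coupled column pairs are planted by
#' forcing covariation between two columns across the family with the
#' given strength. Substitutions are background draws (no substitution
#' matrix) and families carry no internal gaps: deliberately simple,
#' non-biological dynamics that keep every downstream oracle exact.
#'
#' @param seed Integer seed; regeneration with the same parameters is
#'   bit-identical.
#' @param length Ancestral length (>= 5).
#' @param n_seq Sequences per family MSA (>= 2).
#' @param divergence Per-column substitution probability ancestor ->
#'   descendant, in \[0, 1\].
#' @param indel_rate Per-column probability of a deletion (and, half as
#'   often per side, an insertion) in each descendant, in \[0, 1\].
#' @param mutation_rate Within-family per-column substitution probability.
#' @param annotation_agreement Probability that a truly aligned column pair
#'   shares its structural state and exposure label.
#' @param coupled_pairs Integer matrix (two columns) of ancestral column
#'   pairs to couple in both families, or `NULL`.
#' @param coupling_strength Probability in \[0, 1\] that a family sequence
#'   obeys the planted covariation at a coupled pair.
#' @return Object of class `synthetic_pair`: `msa_q`, `msa_t` ([msa]),
#'   `ann_q`, `ann_t` ([structural_annotation]), `true_alignment`
#'   (a [pairwise_alignment] of MM rows), `reference`
#'   (a [reference_alignment]), `partners_q`, `partners_t` (planted
#'   partner maps in descendant coordinates), and `params`.
#' @examples
#' sp <- generate_pair(seed = 7, length = 30)
#' sp$true_alignment
#' @export
generate_pair <- function(seed = 1L, length = 60L, n_seq = 20L,
                          divergence = 0.3, indel_rate = 0.05,
                          mutation_rate = 0.1, annotation_agreement = 0.9,
                          coupled_pairs = NULL, coupling_strength = 0.9) {
  if (length < 5L) .stopf("length must be >= 5")
  if (n_seq < 2L) .stopf("n_seq must be >= 2")
  for (r in c(divergence, indel_rate, mutation_rate, annotation_agreement,
              coupling_strength))
    if (r < 0 || r > 1) .stopf("rates must lie in [0, 1]")
  set.seed(seed)
  bg <- default_background()

  anc <- sample(AA_ALPHABET, length, replace = TRUE, prob = bg)
  anc_state <- sample_ss_runs(length)
  anc_sa <- sample(c("e", "b"), length, replace = TRUE)

  desc <- function(copy_states_from = NULL) {
    keep <- runif(length) >= indel_rate
    res <- character(0); src <- integer(0)
    for (i in seq_len(length)) {
      if (keep[i]) {
        r <- if (runif(1) < divergence)
          sample(AA_ALPHABET, 1, prob = bg) else anc[i]
        res <- c(res, r); src <- c(src, i)
      }
      if (runif(1) < indel_rate / 2) {  # insertion after column i
        res <- c(res, sample(AA_ALPHABET, 1, prob = bg))
        src <- c(src, NA_integer_)
      }
    }
    if (base::length(res) < 1L)
      .stopf("degenerate parameters: a descendant lost every column")
    list(res = res, src = src)
  }
  dq <- desc(); dt <- desc()

  # true alignment: ancestral columns surviving in both descendants
  common <- intersect(dq$src[!is.na(dq$src)], dt$src[!is.na(dt$src)])
  if (base::length(common) == 0L)
    .stopf("degenerate parameters: descendants share no columns")
  qpos <- match(common, dq$src); tpos <- match(common, dt$src)
  true_aln <- pairwise_alignment(qpos, tpos, rep("MM", base::length(common)),
                                 query = "query", template = "template")
  reference <- reference_alignment(cbind(qpos, tpos))

  # structural states: query inherits the ancestor; template agrees on
  # truly aligned columns with the given probability, otherwise resamples
  st_q <- derive_states(dq$src, anc_state)
  sa_q <- derive_states(dq$src, anc_sa, fallback = c("e", "b"))
  st_t <- derive_states(dt$src, anc_state)
  sa_t <- derive_states(dt$src, anc_sa, fallback = c("e", "b"))
  for (k in seq_along(qpos)) {
    if (runif(1) >= annotation_agreement)
      st_t[tpos[k]] <- sample(setdiff(c("H", "E", "C"), st_q[qpos[k]]), 1)
    else st_t[tpos[k]] <- st_q[qpos[k]]
    if (runif(1) >= annotation_agreement)
      sa_t[tpos[k]] <- setdiff(c("e", "b"), sa_q[qpos[k]])
    else sa_t[tpos[k]] <- sa_q[qpos[k]]
  }
  ann_q <- annotate_from_states(st_q, sa_q)
  ann_t <- annotate_from_states(st_t, sa_t)

  # family MSAs by shallow mutation of each descendant
  fam <- function(d) {
    t(vapply(seq_len(n_seq), function(s) {
      mut <- runif(base::length(d$res)) < mutation_rate
      out <- d$res
      out[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE, prob = bg)
      out
    }, character(base::length(d$res))))
  }
  mq <- fam(dq); mt <- fam(dt)

  # plant covarying column pairs (ancestral coordinates -> each family)
  part_q <- rep(NA_integer_, base::length(dq$res))
  part_t <- rep(NA_integer_, base::length(dt$res))
  if (!is.null(coupled_pairs)) {
    coupled_pairs <- matrix(as.integer(coupled_pairs), ncol = 2L)
    perm <- c(seq_along(AA_ALPHABET)[-1], 1L)  # fixed residue pairing rule
    plant <- function(m, d, part) {
      for (r in seq_len(nrow(coupled_pairs))) {
        a <- match(coupled_pairs[r, 1], d$src)
        b <- match(coupled_pairs[r, 2], d$src)
        if (is.na(a) || is.na(b)) next
        obey <- runif(nrow(m)) < coupling_strength
        code <- match(m[obey, a], AA_ALPHABET)
        m[obey, b] <- AA_ALPHABET[perm[code]]
        part[a] <- b; part[b] <- a
      }
      list(m = m, part = part)
    }
    pq <- plant(mq, dq, part_q); mq <- pq$m; part_q <- pq$part
    pt <- plant(mt, dt, part_t); mt <- pt$m; part_t <- pt$part
  }

  structure(list(
    msa_q = msa(mq, ids = paste0("q", seq_len(n_seq))),
    msa_t = msa(mt, ids = paste0("t", seq_len(n_seq))),
    ann_q = ann_q, ann_t = ann_t,
    true_alignment = true_aln, reference = reference,
    partners_q = structure(part_q, class = "partner_map"),
    partners_t = structure(part_t, class = "partner_map"),
    params = list(seed = seed, length = length, n_seq = n_seq,
                  divergence = divergence, indel_rate = indel_rate,
                  mutation_rate = mutation_rate,
                  annotation_agreement = annotation_agreement,
                  coupled_pairs = coupled_pairs,
                  coupling_strength = coupling_strength)),
    class = "synthetic_pair")
}

# helix/strand/coil runs of length 3-8
sample_ss_runs <- function(L) {
  out <- character(0)
  while (base::length(out) < L) {
    out <- c(out, rep(sample(c("H", "E", "C"), 1), sample(3:8, 1)))
  }
  out[seq_len(L)]
}

# map descendant columns to ancestral per-column states; inserted columns
# draw a fresh state
derive_states <- function(src, anc_states, fallback = c("H", "E", "C")) {
  out <- character(base::length(src))
  known <- !is.na(src)
  out[known] <- anc_states[src[known]]
  if (any(!known))
    out[!known] <- sample(fallback, sum(!known), replace = TRUE)
  out
}

# canonical torsion-angle basins per state, with noise
annotate_from_states <- function(st, sa, noise_sd = 15) {
  basin <- list(H = c(-60, -45), E = c(-120, 130), C = c(-75, 150))
  phi <- vapply(st, function(s) basin[[s]][1], numeric(1)) +
    stats::rnorm(base::length(st), 0, noise_sd)
  psi <- vapply(st, function(s) basin[[s]][2], numeric(1)) +
    stats::rnorm(base::length(st), 0, noise_sd)
  clip <- function(x) pmin(pmax(x, -180), 180)
  structural_annotation(ss = st, sa = sa, phi = clip(phi), psi = clip(psi))
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf(paste0("synthetic_pair (seed %d): query %d cols, template %d",
                     " cols, %d true pairs\n"),
              x$params$seed, x$msa_q$n_col, x$msa_t$n_col,
              nrow(x$true_alignment)))
  invisible(x)
}

#' Write all fixture files of a synthetic pair
#'
#' Emits, under `dir`: `query.fasta` / `template.fasta` (family MSAs),
#' `query.ann` / `template.ann` (annotation tables), `reference.fasta`
#' (two-row aligned FASTA of the descendant consensus sequences under the
#' true alignment) and, when partners were planted, `query.partners` /
#' `template.partners`.
#'
#' @param x A [generate_pair] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_pair <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_msa(x$msa_q, fp("query.fasta"))
  write_msa(x$msa_t, fp("template.fasta"))
  write_annotation_table(x$ann_q, fp("query.ann"))
  write_annotation_table(x$ann_t, fp("template.ann"))
  writeLines(render_reference_fasta(x), fp("reference.fasta"))
  if (any(!is.na(x$partners_q)))
    write_partner_map(x$partners_q, fp("query.partners"))
  if (any(!is.na(x$partners_t)))
    write_partner_map(x$partners_t, fp("template.partners"))
  invisible(dir)
}

# two-row aligned FASTA from the true pairs and the family consensus rows
render_reference_fasta <- function(x) {
  cons <- function(m) apply(m$seqs, 2L, function(col) {
    tb <- table(col[col %in% AA_ALPHABET])
    if (base::length(tb) == 0L) "X" else names(tb)[which.max(tb)]
  })
  cq <- cons(x$msa_q); ct <- cons(x$msa_t)
  pr <- x$reference$pairs
  qi <- 1L; ti <- 1L
  rq <- character(0); rt <- character(0)
  emit_gap <- function(upto_q, upto_t) {
    while (qi < upto_q) { rq <<- c(rq, cq[qi]); rt <<- c(rt, "-"); qi <<- qi + 1L }
    while (ti < upto_t) { rq <<- c(rq, "-"); rt <<- c(rt, ct[ti]); ti <<- ti + 1L }
  }
  for (k in seq_len(nrow(pr))) {
    emit_gap(pr[k, 1], pr[k, 2])
    rq <- c(rq, cq[qi]); rt <- c(rt, ct[ti]); qi <- qi + 1L; ti <- ti + 1L
  }
  emit_gap(base::length(cq) + 1L, base::length(ct) + 1L)
  c(">query", paste(rq, collapse = ""),
    ">template", paste(rt, collapse = ""))
}
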