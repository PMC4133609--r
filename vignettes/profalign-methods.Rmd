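---
title: "Structure-augmented profile-HMM alignment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-augmented profile-HMM alignment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profalign)
```

## The model

Each protein family enters as a profile HMM: per column `i`, an emission
distribution `q_i(a)` over the 20 amino acids and seven transition
probabilities (M→M, M→I, M→D, I→M, I→I, D→M, D→D). Aligning two HMMs
means threading a path through pair states `MM, MI, IM, DG, GD` — `MI`
and `DG` consume a query column against a template insert or gap, `IM`
and `GD` the reverse — and scoring it by the log-sum-of-odds objective:
the sum over matched column pairs of the column score

    S_aa(i, j) = log2 sum_a q_i(a) t_j(a) / f(a)

plus the log2 transition probabilities along the path. `f(a)` is a fixed
background (Robinson–Robinson database composition, replaceable via
`background_model()`). On top of `S_aa` the match-match score adds three
structural agreement terms with weights and a constant shift:

    S(q_i, t_j) = S_aa + w_ss*S_ss + w_sa*S_sa + w_tors*S_tors + S_shift

`S_ss` is a 3-state secondary-structure table lookup (+1/-1 by default,
user-replaceable 3×3 matrix); `S_sa` is the Kronecker delta on the
exposed/buried state (threshold: 25% relative accessibility, boundary
exposed); `S_tors` compares backbone torsion angles. Any unknown
annotation value makes its term exactly 0, so missing predictions never
bias the alignment in either direction.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `w_ss` | 0.11 | weight of the secondary-structure term |
| `w_sa` | 0.72 | weight of the solvent-accessibility delta |
| `w_tors` | 0.4 | weight of the torsion-angle term |
| `S_shift` | -0.03 | constant offset per matched pair |
| `w_ec` | 0.1 | coupling bonus in the MAC re-trace |
| `mact` | 0.3501 | MAC greediness penalty, in [0, 1) |
| `tau` | 0.1 | background admixture in profile construction |

The four score weights and `mact` are the method's optimized operating
point and are exposed unchanged through `scoring_weights()` and the CLI
flags. `mact` trades alignment length against precision: 0 yields nearly
global alignments, values near 1 very short, confident local ones.

## Decoders

**Viterbi.** Five score matrices are filled with the standard
profile-profile recursions; gap states carry transition log-odds only
(insert emissions cancel against the background). Local mode allows a
path to start and end at any cell (the empty alignment scores 0); ties
prefer `MM > MI > IM > DG > GD`, then the diagonal predecessor, making
output deterministic.

**Forward–Backward and MAC.** The same augmented match score enters the
partition functions as an odds factor `P_match = 2^S`; insert/delete
partition states carry transition factors only (the structural terms are
match-state properties). Posteriors are
`p(i~j) = F_MM(i,j) B_MM(i,j) / Z`. The maximum-accuracy alignment then
maximizes `sum p(i~j) - mact * pairs` with gap moves costing `mact/2`
(the constant of the cited MAC formulation), by the recursion

    AS(i,j) = max( AS(i-1,j-1) + p(i~j) - mact,
                   AS(i-1,j) - mact/2, AS(i,j-1) - mact/2, 0 )

traced back from the maximum cell until a zero cell.

**Coupling-guided traceback.** Mutual information over 21 symbols (20
residues + gap) is computed between all column pairs of each family MSA;
the top pairs (default `ceil(L/10)`, minimum separation 5, each column
used once, ties to the lexicographically smaller pair) become partner
maps `k(·)`. A first, standard MAC traceback yields the matched-column
maps `M_q`, `M_t`; a second traceback then reads the augmented matrix
`AS'(i,j) = AS(i,j) + w_ec*δ(M_q(k_q(i)), k_t(j)) +
w_ec*δ(M_t(k_t(j)), k_q(i))`, rewarding cells whose coupled partners
were matched to each other. With `w_ec = 0` or no partners the re-trace
is bitwise identical to the standard one.

## Design choices where the design was open

* **Torsion score form.** The published description of the torsion term
  was not recoverable in detail, so the package defines it as
  `[cos(φ_q-φ_t) + cos(ψ_q-ψ_t)]/2`: the simplest smooth similarity that
  is symmetric, bounded in [-1, 1] and naturally 360°-periodic, so -180°
  and +180° are correctly identified. This is a deliberate, prominently
  flagged package choice.
* **Secondary-structure table.** The upstream confidence-conditioned
  substitution matrix is out of scope; the default here is +1 match / -1
  mismatch / 0 with unknown, replaceable by any 3×3 table.
* **Global mode.** Defined strictly: the first matched pair is (1,1) and
  the last (L_q, L_t), with no terminal gap states. A corollary is that
  profiles of shapes 1×L (L > 1) admit no global path; the package
  raises a clear error rather than inventing a score. Local mode is the
  default and matches common practice.
* **Forward–Backward start/end weights.** `p_min` multiplies the start
  and end weight of every non-terminal cell, so `p_min = 1` is the local
  model, `p_min = 0` the global one (matching the convention above); the
  local total partition sums `F_MM` over all cells.
* **Two-pass EC traceback.** The coupling bonus reads pass-1 matches
  only; augmentation does not cascade into re-derived matches within
  pass 2. This freezes an interpretation of the published figure and
  keeps the procedure deterministic.
* **MI estimation.** Natural log; the additive pseudocount (default
  `1/n_seq`) is applied to the joint counts and the marginals are then
  obtained by summing the joint, which guarantees MI ≥ 0. With
  pseudocount 0 the estimator is the exact plug-in MI (used by the
  analytic tests).
* **Partner selection.** Pairs with MI equal to 0 are never selected:
  zero mutual information is no evidence of coupling.
* **Profile construction.** Emissions are `(1-τ)·observed + τ·f`,
  floored at 1e-6 and renormalized (so `S_aa` never sees log 0; with
  τ = 1 the floor is inactive and emissions equal the background
  exactly). Sequence weighting defaults to uniform, with Henikoff
  position-based weights behind a flag. Transitions come from the
  gap-run structure of the MSA shrunk toward a documented default table
  (M→M 0.97, M→I = M→D 0.015, I and D splits 0.5/0.5) with one
  pseudo-observation; insert transitions stay at their defaults because
  A3M insert columns are removed on reading.
* **Numerics.** All DP kernels run in log2 space with log-sum-exp
  accumulation, so no rescaling bookkeeping is needed and posteriors are
  exact to rounding at any realistic profile length. The column score
  floors its inner sum at 1e-6 (≈ -19.9 bits) to keep zero-overlap
  columns finite.

## The synthetic generator: what a green test establishes

`generate_pair()` draws an ancestral sequence from the background,
derives two descendants by background-draw substitutions (default rate
0.3, a moderate divergence) and per-column indels (default 0.05), and
records the true alignment from the shared surviving columns. Each
descendant then seeds a family MSA by shallow mutation (rate 0.1, no
internal gaps). Structural states (helix/strand/coil runs of length 3–8,
independent exposed/buried labels) are inherited along the true
alignment with probability `annotation_agreement` (default 0.9, a high
agreement mimicking good predictions); torsion angles are drawn from
canonical basins per state (helix -60/-45, strand -120/130, coil
-75/150, Gaussian noise sd 15°). Coupled column pairs are planted by
forcing a fixed residue-pairing rule at the chosen pairs across the
family with the given strength.

This stated world is deliberately simple: substitutions ignore
substitution-matrix structure, families have no phylogeny and no
internal indels, and annotations have no systematic predictor bias. A
green directional test (structural weights not hurting mean SP at high
annotation agreement) therefore establishes that the terms are wired
with the right sign and magnitude discipline — not that the default
weights are optimal for real proteins, which was established on external
benchmark data out of scope here.

## Evaluation

SP is the percentage of core-block reference residue pairs recovered;
TC the percentage of correctly aligned core columns. For strictly
pairwise alignments a column is a residue pair, so the two metrics
coincide by construction; both are kept for reporting parity with the
benchmarking literature. References are consumed as two-row aligned
FASTA with an optional `core` mask record (`*` columns); without a mask
every reference pair is core.

## Known limitations

* No E-value or probability calibration of Viterbi scores (requires
  database-scale score fitting) and no database search mode.
* The HHM profile dialect is not read; profiles come from MSAs or the
  native text format.
* Direct-information couplings and APC correction are out of scope; MI
  is the implemented coupling statistic.
* Strict global mode cannot represent terminal deletions (see above);
  use local mode (default) for end-free behaviour.
* MAC length monotonicity in `mact` is an empirical property verified on
  the test fixtures, not a theorem; pathological posterior matrices
  could in principle violate it.
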