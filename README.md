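# profalign

Pairwise profile-HMM alignment of two proteins, with match scores augmented
by predicted structural features and a traceback optionally guided by
evolutionary residue coupling.

## The problem

Remote protein homologs are routinely found by aligning two *profile hidden
Markov models* (one per protein family) rather than two sequences: each
profile column carries an emission distribution `q_i(a)` over the 20 amino
acids plus match/insert/delete transition probabilities, and the aligner
maximizes the log-sum-of-odds score

    S_LSO = log2 [ prod_k  sum_a q_i(k)(a) t_j(k)(a) / f(a) ]  +  log2 P_tr

over all alignments of the two HMMs, where `f(a)` is the background
frequency and `P_tr` the product of transition probabilities along the
path. This package implements that aligner and extends its match-match
score with three structural agreement terms:

    S(q_i, t_j) = S_aa + w_ss * S_ss + w_sa * S_sa + w_tors * S_tors + S_shift

* `S_ss` — secondary-structure agreement (3-state H/E/C, score table),
* `S_sa` — Kronecker delta on the 2-state solvent accessibility
  (exposed ≥ 25% of maximum area, else buried),
* `S_tors` — torsion-angle similarity
  `[cos(Δφ) + cos(Δψ)] / 2` in [-1, 1],

with optimized default weights `w_ss = 0.11`, `w_sa = 0.72`,
`w_tors = 0.4`, `S_shift = -0.03`. Two decoders are provided: a
five-matrix Viterbi recursion over the pair states
`{MM, MI, IM, DG, GD}` (reports `S_LSO`), and maximum-accuracy (MAC)
realignment from Forward-Backward posteriors `p(i~j)` with greediness
penalty `mact` (default 0.3501), which produces the final alignment. The
MAC traceback can additionally be biased (`w_ec = 0.1`) toward matching
up co-evolving column pairs detected by 21-symbol mutual information in
each family's MSA. Alignments are benchmarked against reference
alignments with SP/TC scores over core blocks, and a seeded synthetic
homolog-pair generator makes the whole pipeline testable without any
external data.

## Worked example

```r
library(profalign)
sp <- generate_pair(seed = 42, length = 40)          # synthetic homolog pair
q <- build_profile(sp$msa_q, name = "T0642", annotation = sp$ann_q)
t <- build_profile(sp$msa_t, name = "2l09A", annotation = sp$ann_t)
rep <- align_pair(q, t)
rep
#> alignment_report T0642 ~ 2l09A
#>   S_LSO = 53.9261 bits
#>   MAC best AS = 20.5571
#>   final alignment: 39 columns, 36 matched pairs
sp_score(rep$final, sp$reference)
#> [1] 97.14286
head(as.data.frame(rep$final), 3)
#>   qpos tpos state     score
#> 1    2    1    MM 0.6093694
#> 2    3    2    MM 0.6215171
#> 3    4    3    MM 0.6907745
```

`S_LSO` is the Viterbi log-sum-of-odds score in bits (how much better than
chance the two families co-emit along the best path). `MAC best AS` is the
maximum-accuracy objective: the sum of match posteriors along the final
alignment minus the `mact` penalties. Each final alignment row carries the
posterior probability that the two columns are truly aligned; the SP score
says the alignment recovers 97% of the planted true residue pairs.

A command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/profalign simulate --seed 4 --length 60 --out fix
Rscript inst/cli/profalign align --query fix/query.fasta \
    --template fix/template.fasta --query-ann fix/query.ann \
    --template-ann fix/template.ann --out aln
Rscript inst/cli/profalign evaluate --predicted aln.tsv \
    --reference fix/reference.fasta --out eval.tsv
```

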