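# eicotriage

Remote-ortholog triage by combined sequence and structural analysis.

## The problem

Many enzyme families diverge so far between distantly related species that
plain pairwise search (BLASTP-style) no longer finds the ortholog: sequence
identity drops toward or below ~20%, coverage fragments, and E-values lose
significance — even when the fold and the catalytic machinery are intact. A
concrete case is the eicosanoid (prostaglandin/leukotriene) synthesis
pathway: most of its human enzymes have no annotated counterpart in
*Drosophila melanogaster*, yet candidate genes exist that conserve the fold
and the catalytic residues of their human analogs.

`eicotriage` implements the full triage pipeline such a study needs, as a
reusable R package:

1. **Iterative profile search.** A position-specific scoring matrix (PSSM)
   is built from the query (or a seed alignment) with Henikoff sequence
   weights and substitution-matrix pseudocounts; Smith–Waterman affine-gap
   alignment (compiled DP kernel) scores every database sequence; raw
   scores get E-values from a Gumbel (Karlin–Altschul) model fitted by
   maximum likelihood on shuffled-sequence nulls,
   `E(S) = K · m · n · exp(−λS)`. Hits with `E ≤ 0.005` are folded back
   into the profile and the search repeats (3 rounds by default).
2. **Conservation screening.** Candidates are aligned into the reference
   family alignment; annotated catalytic residues are mapped column-wise
   and classified *identical* / *equivalent* (Y↔F, D↔N, C↔U plus optional
   conservative groups) / *missing*, with a structural *proximity rescue*:
   a missing residue is recovered if an equivalent residue's superposed
   Cα lies within 5 Å. Domain architectures and 3-state secondary
   structure are compared alongside.
3. **Structural comparison.** Closed-form Kabsch superposition (SVD with
   determinant correction), RMSD over the paired residues, TM-score
   normalized by the reference length
   (`d0 = 1.24·(L−15)^(1/3) − 1.8`, clamped at 0.5), and an iterative
   structure-based sequence alignment (superpose → re-match residues
   within 8 Å by DP → repeat).
4. **Tier assignment.** Each candidate record is placed in one of three
   confidence tiers — high-confidence (group 1: identity ≥ 30%, same
   fold, full functional residue set), mid-range (group 2: identity
   ≥ 20%, fold-level similarity, partial residue set), distant (group 3:
   not detectable as a full-length pairwise match) — or rejected by the
   screen.

A first-class synthetic-data module generates ortholog families at a
controlled identity with planted catalytic motifs, shuffled decoys, and
Cα structures perturbed by a known rigid transform, Gaussian noise and
loop insertions — so every stage is testable against ground truth without
any database access.

## Worked example

Generate a family of remote orthologs (30% identity to the root, a
7-residue planted catalytic motif), add 20 shuffled decoys, and run the
whole pipeline:

```r
library(eicotriage)

fam <- generate_family(family_spec(
  root_length = 200, n_orthologs = 4, target_identity = 30,
  motif_positions = c(20, 55, 90, 120, 150, 170, 190),
  indel_rate = 0.02, seed = 7))
query  <- fam$sequences$root
decoys <- lapply(1:20, function(i) {
  d <- shuffle_decoy(query, seed = 900 + i); d$id <- sprintf("decoy%02d", i); d })
db <- c(fam$sequences[-1], decoys)

res <- screen_candidates(query, db, fam$motif, seed = 1)
head(res$summary[order(res$summary$best_evalue), ], 6)
#>   target  best_evalue identity coverage    group                                                 rationale
#>   orth01 1.351140e-90 30.10204     96.5        2           identity 30% >= 20% with a partial residue set
#>   orth03 1.229422e-89 30.41237     95.5        1 identity 30% >= 30% with the full functional residue set
#>   orth02 9.504924e-82 30.97826     91.5        1 identity 31% >= 30% with the full functional residue set
#>   orth04 5.355505e-58 32.73810     82.0        2           identity 33% >= 20% with a partial residue set
#>  decoy17 6.410841e-01       NA       NA rejected                         no statistically significant hit
#>  decoy03 1.112764e+00       NA       NA rejected                         no statistically significant hit
```

Every planted ortholog is recovered (E ≪ 0.005) and triaged into group 1
or 2 depending on whether all seven motif residues survived mutation and
alignment; every decoy is rejected.

Structure recovery under known noise (σ = 0.5 Å per coordinate):

```r
b    <- generate_helix_bundle(4, 25, spacing = 10)
pert <- perturb_structure(b, structure_perturb_spec(sigma = 0.5, seed = 3))
kabsch_superpose(b, pert$structure, pert$correspondence)
#> <superposition> RMSD 0.824 A over 100 residues, TM-score 0.953
```

The observed RMSD matches the theoretical `σ√3 ≈ 0.87 Å` (slightly less
after fitting).

The package also ships the transcribed published candidate table for the
fly eicosanoid-enzyme study and reclassifies it with the same tier rules:

```r
cl <- classify_published_candidates()
cl$counts
#>        1        2        3 rejected
#>        8        5        7        0
head(cl$table[, c("human_gene", "candidate", "identity", "evalue", "group")], 5)
#>  human_gene candidate identity evalue group
#>      AKR1B1    CG6084       49  5e-94     1
#>     ALOX5AP   CG33177      33* 6e-20*     3
#>        CBR1   CG11200       30  8e-19     2
#>        CPA1   CG18585       35  9e-82     1
#>       DPEP1    CG6154       49 3e-125     1
```

(the `*` marks statistics measured against an HMM/PSSM profile rather
than the plain sequence, following the published table's convention).

## Package layout

- `R/` — io (FASTA / aligned-FASTA / Stockholm / PDB Cα / TSV), synthetic
  data generators, PSSM + alignment engines, E-value calibration,
  iterative search, conservation screening, structure comparison, tier
  assignment.
- `src/` — the affine-gap DP kernel (Rcpp), shared by profile search,
  pairwise statistics, MSA augmentation and structure-based matching.
- `vignettes/methods.Rmd` — the model, its assumptions, parameter
  defaults, and known limitations.
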