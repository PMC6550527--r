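---
title: "Methods: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific models behind `mesoimmunity`, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate. It states no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The biological setting

Cluster A temperate mycobacteriophages regulate lysogeny with a single
immunity repressor (Rep) that binds, as a monomer, 13–14 bp asymmetric sites.
A few of these are true operators inside promoters; the majority — 20 to 30
per genome — are "stoperators" scattered through the genome, oriented with
the direction of transcription, where bound Rep blocks transcription
elongation. Superinfection immunity between two phages is therefore a
function of how well the resident prophage's repressor recognizes the
challenger's sites. Closely related (homotypic) systems give symmetric
complete immunity, unrelated (heterotypic) systems give symmetric complete
infection, and moderately diverged (mesotypic) systems give the intermediate,
often asymmetric phenotypes this package is named after.

## Stoperator discovery (EM motif finder)

`discover_stoperators()` implements a site-sampler-free EM under an
"any number of repetitions" model: every genome window (both strands) is a
potential site with a shared prior γ.

* **Widths 12–16 bp, 10–50 sites, ≤ 2 motifs, both strands.** These
  constraints are the discovery envelope for this family of sites; the core
  comparison width is 13 bp.
* **Seeding.** For each width, the most frequent exact w-mers (count ≥ 2,
  collapsed over near-duplicates and reverse complements) seed the EM; this
  makes discovery fully deterministic — there is no RNG in the finder.
* **E-step/M-step.** Posteriors are
  `z_i = γ·2^llr_i / (γ·2^llr_i + (1−γ))` with `llr` the log2
  probability-ratio score; soft counts (plus 0.5 smoothing) update the
  probability matrix, and γ is re-estimated with a cap of 0.02 (a 50-kb
  genome should not be more than ~2% motif).
* **Model selection.** Candidates are ranked by *mean per-column information
  content × supporting site count*. Mean (not total) information keeps a
  13-bp signal embedded in a 16-bp window from outranking the correctly
  sized model. When a reference motif is supplied (mirroring selection
  against empirically determined sites), the candidate — in either
  orientation — minimizing `motif_distance()` to the reference wins.
* **"Not found".** A best candidate below `ic_floor = 10` bits total
  information is reported as not found; i.i.d. sequence converges to diffuse,
  low-information motifs well under this floor, while ~25 planted sites
  yield ≳ 18 bits.
* **Site calling.** The natural threshold is half the consensus log-odds
  score; the called count is clamped into the 10–50 envelope by threshold
  adjustment (top-N by score). The final site set is called with the final
  (site-rebuilt) matrix, so re-scanning with the reported model at the
  reported threshold reproduces a superset of the reported sites.
* **Overlaps.** Scanning resolves overlaps greedily best-score-first; ties
  break leftmost, then to the '+' strand (this also makes palindromic sites
  single-reported, on '+').

## Position weight matrices and motif distance

`build_pwm()` uses square-root pseudocount smoothing,

P[b,j] = (n[b,j] + k·bg_b·√N) / (N + k·√N),  W = log2(P / bg),

with `k = 0.8` and a uniform background — the conventional defaults for
log2 probability-ratio matrices in the R motif stack. `motif_distance()` is
the per-column normalized Euclidean distance

D = (1/w) · Σ_j sqrt( Σ_b (P1[b,j] − P2[b,j])² / 2 ),

which is 0 iff the probability matrices are identical, at most 1 (the 1/√2
factor normalizes a column that moves all mass between two bases), symmetric,
and empirically satisfies the triangle inequality (property-tested on random
triples). The exact normalization inside the upstream tooling this mirrors is
not published; only the contract (zero iff identical, larger = more
dissimilar) is guaranteed, and this concrete formula is our documented
choice. Widths 13 vs 14 are compared in best-offset mode (minimum over
full-overlap offsets of the shorter within the longer).

## Genome distances

* **`nucleotide_distance()`** (`D_Nuc ∈ [0, 0.5]`) is an anchor-based
  estimator: exact 13-mer seeds on both strands, merged into maximal
  same-diagonal runs, coverage summed on both genomes, and
  `D = (1 − f)/2` with `f` the matched fraction. Two constants matter:
  `min_anchor = 40` bp (runs shorter than this are chance hits — at 13 bp
  seeds, two unrelated 20-kb sequences would otherwise occasionally share a
  short diagonal run, especially between reduced-alphabet constructions and
  reverse complements) and `max_occ = 10` (a low-complexity filter on
  repetitive seeds). Identical genomes give exactly 0; genomes with no
  shared segments give exactly 0.5; replacing half a genome gives ≈ 0.25.
  The estimator is deliberately conservative between highly diverged
  genomes (it counts only long exact runs, not gapped alignments), which is
  sufficient for the endpoint and monotonicity contracts it carries here.
* **`gene_content_dissimilarity()`** is exactly
  `1 − mean(|A∩B|/|A|, |A∩B|/|B|)` on pham (gene phamily) sets: 0 when all
  phams are shared, 1 when none are.
* **`protein_distance()`** globally aligns (BLOSUM62, gap open 10, extend
  0.5 — documented because the upstream analyses used whole-phamily multiple
  alignments instead of pairs) and reports
  `100 × mismatched non-gap columns / non-gap columns` — an uncorrected
  p-distance per 100 aa with no gap weight: an insertion contributes
  nothing. On gap-free equal-length pairs this equals naive Hamming/length
  (oracle-tested).
* **Repressor regions.** The N-/C-terminal split defaults to residue 60 —
  just downstream of the 20-aa helix-turn-helix DNA-binding domain (residues
  ~21–40 in the synthetic repressors) — and is configurable because the
  published split cites prior work without printing a coordinate.
  `hth_hamming()` is a strict 20-position Hamming count.

## The infection rubric and phenotype statistics

`score_observation()` encodes the ordinal 0–6 rubric: 0 (no spots or
plaques), 1 (lysis at the highest 1–2 dilutions, no plaques), 2 (plaques
with EOP < 1e−3, or lysis at 3 dilutions), 3 (plaques with EOP 1e−3–1e−1,
or lysis at 4–5 dilutions), 4/5/6 (order-unity EOP with worse / identical /
better phenotype than the naive-host control). The published EOP boundaries
are fuzzy ("~10⁻³–10⁻⁴", "of 1"); we fix half-open bins at 1e−3 and 1e−1
and read "EOP of 1" as order-unity (`eop ≥ 0.5`), with everything between
1e−1 and 0.5 falling to score 3. All three edges are arguments.

Aggregation is the arithmetic mean over replicates with n/min/max retained.
ΔΙ is defined over lysogen defenders only (a CRS has no challenging
identity). Profile correlations are Pearson by default (the source analyses
say only "correlation coefficient"); Spearman is a flag. Regressions are
ordinary least squares, with an optional clade filter on both members of
each comparison (the "intra-clade only" scope). Campaign summaries count
unique (challenger, defender, kind) triples, unordered reciprocal lysogen
pairs, and lysogen–CRS paired comparisons as two per complete pair sharing a
challenger — the reading consistent with n pairs appearing as 2n
comparisons.

## Mutation notation and repressor impact

The parser covers substitutions (`G44351A`), inclusive-coordinate deletions
(`Δ45310:48001`), adjacent-coordinate insertions (length-only
`44333:44334 27-bp ins` or sequence `45315:45316 G insertion`), crossover
windows (`rec Tx 44620:44630 and RR 44127:44137`), optional donor-genome
prefixes, and parenthesized protein annotations; `format_mutation()` is its
exact inverse. Edits apply right-to-left so parent-frame coordinates stay
valid. Recombination entries give windows, not junctions, so they are never
auto-applied; `build_recombinant()` builds a hybrid from user-chosen
junctions inside the windows.

`classify_rep_impact()` reconstructs the mutant open reading frame in sense
space (reading through the 3′ end by a 600-bp margin so frameshifts
terminate naturally) and compares translations: whole-gene deletion →
`deleted`; deletion of the 5′ end → `truncated_5prime`; net indel length
≢ 0 (mod 3) → `frameshift` at the first changed codon; premature stop →
`nonsense` at that codon; amino acid change (including in-frame indels) →
`missense`; silent nucleotide change → `sense`. Because the real parent
genomes are not shipped, the tests validate the classifier against synthetic
parent genomes (`synthetic_parent_genome()`) whose rep-gene geometry is
pinned by the catalog's own coordinates — e.g. the two Et2Brutus mutations
independently imply the same rep 3′ end, and the synthetic layout honors it.

Virulence breadth uses escape threshold Ι ≥ 3 (plaque formation) by
default: a "gain" is a defender where the DEM reaches the threshold and its
parent does not; gains confined to the parent's own system are
narrow-homotypic, gains on at most two foreign systems are narrow-mesotypic,
anything spanning the homotypic system plus mesotypic defenders (or many
systems) is broad.

## Binding fits

`fit_one_site()` fits `Y = Bmax·X/(K_D + X)` by bounded least squares
(`nls`, port algorithm; `K_D > 0`, `0 < Bmax ≤ 1.2` — a mild bound, since
fully unconstrained Bmax can run away on truncated titrations) with
deterministic multi-starts from the minimum, median and maximum
concentration. Percent-bound inputs are auto-detected (max > 1.5) and
normalized. All-zero titrations return an above-range sentinel
(1000 × max concentration) with `converged = FALSE` rather than a fake
estimate. Substrates are 30 bp: 8 bp upstream flank + 13 bp core + 9 bp
downstream flank, with the core at positions 9–21; substitution series keep
the source substrate's flanks invariable and enumerate target-base subsets
(all subsets containing the anchor when one is given — 2^(k−1) substrates
for k differing positions — ordered by subset size then position, ending at
the full target site).

## What the synthetic generator emulates — and what it does not

`simulate_clade()` evolves four things along a phylogeny (default: balanced
16-taxon tree, unit branch lengths): the 13-bp stoperator consensus
(per-position substitution probability 0.04 per unit branch length), the
pham complement (loss probability 0.03 per pham per unit length, matched by
novel gains), the repressor (0.01 per site N-terminal vs 0.03 C-terminal —
the 3× faster C-terminal drift seen in these repressors), and the genome
background (0.01 per bp). Genomes are ~50 kb by default with 20–30 planted
sites (each deviating from its genome's consensus with per-position
probability 0.03, i.e. mostly 0–2 mismatches), an integrase marker defining
the center, and 95% syn orientation. All randomness is drawn at the clade
root and perturbed only along edges, so zero branch lengths give
byte-identical genomes, and every generator is a pure function of
(config, seed).

`simulate_immunity()` generates scores from *distances*, not from
repressor–operator biophysics:

Ι(defender A, challenger B) = clamp(round(5·g(β·D(A,B) − α·promiscuity_A)), 0, 6)

with `g(x) = max(0, 2/(1+e^(−x)) − 1)`, β = 10 (distances of ~0.3 saturate,
matching the heterotypic extreme; outgroup pairs are additionally forced to
5), per-defender latent promiscuity scaled by α producing asymmetric ΔΙ,
and ±1 ordinal replicate noise (default rate 0.15). This functional form is
a deliberate stand-in: it exercises every analysis stage (ordinal scores,
asymmetry, monotone distance–phenotype coupling) but contains no mechanism,
so passing tests demonstrate that the *pipeline* recovers planted structure,
not that real immunity follows a logistic in motif distance. Real data also
differ in ways the generator ignores: operators vs stoperators are not
distinguished, secondary loci and host factors are absent, pham turnover is
independent of the motif drift, and recombination between clade members is
not simulated.

## Problem sizes and numerical notes

The test suite exercises discovery on one 50-kb genome (the scale of a real
Cluster A genome) and otherwise uses 6–10 kb genomes with 6–10 taxa and 20
generator seeds, which keeps the full suite under a few minutes while every
assertion retains comfortable statistical margin. Two statistically
marginal scenarios are sized explicitly: the syn-orientation invariant pools
sites over five independent clades planted at syn probability 0.97 (within
one clade, orientations are inherited from the root, so a single clade
offers only ~25 independent draws against a 0.9 bound), and the K_D
Monte-Carlo uses a half-log titration from 1 to 200 nM spanning both sides
of half-saturation (bottom-heavy designs clip near zero bound fraction and
bias the fit). Floating-point contracts are tested at 1e−10–1e−12 against
independent brute-force oracles for the PWM formula, motif distance,
Pearson correlation, OLS and replicate aggregation.

## Known limitations

* `D_Nuc` is an endpoint-faithful estimator, not a reimplementation of the
  original alignment-based computation; between moderately diverged genomes
  it saturates faster than a gapped-alignment distance would.
* The published N-/C-terminal repressor split coordinate is not printed in
  the source material; residue 60 is a configurable default, not a claim.
* Motif discovery assumes one dominant motif family per genome (plus one
  alternative candidate); genomes with two equally strong unrelated motifs
  will surface only the stronger unless a reference motif arbitrates.
* The immunity simulator's link function is phenomenological (see above).
* Recombinant escape genotypes are constructed, not evolved.
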