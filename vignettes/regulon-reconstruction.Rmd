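---
title: "Comparative reconstruction of palindrome-binding TF regulons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative reconstruction of palindrome-binding TF regulons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulogr)
```

## The model

`regulogr` reconstructs the regulon of a homodimeric transcription
factor (TF) across a clade of related bacterial genomes. The method
rests on three empirical regularities of this TF class:

* binding sites are **palindromes** — the TF binds as a dimer, so the
  motif equals its own reverse complement at the consensus level, is
  almost always of even width (14–24 bp), and typically carries a CG
  pair at its centre;
* sites concentrate in a narrow band of the promoter, mostly
  **140–30 bp upstream of the translational start**, with a minority
  inside coding sequence or far upstream;
* regulation is **conserved**: if an operon is a true regulon member,
  orthologous operons in related genomes tend to carry sites too.

The third point is the crux. A position weight matrix (PWM) scanned
against a single genome produces many background hits near any usable
threshold; demanding cross-genome support ("consistency check") removes
genome-specific false positives at almost no cost in recall, because
true members are supported by their orthologs.

### Scoring

A PWM stores per-position base frequencies `f(i, b)` estimated from `n`
aligned sites with pseudocount `c` (default 0.5):

```
f(i, b) = (count(i, b) + c) / (n + 4c)
score(s) = sum_i log2( f(i, s_i) / bg(s_i) )      [bits]
```

Palindrome symmetry is enforced by count-matrix symmetrisation,
`C ← (C + revcomp(C)) / 2`, which makes every score exactly strand
invariant — one strand of each promoter suffices for scanning. The
absolute score scale is arbitrary; all decisions use thresholds derived
from training sites, never fixed cutoffs. The scan threshold is the
**minimum score over the training set**, so training sites are always
recovered when their promoters are rescanned. The membership rule uses
`score >= threshold` (non-strict), keeping that self-consistency exact.

### Motif discovery

Discovery runs expectation–maximization under a zero-or-one-occurrence
per-sequence model: each promoter contains at most one site, with prior
probability `q` (default 0.75, matching the autoregulation frequency of
the training promoters the pipeline uses). Per width in {14, 16, 18,
20, 22, 24}, EM restarts are seeded deterministically from the most
palindromic windows (plus one random restart under the run seed) and
the count matrix is symmetrised every iteration. Multiple sites per
promoter are recovered later by scanning, not during discovery.

Width selection maximises total information content (IC) minus a
per-column penalty (default 0.25 bits/column). The penalty must exceed
the apparent IC of a background column: with a small training set, the
per-promoter argmax step inflates background-column IC well above the
classical small-sample bias `3 / (2 n ln 2)`, so after selection the
motif is additionally trimmed — outermost column pairs whose mean IC
stays below the 0.5 bits/column floor are removed. Without trimming, EM
at an overwide width pads the true palindrome with selection-inflated
noise columns and the wider width occasionally wins. Odd widths are
searchable by passing them explicitly; the default grid is even because
palindromes of dimeric TFs overwhelmingly are.

### The pipeline's training set

Which promoters seed discovery? The package uses the TF's own operon
promoter in every genome: regulators of this family are predominantly
autoregulated, so pooling the TF's upstream regions across a clade is
the cross-genome analogue of starting from known regulated genes.
Promoters of genomes where the TF happens not to be autoregulated are
absorbed by the zero-or-one model (their posterior site probability
stays low and they drop out of the training set).

After the first scan and consistency filter, a **phylogenetic-footprint
refinement** widens the training set: for every ortholog operon group
supported in at least half the genomes, the best-scoring window of each
orthologous promoter is taken as a predicted site, *gated* by a
conserved-island criterion — at most 25% of positions may mismatch the
consensus. The PWM and the minimum-training-score threshold are then
re-derived and the scan repeated. The gate matters: without it, a group
member that genuinely lacks a site contributes an arbitrary background
argmax, and a single such window collapses the threshold. The 25% value
marks the edge of the functional-site regime: at the motif's
information density (~1.3–1.9 bits/column), windows more than a quarter
diverged are not conserved islands. With the small initial training set
alone, the low-scoring tail of real sites falls below the happenstance
minimum of ~7 training scores and recall plateaus near 0.87; the
refinement recovers it.

### Operons and divergons

Operons are maximal runs of same-strand adjacent genes with intergenic
distance ≤ 100 bp — read inclusively, with overlapping genes always
merged — and no predicted TF site centred in an internal gap. Because
the site rule depends on the scan, operon prediction is two-pass:
layout-only operons are scanned, then re-split around internal sites.
The promoter window (−400 to +100 bp around the translational start of
the operon's first gene) is deliberately **not** clipped at upstream
gene boundaries: sites of this family occur within coding sequence, so
clipping would lose them. In divergons (divergently transcribed operon
pairs with overlapping windows) a shared site is attributed to both
operons — the convention used for regulatory annotation of such
regions, and mirrored by the simulator's ground truth.

### Orthology

Ortholog groups are connected components of the bidirectional-best-hit
graph over all genome pairs; similarity is either a shared-k-mer
fraction (default, k = 4) or BLOSUM62 local alignment. Ties are broken
lexicographically and flagged. TF groups are additionally split so that
all members share similar motifs (mean best-aligned per-column Pearson
correlation ≥ τ = 0.8, single linkage) — the operational counterpart of
tree-based TF orthology; tree inference itself is out of scope, and
effector specificity, which is not computable from sequence, is carried
as a free-text annotation instead of a grouping criterion. τ = 0.8 is a
package choice exposed as a parameter; no quantitative value for
"highly similar motifs" exists to inherit.

## The simulator

`simulate_pangenome()` generates the study conditions: `n_genomes`
related genomes sharing an ortholog complement laid out in operons
(sizes 1–4; within-operon gaps 5–80 bp, between-operon gaps
200–420 bp), one TF gene per genome, and a planted even palindrome
(default width 18, central CG, per-position conservation 0.9) upstream
of `n_regulated_operons = 6` shared operon groups plus — with
probability 0.72 — the TF's own operon. 75% of site centres fall in
[−140, −30] relative to the start codon, the rest spread over the
remaining window. Proteins are per-group random ancestors mutated at
5% per residue per genome; non-anchor genes drop out at
`gene_loss_rate = 0.1`. With `tandem_spacing` set, a second site is
planted at that centre-to-centre distance, reproducing the helical-
period spacing structure of cooperative dimer pairs.

Choices worth stating explicitly:

* **Functional-site truncation.** Site instances are drawn at
  substitution rate `1 − 0.9` per position but redrawn if they exceed
  `floor(width/4)` total substitutions. An unconstrained draw
  occasionally yields a 6–7-fold mutated "site" scoring at background
  level — a sequence the factor could not bind and hence not a sensible
  ground-truth site; it would also drag the ground-truth threshold (the
  minimum planted-site score) into the background regime. The rate is
  untouched; only the nonfunctional tail is excluded.
* **Decoys.** Each genome receives ~Poisson(2) palindromic decoys in
  promoters of unregulated operons, aimed at the ground-truth
  threshold. Because per-position log-odds are quantised (~4.7 bits per
  substitution at conservation 0.9), an exact ±1-bit band is usually
  unreachable; decoys take the largest achievable score not above
  threshold + 1, i.e. they sit at the level of the weakest genuine
  site — the most adversarial placement the lattice allows. Decoy
  generation is deferred until all sites are planted so the target is
  the realised threshold, not an estimate.
* **Genome size.** Default `n_genes = 160` (~70 operons). The decoy
  contract — independent decoys are removed by the consistency filter
  with probability approaching 1 — is an asymptotic property of genome
  size: with only a dozen free operon groups, two genomes' independent
  decoys collide on the same ortholog group far too often, which no
  real genome exhibits. 160 genes keeps collisions in a realistic
  regime while staying desk-scale.
* **Background** is i.i.d. at the configured GC content, with no
  higher-order structure — sufficient for motif recovery testing, but
  it understates the clustered false positives (repeats, tandem
  duplications) of real genomes. Passing tests therefore demonstrate
  correctness of the machinery and the filter's behaviour under
  independent noise, not performance on real genomic backgrounds.
* Ground-truth membership is defined by window containment of planted
  site centres, so divergon neighbours are true members exactly as the
  reconstruction attributes them.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 I/O converts
  from/to 1-based inclusive, BED output is 0-based half-open.
* Gene-order ties (equal start) break by gene id; best-hit score ties
  break lexicographically and are flagged; EM is seed-deterministic,
  and all pipeline randomness flows from one root seed expanded per
  stage.
* Windows containing N are skipped, never scored; sites with N are
  rejected from PWM training.
* Site "position" statistics use the centre (`start + floor(w/2)`) by
  default; a 3'-end convention is available, since the anchoring
  convention of published distance histograms is often unstated.
  Intersite distances are centre-to-centre of adjacent sites, making
  the 22/32-bp helical-period interpretation literal.
* Empty inputs: an empty regulon is valid output; empty site sets give
  empty histograms with null fractions; precision of an empty
  prediction is reported as `NA`, not 0.
* `motif_similarity` compares frequency columns over full-inclusion
  offsets and both orientations; motifs differing in width by more than
  4 return 0 with an `incomparable` flag rather than an error.

## Problem sizes used by tests and the acceptance script

Motif recovery is measured over 50 seeded simulations (10 genomes, 8
regulated operons, width 18, conservation 0.9); end-to-end recovery
over 25 simulations at the default configuration (decoys on,
`min_genomes = 2`), each also re-filtered at `min_genomes = 1` to
quantify filter efficacy; the site-position contract over 10,000
planted sites; the autoregulation contract over 200 simulated genomes.
These sizes give binomial standard errors comfortably inside the
margins being checked and are stated here as the package's chosen
experiment sizes.

## Known limitations

* The EM objective and bit-scale scores are this package's own; the
  interactive tools historically used for such curation do not publish
  their objective or score scale, so validation is by parameter
  recovery on planted data, not score equality.
* BBH components plus motif-similarity splitting approximate, but do
  not reproduce, tree-based orthology with manual curation; paralogy
  resolution beyond recent duplications is out of scope.
* No spaced-dyad motifs with variable gaps, no higher-order background,
  no activator/repressor mode prediction from site position, and no
  effector inference.
* Runtime scales linearly in genomes and promoter length but
  quadratically in proteome size through the all-vs-all similarity
  stage; clade sizes beyond a few dozen genomes deserve an external
  aligner for that stage.
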