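---
title: "Comparative mitogenomics with mitocomp: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## What the package computes

`mitocomp` implements the desk-scale core of a comparative mitogenomics
study of the two major dengue vectors, *Aedes aegypti* and
*Aedes albopictus*. An animal mitogenome is a circular molecule of about
16.6 kb carrying 13 protein-coding genes (PCGs), 22 tRNAs, 2 rRNAs and
one AT-rich control region (CR). The package covers four analysis layers
and one simulation layer:

1. **Characterization** — gene inventory, sizes and strands from GenBank
   flat files or tab-separated feature tables; base composition; AT/GC
   skews; relative synonymous codon usage (RSCU); start/stop-codon
   classification.
2. **Intraspecific divergence** — per-gene Kimura two-parameter (K2P)
   distance, SNP counts and bp-per-SNP density, percent identity.
3. **Phylogeny** — concatenation of the 13 PCGs into a supermatrix, a
   native Saitou–Nei neighbor-joining (NJ) tree on K2P distances with
   nonparametric bootstrap, and supermatrix/partition exports for
   external maximum-likelihood or Bayesian tools.
4. **Reporting** — deterministic TSV/JSON artifact sets with one JSON
   run manifest per output directory.
5. **Simulation** — a K80 mitogenome-evolution generator that produces
   annotated, frame-valid, AT-biased genomes and conspecific panels with
   full ground truth, so every estimator above is testable without any
   download.

## The statistics and their assumptions

### Composition and skew

For counts $A, C, G, T$ (with $N$ excluded from every numerator and from
the $AT+GC$ denominator),

$$\mathrm{AT\%} = 100\,\frac{A+T}{A+C+G+T},\qquad
\mathrm{AT\ skew} = \frac{A-T}{A+T},\qquad
\mathrm{GC\ skew} = \frac{G-C}{G+C}.$$

A zero denominator yields a missing value, never 0 — a sequence with no
G or C has *undefined*, not neutral, GC skew. All values are carried at
full precision; rounding to the customary 2–3 decimals happens only in
rendered tables.

### RSCU

For codon $c$ with count $X_c$ in a synonymous family of size $n$,

$$\mathrm{RSCU}_c = \frac{X_c}{\frac{1}{n}\sum_{c'\in\mathrm{fam}(c)} X_{c'}},$$

so RSCU sums to $n$ over each observed family. The default code is NCBI
translation table 5 (invertebrate mitochondrial: `AGA`/`AGG` = Ser,
`TGA` = Trp, `ATA` = Met; 62 sense codons, stops `TAA`/`TAG`; Leu has 6
synonymous codons and Ser 8). The engine is code-table generic; the
registry is taken from the NCBI tables shipped with Biostrings and is
asserted in the test suite. Families with zero observed codons are
reported missing rather than 0. RSCU is always emitted at both scopes:
per gene and pooled over the 13 PCGs, because genome-level codon-bias
summaries (e.g. the cumulative RSCU of `TTA`) sum per-gene values.

Start/stop classification is annotation-driven: the CDS length modulo 3
decides between a complete terminal codon and the incomplete-stop
notation `T(AA)` / `TA(A)` (a trailing T or TA completed to `TAA`
post-transcriptionally). Unusual but genuine start codons — e.g. the
non-canonical `TCG` of mosquito *cox1* — are reported verbatim, never
"corrected" to `ATN`. No polyadenylation modelling is attempted.

### K2P distance and SNP density

With transition proportion $P$ (A↔G, C↔T) and transversion proportion
$Q$ over comparable sites,

$$\hat d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q).$$

Columns containing a gap or `N` are deleted pairwise; the policy string
is recorded in summary output. When $1-2P-Q \le 0$ or $1-2Q \le 0$ the
pair is reported as saturated (missing distance plus a flag) rather than
silently truncated. The model assumes site independence and homogeneity
— exactly the regime the simulator generates, which is what makes the
parameter-recovery tests sharp.

A SNP column holds at least two distinct `{A,C,G,T}` bases; the
bp-per-SNP denominator is the number of columns with at least two
comparable bases, not the raw gene length, which makes the density
robust to ragged gap structure. Species-level summaries average
per-gene values unweighted (each gene counts once), mirroring the
per-gene presentation of such analyses; note this gives short genes the
same vote as *nad5*. Both all-pairs and to-reference pair modes exist;
all-pairs is the default.

### Neighbor joining and bootstrap

`nj_tree()` is a native Saitou–Nei implementation. Two contracts matter
and are part of the test surface:

* **determinism** — ties in the $Q$ criterion are broken by the smallest
  taxon-index pair, so identical input gives identical trees;
* **clamping** — a negative branch estimate is set to 0 and the deficit
  moved to the sister edge, preserving the path length through the join.

On additive matrices the algorithm reproduces the generating tree and
its branch lengths exactly; this is asserted against 4- and 5-taxon
constructions and against the reference implementation in `ape`.
Bootstrap resamples supermatrix columns with replacement; one master
seed spawns a stable stream of per-replicate seeds, so increasing the
replicate count extends rather than reshuffles the earlier replicates.
Saturated replicates are skipped and counted. Supports are percentages
of successful replicates containing each internal bipartition of the
point-estimate tree; following common practice, values ≥ 70% are read
as moderately confident. Trees are unrooted throughout; an outgroup
(the analyses this package mirrors used *Culex quinquefasciatus*) roots
the output for display only.

Maximum-likelihood and Bayesian inference are deliberately not
reimplemented: the package exports the concatenated supermatrix (FASTA
and relaxed PHYLIP) with a partition table so those analyses can be run
in dedicated tools, while NJ on K2P distances provides the in-package,
fully testable topology engine — a defensible stand-in for
near-identical conspecific mitogenomes.

### The pairwise aligner

`align_pair()` is a Needleman–Wunsch–Gotoh global aligner with match
+1, mismatch −1 and affine gap cost $-(5 + k)$ for a $k$-residue gap
(the first gap residue pays both the opening and the extension
penalty). Traceback ties prefer diagonal over up over left, so output
is deterministic. It is a desk-scale tool for short or near-identical
sequences; large panels should be aligned externally and read back as
aligned FASTA, which every downstream function accepts. Scores are
verified against exhaustive alignment-path enumeration for all length
combinations up to 8×8 and against `Biostrings::pairwiseAlignment`.

## The simulator: what it emulates and what it does not

`make_ancestor()` draws bases i.i.d. with
$P(A)=P(T)=\texttt{at\_bias}/2$ (default 0.79, the AT content typical
of *Aedes* mitogenomes), then repairs every PCG: the annotated start
codon is written in place, the annotated complete or incomplete stop is
placed at the gene end, and internal stops are removed by minimal
edits, preferring the third codon position and falling back to second
or first only where another gene's forced start/stop locks a site
(genes overlap in real layouts — e.g. *atp8*/*atp6* — so repair
iterates to a fixed point). The default layout is the shipped
*Ae. aegypti* annotation (16,662 bp, 38 features).

`evolve_sequences()` substitutes site-wise along each branch using the
exact K80 transition probabilities for branch length $b$ (expected
substitutions/site) and ts/tv rate ratio $\kappa$ (default 4, a typical
animal-mtDNA value), so multiple hits are modelled. Ground truth —
tree, per-branch realized transition/transversion counts, true pairwise
path lengths — is returned for recovery tests. A `protect_frame` mode
confines change to third codon positions and rejects stop-creating
substitutions, for tests that need valid ORFs at the leaves; it is off
by default because the restriction lowers the realized rate inside PCGs
and would bias distance checks.

Deliberately **not** simulated: indels (the divergence metrics are
substitution-based; alignment code is exercised with hand-made gapped
fixtures), control-region repeats and homopolymers, rate heterogeneity
across sites, and base-composition drift. Passing tests therefore show
estimator correctness under the model the estimators assume — they do
not certify behaviour on real data with alignment error, heterotachy or
compositional bias.

### Calibrated panels and chosen study conditions

The packaged study conditions were chosen once and frozen:

* ancestor layout: shipped *Ae. aegypti* table; `at_bias` 0.79;
  $\kappa = 4$;
* conspecific panels via `species_panel()`: 6 genomes ("aegypti-like")
  and 13 genomes ("albopictus-like"), matching the specimen counts of
  the study being mirrored, on star trees;
* star tip depths 0.00362 and 0.00207 with frozen seeds: each panel is
  a calibration run at a fixed seed, tuned once so the unweighted
  across-gene mean K2P of the shipped panel lands on the published
  species means (≈0.008 and ≈0.004). The expectation of that mean over
  seeds is close to `2 × depth`, but a single small panel realizes it
  with a coefficient of variation near 7% (few shared star branches),
  which is why the calibration fixes seed and depth together and the
  default panels serve as reproducible reference datasets.

Problem sizes used by the test suite and the acceptance script — 10 kb
sequences and 100 replicates for estimator recovery, 1.5 kb
supermatrices for the 100-run topology-recovery sweep, 100 bootstrap
replicates on 8-taxon two-species simulations — were chosen as the
smallest sizes at which the binomial error bands in the checks are
informative.

## Numerical and edge-case policy

* Coordinates are 1-based inclusive everywhere (GenBank convention);
  `end < start` marks a feature wrapping the origin of a circular
  genome, with size $(L-\mathrm{start}+1)+\mathrm{end}$.
* Published intergenic-spacing columns are ignored and recomputed as
  `next.start − prev.end − 1` (negative = overlap): the printed columns
  in real annotation tables are frequently inconsistent with their own
  coordinates.
* When a feature table carries a `size` column it is cross-checked;
  mismatches are reported and coordinates win. Three rows of the
  shipped fixtures were curated before packaging where the printed
  coordinates contradicted the printed size (a transcription error in
  the source table); the curated rows are internally consistent and
  reproduce the published totals.
* Ambiguity codes other than `N` are rejected at read time: the
  analyses assume `{A,C,G,T,N}`, and silently remapping IUPAC codes
  would corrupt skew and distance estimates.
* Undefined ratios (skews, RSCU of empty families, bp-per-SNP with zero
  SNPs, saturated distances) are missing values with flags, never 0.
* All RNG-dependent stages take explicit seeds and are byte-identical
  on re-run; run manifests record parameters, seeds and input digests.

## Known limitations

* The GenBank reader is a minimal single-record flat-file parser
  (LOCUS/FEATURES/ORIGIN with `complement`, origin-spanning `join`,
  `/gene`, `/product`, `/note`); it is not a general GenBank toolkit.
* The aligner is quadratic in sequence length and intended for short or
  near-identical inputs; it is not a substitute for a multiple aligner.
* NJ on K2P distances is a distance method: for deep divergences or
  strong rate variation, use the exported supermatrix with a
  likelihood tool.
* tRNA identification relies on annotation (names/products); no
  structure-based annotation is attempted, and leucine/serine tRNA
  paralogs (`trnL1`/`trnL2`, `trnS1`/`trnS2`) can only be separated
  when the source annotation separates them.

## A worked example

```{r example, eval = FALSE}
library(mitocomp)

# 1. characterize the shipped Ae. aegypti annotation table
rec <- fixture_record("aegypti")
out <- characterize(rec, "aegypti_out")
out$pcg_extent          # 11191
out$n_functional_genes  # 37

# 2. simulate an aegypti-like conspecific panel and summarize divergence
panel <- species_panel("aegypti_like")
div <- divergence_table(panel, species = "aegypti-like",
                        outdir = "divergence_out")
attr(div, "species_mean_k2p")   # ~0.008

# 3. distance phylogeny with bootstrap from the same panel
phy <- phylo_pipeline(panel, outdir = "phylo_out",
                      n_replicates = 100, seed = 1)
phy$bootstrap$tree
```
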