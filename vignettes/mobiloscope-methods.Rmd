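---
title: "Detecting mobile LTR retrotransposons from eccDNA sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mobile LTR retrotransposons from eccDNA sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mobiloscope)
```

## The biological problem

LTR retrotransposons (LTR-RTs) multiply through a copy-and-paste cycle:
transcription, reverse transcription into a linear double-stranded copy
bounded by two identical long terminal repeats (LTRs), and integration into
a new locus flanked by a short target-site duplication (TSD). Two by-products
make recent activity observable without catching an integration in the act:

* **Copy-number variation.** Active families accumulate copies, so read
  coverage on a family's consensus sequence, normalized by genome-wide
  coverage, is a *proxy copy number* (pCN) comparable across accessions.
* **Extrachromosomal circular DNA (eccDNA).** Linear extrachromosomal
  copies are circularized by end joining into *2-LTR circles*, whose
  diagnostic feature is the head-to-tail adjacency of the two LTRs — a
  sequence configuration absent from the integrated copy, which carries
  flanking DNA at those positions. Circles with one LTR (LTR–LTR
  recombination products) or fragments of an element also occur but are not
  evidence of transposition competence. Mobilome sequencing (exonuclease
  digestion of linear DNA, rolling-circle amplification, short-read
  sequencing) enriches this circular fraction.

`mobiloscope` implements the computational side of both observables, plus
the downstream steps a study of natural populations needs: discovery of
circle-forming genomic regions from assembled mobilome contigs, association
of pCNs with bioclimatic variables under population structure, filtering of
transposon insertion polymorphisms (TIPs), and extraction of GWAS candidate
windows. Every stage is exercised against a ground-truthed simulator.

## The synthetic mobilome generator

The generator is first-class, tested code; it defines the conditions under
which the pipeline's claims are verified.

* `make_family_panel()` draws family consensus sequences `LTR + internal +
  LTR` with independent random sequence per family (pairwise LTR identity
  is enforced `< 80%`; random sequences sit near 25%).
* `build_genome()` plants full-length copies into a random background
  chromosome on random strands, flanked by exact TSDs (default 5 bp,
  typical of Copia-type integrases). Divergence is modelled as uniform
  substitutions per copy — no indels, no nested insertions — so the two
  LTRs of an old copy drift apart independently, as in real elements.
* `simulate_eccdna_pool()` produces the three circle classes. The class
  invariants (a 2-LTR circle is the circularized full-length element; a
  1-LTR circle contains exactly one LTR per wrap; a fragment is a proper
  internal substring) are asserted by tests via substring scans.
* `rca_reads()` models rolling-circle amplification as uniform fragment
  sampling on the circle with wrap-around: circularity is represented by
  the linear sequence plus sampling on the doubled string, so reads cross
  the closure point with expected frequency `read_len / circle_len`.
* `simulate_accession_panel()` generates per-accession pCNs under exactly
  the random-intercept model the association stage fits (clade intercepts,
  standardized bioclimatic covariates, Gaussian noise, truncation at zero
  kept inert by a baseline mean of 10), and records the generating marginal
  R² in its truth metadata.

What the generator does **not** emulate: sequencing indels, quality-score
structure, PCR/ligation chimeras, organellar read load (organelle filtering
is tested with separately simulated organelle reads), nested/truncated
genomic copies, and assembly errors (contigs are derived from circles by
rotation and trimming, since de novo assembly is outside scope). Green
tests therefore demonstrate the correctness of the *rules* — junction
geometry, coverage arithmetic, filters, model fitting — not robustness to
every artifact of real libraries.

## Alignment

All stages run on `naive_align()`, an Rcpp seed-and-extend aligner: exact
31-mer seeds every 7 bp on both strands, ungapped extension under a
mismatch budget (2 per 100 bp of query) with an X-drop rule (match +1,
mismatch −4, stop at 10 below the running maximum), soft-clipping the
unextended tails; with `all_hits = TRUE` every passing placement is
reported. The X-drop rule matters: with a plain mismatch budget, extension
creeps a few chance-matching bases past a breakpoint, and at a 2-LTR
junction record a genomic read ending at the junction could leak ≥ 5 bases
across and masquerade as junction-spanning. Ending blocks at the
best-scoring match keeps breakpoints sharp (the probability of a ≥ 5-base
spurious crossing is `4^-5` per read-end). The aligner does no gapped
alignment and no quality modelling; external SAM alignments can be
substituted at every stage via `read_sam()`.

## Proxy copy numbers

For one accession, `pCN_f = mean depth on consensus f / genome-wide mean
depth`. Two conventions are deliberate:

* **Consensus side, all-hits:** every reported placement contributes, so
  reads from any genomic copy stack on the consensus. Reads lying fully
  inside an LTR match both LTR positions of the consensus and are counted
  twice; this inflates pCN by roughly `2·L_LTR / L_consensus` (about 7%
  at 150 bp LTRs on a 4.3 kb element). It is the documented price of the
  all-alignments convention, not corrected.
* **Genome side, best-hit:** the normalizer uses one location per read.
  Counting secondary placements here would scale with the *square* of
  copy number on a repeat-rich genome and destroy the depth estimate; one
  location per read keeps the genome-wide mean at true sequencing depth
  (recovered within 2% at 15× in tests).

Verified properties: a planted {2, 8, 32} grid is recovered within ±15%
with perfect rank order at 15×, and estimates shift < 2% when depth
doubles.

## The mixed model and marginal R²

Associations between a family's pCN and a bioclimatic variable are fitted
per (family, variable) as `pcn = b0 + b1·x + u_clade + e`, with the
accession's clade of origin as a random intercept absorbing population
structure. The fit is REML, profiled to a one-dimensional optimization over
the variance ratio `λ = σ²_clade / σ²_resid`: for a single grouping factor
`(I + λZZ')⁻¹` is block-diagonal with the closed form
`I − λ/(1 + λ n_j) J` per clade, so each evaluation is O(n). The
implementation agrees with `lme4::lmer` to numerical precision on shared
fixtures (coefficients, standard errors, variance components, REML
log-likelihood) — lme4 serves as cross-check, not implementation.

Variance explained by the fixed effect alone is the Nakagawa–Schielzeth
marginal R²: `Var(Xβ) / (Var(Xβ) + σ²_clade + σ²_resid)`. Wald p-values
(normal reference) are used; with n = 320 and clade-unconfounded
covariates the realized type-I rate is ≈ 0.052–0.057, within the tested
0.05 ± 0.02 band. P-values are reported per test without multiple-testing
correction by default, matching the per-test p < 0.05 display convention
of the analysis this package supports; `adjust = "BH"` is available.
Recovery is verified at generating R² ∈ {0, 0.10, 0.40}: the mean over 200
replicates is within ±0.03 (the small upward bias at R² = 0, ≈ 1/n, is
estimation noise in `Var(Xβ̂)`).

## 2-LTR junction detection

For every annotated full-length copy, the last 300 bp of the 3' LTR are
fused to the first 300 bp of the 5' LTR (element orientation; minus-strand
copies are reverse-complemented first; LTRs shorter than the flank
contribute their full length). A mobilome read supports a 2-LTR circle when
one *contiguous* matched block crosses the junction with ≥ 5 matched bases
on both sides — split alignments abutting the junction do not count,
because a genuine circular template yields contiguous sequence across it.
Duplicate placements (identical reference, start, end, strand) are
collapsed before coverage is summed, mirroring the ignore-duplicates
convention of coverage tools on amplified material.

Raw per-copy junction coverage is normalized by the sample's total genome
coverage (summed per-base depth of the same reads on the reference) and
scaled ×10⁶ — per million aligned bases. The scale constant is a
readability choice; every comparison the pipeline draws is ratio-based, so
it is inert. Per-family signals are sums over copies; reads cross-mapping
between identical copies of a family count at every placement (greedy-all
attribution), consistent with the all-hits convention. A genomic-read
control runs the identical computation on WGS reads of the same genotype:
undigested linear DNA can contain junction look-alikes at tandem or nested
insertions, and mobilome-specific evidence is signal in excess of this
background (zero on simulated genomes without engineered tandems; an
engineered head-to-tail tandem pair produces the expected nonzero control).

## Circle-forming regions

Per sample, the ten longest contigs (length ranking — rolling-circle
amplification makes full-length mobile elements the longest assemblies) are
mapped split-aware to the reference; each matched block becomes a labeled
interval; overlapping or book-ended intervals merge (bedtools-style, with
distinct contig and sample bookkeeping); regions seen in fewer than three
samples are discarded; remaining regions are annotated with every
overlapping gene/TE name (";"-concatenated) and sequences ≥ 2 kb are
extracted. Specificity is computed independently on the stress and genotype
axes: the fraction of a region's contigs from the modal category, SPECIFIC
if strictly > 0.5 (a tie can never be a majority and falls through),
otherwise RECURRENT if the region occurs in ≥ 10 samples, else NONE.

## TIP filtering and zygosity evidence

Candidate insertions are clustered per (chromosome, family) by
single-linkage with a 10 bp tolerance (absorbing TSD-induced breakpoint
ambiguity), and clusters observed in ≥ 2 individuals spanning ≥ 2 genetic
backgrounds are removed: such sites are standing variation or systematic
artifacts, not de novo insertions of the focal line. At a retained site the
clipped-read fraction among reads at the insertion point summarizes
zygosity: ≈ 1 for homozygous insertions, intermediate for heterozygous,
markedly low when only a fraction of cells carry the insertion
(somatic-like). Note a structural asymmetry: a full-length insertion sheds
clipped reads from *both* of its junctions, and both project onto the same
reference coordinate, while the insertion-free haplotype contributes
spanning reads once — so heterozygous sites center near 0.57 rather than
0.50 at equal haplotype depth. The reporting bands (< 0.35 somatic-like,
0.35–0.85 heterozygous-like, > 0.85 homozygous-like, split support < 2
"support-poor") are calibrated to this counting; they are curation aids,
not genotype calls.

## GWAS candidate regions

Sites are filtered at MAF ≥ 0.05 and missingness ≤ 0.05 (the "more than 5%
missing" convention — the boundary itself is kept). Significance uses
Benjamini–Hochberg FDR < 0.05 (`stats::p.adjust`, verified against the
step-up definition on random vectors) or the Bonferroni threshold
`α / n_tests` (whose significant set is provably a subset of BH's, also
tested). Candidate windows are 20 kb, sliding by 10 kb, *anchored at
multiples of 10 kb from position 0* per chromosome — the anchoring makes
window coordinates reproducible across runs and families — and kept when
they contain ≥ 2 significant SNPs. Genes overlap a window by the ≥ 1 bp
rule; per-family gene sets feed UpSet-style exclusive intersection counts,
and a ± 10 kb linkage annotation is available for SNP-to-feature distance
checks. A 50 kb window option exists for broader candidate sweeps.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; conversion happens
  only at GFF3/SAM boundaries (1-based). BED output is 0-based half-open.
* Ties: contig length ties break by input order (stable sort); modal-category
  ties in specificity are treated as no-majority.
* A family with no alignments has depth 0 (not an error); zero genome
  depth, zero total coverage, or zero-variance covariates raise errors;
  a site with no overlapping reads reports a missing fraction, never 0.
* Single-clade panels degrade to ordinary least squares with a warning;
  REML variance estimates are floored at 0 via the boundary check λ = 0.
* All randomness flows from one integer seed through stream-specific
  derived seeds, so adding a simulation stage does not perturb others;
  identical seeds give byte-identical FASTA/FASTQ output.

## Problem sizes used by the test and acceptance runs

End-to-end checks use 4 families × 5 copies in a 500 kb background with 12
samples at 20× circle depth over 20 seeds; pCN checks use a {2, 8, 32} grid
in a ~580 kb genome at 15× and 30×; mixed-model checks use n = 320
accessions, 5 clades, 200 replicates per R² level (1000 under the null).
These sizes were chosen so each claim is tested at comfortable statistical
resolution while a full run stays in the minutes range on one CPU.

## Known limitations

* The aligner is ungapped; indel-rich data would fragment blocks and
  undercount junction-spanning reads. Real studies should feed external
  SAM alignments (BWA-MEM-style) through `read_sam()`.
* pCN inherits the all-hits inflation on internally repetitive consensus
  sequences and assumes the consensus represents the family; highly
  diverged or chimeric families blur the estimate.
* Specificity classification assumes one contig's sample is unambiguous; a
  contig chimerically assembled from two samples' reads has no
  representation here.
* The eccDNA generator draws circles independently; it does not model
  enrichment efficiency (linear carryover defaults to zero) or
  amplification bias between circles.
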