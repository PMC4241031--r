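---
title: "Mapping-by-sequencing for ENU outcross pedigrees: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping-by-sequencing for ENU outcross pedigrees: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enumap)
```

# The problem

ENU (N-ethyl-N-nitrosourea) mutagenesis scatters random point mutations
through the spermatogonial genome of a founder male. A recessive phenotype
surfacing in his third-generation descendants is caused by one of those
mutations, brought to homozygosity by the breeding scheme. To find it, the
pedigree is outcrossed to a divergent inbred strain (CBA/J here, against a
C57BL/6 founder background): the dense strain-specific polymorphism between
the two backgrounds turns every chromosome segment into a readable record of
its ancestry. `enumap` implements the desk side of that experiment:
low-coverage whole-genome variant calls from one affected animal are
filtered, the genome is segmented into diplotype-ancestry states, a marker
panel is scanned for linkage, and homozygous protein-sense-affecting
variants inside the founder-homozygous region are nominated as candidates.

Because each step's behaviour depends on distributional structure (variant
densities, mosaic block lengths, genotyping noise) the package carries a
first-class simulator that generates that structure with known ground
truth; every end-to-end claim the test suite makes is measured against that
truth.

# The synthetic cross

`sim_config()` + `simulate_pedigree()` generate a pedigree of ancestry
mosaics. Defaults describe the study conditions the package is designed
around:

* genome: 20 autosomes x 50 Mb (sex chromosomes are not modelled; the
  method targets autosomal recessives);
* `strain_snp_rate = 5e-4`/bp: CBA-vs-reference SNPs, carried by every
  CBA-derived haplotype. This reproduces the qualitative density ordering
  seen in real crosses (CBA segments orders of magnitude denser than
  founder segments) at a rate that keeps desk-scale runs light;
* `enu_rate = 1e-6`/bp: ENU point mutations on the single mutagenized
  founder haplotype, ~1000 per genome — the order of magnitude expected
  from high-dose ENU regimes. The true per-locus ENU rate in any given
  experiment depends on dose and locus; this default is a free parameter of
  the simulator, not a literature estimate;
* `cm_per_mb = 0.5`: the genome-wide average mouse map density, with a
  Haldane (no-interference) map: crossovers per meiosis are Poisson with
  mean L(Mb) x cM/Mb / 100, positions uniform. No interference model is
  assumed anywhere downstream, so the simplest map is used;
* `n_meioses = 4`: each haplotype of a bred mouse is an F1 gamete passed
  through three further meioses against fresh F1 gametes. The pedigree is
  deliberately abstracted to its informative meioses: the analysis only
  sees the resulting mosaic block-length distribution, so named generations
  add nothing but bookkeeping. Setting `n_meioses = 1` reproduces a plain
  F2 intercross, which the test suite exploits to check marker genotype
  frequencies against closed-form intercross probabilities
  (`2*theta*(1-theta) + theta^2` at Haldane theta);
* noise at ~6x coverage: `mean_depth = 5.8` with depths truncated below 2
  (a caller cannot emit a variant with fewer than two supporting reads),
  `het_miscall_rate = 0.1` (the chance that every sampled read carries one
  allele at that depth is about `2 * exp(-depth/2)` which is 0.11 at 5.8x), and
  `dropout_rate = 0.03` (sites effectively uncovered or uncalled,
  `P(depth < 2) = 0.02` at 5.8x plus caller losses);
* `fp_rate = 2e-8`/bp false calls, emitted strand-skewed and low-quality so
  the strand filter has something real to do;
* one planted causal mutation, always missense-capable and inside a gene
  model, because the end-to-end experiment needs a recoverable target;
  `enu_rate = 0` is rejected for the same reason. The sequenced proband is
  bred (by rejection) to be founder-homozygous at that locus, and a mouse
  is affected iff it is FF there: full penetrance, no phenocopies.

Strain SNPs are shared by all CBA haplotypes, so they appear homozygous in
CC segments and heterozygous in CF segments; ENU mutations live on one
founder haplotype, so they appear homozygous in FF segments and
heterozygous in CF. That coupling of density and zygosity to ancestry is
the entire signal the HMM uses.

What the simulator does *not* emulate: reads (the pipeline starts from
variant calls), indels and mutation spectra, repeat-driven artefact
clustering, sex chromosomes, litter structure, and reference errors.
Passing tests therefore demonstrate correctness of the analysis under the
stated statistical model, not robustness to every artefact of a real
sequencing run — the filter stages for repeats and clusters are exercised
with synthetic masks and dense random sites instead.

A note on scale: gene CDS sequences are generated per gene under derived
seeds, so a genome can be built with or without materialized sequence
(`make_genome(cfg, sequence = TRUE)`); sequence-free genomes make
20 x 50 Mb simulations cheap, while desk-scale end-to-end runs (4 x 25 Mb
in the examples and acceptance script) materialize the FASTA for the
homopolymer filter and consequence caller.

# The filter cascade

`filter_cascade()` mirrors the filtering a real run applies between raw
calls and analysis: known-variant blacklist subtraction, then six
site-quality stages in a fixed order — depth, allele balance, strand skew,
homopolymer context, repeat mask, local cluster — each seeing only the
survivors of the previous stage, with per-stage accounting
(`input = survivors + removed` is asserted on every run).

Published descriptions of such filters rarely pin down the statistics, so
the rules here are declared interpretations with conservative defaults:

* depth in [2, 30] (about 5x the mean coverage as the upper bound; high
  depth flags collapsed repeats);
* heterozygous allele balance >= 0.2;
* strand skew `|fwd - rev| / alt <= 0.9`, applied only when `alt_depth >= 4`
  — a ratio rule rather than an exact test, with the minimum count keeping
  binomial noise at low depth from dominating; records without strand
  counts are exempt rather than guessed;
* homopolymer: a single-base run of >= 6 within +-5 bp of the call;
* "quality of local variation" is interpreted as a cluster rule: every
  variant inside any 100 bp window holding > 3 variants is removed. Dense
  local variation at 5.8x is more often misalignment than biology;
* blacklist matching on (chrom, pos, ref, alt) by default, position-only
  selectable, since published subtraction procedures rarely state their key.

Every threshold is a `filter_config()` field; disabling values are
documented so any stage can be switched off.

# Two-point LOD linkage

For a fully penetrant recessive in a coupling-phase intercross, with B the
founder allele and theta the recombination fraction, affected mice are m/m,
so `P(BB) = (1-theta)^2`, `P(BC) = 2 theta (1-theta)`, `P(CC) = theta^2`;
unaffected mice are the renormalized remainder, e.g.
`P(BB | unaffected) = (1 - (1-theta)^2) / 3`. The LOD is the base-10 log
ratio against theta = 0.5, maximized on a grid over [0, 0.5) (default step
0.001, ties to smaller theta, the 0.5 anchor pinned at LOD 0). Unaffected
mice are included by default because typed unaffected siblings carry real
information; an affected-only mode exists. Penetrance is fixed at 1 — the
phenotype this design models is tracked with a reliable assay — and is the
main assumption to revisit before reusing the module elsewhere.

A marker is *fully consistent* when every affected mouse is BB and no
unaffected mouse is BB; the mapped region runs from the nearest
non-consistent marker to the left of the leftmost consistent marker to the
nearest on the right of the rightmost, clipped to the chromosome. The
affected-only variant of the rule is selectable.

One subtlety the simulation makes visible: two fully consistent markers
have *identical* maximal LOD (each affected contributes log10(4), each
unaffected log10(4/3), at theta = 0, regardless of the BC/CC split), so in
a finite pedigree the scan's argmax is frequently a tie between the
causal-position marker and a tightly linked neighbour. The scan reports all
markers; end-to-end checks in this package score success as the
causal-position marker *attaining* the maximal LOD, which is the strongest
statement a tied scan supports.

# Ancestry segmentation

`segment_genome()` bins filtered calls into 250 kb windows of
(homozygous, heterozygous) counts and decodes a three-state HMM (CC, CF,
FF) with independent Poisson emissions per window, uniform switch
probability rho per boundary (stay `1-rho`, switch `rho/2` each way), and
per-chromosome decoding with a fresh initial distribution. 250 kb resolves
multi-Mb mosaic blocks while keeping expected ENU counts per window well
below 1 and strain counts well above it. `rho` defaults to
`2 * n_meioses * (cM/Mb / 100) * window`, the expected diplotype junction
rate per window under the simulated breeding depth. All arithmetic is in
log space; a zero rate with a positive count yields -Inf emissions rather
than an error, and Viterbi ties break toward the earlier state in CC < CF
< FF order. Both the Viterbi path and per-window forward-backward
posteriors are emitted, so either a hard or a threshold-based segmentation
convention can be compared downstream.

Emission rates can be supplied, or estimated from the genome-wide count
histogram by a three-component Poisson-mixture EM (max 500 iterations,
tolerance 1e-6, deterministic k-means-style initialization: windows are
hard-assigned to the nearest of three prototype centres in log1p space —
hom-dense, het-dense, depleted — and component moments start the EM).
Component labelling deserves care: ranking by raw rates breaks when an
ancestry state is absent from a small genome (three components then carve
up two clusters). Labels are therefore assigned structurally: CF is the
het-dominant component, and a component is accepted as CC only if its
homozygous rate is on the same scale as CF's heterozygous rate — both
measure the same strain-SNP density — otherwise CC is declared absent and
the bulk remaining component is FF. This self-calibrates from the data and
needs no extra parameter.

Degenerate inputs: empty chromosomes decode to empty paths; a window count
table with fewer than three windows refuses estimation (supply parameters);
rates are floored at 1e-4 to keep EM responsibilities finite.

# Candidate nomination

`classify_consequence()` translates the affected codon before and after a
substitution (strand-aware; codon index 1-based from the CDS start across
spliced exons; labels like `C185Y`, stop written `*`), calls the two
intronic bases flanking each CDS junction `splice` (the canonical +-2
window), and everything else `noncoding`. Only SNVs are accepted — ENU
makes point mutations and the simulator emits nothing else — indels are
rejected with a clear error rather than mis-annotated. The independent
check retranslates the whole mutant CDS and diffs the proteins.

`nominate_candidates()` keeps variants that are homozygous,
missense/nonsense/splice, and inside the region set: FF segments, the
linkage region, or their intersection when both are supplied — a recessive
causal mutation must be homozygous founder-derived *and* under the linkage
peak, so applying both filters is the natural composition of the two
mapping routes.

# Pipeline, seeding, reproducibility

`run_pipeline()` chains simulate, filter, linkage, segment and candidates,
writing each stage's artifacts (VCF, TSV, BED, JSON) so any stage can be
rerun in isolation from files. Every stage draws its randomness under a
seed derived deterministically from the global seed and the stage name
(`derive_seed()`), which makes whole-pipeline output byte-identical under a
fixed seed and identical whether stages run chained or separately. Seeds
are recorded in the VCF header, the run log and the JSON report; plain
data TSVs are left comment-free so standard readers ingest them unchanged.

# Problem sizes used in the checks

The test-suite and acceptance-script studies use: the full 20 x 50 Mb
default genome (sequence-free, proband only) for segmentation recovery,
100 seeds in the tests and 25 in the script; a 4 x 25 Mb desk genome with
materialized sequence for end-to-end recovery, 100 and 50 seeds
respectively; 27 mice per pedigree throughout, matching the typed-animal
count this design assumes. With the default noise rates the expected
per-replicate causal loss is about 3% dropout, 2-3% strand/homopolymer
filtering, and about 1% segmentation boundary effects; the observed
recovery rates in the acceptance output sit where that arithmetic predicts.

# Known limitations

* Variant calls are taken at face value: no genotype-likelihood modelling,
  no indel handling, no read-level evidence.
* The HMM's uniform switch probability ignores recombination-map
  heterogeneity; segment boundaries are window-quantized.
* Full penetrance and a single biallelic causal locus are assumed end to
  end.
* Toy gene models have codon-aligned exon junctions; the consequence
  caller itself handles junction-spanning codons, and is tested on
  hand-built genes, but the simulator never produces them.
* The marker panel is noise-free (genotyping a handful of SSLP/SNP markers
  is essentially error-free compared to 6x WGS calls), so linkage results
  are optimistic about marker quality.
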