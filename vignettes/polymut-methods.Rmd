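---
title: "Detecting induced mutations in polyploid GBS data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting induced mutations in polyploid GBS data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polymut)
library(data.table)
```

## The problem

Hexaploid bread wheat carries three closely related subgenomes (A, B, D).
When short reads from a reduced-representation (genotyping-by-sequencing,
GBS) library are aligned against a collapsed unigene transcriptome, reads
from the three homoeologous gene copies pile onto a single reference
sequence. Every fixed difference among the copies then looks like a
heterozygous variant — in **every** plant. A chemically induced point
mutation (EMS, ethylmethane sulfonate, which alkylates guanine and drives
G/C→A/T transitions) instead appears in **exactly one** plant of a
mutagenized population. `polymut` implements this cross-sample logic as a
complete pipeline: demultiplexing, mapping, multi-sample diploid
genotyping, and a classifier that partitions variant calls into
EMS-induced, homoeologous, and intervarietal (cultivar-vs-reference)
classes, with downstream characterization and chromosome-region mapping.

## Pipeline stages and their models

### Read preparation

Reads are accepted only when they begin with an exact sample barcode
followed by the four-base *Ape*KI cut-site remnant `C[A/T]GC`; barcodes
are 4–8 bp and prefix-free, so assignment is unambiguous and no mismatch
rescue is attempted. Retained reads are screened for `N` within the first
72 bases of the original read, screened for common-adapter contamination,
and trimmed to a fixed 64 bp analysis length that includes the remnant.
Reads shorter than 64 bp are dropped rather than padded, keeping one
uniform analysis length.

The adapter screen drops any read in which at least 12 bases of the common
adapter begin inside the 64-bp window. This catches adapter/adapter dimers
and — just as important — *read-through* on short restriction fragments.
Read-through matters more than it may seem: an induced mutation can create
or destroy a GCWGC site, producing a plant-private short fragment whose
adapter tail would otherwise be mis-read as a cluster of plant-private
"variants" precisely where the classifier is most sensitive.

### Mapping

The mapper is a deterministic seed-and-extend aligner: tiled 16-mers seed
candidate loci, candidates are verified mismatch-only first and otherwise
by a small-window alignment with affine gap costs (mismatch 3, gap open 4,
gap extension 1), accepting at most 4 mismatches and 4 gap bases. The
affine costs make one contiguous indel strictly cheaper than any split
placement, so all reads spanning the same indel report the same event.
Mapping quality is 60 for a unique placement, 0 for a tied best placement,
and otherwise `min(60, 5 * (best − second best score))` — the downstream
filter only consumes the MQ ≥ 30 threshold, so the essential property is
that unique placements clear it and ambiguous ones do not. Homoeologous
copies are *expected* to co-map onto one unigene; the aligner makes no
attempt to separate them.

### Pileup and genotyping

Pileups accumulate per-position, per-sample base observations (Phred ≥ 13;
the floor is the conventional mpileup default) plus insertion/deletion
observations anchored on the preceding reference base and normalized to
their left-most (canonical VCF) representation. Each sample is genotyped
under a **diploid** model even though the organism is hexaploid: this
mirrors how the read pools behave (a homoeologous site has an alternate
allele fraction near 1/3 and is called 0/1 in every sample) and is exactly
the signal the classifier exploits. Genotype likelihoods are binomial with
per-read error probabilities from base qualities; GT is the maximum
posterior under a uniform prior, GQ the phred-scaled posterior mass of the
non-called genotypes (capped at 99), site QUAL the summed phred-scaled
posterior that each covered sample is homozygous reference, and MQ the RMS
mapping quality of covering reads. Multi-allelic sites keep the reference
plus the most frequent alternate allele; remaining observations are
dropped and tallied.

### Classification

Sites first pass four inclusive filters: QUAL ≥ 30, combined depth DP ≥ 10
(at least ~3× per homoeologous copy), MQ ≥ 30, and reads from more than
one sample. Retained sites are classified by their cross-sample genotype
pattern, in a fixed precedence:

1. **intervarietal** — every covered sample is 1/1 (the cultivar differs
   from the reference);
2. **singleton deviation** — exactly one covered sample differs from a
   genotype shared by all other covered samples (at least two uniform
   others are required, and samples without reads are ignored), and, for
   an alternate-carrying deviator, no other sample's *reads* contain the
   alternate allele. The read-level condition matters: a homoeologous
   variant can fail to reach a genotype call in a sample that happens to
   draw few reads from the variant-bearing copy, yet still leave read
   evidence there — a change present in more than one plant's reads is
   homoeologous whatever the genotypes say. A deviating *mutant* plant
   with genotype quality GQ ≥ 30 (stringent) or ≥ 20 (redefined) becomes
   an EMS call — heterozygous if 0/1, homozygous if 1/1, including the
   sole-0/0-carrier-among-1/1 case. A deviating *wild-type* plant is
   never EMS; it feeds the error-rate estimate;
3. **homoeologous** — the alternate allele is present in the reads of two
   or more samples (per-sample alternate depths travel in the VCF `AD`
   field; an external VCF without `AD` falls back to genotype-level
   evidence);
4. otherwise **filtered**.

Because wild-type plants carry no induced mutations, the rate at which a
wild-type plant is the sole deviator measures the false-calling process:
`error rate = 100 × (wild-type sole-deviator sites) / (retained sites with
wild-type reads)`.

## The synthetic experiment

The simulator generates the full study design so that every stage is
testable against known ground truth: random unigenes (300–900 bp), three
homoeologous copies per unigene, per-plant EMS events, *Ape*KI digestion
(all GCWGC sites cut; the enzyme's methylation sensitivity is irrelevant
here since it serves only as a genome-reduction device), barcode + remnant
read structure, Poisson per-fragment depth, per-base errors, and a junk
fraction to exercise the filters.

Default parameters (fixed once as the package's study conditions):

| parameter | default | rationale |
|---|---|---|
| unigenes | 200 × 300–900 bp | average ~600 bp, matching a transcript-contig reference at desk scale |
| plants | 5 mutant + 2 wild type | scaled-down version of the 21 + 2 study design |
| homoeolog divergence | 0.02 / bp pairwise | realistic subgenome divergence; sites are drawn at 1.5× this rate and assign the alternate base to one of three copies, giving the stated pairwise rate |
| intervarietal rate | 0.005 / bp | keeps the intervarietal:homoeologous call ratio in the observed regime |
| EMS SNPs / INDELs per plant | 60 / 6 | the true per-plant load before detection is unknown; these give enough detectable events for stable recall/precision estimates |
| GC→AT fraction | 0.43 | the observed (not canonical) fraction in this population |
| heterozygous fraction | 0.89 | observed heterozygous share of single-plant calls |
| insertion fraction | 0.36 | observed 79 insertions / 139 deletions; deletions 1–3 bp, insertions 1–4 bp |
| per-fragment depth | Poisson(20) per chromatid fragment | "depth 20" study condition |
| base error rate | 0.001 | Q30-class sequencing; correct bases Q40, error bases Q2–15 |
| junk fraction | 0.05 | exercises the barcode/remnant/N/dimer filters |
| read/trim length | 100 / 64 bp | single-end GBS as in the study design |

Each plant carries **two chromatids** per homoeologous copy; heterozygous
events mutate one chromatid, homozygous events both. This reproduces the
0/1 vs 1/1 genotype classes. Every chromatid is digested independently, so
mutation-created or -destroyed cut sites propagate into realistic
plant-private fragment patterns.

What the simulator deliberately does **not** model: PCR duplicates
(irremovable in single-end GBS), paired-end structure, methylation
sensitivity, large structural variants, and reference redundancy
(real unigene sets contain near-duplicate contigs that absorb reads at
MQ 0). Passing the synthetic validation therefore demonstrates the
correctness of the pipeline's logic under its stated error model, not
performance on any real library.

## Numerical and design choices

* **Positions** are 1-based throughout the R API, matching VCF.
* **Indel anchors**: insertions and deletions attach to the reference base
  preceding the event and are left-aligned; planted truth events are
  normalized the same way before comparison.
* **QUAL for uncovered samples**: samples without reads contribute nothing
  to site QUAL (their posterior is the uninformative prior).
* **Ties**: a read with two equally good placements gets MQ 0 and is
  removed by the MQ filter; equal-count alternate alleles resolve
  alphabetically; a site where each of two covered samples deviates from
  the other is not a singleton pattern.
* **"Uniform rest"** in the singleton test requires ≥ 2 other covered
  samples; with exactly two covered samples the deviator is undefined.
* **Singleton GQ failures** fall through to the homoeologous test rather
  than directly to `filtered`, since an alternate allele seen in ≥ 2
  samples is a homoeologous change by definition.
* **The longest ORF** is the longest stop-free codon stretch over all six
  frames, with no ATG requirement — transcript fragments (ESTs, partial
  contigs) routinely truncate the true start codon. The definition is
  recorded in the result so an ATG-anchored variant can be swapped in.
* **Region-load arithmetic**: normalized per-region loads are displayed to
  two decimals, but arm and chromosome totals are computed from the
  *unrounded* region values and rounded last — the summation order that
  reproduces the published consensus-map table exactly.
* **Extrapolation** truncates (rather than rounds) the scaled counts and
  carries the unrounded full-coverage quotient into the genome-wide step,
  again matching the published arithmetic.
* **EST anchoring** replaces a BLAST e-value cutoff with ≥ 95% identity
  over ≥ 200 aligned bases of a local alignment; unigenes whose two best
  hits tie across regions stay unassigned.

## Validation

The test suite validates each stage against an independent oracle: pileup
depths against a per-read CIGAR-walk recount; genotype posteriors against
explicit enumeration over per-read outcomes at depth ≤ 12; coverage
summaries against per-base recounts; synonymous/non-synonymous calls
against whole-protein translate-and-compare; the mapper against an
exhaustive all-positions alignment on small references. The end-to-end
synthetic run (the default configuration above) is required to recover
planted EMS events with recall ≥ 0.9 and precision ≥ 0.95 among
filter-passing sites, to call no multi-plant-visible homoeologous site as
EMS, and to call no fewer EMS variants under the redefined (GQ ≥ 20)
criteria than under the stringent ones.

## Known limitations

* A homoeologous variant visible in only **one** plant's read pool — for
  example when an induced deletion stretches that plant's fixed-length
  reads across a boundary no other plant's reads reach, or when a
  cut-site polymorphism restricts a fragment to one copy — is
  indistinguishable from an induced mutation by cross-sample logic alone.
  This is the error class the wild-type error rate quantifies; base
  alignment quality (BAQ)-style realignment, which would suppress part of
  it, is out of scope.
* The diploid genotype model saturates at allele fractions near 1/2;
  dosage within the six chromatids (e.g. 1-of-6 vs 3-of-6) is not
  estimated. A polyploid genotype model is future work.
* The mapper performs no soft-clipping; reads whose tails run off a
  unigene end or into unremoved adapter are unmapped rather than clipped.
* Saturation analysis recomputes pooled coverage from scratch at each
  step, which is quadratic in total reads; it is intended for per-sample
  scales, not full-flowcell data.

## A worked example

```{r example, eval = FALSE}
library(polymut)

cfg <- sim_config(seed = 42)          # the default study conditions
run <- run_pipeline(run_config("polymut_demo", sim = cfg, seed = 42))

run$truth_comparison$ems_recall       # ~0.95-1.00
run$truth_comparison$ems_precision    # ~0.95-1.00
run$stages$classify$by_category      # EMS / homoeologous / intervarietal counts
```

The same stages are available individually (`simulate_gbs()`,
`demultiplex()`, `quality_filter_and_trim()`, `build_index()`,
`map_reads()`, `pileup()`, `genotype_sites()`, `apply_site_filters()`,
`classify_variants()`, …) and as a command-line tool
(`inst/scripts/polymut`).
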