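---
title: "Detecting selection-driven mutations in low-relatedness experimental evolution"
author: "dictyvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection-driven mutations in low-relatedness experimental evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

When *Dictyostelium discoideum* is evolved at low relatedness — replicate
lines serially passaged by replating a million thoroughly mixed spores —
mutations that make a cell exploit cooperative fruiting-body formation
(cheaters) are no longer penalised, and many lines accumulate clones that
cannot fruit on their own. Identifying the responsible mutations requires
calling variants in haploid bulk ("population") samples and in clonal
isolates, then separating a handful of genuinely selected new mutations
from ancestral polymorphism and caller artifacts.

`dictyvar` implements that inference pipeline: ancestral-polymorphism
masking by major allele frequency, two parallel hard-filter sets mirroring
the two variant callers used on such data, custom site-level filters,
cross-caller intersection, read-support validation against the origin
population, structural-variant quality filtering, consequence annotation on
toy gene models, per-gene parallelism summaries, and a clone-genotype
association screen (Fisher's exact test, exact binomial prevalence
intervals). A synthetic-data module simulates the whole experiment so the
pipeline can be validated against a known truth set.

## The filtration cascade

Variants enter as two per-caller call sets over the same samples (one
ancestor, one population per line, zero or more non-fruiting clones per
line), plus a per-site per-sample table of allele read counts.

1. **Ancestral masking.** A site is removed from *all* samples if the
   ancestor was called as a variant, was left uncalled, or has a major
   allele frequency (largest base count / depth) below 0.90 in its read
   counts. The MAF rule catches standing polymorphism segregating below the
   calling threshold. Sites absent from the ancestor's counts are treated
   as uncalled but flagged distinctly (`ancestor_missing_counts`) so the
   audit trail separates "no data" from "ambiguous data".
2. **Hard filters.** Caller A records pass iff QD > 2, FS < 60, SOR < 3,
   MQ > 40, MQRankSum > −12.5 and ReadPosRankSum > −8 (the standard
   germline recommendations). Caller B records pass iff MQM > 40, SAF > 0
   and SAR > 0, SAP > 0.5 and SRP > 0.5, RPR > 1 and RPL > 1. All
   inequalities are strict, matching how the thresholds are conventionally
   written. A missing metric does not fail its rule by default — rank-sum
   metrics are legitimately absent at sites without reads for both alleles
   — but is flagged `metric_absent:<name>`, and the policy is configurable
   (`missing_metric_fails`).
3. **Custom filters**, in order: drop indels and multi-allelic sites (the
   analysis is restricted to biallelic SNVs); drop sites uncalled in more
   than 10 samples; drop sites with haploid alternate allele count above 3
   (a line-specific mutation can appear at most in one population plus its
   sequenced clones — up to three samples for lines with two clones); keep
   only QUAL ≥ 200 ("a minimum of 200" is inclusive); finally drop sites
   whose DP exceeds 1.5× the mean DP *of the sites surviving the preceding
   rules of this stage*. Computing the mean on the cleaned set follows the
   caller-B description of the source pipeline and is applied symmetrically
   to caller A, whose description does not specify the averaging set. This
   makes the DP rule order dependent by construction; it is the one rule
   excluded when we assert order-invariance and threshold-monotonicity
   properties in the tests.
4. **Intersection.** A site survives only if present, with the same
   alternate allele, in both independently filtered call sets; consensus
   records carry caller A's annotations. Same-position/different-allele
   pairs are flagged `alt_mismatch` rather than silently dropped.
5. **Read support.** Every call made in a clone must be backed by at least
   5 reads of the same alternate allele in the clone's origin population.
   Rather than discarding the whole SNP outright, the unsupported clone
   call is first rejected (flagged `clone_call_rejected`); the SNP is
   dropped only when no supported call remains. This reproduces both
   documented outcomes of the manual step it replaces: removal of an
   unsupported SNP, and rejection of a single sample from an otherwise
   supported call. Finally, a SNP whose allele has low-level support
   (≥ 2 reads) in the populations of ≥ 2 lines *other than those in which
   it was called* is dropped as a shared artifact: true new mutations
   should be private to one line. The exact numeric criterion behind the
   published "shared low-level support across multiple lines" rule is not
   stated; ≥2 reads in ≥2 other lines is this package's default and both
   numbers are exposed in `filter_config()`.

Every stage emits machine-checkable decisions (site, stage, verdict,
reasons); there are no silent drops. This audit trail is the rule-based
replacement for the manual browser review used in the original workflow.

Structural variants are filtered with the analogous rules: `PASS` flag,
QUAL ≥ 20 (inclusive, as published), paired-end support PE > 3 (PE > 5
would apply to translocations, but translocations are excluded outright as
interchromosomal), simple intrachromosomal types only (DEL/DUP/INV/INS),
and at most 3 genotyped samples. "Simple" is interpreted as
single-interval, non-breakend events.

## The association screen

Clones isolated from an evolved line are scored for (1) fruiting in
isolation and (2) carriage of a candidate variant, giving a 2×2 table per
line, per variant, or pooled per gene region. The two halves of a
two-domain receptor gene — the 5′ half encoding signal peptide and
extracellular binding domain, the 3′ half the seven-transmembrane domain —
are the motivating regions; `assign_region()` splits a gene's CDS at a
configurable boundary, by default the transcript-coordinate end of exon 1,
because the two exons of the focal gene closely match its two halves.
Flanking variants and structural variants starting upstream of the CDS are
assigned to the 5′ region.

`fisher_exact()` computes the two-sided p-value from first principles:
with both margins fixed, hypergeometric probabilities over the whole
support are evaluated in log space via log-gamma, and the p-value sums all
tables whose probability does not exceed the observed table's (relative
tie tolerance 1e-7). Two-sidedness by this minimum-likelihood rule matches
the default of mainstream statistical software; the original report does
not state sidedness, and two-sided is the conservative choice. Per-line
tests are primary and no multiplicity correction is applied, matching the
original analysis; pooled regional tables are simple sums over lines.

`prevalence()` gives exact (Clopper–Pearson) binomial intervals for the
frequency of non-fruiting clones, computed by numerically inverting the
binomial tail probabilities with `uniroot` (tolerance 1e-12); the tests
cross-check the endpoints against the closed-form beta-quantile
expression, keeping the two routes independent.

## The simulator and what it does (and does not) emulate

The generator's defaults are the study conditions: 24 lines, 31 passages,
10^6 founder spores per passage, mean mapped depths of 195× for population
samples and 54× for clones, and a single master seed from which every
stage derives a labelled substream (so runs are bit-reproducible and
stages are independently perturbable).

**Evolution dynamics.** The source experiment reports design and outcome
but no dynamical model, so the simulator adopts the simplest process
consistent with the passaging scheme: per passage, deterministic logistic
selection `f' = f(1+s)/(1+fs)` followed by binomial resampling of the
founder pool. New mutations arise as a Poisson process (default 0.1
selected mutations per line per passage) and enter at frequency 1e-4 —
on the order of a hundred copies among the million founders — representing
clonal expansion during the ~9 generations of vegetative growth within the
passage in which they arise (~290 generations over 31 passages implies
roughly 9 per passage); treating a passage as a single
selection-plus-resampling step leaves within-passage growth implicit. The
default selection coefficient of 0.6 per passage lets mutations arising in
the first third of the experiment reach the intermediate-to-high
population frequencies at which the real study called its variants. Loci
evolve independently: no linkage, interference, or competition between
cheater lineages, so per-line frequencies are marginals and can sum above
one. Phenotype follows the study's empirical association: only
5′-class mutations cause non-fruiting (with configurable penetrance,
default 1), while 3′-class mutations are selected but phenotype-neutral in
isolation.

**Sequencing.** Reads are emulated at the mapped-depth level only: depth
is Poisson per site/sample, alternate reads are binomial at the sample's
allele frequency, and a scalar error rate (default 1e-3) redistributes
reads uniformly over the other three bases. There is no read-level FASTQ
simulation, alignment, mapping bias, indel error, or base-quality
structure — the pipeline consumes call sets and read counts, not reads, so
these upstream processes are out of scope. Consequently, passing recovery
tests demonstrates that the *filtration logic* behaves as specified under
the stated statistical structure; they cannot certify behaviour against
alignment artifacts or systematic sequencing error in real data.

**Caller emulation.** A sample is called alternate when it has ≥ 3
alternate reads making up ≥ 5% of its depth (an emulation parameter, not a
published rule; exposed in `sim_config()`). True calls receive passing
metrics drawn from comfortable ranges and a QUAL that scales linearly with
total supporting reads. Injected false positives each carry exactly one
designed defect — low QD, low MQM, strand bias, low QUAL, excess DP,
missingness above threshold, alternate allele count above 3 (planted
across four lines), presence in a single caller, a clone call with only 4
origin-population reads, or 3 supporting reads planted in two other lines'
populations — so that every removal in the recovery test is attributable
to one rule. Ancestor-level artifacts (fixed ancestral variants, zero
ancestor coverage, ancestral polymorphism with MAF drawn from
U(0.55, 0.89)) exercise the three masking reasons. The SV set likewise
contains planted true events plus one failure per SV rule.

## Numerical and design choices

- Coordinates are 1-based closed throughout (VCF convention); SV/gene
  overlap treats intervals as closed, so an SV abutting a CDS end
  coordinate overlaps it.
- Haploid genotypes: `"1"`/`"0"`/`"."`; an uncalled sample contributes to
  missingness, never to AC.
- Sample naming: populations are the bare line number, clones
  `<line>-NF<k>`; the line of any sample is its leading integer, and a
  clone plus its own population count as one line in sharing and tally
  logic.
- The hypergeometric tie tolerance (1e-7 relative) makes the ≤-probability
  comparison robust to floating point; the cascade and SV filters are
  deterministic and need no tolerances.
- Degenerate inputs: empty call sets flow through every stage; a
  contingency table with an empty phenotype class reports carrier
  percentages as explicit missing values; `prevalence()` rejects n = 0;
  zero-depth samples have undefined AF rather than 0.
- Toy genomes default to 77% AT to mirror the extreme AT richness of the
  modelled genome; gene models are two-exon with the transcript end of
  exon 1 as the default 5′/3′ boundary, and a full-size two-domain
  receptor stand-in is available via `exon_codons = c(383, 390)`.

## Problem sizes used in validation

The packaged tests and the acceptance script validate at sizes chosen to
exercise every rule while keeping a full run comfortably interactive:
recovery simulations use 6 lines × 31 passages at the study depths
(195×/54×) with 12 genes on three 60 kb chromosomes; the
cascade-vs-brute-force property uses 100-site random call sets over 200
seeds; Fisher enumeration is checked exhaustively for all tables with
total ≤ 14 and on dense random samples up to total 60. These sizes are the
package's validation design, and all of them are parameters a user can
raise.

## Known limitations

- The independent-locus assumption misstates within-line dynamics when
  several strong mutations segregate simultaneously (no clonal
  interference); summed marginal frequencies can exceed 1.
- A clone's genotype vector is drawn independently per mutation at final
  frequencies, which ignores within-line haplotype structure.
- Consequence annotation covers CDS point substitutions and fixed-size
  flanks only — no splice, UTR, or regulatory classification — and only
  the standard nuclear codon table.
- The genome-scale figures of the motivating study (total SV counts,
  genome-wide read-support averages) depend on its deposited sequencing
  data and are out of scope; the simulation-recovery properties cover the
  corresponding logic qualitatively.
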