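---
title: "Methods: temporal genomic erosion and extinction-risk simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal genomic erosion and extinction-risk simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Long-lived, heavily exploited species such as the Chinese pangolin have
declined over decades. Museum and modern specimens make it possible to ask
how the genome responded: did diversity erode, did inbreeding rise, did
deleterious variation accumulate, and what do current effective sizes imply
for future viability? `erosionscope` implements that workflow as a tested
pipeline: per-period genetic diversity, ROH-based inbreeding, Grantham-score
genetic load and LD-based effective population size from VCF genotypes,
compared across sampling periods by equal-n resampling and rank-sum tests,
plus an individual-based non-Wright-Fisher (nonWF) forward simulator for
extinction risk under carrying-capacity scenarios. A synthetic-cohort
generator supplies inputs with known truth so every stage is testable
without restricted data.

# Empirical pipeline

## Site filtering (`vcfio`)

Hard filters are GATK-style fail conditions applied per site: QUAL < 30,
QD < 2, MQ < 40, FS > 60, SOR > 3, MQRankSum < -12.5, ReadPosRankSum < -8,
DP < 3, with optional caller-specific SB/MQ0 rules that stay inactive when
the tag is absent. All comparisons are strict as written, so a site at a
boundary value (QD = 2.0) survives. A rule whose annotation is missing on a
record is skipped for that record and counted, mirroring how GATK treats
absent annotations; discarding records for absent tags would silently bias
against sparsely annotated cohorts.

The stage order is fixed and documented: hard filters, then restriction to
biallelic SNPs (applied at read time), then missingness (strictly greater
than 20% missing fails), then empirical depth percentiles (2.5% and 97.5%,
inclusive) computed on the sites that survived missingness, then optional
10-kb thinning. Depth percentiles are recomputed after missingness because
heavily missing sites carry unrepresentative depths. Depth is site-summed
(INFO DP): the inputs state site depth distributions, not per-sample ones.

Thinning keeps the *first* site of each non-overlapping 10-kb bin. This is
deterministic, idempotent, and the most literal reading of "one site every
10 kb"; a max-MAF rule would couple thinning to the sample drawn.
Coordinates are 1-based inclusive in VCF and half-open internally.

## Diversity and inbreeding (`metrics`)

Per-site diversity uses allele-count arithmetic: with `n` non-missing
alleles and `a` alternate copies, `site_pi = 2a(n-a)/(n(n-1))`, summed in
50-kb non-overlapping windows and divided by the window width. The final
partial window of a chromosome is reported with its true span and flagged.
The implementation is tested for exact agreement with a brute-force
pairwise-difference oracle.

ROH detection is a PLINK-style sliding scan. Only two parameters are fixed
by the analysis design (20-SNP windows, at most 1 heterozygous call per
window); the rest (window missingness 5, hit-fraction threshold 0.05,
minimum 100 SNPs, minimum length 100 kb, maximum gap 1 Mb) default to
PLINK 1.9 conventions and are exposed, because desk-scale genomes need
scaled thresholds. Results are therefore validated against rule-application
oracles, not against any published per-individual values. F_ROH divides the
summed length of ROH longer than 100 kb by the genome length taken from the
VCF contig headers (the reference-genome length, not the callable-site
count), and decomposes exactly into 100 kb-1 Mb and >1 Mb classes.

## Genetic load (`load`)

Polarization requires both lines of evidence: an allele is ancestral only
if strictly more than 50% of genotyped ingroup individuals are homozygous
for it *and* every genotyped outgroup individual is homozygous for the same
allele. We interpret "of the individuals" as *genotyped* individuals at the
site — missing calls say nothing about the major allele. Everything else is
unpolarized and excluded from load.

Consequences are a minimal SNP-only SnpEff-style classifier: the affected
codon is translated before and after the change (strand-aware), positions
within 2 bp of an intron boundary are splice sites, and the LOF set is
{stop gained, stop lost, start lost, splice site} — the HIGH-impact SNP
classes. Missense changes with Grantham distance strictly greater than 150
are deleterious missense; exactly 150 is tolerated. The Grantham matrix
ships as a checksummed data file (`grantham_checksum()`).

The realized load ratio is `hom / (hom + het)` over genotypes carrying the
*derived* deleterious allele. Counting is polarization-driven: where the
reference allele is derived, homozygous-reference genotypes count as
homozygous derived. The formula is about derived deleterious alleles, not
about ALT alleles; an ALT-driven count would silently depend on which
individual was chosen as the reference.

## Effective population size (`neest`)

LD-based Ne uses the squared Pearson correlation of genotype dosages (the
Burrows composite measure normalized by allele-frequency variances) over
locus pairs on *different* chromosomes (physical linkage would bias the
drift signal upward; same-chromosome pairing is available by option). The
drift relation is `Ne = 1/(3 (r2 - E[r2_sample]))`, with a non-positive
denominator reported as infinite Ne, the estimator's standard convention.
Three sampling-expectation options exist: `1/S` (the textbook term and the
`ld_ne()` default), `1/(S-1)` (`"pearson"`, the finite-sample expectation
of a squared product-moment correlation between independent loci, which we
measured to be near-unbiased for this dosage r2 and which
`resample_ne()` uses by default), and the Waples empirical correction.
The MAF cutoff defaults to 0.05, the NeEstimator convention. Locus-pair
budgets beyond `max_pairs` are thinned deterministically (evenly spaced)
so that replicates with identical samples give identical estimates.

`resample_ne()` draws equal-n samples without replacement, 100 replicates
by default, each replicate on an independently derived seed.

## Temporal comparison (`temporal`)

Metrics are resampled per period (without replacement — "selected randomly"
from small cohorts; bootstrap would inflate ties at n = 5-10), each draw
summarized by its median, and the period summarized by the median of draws
with a 2.5/25/75/97.5 percentile box. Proportional change is
`(after - before)/before`. Comparisons cover period I (oldest vs middle),
period II (middle vs newest) and overall.

The rank-sum test enumerates all group assignments exactly for combined
sizes up to 12 (valid under ties, which the classical exact distribution is
not), and uses the tie-corrected normal approximation with continuity
correction beyond that; the two branches are cross-checked against
enumeration and `stats::wilcox.test` respectively.

**A deliberate caveat**: by default significance is computed on the 100
replicate values, which mirrors the figure-style presentation of this kind
of analysis but pseudo-replicates individuals and therefore overstates
evidence — with any real shift, p-values become extreme. The package also
exposes `test_on = "individuals"`, which tests the raw per-individual
values and holds its nominal type-I error (verified over 200 null runs).
No multiple-testing correction is applied by default; a Benjamini-Hochberg
column is included in the output.

# The non-Wright-Fisher simulator (`forwardsim`)

## Model

The genome is 19 chromosomes carrying 20,000 genes of 1500 bp at full
scale, apportioned to chromosomes by largest-remainder rounding on length
and placed with uniform spacers. Mutations arise at 1.47e-8 per site per
generation; 2.31:1 nonsynonymous:synonymous. Nonsynonymous selection
coefficients are gamma-distributed (shape 0.186, mean |s| 0.01314 — the
human nonsynonymous DFE convention; the source analysis prints no DFE
parameters, so this default is the package's own documented choice).
Dominance follows the threshold rule: h = 0 when s < -0.01, h = 0.25 when
s >= -0.01. Fitness is multiplicative: homozygotes contribute (1+s), then
heterozygotes (1+hs), floored at zero. Strength classes are strong
(s <= -0.01), moderate (-0.01 < s <= -0.001), weak (-0.001 < s <= -1e-5),
neutral otherwise, always assigned on the unscaled s.

Each year: females aged >= 1 produce at most one offspring each (Bernoulli
with fecundity 0.9 — the species' single-offspring litter, with a
configurable probability since the true schedule is unpublished) with a
random male aged >= 1; gametes recombine at gene boundaries (1e-3 per
boundary, free assortment between chromosomes, no intra-gene
recombination) and receive Poisson new mutations; then every individual,
newborns included, survives with probability `min(1, w K / N)` where `N`
is the post-reproduction census — fitness-scaled density regulation, the
standard nonWF viability rule; a configurable maximum age (12 years)
imposes senescence. Under this cycle an unconstrained population of even
sex ratio grows by a factor ~1.5 per year, and a crowded one returns to
`w*K`. An empty census is an absorbing extinct state.

Fixed deleterious mutations are periodically moved out of the per-haplotype
vectors into a population-level log-fitness constant: absolute fitness
(which drives survival) is unchanged, but haplotypes stay short. This
preserves drift load — fixation of deleterious alleles permanently lowers
fitness, the mechanism behind mutational meltdown.

## Rescaling

With rescaling factor lambda, K and generation counts divide by lambda; mu,
recombination and s multiply by it (scaled s capped at -1, i.e. rescaled
strongly deleterious mutations become homozygous-lethal). The desk-scale
profile (`desk_sim_config()`, lambda = 100: K = 100 for 1000 generations,
1000 genes) burns in to a stable census near `w*K` with segregating neutral
and deleterious variation in about 1.5 minutes; the full-scale
configuration is the same code with lambda = 1 and is a cluster-sized run.

## Scenarios and outputs

`run_scenarios()` runs independent replicates per carrying capacity from
the same burned-in population on derived seeds, recording yearly census,
mean fitness and the homozygous-load proportion, extinction year per
replicate, extinction probability (extinct/total) and mean extinction time
with standard error. Two fitness-like statistics are reported deliberately:
the mean multiplicative fitness, and the literal pooled proportion of
homozygous deleterious genotypes among all deleterious genotypes; the
source text conflates the two, so both are emitted and neither is asserted
to be "the" published curve.

Validation is physical rather than curve-matching: extinction probability
is monotone non-increasing in K under paired seed streams; with selection
off, realized drift variance matches a Wright-Fisher oracle run at the
temporal-variance effective size measured from the run itself; neutral
burn-in heterozygosity agrees with the diffusion expectation
`theta/(1+theta)` with `theta = 4 Ne_year b mu_syn`, where `Ne_year` is the
incremental temporal-variance effective size (short increments avoid the
saturation bias of one long window) and `b` is the realized newborn
fraction of the census, the survival-adjusted conversion from per-gamete to
per-year mutation input in an overlapping-generations population.

# Synthetic cohorts (`syndata`)

The generator is a discrete-generation diploid Wright-Fisher simulation
with viability selection and optional selfing, over unlinked biallelic
sites laid out across chromosomes; it emits VCF (with synthesized INFO
annotations whose distributions are declared in the config, including a
deliberate low-quality fraction for filter tests), sample metadata with
period labels and collection years, an outgroup column set, toy gene models
(valid CDS with mixed strands and introns), and a truth file (per-site
class, ancestral allele and effects; per-individual selfing-derived F;
per-epoch true Ne). The same seed reproduces every output byte for byte.

What it emulates: three-period sampling of two populations with stepwise
declining Ne; drift LD at the recent effective size; selection against
deleterious derived alleles; selfing-driven homozygosity; post-mortem
C-to-T / G-to-A damage at museum-sample rates (0-2% per allele call).
What it does not: physical linkage within chromosomes (sites are unlinked,
so ROH arise from genome-wide homozygosity rather than IBD tracts),
read-level error structure, admixture or migration, and indels. Passing
tests therefore demonstrate correct rule application and directional
recovery of generator truth, not concordance with any real-data values.

Study-condition designs used by the test suite (chosen once, by power
analysis on the generator, and documented here as package choices):

* Ne-ordering recovery: 20 cohorts of a 1000 > 450 > 330 decline over
  epochs of 30/25/25 generations, 60 samples per period, 3000 sites,
  resampled at n = 55 with 4 replicates, pairs capped at 200,000. LD at
  sample sizes this small cannot resolve adjacent sizes reliably below
  ~50 samples, which is why the validated design uses more individuals
  and loci than the empirical sampling tables.
* Diversity-decline power: a late bottleneck (150, 150, 25 over 20/20/40
  generations) injects a ~50% drop in pi; period-II comparisons at n = 10
  and 100 replicates.
* Inbreeding/load gradient: selfing rates 0, 0.45, 0.9 in the final
  epoch, 20 seeds, medians averaged over seeds.
* Simulator checks run at lambda = 100 with 250-300 genes; the headline
  extinction run uses the full desk profile (1000 genes, K = 100, 1000
  generations, 100 replicates at K = 10 for 1000 years).

# Numerical and degenerate-input choices

* Empty filter results raise a classed condition
  (`erosion_empty_error`), not a silent empty object.
* Sites with fewer than two called alleles contribute zero diversity and
  are counted in `n_flagged`.
* A zero load denominator yields `NA` with `defined = FALSE`.
* `before = 0` in proportional change warns and returns `NA`.
* Monomorphic loci are excluded from LD pairs; sub-MAF loci likewise.
* All seeded entry points restore the caller's RNG state; one global seed
  fans out through a fixed multiplicative hash (`derive_seed()`), so any
  stage or replicate is independently reproducible.
* Ties in the rank-sum exact branch are handled by enumerating the
  permutation distribution of U on midranks.

# Known limitations

* The ROH caller is parameter-sensitive by construction; absolute F_ROH
  values depend on thresholds the source does not fix.
* The figure-style replicate-level rank-sum test overstates significance
  (see above); use `test_on = "individuals"` for calibrated inference.
* The nonWF mortality schedule beyond fitness-density survival and the
  exact litter probability are not published; extinction *times* are
  therefore less transferable than extinction *order* across K.
* Unlinked synthetic sites make ROH length classes compress toward the
  short end; tests scale thresholds accordingly.
* The consequence annotator handles SNPs only (no indels, MNVs or
  regulatory features).
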