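---
title: "Methods: window-based sweep scans, retro-copy detection and tail-phenotype association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based sweep scans, retro-copy detection and tail-phenotype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailsweep)
```

# Scope

`tailsweep` implements a window-based scan for recent selective sweeps in a
three-population resequencing design — a focal ("selected") lineage, a close
sister lineage and an outgroup — together with three companion analyses of a
swept locus: detection of retro-transposed gene copies by intron loss,
repeat-class density and enrichment from RepeatMasker annotation, and
marker–phenotype association in a crossbred cohort. The motivating use case
is the genetics of tail fat storage in domestic sheep, where a fat-tailed
lineage is contrasted with two thin-tailed lineages and the swept interval
is an intergenic, retro-transposon-rich region; the machinery is generic
for any three-population design with bi-allelic SNVs.

Every analysis can be exercised end to end on synthetic data with known
ground truth; the generators are part of the package, not test scaffolding.

# The window statistics

All statistics are computed on sliding windows (default 30 kb with a 15 kb
step) from per-population allele frequencies.

**Fixation index.** The default estimator is the frequency-based
ratio-of-sums form over the sites of a window,
$FI = \sum_k (H_{T,k} - H_{S,k}) / \sum_k H_{T,k}$, with
$H_{T,k} = 2\bar p_k \bar q_k$ from the mean of the two population
frequencies and $H_{S,k}$ the mean within-population heterozygosity. No
sample-size correction is applied: the intended input is cohort-level
frequency data (as from imputed call sets), where the frequencies are taken
at face value. Hudson's corrected estimator, which uses called-allele
counts and can legitimately go negative, is available via
`estimator = "hudson"`; negative values are not clamped, preferring
unbiasedness over cosmetics.

**Lineage-specific branch length.** For the selected (M), sister (T) and
outgroup (E) populations,
$LSBL_M = (FI_{M,T} + FI_{M,E} - FI_{T,E}) / 2$ and symmetrically for the
other two lineages. The three branch lengths always sum to half the sum of
the pairwise indices; this identity is tested on random fixtures. A sweep
confined to the selected lineage inflates $FI_{M,T}$ and $FI_{M,E}$ but not
$FI_{T,E}$, so $LSBL_M$ isolates selected-lineage differentiation.

**Between-population distance.** With the major/minor labelling below,
the default `per_site` mode of `window_dxy()` averages
$f_{x,major}f_{y,minor} + f_{y,major}f_{x,minor}$ over sites — the
probability that one allele drawn from each population differs. A
`literal` mode computes the product of *window-summed* frequencies
instead. The window-sum form scales with the squared site count, so it is
only comparable between windows with equal numbers of sites; the per-site
form is the default for that reason, and the literal form is retained
behind a flag for users who want the unnormalized variant.

**Pooled heterozygosity.** `window_hp()` computes
$H_P = 2 S_{maj} S_{min} / (S_{maj} + S_{min})^2$ from the window sums of
major- and minor-allele frequencies. This pooled form is bounded in
$[0, 0.5]$ and is depressed where one allele is near fixation across the
window — the footprint of a sweep. `standardize_zhp()` converts window
$H_P$ to $ZH_P = (H_P - \mu)/\sigma$ with $\mu$, $\sigma$ taken across all
non-NA windows of one population genome-wide. The sample (n−1) standard
deviation is used by default (a population-sd flag exists); the choice is
immaterial beyond a few hundred windows but had to be fixed.

## Major/minor allele convention

The statistics need per-site "major" and "minor" frequencies per
population, and it matters whether those labels are assigned per
population or once for the whole cohort. The default is **global**: the
major allele is the one whose pooled all-sample frequency is at least 0.5
(ties go to the VCF REF allele), and the same nucleotide is labelled major
in every population. Only a shared allele identity makes the cross terms
of the distance statistic refer to the same nucleotide, makes the distance
symmetric, and lets it reduce to within-population heterozygosity when
applied to a population against itself. A `per_pop` scope (each
population's own commoner allele) is implemented for comparison; the
fixation index is invariant to the choice, the distance is not. The
heterozygosity statistic is a separate case: inside `scan_genome()` the
per-window $H_P$ always uses each population's own per-site commoner
allele, because intra-population heterozygosity must be depressed wherever
that population is near fixation regardless of *which* allele it is fixed
for — under a shared cohort-wide labelling a swept window can masquerade
as heterozygous when the swept allele is the cohort-minor one.

## Windowing and degenerate inputs

Windows are 0-based half-open, tiled from position 0; the trailing partial
window of each chromosome is kept and flagged rather than dropped, so
terminal features are not silently lost. Windows with fewer than
`min_sites` sites (default 10; the variance of a ratio-of-sums over fewer
sites is unacceptable) carry NA statistics, which propagate through the
branch lengths and are skipped by the genome-wide standardization. A
window where both populations are monomorphic at every site has an
undefined fixation index and yields NA, not 0. Missing genotypes shrink
the frequency denominators; no imputation is performed, and a population
with zero called alleles at a site contributes NA at that site.
`top_windows()` uses the empirical quantile (R's default type 7) and
includes all ties at the threshold.

# The synthetic cohort generator

`simulate_cohort()` draws, per site, an ancestral derived-allele frequency
$p \sim U(0.05, 0.95)$ and per-population frequencies from the
Balding–Nichols distribution
$\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ with per-population drift $F$.
Balding–Nichols was chosen because it yields an analytically checkable
expectation: for two populations drifted independently with the same $F$,
$E[H_S] = 2p(1-p)(1-F)$ and $E[H_T] = 2p(1-p)(1-F/2)$, so the expected
pairwise fixation index is $F/(2-F) \approx F/2$ — verified numerically in
the tests. The sweep is planted as a frequency override: inside the sweep
interval the selected population's derived-allele frequency is set to
`sweep_freq` (the VCF REF allele is defined as ancestral, so the sweep
elevates ALT). This is sufficient to create the high-branch-length /
low-heterozygosity signature the scan must detect; it does not attempt to
model the sojourn of a beneficial haplotype.

Genotypes are Binomial(2, f) per sample, i.e. sites are independent:
there is **no linkage disequilibrium, recombination or coalescent
structure** outside the planted sweep, no missingness by default, and no
site-frequency-spectrum realism beyond the uniform ancestral draw.
Passing recovery tests therefore demonstrates that the statistics rank a
region of near-fixed differentiated alleles above drift background — not
that the scan is calibrated against the LD and demography of real
populations. Site positions are drawn uniformly without replacement and
sorted, so ties are impossible by construction.

Default study conditions for the recovery analyses, chosen once as a
desk-scale version of a livestock resequencing contrast: a 10-Mb
chromosome with 20,000 sites (2 sites/kb, giving a comfortable ~60 sites
per 30-kb window against the `min_sites = 10` floor), 30 samples in each
of three populations, background drift $F = 0.01$, and a 200-kb sweep at
derived-allele frequency 0.98. Twenty seeded replicates are used wherever
a rate is reported.

# Retro-copy detection

A retro-copy (retrogene) is a gene copy produced by reverse transcription
of processed mRNA, recognizable because the introns of the parent gene are
absent at the exon–exon junctions of the copy. The detector takes
intron-containing parent gene models and a target genomic region and runs:

1. **Seed–chain–extend alignment** (`chain_alignments()`) of the spliced
   (exon-concatenated) parent sequence against the region. Exact k-mer
   seeds (default $k = 12$: specific enough that a ~1-Mb region yields few
   random hits, sensitive at 80% identity where a 12-mer survives with
   probability $0.8^{12} \approx 0.07$ per position but hundreds of
   positions are available) are grouped into diagonal bands (tolerance 50
   bp), bands are scored by the query bases their seeds cover, and bands
   scoring ≥ 40 bp are extended by gapped local alignment
   (match 2, mismatch −3, gap open 5, extend 2 — BLASTN-like). Both
   strands are searched. The aligner is implemented in the package; no
   external alignment binary is invoked.
2. **Candidate filter** (`candidate_filter()`): a locus qualifies when
   strictly more than 500 bp align with length-weighted identity strictly
   above 0.80. The length-weighted mean across blocks implements a single
   identity figure for multi-block hits. Both inequalities are strict and
   tested at the boundary.
3. **Junction classification** (`detect_intron_loss()`): each exon is
   locally aligned inside the candidate locus; for each junction between
   consecutive aligned exons the target-side gap is compared with the
   parent intron length. Collapsed: gap ≤ 30 bp while the intron is
   longer than that. Retained: gap within 20% of the intron length.
   Ambiguous otherwise; uncalled when a flanking exon does not align
   (less than half its length aligned, or identity < 0.7) or the exons
   are out of order.
4. **Verdict**: `retrocopy` when at least half the junctions are
   collapsed; `duplication_with_introns` when at least half are retained;
   `no_intron_evidence` for single-exon parents or all-uncalled junctions
   (intron evidence simply cannot exist there, and the package refuses to
   force such cases into either class); `ambiguous` otherwise;
   `no_candidate` below the thresholds.

The 30-bp junction-gap ceiling, the ≥50%-of-junctions rule and the exon
acceptance thresholds are package defaults (config-exposed): an expert
reading a dot plot applies an equivalent judgement visually, and these
values reproduce that judgement on planted fixtures across the 0.85–0.95
identity range while never mislabelling an intron-retaining duplicate.
`plant_retrocopy()` applies substitutions at rate $1 - \mathrm{identity}$;
note the realized identity of a single ~1-kb copy scatters around the
target rate with sd ≈ 0.01, so identity-recovery checks compare against
the realized value recorded in the truth.

# Repeat density and enrichment

`parse_repeatmasker_out()` reads the standard 15-column RepeatMasker
`.out` dialect (1-based inclusive coordinates converted to 0-based
half-open, strand `C` mapped to `-`). Coverage (`class_coverage()`) is the
**union** of member intervals divided by the region length — nested and
overlapping elements are counted once, so fractions cannot exceed 100%,
matching how per-class percentages of a region are conventionally
reported. `windowed_density()` tiles the region (default 50-kb windows;
the step defaults to half the window, exposed because only the window
size is conventionally fixed). `random_region_comparison()` draws `n`
random regions of the focal length uniformly, rejecting overlaps with the
focal region and with each other so the null sample is independent, and
reports the focal fraction against the random mean ± sample sd.
`simulate_repeat_annotation()` builds annotations with per-class target
coverages hit to within 1% absolute (the last element of a class is
trimmed to land the total), log-normal element lengths (meanlog log(800),
sdlog 0.7, 50 bp minimum — the scale of common LINE/SINE fragments) and
uniform placement of the element sequence over the free space.

# Genotype–phenotype association

Markers are coded as counts of the *mutated* allele — the allele enriched
in the selected lineage. Which allele is counted must be declared by the
producer of the table; it is never inferred from frequencies, because in a
crossbred cohort the mutated allele need not be minor. Three genetic
models re-encode the count: additive (0/1/2), dominant (carrier 0/1),
recessive (mutant homozygote 0/1). `fit_association()` is ordinary least
squares of the phenotype on the encoded genotype with optional age and sex
covariates (sex coded 0 = male, 1 = female, stated in the output);
complete-case handling with `n_used` reported so drops are visible; the
genotype coefficient's two-sided t-test supplies the p-value, unadjusted
for multiple testing (the report presents per-model tests side by side).
A constant genotype column yields an explicit `estimable = FALSE` row
rather than an error; a collinear covariate set is an error naming the
columns.

`simulate_tailcross()` emulates the validation cohort the association
module targets: 116 crossbred animals (28 females, 88 males), two swept-
region markers in complete LD (identical genotype columns by
construction), one near-sweep gene marker and one unlinked-region marker,
with additive effects of −3.3 cm on tail length and +3.5 cm on tail width
per mutated allele. The residual standard deviations (2.7 cm length,
2.0 cm width) were set so that the implied standard errors of the fitted
effects (~0.33 and ~0.24 cm) match the order of magnitude of the
association strengths such a cohort reports; age (2–7 years) and sex
carry moderate covariate effects so that adjustment is exercised.

# What the tests do and do not establish

The test suite verifies: exact arithmetic of all window statistics against
brute-force per-site oracles (1e-10), the branch-length additivity,
symmetry, bound and standardization identities on 1000 random fixtures,
recovery of planted sweeps (top-0.5% hit rate and lowest-decile $ZH_P$
over 20 replicates), perfect sensitivity with zero false intron-loss calls
on 20 planted retro-copy fixtures, enrichment detection at a 2× contrast,
OLS equivalence with the normal equations, and confidence-interval
coverage over 50 simulated cohorts. Because the generators omit LD,
demography, alignment repeats and genotyping error, these results bound
correctness of the implementation, not the field performance of the
statistics on real resequencing data — thresholds such as the top-0.5%
window rule remain empirical conventions, not calibrated significance
levels.
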