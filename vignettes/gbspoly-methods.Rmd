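---
title: "Methods and design of gbspoly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of gbspoly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbspoly)
```

## The problem

Sugarcane and its wild relatives are extreme polyploids (6 to 12 or more
chromosome sets, genomes up to 10 Gbp). Genotyping-by-sequencing (GBS)
makes genome-wide variant discovery tractable in such species by cutting
genomic DNA with a rare-cutting restriction enzyme (PstI, recognition site
CTGCAG), barcoding and pooling samples, and sequencing the fragment ends.
But polyploidy changes the analytical calculus at every step: a
heterozygous allele may be present at only one of twelve chromosome
copies, so the read depth needed to even *see* it is several times what a
diploid study would budget; allele dosage (how many copies of each allele
a genotype carries) becomes a first-class quantity; and copy-number and
presence/absence variation between accessions must be read out of
coverage, not genotypes.

gbspoly packages the computational steps of such a study as reusable,
tested functions: read demultiplexing, in-silico digestion, the binomial
depth model, multi-caller SNP analytics, and PAV/CNV detection — together
with a synthetic-data generator that produces every input with known
ground truth, so each step can be validated quantitatively.

## The binomial depth model

At a bi-allelic locus genotyped to total depth $n$, the number of reads
carrying an allele at within-genotype frequency $x$ is
$\mathrm{Binomial}(n, x)$; the probability of observing it at least $k$
times is

$$P = 1 - \sum_{i=0}^{k-1} \binom{n}{i} x^i (1-x)^{n-i}.$$

For a single-dose (SD) allele in a $p$-ploid genotype, $x = 1/p$. SD
markers segregate 1:1 and are the workhorse of polyploid linkage analysis,
so the planning question is: what minimum depth guarantees $k$ reads of an
SD minor allele with 95% probability? `min_depth()` answers by incremental
search from $n = k$ (the tail probability is monotone in $n$, so the first
$n$ that passes is the exact minimum). At $k = 2$ and 95% confidence the
answer is 27 for hexaploids, 37 for octoploids, 46 for decaploids and 56
for dodecaploids. Each emitted value is verified in the tests against an
independent term-by-term summation of the formula above, and the
implementation uses `stats::pbinom` rather than explicit summation for
numerical stability at large $n$.

Assumptions: no sequencing error in the clean reads, and read sampling
that is independent across chromosome copies. Both idealize real data —
the model is a lower bound on the depth a real study needs, not an upper
one. "Probability higher than 95%" is implemented as the weak inequality
$P \ge 0.95$, which direct computation shows is the convention consistent
with the depth values above.

`subsample_saturation()` addresses the complementary empirical question —
whether the achieved depth saturates SNP discovery. Fractions of the whole
read set are drawn without replacement (default 20–90% in steps of 10, ten
replicates each, seeded), a discovery rule is applied to each subset
(default: a locus is discovered at $\ge 2$ reads), and recovery relative
to the whole set is summarized. A least-squares line through
(fraction, mean recovery) gives `required_fraction_for(target)`. The fit
is unweighted, matching the usual practice of reading a requirement off a
simple linear model; recovery at fraction 1 is exactly 1 by construction.

## In-silico digestion

`digest()` models complete digestion: each occurrence of the recognition
site at 0-based index $i$ cuts at $i + \mathrm{cut\_offset}$ (5 for PstI,
which cuts CTGCA^G), and a sequence with $c$ cut sites yields exactly
$c + 1$ fragments that tile it. Size selection (default 51–500 bp,
inclusive bounds) models the library-construction window; the selected
fragment set is also the target-region universe for PAV/CNV analysis.
Conventions worth stating:

* Coordinates are 0-based half-open internally; GFF3 input is converted
  on import (`read_gene_models()`), and variant positions are 1-based as
  in VCF. A 1-based position $p$ is genic iff a gene interval $[s, e)$
  satisfies $s < p \le e$.
* N runs never match the recognition site but do not split fragments;
  only cuts split.
* Overlapping occurrences of a recognition site are all reported. For the
  palindromic CTGCAG this cannot occur, but the scan is defined for
  general sites.
* A single cut coordinate per site is modeled (top strand). Because the
  PstI cut is off-center, digesting a reverse-complemented genome
  preserves the fragment count and all interior (cut-to-cut) fragment
  lengths but shifts the two terminal fragments of each sequence by the
  offset asymmetry (4 bp for PstI); the tests assert exactly this
  invariant. Modeling sticky-end geometry was deliberately left out — it
  affects no downstream count.
* "Genic" means any overlap ($\ge 1$ bp) with a feature of type `gene`;
  no CDS/UTR refinement is attempted.

## Read preprocessing

`filter_reads()` keeps a read iff it begins with exactly one barcode
immediately followed by the expected cut-site remnant; the barcode is
stripped and the remnant retained (the convention of reference GBS
pipelines, configurable). The remnant defaults to the full recognition
sequence CTGCAG; biochemically a PstI ligation remnant is often TGCAG, so
it is a parameter rather than a constant. Barcode matching is exact — no
mismatch tolerance — which keeps demultiplexing deterministic and
testable; `validate_barcodes()` enforces the prefix-free property that
makes "exactly one match" well-defined. Kept reads are length-normalized
to 64 bp by `trim_pad()`: longer reads truncated, shorter ones padded
with A (pad positions get quality `!`, keeping FASTQ records valid).
Reads shorter than barcode+remnant are rejected, not padded first:
padding applies only after demultiplexing.

## Variant analytics

`load_caller_vcf()` normalizes each caller's VCF into one row per
(site, sample) with the genotype parsed into an allele→copy-count map
(dosage). Sites are matched across callers on (sequence, position, ref,
alt-set) — position alone would conflate different substitutions.
`concordance()` then tallies every Venn cell; the cells partition the
union, whose size is the non-redundant SNP count.

Dosage classes (`classify_dosage()`): one allele at full ploidy is
homozygous; two alleles with the rarer at one copy is single-dose; two
alleles both $\ge 2$ copies is multi-dose; $\ge 3$ alleles is
multi-allelic (possible only in polyploids). Minor-allele ties (e.g. 3:3)
break to the lexicographically smaller allele — this is reporting-only
and can never affect an SD call, which requires a 1-copy allele.
Multi-allelic status is a per-sample property of the genotype, not a
per-site property of the alt list, because the per-accession statistics
it feeds are genotype statistics.

Per-sample summaries use the sample's non-missing loci as the common
denominator: heterozygosity% (loci with $\ge 2$ distinct alleles), SD%,
multi-allelic%. Ts/Tv counts transitions (A↔G, C↔T) against the four
transversion pairs. In per-sample mode the site set is the loci where the
sample carries exactly one distinct non-reference allele, and the pair is
(ref, carried allele): per-accession ratios must differ between
accessions, which requires a sample-conditional site set, and using the
carried allele rather than the site's (possibly multi-accession) alt set
makes the statistic independent of which other accessions happen to
segregate at the locus. `depth_filter()` defaults to the strict reading
of a per-sample minimum depth — every non-missing sample must reach the
threshold — with `scope = "any"` available, since the looser reading is
also defensible.

## PAV and CNV detection

Region read counts are normalized as
$\mathrm{depth} = 10^9 \cdot \mathrm{count} / (\mathrm{total\ mapped\ reads}
\times \mathrm{region\ length})$, which removes library-size and
region-length effects and is invariant under jointly scaling an
accession's counts and total.

A region is a PAV iff some accession has zero reads while another has at
least `min_reads` (default 5) — absence is judged on raw counts, because
a zero is a zero regardless of library size.

CNVs are outliers of the pairwise log2 ratio of normalized depths:
for each unordered accession pair, regions with ratios outside
mean ± 3 sd are flagged, and a region flagged in any pair counts once as
a CNV. Design choices the rule leaves open, and how they were resolved:

* Statistics are computed **per pair** (each pair has its own library and
  noise structure), not pooled across pairs; a pooled mode could be added
  but the per-pair form is the conservative default.
* The literal mean ± 3 sd rule is used (the 99.73% Gaussian range), not a
  99% quantile; sd is the sample standard deviation ($n - 1$).
* Zero counts are the PAV signal, not a copy number: by default regions
  with a zero in either accession are excluded from that pair's CNV
  statistics (`exclude_pav = TRUE`). Alternatively a pseudocount scaled
  to each accession's normalization unit can be added.
* Pairs with zero ratio-sd (e.g. constant matrices) flag nothing.

Under a null in which normalized depths are equal in expectation and
noise is multiplicative log-normal, the per-pair flag rate should be
$2\Phi(-3) \approx 0.27\%$ ($4.55\%$ at 2 sd). The test suite verifies
this calibration against simulation.

## The synthetic-data generator

Every pipeline input can be generated with known truth, under a fixed
seed (generators save and restore the caller's RNG state):

* **Genomes** with recognition sites planted at fixed or geometric
  spacing; a rejection pass mutates accidental occurrences so the planted
  positions are the complete truth.
* **Genotypes**: per locus and accession the class is drawn from
  {homozygous-ref, single-dose, multi-dose, multi-allelic} with
  configured probabilities; alternate alleles are transitions with
  probability `ts_fraction`. Defaults emulate a diverse polyploid
  germplasm panel: 14 accessions at ploidy 6/8/12 (four, six and four
  respectively), heterozygosity 55%, SD fraction 50%, multi-allelic 3%,
  and `ts_fraction = 1.66/2.66` (a Ts/Tv ratio of 1.66, typical of grass
  genomes). These sit inside the ranges such panels report (SD% roughly
  38–62% per accession, Ts/Tv 1.5–1.7).
* **Allele reads**: total depth Poisson around `mean_depth` (default 56,
  the depth a dodecaploid needs for two SD minor-allele reads), allele
  reads multinomial with probabilities dosage/ploidy — exactly the model
  the depth calculations assume. A fixed-depth mode exists for exact
  binomial checks.
* **Caller VCFs**: each caller reports each truth locus with its
  sensitivity probability; false positives are placed at positions
  disjoint from the truth set so the all-caller intersection stays
  interpretable.
* **Region counts**: expected count proportional to region length times
  accession total (so normalized depths are equal in expectation),
  multiplied by log-normal noise (`noise_sd_log2`, default 0.2 in log2
  units), then Poisson-sampled. PAVs zero out the expectation in a random
  accession subset; CNVs multiply it by `cnv_fold` in one accession.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sequencing error and base-quality structure,
alignment ambiguity in repetitive or homoeologous regions (the dominant
loss channel in real polyploid GBS, where most reads fail to map
uniquely), locus dropout from restriction-site polymorphism, caller
errors that are correlated across callers, and over-dispersion of
coverage beyond Poisson-log-normal. The tests validate the computations,
not the biology.

## Problem sizes and numerical checks

The validation suite runs at desk scale, chosen so each stochastic check
has clear resolution: 10,000 loci for binomial-model recovery (3
binomial-sd tolerance), 10,000 regions × 4 accessions for the CNV null
calibration, and 2,000 regions with mean expected count 1,000 for
PAV/CNV recovery. The high baseline in the recovery run keeps the
Poisson component of the log2-ratio noise small relative to the
log-normal component (pair sd ≈ 0.29), so an implanted 4-fold change
(|log2| = 2) clears the 3-sd fence in every informative pair by a wide
margin and 100% recovery is the correct expectation, not luck. Large
data-bound quantities from real germplasm studies (total SNP counts, PAV
and CNV totals, per-accession Ts/Tv values) depend on the organisms and
read sets and are not reproduced here; the package validates the methods
that produce them.

One discrepancy is deliberately surfaced rather than smoothed over: for
decaploids the binomial model gives a minimum depth of 46 (for two
minor-allele reads at 95%), while 48 has circulated in the applied
literature; `depth_table()` reports the computed value, and the test
suite pins it to the independent summation oracle rather than to any
printed number.

## Known limitations

* Complete digestion only: no partial digests, methylation sensitivity,
  or two-enzyme protocols.
* The depth model ignores sequencing error and mapping bias; it is a
  planning bound.
* CNV calling is a pairwise outlier rule, not segmentation; it assigns no
  absolute copy numbers and resolves no breakpoints.
* VCF ingestion requires GT with ploidy-many slots and per-sample DP;
  callers that emit diploidized genotypes for polyploids are flagged row
  by row rather than reinterpreted.
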