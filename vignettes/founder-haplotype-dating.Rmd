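---
title: "Founder-haplotype mapping and dating: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder-haplotype mapping and dating: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderhap)
```

## The problem

Several unrelated patients carry the same rare pathogenic variant in
homozygous state. If they descend from one founder, each is autozygous
around the variant, and all of them still carry a remnant of the founder's
chromosome — a shared haplotype whose genetic length shrinks, generation by
generation, as recombination whittles it down. Mapping that haplotype
supports a common origin, bounds the gene search, and its length dates the
founder. `founderhap` implements this analysis end to end, plus the
recessive-model trio filtering that nominates candidate genes in the same
studies, and a simulator that generates cohorts with known truth.

## Marker confidence

Every downstream step runs on high-confidence marker tracks: non-indel
SNVs (reference and all alternates single bases), read depth at least
`min_depth` (default 10×, boundary inclusive), genotype called. Half-calls
and genotypes containing a missing allele count as missing. Per-sample
`DP` is preferred; site-level `INFO/DP` is the fallback; absent depth is
recorded as 0 and therefore filtered. The filter is idempotent and
order-stable, and `filter_tally()` accounts for every removed call.

## ROH delimitation and the shared haplotype

From a homozygous-alternate index call, `extend_roh()` walks outward to
the first high-confidence heterozygote on each side. Three conventions
matter and are deliberate:

* the outer boundary sits one bp inside the flanking heterozygote, so the
  het itself is excluded and boundaries are evidence-anchored;
* homozygous-reference calls do **not** interrupt a run — runs of
  homozygosity are about homozygosity, not alt-allele status; only
  heterozygotes terminate extension, and filtered/missing sites are
  invisible to it;
* with no flanking het, the boundary clips at the first/last marker of the
  track (not the chromosome end — there is no evidence beyond the
  markers), and the `clipped_*` flag says so.

`trim_to_shared()` then pulls each outer boundary back to the outermost
*shared homozygote*: a marker where every carrier is homozygous for the
identical alternate allele, the signature of the founder haplotype. A
site missing or filtered in any carrier never qualifies. If no shared
homozygote besides the index exists, the trimmed interval degenerates to
the index position and is flagged rather than silently reported.
`intersect_regions()` finally takes max-of-starts/min-of-ends across
carriers; since every trimmed region contains the index the intersection
is non-empty by construction. The trim already uses all carriers, which
makes the final intersection partially redundant; both steps are kept
because they are cheap, independently testable, and their intermediate
outputs (per-carrier outer and trimmed ROHs) are reportable evidence.

Intervals are 1-based inclusive throughout (VCF convention); BED
import/export shifts to 0-based half-open via `rtracklayer`. Interval
length is `end - start`, the difference of the printed coordinate pair:
that is how haplotype extents are conventionally quoted (an 800,000 bp
difference reads "800 kb"), and the 1 bp discrepancy against an inclusive
base count is immaterial at these scales. Rendering rounds half-up
(13,995,505 bp is "14.0 Mb").

## From physical to genetic length

`genetic_map()` either interpolates a knotted cumulative map (tab-separated
`position cM`, HapMap-style columns accepted) or applies a uniform rate,
default 1 cM/Mb — the genome-wide average commonly assumed when no map is
at hand. Interpolation is linear between knots and refuses to extrapolate
beyond them: silent extrapolation would corrupt the dating, so an interval
outside the map range is an error.

## Dating the founder

Under Haldane's no-interference crossover model, the ancestral segment
retained around a focal locus after $g$ meioses extends on each side by an
Exponential($g$ per Morgan) length. For $k$ homozygous carriers descending
independently from one founder, the shared haplotype is the intersection
over all $2k$ lineages: each side is the minimum of $2k$ exponentials,
i.e. Exponential($2kg$), and the expected total length is

$$E[L] = \frac{1}{k\,g} \text{ Morgans.}$$

Two inversions are exposed, always labelled, never silently substituted:

* **length inversion** (default): $g = 100 / L_{cM}$ — the classic
  single-pair approximation ($k = 1$ above). For an 0.8 cM haplotype it
  gives 125 generations.
* **model inversion**: $g = 100 / (k\,L_{cM})$, the method-of-moments
  inversion of the $k$-carrier expectation; it coincides with the length
  inversion at $k = 1$ and is smaller by a factor $k$ otherwise.

### Bias, honestly

Both inversions are ratio estimators of a single exponential-family draw,
and that has consequences worth stating plainly. The observed shared
length is the sum of two independent side-minima, so $L \sim
\mathrm{Gamma}(2,\ 2kg)$ and the model inversion satisfies $\hat g = 2g/Y$
with $Y \sim \mathrm{Gamma}(2,1)$. Hence $E[\hat g] = 2g$ (the mean of
$1/Y$ is 1) and $\mathrm{median}(\hat g) = 2g/1.678 \approx 1.19\,g$: the
estimate from a single shared segment is typically some 20% high in the
median and two-fold high in expectation, at *any* marker density. The
single-pair inversion applied to a $k$-carrier haplotype is larger by a
further factor $k$. The package's validation suite demonstrates both
facts on simulated cohorts; treat any single-segment date — including the
package's own output — as an order-of-magnitude statement, not a point
estimate with 15%-level accuracy. Trimming to shared-homozygote anchors
shortens the measured interval by roughly the anchor spacing per side,
adding a few percent more.

### Confidence intervals

`bootstrap_age_ci()` re-simulates shared lengths at the point estimate
under the erosion model the chosen estimator inverts ($k$ lineage-pairs
for the model inversion, one for the length inversion), re-applies the
estimator, and inverts the log-scale pivot from the 2.5/97.5 bootstrap
percentiles: $[\hat g^2/q_{97.5},\ \hat g^2/q_{2.5}]$. For this pure scale
family the raw percentile interval under-covers badly (about 84% at
nominal 95%, analytically), while the pivotal form attains the nominal
level; the suite checks coverage by simulation. Intervals are
deterministic given the seed, and are wide — correctly reflecting the
information content of one segment.

## Recessive-model trio filtering

`run_filter_pipeline()` reproduces the candidate-nomination stage:

* homozygous candidates: proband homozygous-alternate, both parents
  heterozygous (a `lenient_parents` flag relaxes to "not hom-alt");
* compound-heterozygous pairs: two distinct proband hets in one gene, one
  het in the mother with the father homozygous-reference, the other the
  reverse — so no pair can share the transmitting parent;
* panel exclusion: homozygote count > 20 in ExAC-style or > 10 in
  1000-Genomes-style panels removes the variant (boundary exclusive: 20
  and 10 survive); a pair dies with either member, and a surviving member
  orphaned by its partner's removal is logged as such rather than kept.

Variants whose segregation cannot be resolved because a parental genotype
is missing are parked in an `unresolved` bucket, never silently promoted.
Every removal carries a reason, and the buckets partition the input — a
property the tests enforce on random tables. `cds_to_codon()` and
`check_protein_consistency()` provide the codon arithmetic
($\lceil c/3 \rceil$) used to sanity-check HGVS c./p. annotations (c.41 is
codon 14; c.481 is codon 161). Only autosomal inheritance is modelled;
hemizygous/X-linked handling is out of scope.

## The simulator: what it emulates, what it does not

`simulate_cohort()` generates the observed data structure of a founder
cohort: markers from a Poisson process (default 10/Mb, exome-like order of
magnitude) plus a guaranteed marker at the index position; background
alternate-allele frequencies Beta(2,5) truncated to [0.05, 0.5] via
inverse-CDF (no atoms at the bounds), so heterozygotes are common enough
to delimit ROHs sharply; per-haplotype ancestral segments with
Exponential($g$) side-extents, inside which the haplotype carries the
founder allele and outside which alleles are Hardy–Weinberg draws;
genotype errors flipping to each alternative genotype with equal
probability; Poisson read depth independent of genotype. Defaults mirror
the study conditions the package is designed around: $g = 125$, $k = 3$,
index at chr4:122,722,620, uniform 1 cM/Mb. Everything is reproducible
from the config seed, including byte-identical VCF output.

Deliberate non-realism, so that passing tests are read correctly: no
linkage disequilibrium or demography in the background genotypes (sites
are independent), no crossover interference, lineages independent apart
from the shared founder (no inbreeding loops), uniform error model, depth
independent of genotype, and a single chromosome. Tests passing on this
generator validate the algorithmic pipeline and the erosion model's
internal consistency — not robustness to LD structure, population
stratification, or caller-specific artefacts in real exomes.

## Validation problem sizes

The suite exercises: brute-force equivalence of ROH extension on 1,000+
random tracks and of the panel filter on hundreds of random tables;
agreement of the simulator's mean shared length with $1/(kg)$ Morgans
within three standard errors over a $g \in \{25, 50, 125\} \times k \in
\{1,2,3\}$ grid at 5,000 replicates per cell; parameter recovery over 200
simulated cohorts at $g = 50$, $k = 3$ on a 20 Mb chromosome at 150
markers/Mb with zero genotyping error (anchor spacing ≈ 25 kb, small
against the ≈ 560 kb median haplotype); bootstrap coverage over 200
replicates; and byte-level determinism of reports and simulated VCFs.
These sizes were chosen as the smallest at which the Monte-Carlo error is
comfortably below each property's tolerance. Note the recovery experiment
*documents* the median bias derived above rather than contradicting it:
the median model-inversion estimate sits near $1.2$–$1.3 \times g$, and
the single-pair inversion near $k$ times that.

## Known limitations

* Dating assumes the uniform-rate (or supplied) map is right at the locus;
  local recombination-rate variation propagates one-to-one into $\hat g$.
* The estimators are single-observation ratio estimators with the bias
  profile derived above; they cannot be made 15%-accurate in the median by
  denser genotyping.
* "Shared homozygote" requires the identical alternate allele in all
  carriers; recurrent mutation or genotyping errors at anchors shorten the
  reported haplotype.
* Genome-wide ROH scanning, phasing-based IBD detection, and
  likelihood-based allele-age estimation are out of scope.
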