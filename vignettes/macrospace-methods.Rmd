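---
title: "Methods: nutrient-space phenotyping and phenotype-based introgression mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nutrient-space phenotyping and phenotype-based introgression mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macrospace)
```

# The scientific setting

Closely related *Drosophila* species make very different diet choices:
the generalist *D. simulans* develops on decaying fruit that can be rich
in sugar, while the specialist *D. sechellia* is restricted to the
low-sugar fruit of *Morinda citrifolia*. The region of the yeast x sugar
composition plane over which larvae of a genotype develop successfully -
its *macronutrient space* - is a heritable phenotype. macrospace
implements the quantitative machinery for studying it: statistics for
diet-grid pupariation assays, a forward simulator of phenotype-based
introgression of sugar tolerance from a donor into a recipient species,
mapping of introgressed genomic regions from pooled sequencing,
coding-sequence divergence analytics, and gene-set overlap statistics.
A synthetic-data layer generates every input with the statistical
structure the analyses assume, so the whole pipeline runs and is tested
without any external sequencing data.

# Nutrient-space phenotype statistics

## The pupariation index

A vial seeded with $n$ first-instar larvae on one diet is scored for the
cumulative number of pupariated larvae $p_t$ every 24 h from 24 h to
408 h after egg laying. The pupariation index is the maximum rate of
pupariation,

$$\mathrm{Pupind} = \max\left\{\frac{p_t}{t} : t = 24, 48, \ldots, 408\right\},$$

in larvae per hour. It rises with both faster development and higher
survival, which is what makes it a useful single summary over a diet
grid. When several observation times attain the maximum,
`compute_pupind()` reports the earliest; the index is invariant to
appending observations after the counts have saturated.

## Survival and development time

Survival is the final cumulative count over $n$. "Development time" has
no canonical definition for interval-censored vial counts; the package's
default is the earliest observation time at which the cumulative count
reaches half of its final value - the median time-to-pupariation of the
survivors under 24-h censoring. Two alternatives are exposed
(`devtime = "midpoint"`, the mean of event-interval midpoints, and
`devtime = "first"`) because the choice is a genuine free parameter of
this kind of assay; all downstream code accepts any of them. When
nothing pupariates, development time is undefined and reported `NA`.

## Diet calories

The energy density of a diet follows from its composition at
3.25 kcal/g of baker's yeast and 4.06 kcal/g of sucrose, reported per
100 g and rounded half away from zero to one decimal. Two grid cells
(5% yeast with 15% or 20% sucrose) land exactly on a decimal .X5
boundary, where naive `floor(10x + 0.5)` misrounds under binary floating
point; `diet_calories()` therefore evaluates the integer-scaled form
$(650\,y + 812\,s)/20$ before rounding, which reproduces every cell of
the standard 5 x 5 grid:

```{r calories}
calorie_surface()$values
```

## Correlations and effect sizes

`correlate_metric()` computes Pearson correlations of vial-level metric
values against a diet axis, with the two-sided p-value from the t
transform. Whether such correlations should use vial replicates or
diet-cell means is not fixed by convention; vial-level is the default
(it uses the replication the assay actually has) and `by_cell = TRUE`
provides the alternative.

Effect strength in the factorial diet ANOVA is summarised by omega
squared,

$$\omega^2 = \frac{SS_{\mathrm{effect}} - df_{\mathrm{effect}}\,MS_{\mathrm{error}}}{SS_{\mathrm{total}} + MS_{\mathrm{error}}},$$

computed per term from the sequential (Type I) decomposition, which is
orthogonal on the balanced grids this assay design produces; unbalanced
input triggers a warning rather than a silent reinterpretation. The raw
estimator is returned alongside a `[0, 1]`-clamped version: under a null
effect the raw estimator is negative about half the time, and only the
raw version is mean-zero (the clamped one is positively biased by
construction), so distributional checks use `omega_sq_raw` while
reported effect sizes use `omega_sq`.

## Difference surfaces

`metric_surface()` averages a vial metric into the diet grid and
`difference_surface()` subtracts two genotypes cell-wise (optionally as
an absolute difference), the standard way to chart where in nutrient
space one genotype holds an advantage. Missing cells (e.g. diets where a
genotype never survives) propagate as `NA`.

# The grid-assay generator

`simulate_grid_assay()` draws, per larva, a Bernoulli survival with a
logistic probability in the two diet axes and, for survivors, a
log-normal pupariation time whose location shifts linearly with the
axes. Choices worth stating:

* **Log-normal development time.** Pupariation-time distributions are
  positive and right-skewed, with the delay on stressful diets
  stretching the upper tail; a log-scale location/dispersion model
  captures that with two parameters.
* **Survival and timing are independent per larva.** The two traits are
  correlated across diets through their shared diet dependence, but no
  within-vial joint model is imposed - nothing in the assay format
  identifies one.
* **No vial-level random effect by default.** The variance structure of
  vial effects is not identifiable from the published assay summaries;
  replicate vials are iid by default. (The model object is the natural
  place to add an effect if a user has data to fit one.)
* Two reference parameterisations, `model_sugar_tolerant()` and
  `model_sugar_intolerant()`, are invented fixtures that emulate the
  qualitative reaction norms of a generalist (diet response driven by
  yeast, indifferent to sucrose) and a sugar-intolerant specialist
  (development slowed and survival collapsing with dietary sucrose,
  near-complete lethality at 20%/20%). They are calibrated only to
  reproduce sign patterns - positive development-time and negative
  survival correlations with sucrose for the intolerant genotype,
  near-zero sucrose correlations for the tolerant one - not any
  published effect magnitudes.

# The introgression forward simulator

The crossing design being simulated: donor-species females are crossed
to recipient males; the hybrid females are then backcrossed to recipient
males for $g$ generations (10 in the original design) with each
generation reared on a selective high-sugar diet, and the line is closed
with three generations of sib-mating. Because every cross takes females
from the hybrid line and males from the recipient species, the
mitochondria are donor-origin in every individual, in every generation -
a built-in control that phenotypic differences between selected and
unselected lines are nuclear.

The genome model is a set of ancestry tracts: each haplotype partitions
its chromosome into half-open donor/recipient segments
(0-based internally; TSV/VCF output is 1-based, BED output 0-based
half-open). Meiosis in females draws a Poisson number of crossovers per
chromosome from its genetic length (no interference), places breakpoints
uniformly on physical length, and splices the gamete from the two
parental haplotypes. Males never recombine - Drosophila males are
achiasmatic - and the scheme only ever crosses through females until
sib-mating, so male hybrid sterility never arises in-model. Default
genetic lengths (1.1 M per major autosome, 0.7 M for the X) are
round figures on the scale of the *D. melanogaster* linkage map;
they are parameters of `chromosome_map()`, not constants.

Selection is modelled at explicit tolerance loci. The default model
(`all_required`) requires at least one donor allele at every configured
locus - a dominant tolerance allele, matching the observation that
hybrid heterozygotes are rescued - and an `independent` model lets
non-carriers escape with per-locus probabilities, for softer selection.
The census per generation defaults to 200 offspring of random sex
(the original crosses kept at least 100 backcross females per
generation); inability to fill the census within the attempt budget is
reported as extinction with the generation index, since a recipient
line genuinely cannot survive the selective diet.

Without selection the expected donor fraction halves each backcross
generation: $2^{-(g+1)}$ for autosomes after $g$ generations. The X has
a sex-structured recursion (`donor_fraction_recursion()`): a female's
pair is a recombinant maternal gamete plus a recipient paternal X, so
the female X halves like an autosome, while a male's single X is the
maternal gamete unhalved - a sex-balanced population therefore sits at
$1.5\times$ the female value. With selection, every survivor carries a
donor tract containing the locus, and the mean retained tract shortens
as generations accumulate crossovers near it (linked drag); both are
verified by the test suite.

The pooled-sequencing readout (`pool_counts()`) samples 30 females (the
pool size used for the real libraries), computes the true donor allele
frequency of the pool at each diagnostic SNP, and draws depth Poisson
around the target coverage with donor reads Binomial at the true
frequency. The noise-free pool frequencies are carried alongside the
reads, which is what lets the mapping tests define "truth" for boundary
accuracy without a second simulation.

# Introgression-region mapping

Mapping proceeds from species-diagnostic SNPs: sites fixed for
different alleles in the two parental species, called by
`call_diagnostic_snps()` from parental genotype tables with
within-species-polymorphic sites excluded. The windowed
donor-allele-frequency track pools reads as a ratio of sums (robust to
uneven depth), and regions are segmented as threshold runs. The
published analysis used an established pooled-introgression mapping
approach whose internal parameters are not restated; this module
implements the underlying idea - donor-specific SNP frequency along
chromosomes - with every parameter explicit and configurable:

| parameter | default | rationale |
|---|---|---|
| window / step | 100 kb / 100 kb | non-overlapping windows at a scale holding ~100 diagnostic SNPs at 1/kb density |
| min SNPs per window | 5 | below this a pooled frequency is too noisy to classify |
| frequency threshold | 0.25 | a heterozygous introgression segregating in a pool sits near 0.5; 0.25 splits it from 0 |
| max gap | 1 window | bridges single dropout windows without merging distinct regions |
| min windows | 3 | discards isolated noise windows |

Threshold runs (rather than an HMM) suffice at these effect sizes: the
signal steps between ~0 and >=0.5. Segmentation is idempotent on its own
output, and with no introgression in the pool the expected region count
is zero. Gene annotation counts any overlap of at least 1 bp between a
region and a gene span (GFF3 or BED input), under half-open region
coordinates. Cross-species coordinate lift-over is not modelled:
simulated data live in a single coordinate system, and the published
region coordinates - which depend on the real sequencing data and a
reference annotation - are not reproduction targets for the simulator.

# Sequence divergence

`window_snp_density()` lays 100-base windows stepped by 25 bases on the
alignment (not on either ungapped sequence); columns with `N` or a gap
count neither as differences nor in the denominator, and partial
terminal windows are discarded. `background_correct()` estimates the
genomic background difference frequency by pooling aligned background
regions - the published procedure used three 20-kb regions from
different chromosome arms - as total differences over total bases, and
subtracts it from every window; corrected densities may legitimately be
negative.

Substitution classification uses Nei-Gojobori counting, the standard
method when none is otherwise specified: for each differing codon pair
all minimal mutational pathways are enumerated, pathways through stop
codons are excluded, and per-pathway (amino-acid-changing, silent) step
counts are averaged with equal weights. If every pathway crosses a stop
(possible only for some 2-3-difference pairs), the pair is counted by
the minimum-nonsynonymous pathway and flagged. Fractional
pathway-averaged totals are reported alongside integers rounded half
away from zero. Site totals follow the same scheme - each codon position
contributes the synonymous fraction of its possible non-stop changes -
so that $N + S$ is exactly three per compared codon, with sites averaged
over both sequences. $K_a$ and $K_s$ apply the Jukes-Cantor correction
$-\tfrac34\log(1 - \tfrac{4p}{3})$ to the per-site proportions
(an uncorrected mode is available); the ratio is flagged undefined when
$K_s = 0$ and the correction when a proportion reaches 3/4.

The bundled `candidate_gene_substitutions()` table carries the published
per-gene counts of amino-acid-changing vs silent differences for the
nine sugar-tolerance candidate genes. Its Ka/Ks column is reported, not
recomputed: the published ratios rest on per-gene site totals that were
never printed, so they are representation values only. Similarly, the
published heterogeneity chi-squared for these genes (17.03 on 5 df) is
not reproduced by any construction we can form from the printed counts -
the Pearson contingency statistic on the six strong screen hits is 20.5
on the matching 5 df, and on all nine genes 21.3 on 8 df -
so `substitution_contingency()` exposes the construction (any gene
subset) without asserting agreement with the published statistic.

# Overlap statistics

`overlap_test()` is the generic hypergeometric enrichment test on two
gene sets in a universe, evaluated in log space because real comparisons
of this kind reach p-values around $10^{-69}$, far below double
underflow on the natural scale. The published overlap statement fixes
only one side (174 of 587 downregulated genes, 30%); the universe and
second set size behind its p-value were not stated, so the package
reproduces the fraction and treats the printed p-value as out of reach.
`bh_adjust()` applies the standard Benjamini-Hochberg step-up.

# Synthetic genomes and coding pairs

`simulate_parental_genomes()` places fixed interspecies differences and
within-species polymorphisms (Poisson counts in density x length,
uniform positions, disjoint site classes) and tabulates allele counts
for 20 sampled chromosomes per species. Within-species polymorphism
defaults to one tenth of the fixed-difference density - enough to
exercise the diagnostic-SNP exclusion rule without dominating the site
set. `simulate_coding_pair()` plants exactly the requested numbers of
amino-acid-changing and silent substitutions, one single-nucleotide
change per substituted codon, so classification recovers the targets
exactly (the round-trip is a test oracle); multi-hit codons are
exercised separately by `simulate_neutral_pair()`, whose
accept-anything-but-stops process has expected $K_a/K_s = 1$ and
calibrates the estimator. All generators draw every random quantity from
one explicit integer seed through a scoped RNG; no global generator
state is touched.

# What the synthetic data do and do not show

The generators reproduce the statistical structure the analyses assume:
binomial survival and log-normal timing on a diet grid, Poisson site
counts, Mendelian transmission with Poisson recombination, Poisson-
binomial pooled reads, controlled substitution classes. They do not
reproduce crossover interference, segregation distortion, vial-level
environmental variance, microbiome effects on growth, read-level
artefacts (mapping bias, base errors), or cross-species alignment error.
Passing tests therefore certify the statistical machinery, not the
biological conclusions of any particular dataset; analyses of real data
enter through the same TSV/FASTA/GFF3/BED interfaces.

# Numerical choices and problem sizes

Ties in the pupariation index take the earliest time; rounding of
printed counts and calories is half-away-from-zero; calorie arithmetic
is integer-scaled (above); correlations refuse zero-variance input
rather than returning `NaN`; segmentation bounds are half-open.
Simulation-based checks in the test suite and the acceptance script use
fixed problem sizes chosen to make Monte-Carlo standard errors small
relative to the quantities checked: 2,000 sampled backcross individuals
per generation depth for the halving law (50 independent runs of 40,
with standard errors taken across runs, which are iid), 100-200
replicate end-to-end mapping runs at 25 Mb / 1 SNP per kb / 50x depth,
10,000 codons for Ka/Ks calibration, and a 20-kb foreground against
60 kb of background for the centring check of background correction.

# Known limitations

* Selection acts only through the configured loci; there is no
  polygenic fitness model, so the simulator cannot express partial
  tolerance phenotypes.
* Crossovers are interference-free; tract-length variances are
  correspondingly slightly inflated relative to real meiosis.
* The effective selection intensity per generation in the real crosses
  is unknowable from the published design (census sizes after selection
  were not recorded); it is a free parameter here, not an estimate.
* Ka/Ks uses equal-weight pathway averaging and Jukes-Cantor correction;
  maximum-likelihood codon models are out of scope.
* `detect_regions()` is a threshold segmenter; weak introgressions with
  pool frequencies near the threshold would need an HMM and are not the
  regime this pipeline targets.
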