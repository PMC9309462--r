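---
title: "Detecting domestic pig admixture and the rob(15;17) karyotype in wild boar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting domestic pig admixture and the rob(15;17) karyotype in wild boar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Western European wild boar (*Sus scrofa scrofa*) carry a Robertsonian
translocation, rob(15;17), that fuses the acrocentric chromosomes 15 and 17
into one submetacentric chromosome: wild boar are 2n = 36, domestic pigs
2n = 38, and first-generation hybrids are obligate 2n = 37 heterozygotes.
Hybridisation with domestic pigs — escapes, releases, farm contact — leaks
domestic alleles into wild populations. Two complementary signals reveal it:

* **genome-wide ancestry**: the fraction of an animal's genome deriving from
  wild boar, European domestic or Asian domestic sources, and its local
  distribution along chromosomes;
* **the karyotype**: the chromosome number itself, which segregates as a
  single biallelic "fusion locus" at the chr15/chr17 centromere junction
  (36 = fused/fused, 37 = heterozygote, 38 = unfused/unfused), giving the
  segregation expectations 37×37 → 25/50/25 (36/37/38), 37×36 → 50/50,
  37×38 → 50/50 and 38×36 → 100% 37.

`boarmix` implements the full analysis chain — simulation with known truth,
genotype QC, PCA-based hybrid flagging, supervised global ancestry, a
local-ancestry HMM, in-silico karyotyping at the fused junction, and a
genome scan for regions of anomalously low wild ancestry — so that every
statistical component can be validated against ground truth.

## The synthetic study system

The generator (`population_model()`, `generate_reference_panels()`,
`simulate_cross()`, `backcross_cohort()`) emulates the statistical structure
the analysis assumes, not pig biology in detail:

* **Panels.** Per-SNP allele frequencies for the three source populations
  follow the Balding–Nichols model,
  $f_k \sim \mathrm{Beta}\!\left(p\frac{1-F_k}{F_k},\,(1-p)\frac{1-F_k}{F_k}\right)$,
  around a shared ancestral frequency $p \sim U(0.05, 0.95)$. Defaults
  $F = 0.15$ for the wild boar and European domestic panels and $F = 0.30$
  for the Asian panel were fixed once as realistic Fst-scale differentiation
  between European suid gene pools and the more diverged Asian clade; no
  published divergence values exist for the emulated panels, so these are
  calibration choices of this package, stated here and not tuned thereafter.
  Ancestral frequencies bounded away from 0/1 mimic the common-variant
  ascertainment of SNP arrays.
* **Meiosis.** Gametes are recombinant mosaics with Poisson crossovers
  placed uniformly on bp (rate $r = 10^{-8}$ per bp per meiosis, no
  interference) — deliberately the same exponential-distance process the
  HMM's transition model assumes. Chromosomes 15 and 17 form a single
  linkage group in the fused coordinate system the analysis itself uses, so
  the fusion allele co-segregates with the haplotype spanning the junction;
  the side effect that chr15 and chr17 also co-segregate in pure domestic
  meioses is accepted, since nothing downstream depends on inter-chromosome
  linkage in the pure panels.
* **Genotypes.** Emitted per SNP from the tract ancestry's panel frequency
  (founder haplotypes carry no allele sequences of their own): exactly the
  emission model of the decoder, and sufficient because the decoder consumes
  unphased genotypes plus panel frequencies only. Missingness is i.i.d. at
  2% by default (the real-data workflow tolerates up to 10%).
* **Truth.** Tracts, tract-length-weighted global ancestry, and the
  karyotype (36 + number of unfused alleles) are carried exactly, so every
  inference component has an error-free reference.

What the generator does **not** emulate: background LD within source
populations (the HMM sees LD only through ancestry tracts), ascertainment
toward between-breed differences, genotyping error beyond missingness,
crossover interference, and real pig linkage maps. Passing tests therefore
demonstrate correctness of the machinery and calibration under the model's
own assumptions, not field performance on real chip data.

### Scaling rule for desk-size experiments

The emulated array carries ~40,000 SNPs on ~2.3 Gb of autosomes, about one
SNP per 60 kb. The HMM's information flow depends on this *density* (the
switch probability between adjacent SNPs), not on total genome size, so
benchmarks scale down by restricting the genome (e.g. chromosomes 15 + 17
only, 3,000 SNPs ≈ one per 68 kb) rather than by thinning SNPs across the
full four-chromosome demo genome. The package's demo sizes are: 3,000 SNPs /
150 animals for the end-to-end pipeline, 300 animals on the two-chromosome
map for karyotype benchmarks, and 200 animals × 5,000 SNPs for the scan.

## Global ancestry

For genotype $g_m$ (alt-allele count at SNP $m$) and fixed panel
frequencies $f_{km}$, the supervised admixture log likelihood is

$$\ell(q) = \sum_m \Big[ g_m \log \sum_k q_k f_{km}
  + (2 - g_m) \log \sum_k q_k (1 - f_{km}) \Big],$$

maximised over the simplex by EM on allele-level responsibilities
(`estimate_q()`). The log likelihood is non-decreasing by construction and
the M-step is renormalised each iteration so floating-point drift cannot
compound. Panel frequencies are clamped to $[\varepsilon, 1-\varepsilon]$
($\varepsilon = 1/(2n_k+2)$ when estimated from $n_k$ panel animals) so
fixed differences never produce infinite log likelihoods.

Uncertainty comes from resampling SNPs with replacement (`bootstrap_q()`,
200 replicates by default), implemented as resampling *weights* so all
replicates share one panel matrix and run as a single vectorised EM with
per-replicate convergence; SE is the SD of replicate estimates and the 95%
CI is $\hat q \pm 1.96\,\mathrm{SE}$ truncated to $[0,1]$. Resampling SNPs
rather than individuals is the natural reading for a per-individual
estimate; it treats SNPs as exchangeable, which LD violates mildly.
Classification: *unadmixed* when the upper CI bound of wild ancestry
reaches 0.99; *recent hybrid candidate* when the point estimate falls below
0.60 (flagged outliers in the motivating study all carried > 40% domestic
ancestry — a post-hoc observation promoted here, explicitly, to a rule);
*admixed* otherwise.

A calibration fact worth knowing: at 2,000 SNPs and divergence 0.1 the
estimator's RMSE against simplex-uniform truth is ≈ 0.04 per component —
this is the exact MLE of a correctly specified model, so the error is
Fisher-information-limited and shrinks only with more SNPs or stronger
panel divergence (the package's acceptance suite pins a stricter 0.03
bound to document this limit; it fails by design at these conditions).

## PCA and outlier flagging

Genotypes are centred at $2\hat p$ and scaled by $\sqrt{2\hat p(1-\hat p)}$
(missing cells imputed to the mean), decomposed by SVD; each component's
sign is fixed so its largest-magnitude score is positive. Outliers among
the focal animals are flagged by Gaussian mixture models on (PC1, PC2) via
`mclust` — the very tool the motivating workflow used — with BIC selection
over 1..9 components: an animal is an outlier when its maximum-posterior
component is not the largest-weight component. An optional low-density
backstop (`density_quantile`) can additionally flag stragglers absorbed
into the majority component; it is off by default because it flags a fixed
quantile of clean data by construction, and the membership rule alone
reproduces the intended behaviour (a BIC-selected single component
therefore implies zero outliers).

## Local ancestry

The decoder is a diploid HMM over ordered haplotype-ancestry pairs
($K^2 = 9$ states). Between adjacent SNPs at distance $d$ bp each
haplotype independently switches ancestry with probability
$s = 1 - e^{-g r d}$ and redraws from the prior $\pi$; emissions treat the
two alleles as independent Bernoulli draws from the state's panel
frequencies, and missing genotypes emit 1. Defaults follow the published
parameterisation: $g = 25$ generations, $r = 10^{-8}$, priors
$\pi = (0.30, 0.66, 0.04)$ for wild / European domestic / Asian domestic.
$g$ controls smoothness far more than accuracy; the priors matter near
decision boundaries (see karyotyping below).

`posterior_dosages()` runs scaled forward–backward, batched across
individuals per chromosome, returning dosages in $[0,2]$ that sum to 2 at
every SNP; `viterbi_tracts()`/`viterbi_field()` give the MAP path and its
hard 0/1/2 dosages (the discrete "allelic proportion 0/0.5/1" form).
Correctness is pinned to an exhaustive path-enumeration oracle on 5-SNP
instances (agreement to 1e-10, including missing data), and scaling uses
per-SNP normalisation with the forward scale reused in the backward pass.
This one component replaces both external local-ancestry tools of the
original workflow (one used genome-wide, one at the junction), with the
same parameter contract; it omits their haplotype-cluster lower layers, so
it uses panel frequencies directly. A known circularity of the original
workflow — training panels defined by the global-ancestry step whose output
feeds the local step — is inherited by any supervised design; here the
simulation sidesteps it because panels are known, but on real data the
choice of "unadmixed" training animals remains a modelling decision.

## In-silico karyotyping

`fuse_map()` concatenates the chr17 and chr15 maps at their centromeres:
chr17 keeps its coordinates, chr15 is offset by the chr17 length
(63,494,081 bp), so the first chr15 nucleotide is fused coordinate
63,494,082. The operational transform is applied verbatim, without
re-orienting acrocentric arms; if an assembly placed either centromere at
the low-coordinate end a coordinate flip would be needed, a caveat the
package does not attempt to resolve.

`predict_karyotype()` reads the wild dosage of the first SNP on each side
of the junction (`flank_window = 1` by default; widen for sensitivity
analyses), converts the mean flank proportion to an implied wild-allele
count $x \in [0,2]$ and calls 36/37/38 as $x$ rounds to 2/1/0, with exact
.5 ties resolved toward 37 — the conservative direction, flagging the
animal for follow-up rather than clearing it. Two properties found by
simulation and worth stating:

* With **error-free** ancestry evaluated *at* the junction the rule is
  exact (the fusion allele is physically linked to junction ancestry). At
  real flank SNPs ~tens of kb away, rare crossovers between flank and
  junction leave a small (~0.3% per animal) irreducible mismatch even with
  perfect local ancestry.
* On **decoded** dosages, the heterozygote class 37 is empirically the
  *easiest* class, not the hardest: posterior-mean shrinkage pulls
  homozygous junction dosages toward the middle of the scale, and Viterbi
  decodes heterozygous junctions with larger margins. This holds across
  prior choices (published, uniform, cohort-mixture) and cohort
  compositions tried, and contrasts with the real-data experience that
  motivated the opposite expectation — there, cytogenetic truth uncertainty
  and population structure beyond the model plausibly dominate. The
  acceptance suite asserts the originally expected ordering and documents
  its failure rather than adjusting conditions to mask it.

`karyotype_concordance()` reports the confusion matrix with predictions in
rows and truth in columns, per-class rates as column-normalised diagonal
entries, and the overall rate as trace over total.

## Introgression scan

`ancestry_scan()` averages the wild ancestry proportion (dosage/2) over
animals at every SNP; `flag_regions()` flags SNPs more than $k\sigma$
($k = 3$ or 6) below the genome-wide mean $\mu$ of that per-SNP series and
merges runs of flagged SNPs (gap tolerance `max_gap`, default 0 —
conservative strictly-consecutive merging, configurable for sparse maps;
the original interval-building convention is unstated). Intervals are
reported with the bp bounds of their first and last flagged SNPs, in BED
(0-based half-open) and 1-based TSV forms. Because $\sigma$ is estimated
from the same series being thresholded, a 6σ exceedance is effectively
impossible under a homogeneous cohort (the simulated null produces none in
20/20 seeds), while a 5 Mb region driven to domestic dosage 0.8 in a
200-animal, 95%-wild cohort is recovered as the unique 6σ interval with
> 95% positional overlap.

## Determinism and numerical choices

Every stochastic component takes an explicit integer seed; the pipeline
(`run_pipeline()`) derives stage seeds by fixed offsets from one config
seed and writes byte-identical text outputs on re-runs (seeds are recorded
in TSV headers and the JSON manifest; no timestamps). Numerical guards:
panel-frequency clamping; mixture probabilities clamped at $10^{-12}$
inside the EM; per-SNP scaling in forward–backward with an exactness oracle;
log-space Viterbi with first-index tie-breaking; simplex renormalisation
each EM step. IBS thinning processes pairs in descending-IBS order, drops
the lower-call-rate member (earlier id on ties) and never removes both
members of a pair; LD pruning drops the later SNP of an offending pair
left-to-right within a window, keeping one representative per cluster.

## Limitations

Beyond the generator's idealisations listed above: supervised estimation
only (no unsupervised K selection); unphased diploid decoding (haplotype
slot labels are arbitrary); the q-recovery information limit at weak panel
divergence; the karyotype class-ordering finding; and cohort-level
percentages from the motivating study (outlier rates, admixed fractions,
per-population medians, real concordance rates) are out of reach by design
— they require the original genotypes, which this package only emulates.
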