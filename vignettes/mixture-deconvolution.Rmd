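---
title: "Continuous statistical phasing of mitochondrial DNA mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous statistical phasing of mitochondrial DNA mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitophase)
```

## The problem

A forensic mitochondrial DNA mixture is a sample containing the mtDNA of
two (or more) donors. Because mtDNA is haploid, each donor contributes a
single full-genome haplotype (a *mitotype*), and massively parallel
sequencing reports, at every polymorphic position, how many reads support
the reference and the alternative allele. The analytical task is
continuous mixture deconvolution: estimate how many donors are present,
in what proportions, and — most importantly for human identification —
reconstruct each donor's complete mitotype.

`mitophase` implements this as statistical phasing with a reference
panel. Each contributor haplotype is modelled as an imperfect copy of one
mitotype in a panel of known haplotypes (a Li–Stephens copying model with
the recombination rate fixed at zero, appropriate for the non-recombining
mitochondrial genome), while the read counts tie the unknown haplotypes
and their mixing proportions to the data through a binomial likelihood.

## The model

Sites are bi-allelic SNPs relative to the rCRS; insertions, deletions and
multi-allelic positions are filtered out on input (`build_site_universe`).
For a mixture of $K$ strains with proportions $w_1,\dots,w_K$
($\sum_k w_k = 1$) and binary haplotypes $h_{kj}$, the within-sample
alternative allele fraction at site $j$ is

$$ q_j = \sum_k w_k\, h_{kj}, $$

and with a symmetric per-read error rate $e$ the alternative read count
$a_j$ out of depth $n_j$ is

$$ a_j \sim \mathrm{Binomial}\!\left(n_j,\; q_j (1-e) + (1-q_j)\, e\right). $$

Zero-depth sites contribute nothing to the likelihood (drop-out is carried
but never imputed). Proportions are parametrized by Gaussian titres
$t_k \sim N(0, \sigma_t^2)$ through a softmax, which gives an
unconstrained space for the random-walk proposals. Each strain copies a
single panel donor $z_k$ (uniform prior over the $N_p$ panel members) with
per-site mis-copying probability $\mu$: the emission is $1-\mu$ when
$h_{kj}$ matches the donor allele and $\mu$ otherwise. The mis-copying
rate is what allows estimated mitotypes to differ from everything in the
panel — without it, private variants could never be recovered.

## The sampler

One MCMC sweep consists of:

1. **Proportions** — a joint Metropolis–Hastings update of all titres,
   $t_k' = t_k + N(0, \delta)$, accepted with the usual ratio under the
   titre prior.
2. **Titre mean** — the softmax is invariant to a common shift of all
   titres, so the titre mean carries no likelihood information and is
   Gibbs-drawn exactly from its prior, $\bar t \sim N(0, \sigma_t^2/K)$.
   Left to the random walk, this direction would equilibrate only over
   $\sim(\sigma_t/\delta)^2$ sweeps and leave a long spurious trend in the
   log-posterior trace.
3. **Haplotypes** — for each strain in random order, an exact block-Gibbs
   draw of $(z_k, h_k)$ given everything else: donor weights are products
   over sites of the emission-weighted site likelihoods, then each site
   allele is drawn independently given the donor. All products are
   accumulated in log space.
4. **Allele exchange** — a site-wise Metropolis move proposing to swap the
   alleles of a strain pair at each heterozygous-assignment site. This
   move is essential: the single-strain Gibbs conditionals are mutually
   pinning — once two strains hold point-switched alleles at a site,
   neither can move alone without passing through a state the likelihood
   forbids, and near-equal proportions then pin $w$ at $1/K$, freezing the
   chain in a symmetric trap. The exchange move provides the missing joint
   pathway and targets the same posterior (the copying-emission ratio is
   evaluated at the strains' current donors).

Initialization is uniform proportions and random panel rows; the first
half of the chain is discarded as burn-in. For summaries, strains are
sorted by current proportion at every retained sweep; when the top two
proportions are within `align_tol` (default 0.05, the 1:1 label-switching
regime) the orientation is chosen by minimal Hamming distance to the
running modal haplotypes before accumulation. Modal haplotypes are
per-site posterior majority calls, and the reported proportions are
posterior means of the aligned samples.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `K` | 2 | strains modelled (1–5) |
| `n_steps` | 3000 | MCMC sweeps; 800 is reliably too few on full-mitogenome site sets |
| `burn_in_fraction` | 0.5 | discarded share of the chain |
| `read_error` ($e$) | 0.01 | per-read miscall probability |
| `miscopy_rate` ($\mu$) | 0.01 | copying-emission mismatch probability |
| `titre_sd` ($\sigma_t$) | 3 | prior scale of the titres |
| `proposal_sd` ($\delta$) | 0.1 | titre random-walk step |
| `proportion_floor` ($\tau$) | 0.01 | detection threshold for effective contributors |

Read depth is normalized to 100× by the simulator: above that the copying
prior becomes stiff relative to the likelihood and the panel bleeds into
the estimates; below it the minor contributor's handful of reads carries
too little signal.

## Reference panels

The production panel filter keeps database mitotypes within a *graph edit
distance* $d$ of the mixture — the number of allele changes needed for
compatibility with the observed genotypes, where a site with reads on both
alleles accepts either allele and zero-depth sites are free. This is the
minimal-change reading of "compatible with the mixed haplotypes"; distance
is computed against the mixture genotype, not against each contributor
separately, since the contributors are unknown at panel-building time.
Surviving candidates are capped at the `max_panel = 25` nearest (ties
broken lexicographically by sample ID for reproducibility), balancing
copying accuracy against the quadratic runtime cost of panel size. An
empty filter result falls back to the single globally nearest haplotype
with a warning, because the copying model needs at least one donor.

Four experimental designs probe how panel composition bounds accuracy:
the idealized panel containing both contributors (type 1), hold-two-out
cross-validation (type 2), and one-SNP "derived vs ancestral"
perturbations placed either in the mixture copy (type 3) or the panel
copy (type 4) of one contributor.

## Minor interpolation

In a two-person mixture the genotype classes are determined by the allele
union of the contributors, so once the major mitotype is phased exactly,
the minor follows deterministically: complement the major at sites with
reads on both alleles, copy the single observed allele at homozygous
sites, and leave uncovered sites uncalled (a partial mitotype is
acceptable forensic output; defaulting to the reference would fabricate
calls). On exact in silico counts this reconstruction is provably exact
whenever the major is exact, which is why post-interpolation accuracy is
the headline metric for imbalanced ratios: the sampler recovers the major
essentially always, while the minor's own reads are too few to pull its
private variants away from a panel that lacks them.

`interpolate_minor` errors (in strict mode) when the asserted major
carries an allele with zero supporting reads — the premise "the major is
correct" is then untenable. The automated pipeline instead tags such
sites and reports both raw and interpolated minors.

## Accuracy metrics and study statistics

Phasing accuracy uses Hamming distances under the optimal truth–estimate
matching: for pairs, the smaller of $d(A,a)+d(B,b)$ and $d(A,b)+d(B,a)$;
for $K \le 5$, the minimum over all permutations by exhaustive search.
*Deconvolution accuracy* is the percentage of mixtures in which every
contributor is recovered at distance zero (exact binomial CIs are
attached for plotting). Proportion recovery is summarized by the OLS
$R^2$ of observed on expected minor proportions plus per-ratio variances.
The accompanying statistical procedures — the continuity-corrected
two-sample proportion test, the summary-statistic $F$-test for equality
of variances, and the two-predictor regression of accuracy on
mixture-internal distance and minimum panel distance — are thin, tested
wrappers over the standard R machinery (`prop.test`, the $F$
distribution, `lm`).

## The synthetic database generator

Validation needs a population database with haplogroup structure but no
external downloads. `generate_db` draws a star phylogeny from an
rCRS-like root: each of 8 haplogroups receives Poisson($\lambda_b = 15$)
defining substitutions, and each of 4 samples per group adds
Poisson($\lambda_p = 4$) private substitutions at fresh positions, with
alternative bases uniform over the three non-reference bases and no
recurrent mutation within a lineage. The defaults were chosen once so
that pairwise Hamming distances span roughly 1–56 with a mean near 38 —
matching the regime reported for forensic full-mitogenome population
samples (within-group pairs $\approx 2\lambda_p$, between-group pairs
$\approx 2\lambda_b + 2\lambda_p$). The standard fixture takes 10 mixture
sources spread across all haplogroups plus 22 background mitotypes,
mirroring a 32-haplotype study design (45 pairs × 6 ratios = 270
mixtures; crossed with the 3×3×3 grid of depth, steps and edit distance,
7290 runs).

What the generator deliberately does **not** emulate: sequencing noise,
strand bias, point heteroplasmies, NUMT contamination, indel length
variants, and allele drop-out. Mixture counts are exact expectations of
the mixing ratio. Passing tests on this data therefore validate the
*phasing model and sampler*, not robustness to genotyping error — with
real in vitro mixtures, errors are typically dominated by private
heteroplasmies and allele drop-out, which no phasing model repairs.

## Numerical and design choices

- **Count rounding**: `alt = round(D·q)` half-away-from-zero, reference
  fills the remainder, so depth is conserved exactly at every site.
- **Likelihood floor**: each site log-pmf is floored at −745, so $e = 0$
  on inconsistent counts stays finite.
- **Ties**: panel selection and 1:1 major/minor labels break ties
  lexicographically by sample ID; grid seeds derive from a master seed
  and the run labels, so any subset of a grid reproduces independently.
- **Diagnostics**: the Geweke-style $z$ compares the first 10% and last
  50% of the post-burn-in log-posterior trace with batch-means standard
  errors (batches ≥ 20 draws). The statistic is conservative: chains
  whose haplotypes and proportions have plainly converged can keep a
  slow residual drift from donor settling and draw $|z|$ slightly above
  2 in roughly one run in ten. Treat the flag as a prompt to inspect the
  trace, not as a verdict.
- **Effective contributors**: strains with identical modal haplotypes
  are merged before applying the detection floor — when two strains
  converge on the same mitotype the split of proportion mass between
  them is unidentifiable (the likelihood is flat in $w$), and they
  represent a single donor.

## Problem sizes used in validation

The shipped validation suite runs the full 45-pair design at 4:1 and
50:1 with contributors in the panel, and 20 mixtures per non-1:1 ratio
with hold-two-out edit-distance-4 panels (100 runs), all at depth 100
with 3000-step chains over ~250 segregating sites — the sizes at which
the method's headline claims were established, kept at desk scale. The
enumeration-oracle checks compare the sampler against the exact posterior
on 4-site, 2-donor instances where all $2^{2M} N_p^2$ configurations can
be summed directly.

## Known limitations

- Point heteroplasmy is not modelled; a PHP in a contributor will be
  phased as an error or absorbed into the other strain.
- Indels and multi-allelic sites are filtered, discarding some
  diagnostic variation.
- Interpolation is defined for two-person mixtures only.
- 1:1 mixtures remain the hard case: quantitative information vanishes
  and accuracy rests entirely on the panel's haplotype structure.
- The $\rho > 0$ recombination path (panel switching within a strain) is
  not implemented; it is unnecessary for mtDNA.
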