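# mitophase

Continuous statistical phasing for forensic mitochondrial DNA mixture
deconvolution.

## What it does, and for whom

Forensic samples often contain mtDNA from more than one person. Because
mtDNA is haploid, each donor contributes one full-genome haplotype (a
*mitotype*), and massively parallel sequencing yields per-site reference
and alternative read counts for the combined sample. `mitophase`
reconstructs the individual mitotypes and their mixing proportions from
those counts — the continuous (quantitative) approach to mixture
interpretation, aimed at forensic analysts and method developers who need
complete contributor haplotypes rather than haplogroup assignments.

The core is an MCMC sampler over a copying model. At site $j$, with
strain proportions $w_k$ and binary haplotypes $h_{kj}$, the alternative
read count is

$$a_j \sim \mathrm{Binomial}\big(n_j,\ q_j(1-e) + (1-q_j)e\big),
\qquad q_j = \textstyle\sum_k w_k h_{kj},$$

with per-read error rate $e$. Each strain haplotype is a Li–Stephens
imperfect copy of one member of a reference panel of known mitotypes
(mis-copying rate $\mu$; recombination fixed at 0 for mtDNA).
Metropolis–Hastings updates the proportions, a block-Gibbs move redraws
each strain's donor and haplotype, and a site-wise allele-exchange move
protects against point-switch traps. Reference panels are built by
filtering a haplotype database to a *graph edit distance* of the mixture
(allele changes needed for compatibility with the observed genotypes),
capped at the 25 nearest. For imbalanced mixtures, the minor contributor
is *interpolated* from an accurately phased major: complement at
heterozygous sites, copy at homozygous sites.

The package also ships an exact in silico mixture simulator, EMPOP-style
haplotype table I/O, a synthetic haplogroup-structured database
generator, Hamming-pairing accuracy metrics, the associated statistical
tests, a parameter-grid pipeline, and a command-line front end
(`inst/cli/mitophase`).

## Worked example

Simulate a 4:1 two-person mixture at 100× from a synthetic database,
build a hold-two-out edit-distance-4 panel, and deconvolve:

```r
library(mitophase)
fx <- make_fixture_suite(seed = 42)           # 32 mitotypes, 8 haplogroups
spec <- mixture_spec(fx$sources[1], fx$sources[2], c(4L, 1L), 100L)
counts <- make_mixture(fx$haps, spec)
panel <- build_edit_distance_panel(fx$haps, counts, d = 4, max_panel = 25,
                                   exclude = c(spec$major, spec$minor))
panel
#> mito_panel [edit_distance(4)]: 2 haplotypes x 263 sites
res <- run_mcmc(counts, panel, engine_config(seed = 7))
res
#> mito_deconv: K = 2 strains, 263 sites, 1500 kept sweeps
#>   proportions: 0.807, 0.193
#>   MH acceptance 0.55; Geweke z = 0.74 (converged)
```

The posterior-mean proportions (0.807/0.193) recover the 4:1 ratio.
Comparing against the simulation truth under the optimal pairing, and
interpolating the minor from the phased major:

```r
tr <- attr(counts, "truth")
paired_distance(rbind(tr$major, tr$minor), res$haplotypes)$total
#> [1] 0
interp <- interpolate_minor(res$haplotypes[1, ], counts, strict = FALSE)
paired_distance(rbind(tr$major, tr$minor),
                rbind(res$haplotypes[1, ], interp$minor))$total
#> [1] 0
```

A paired Hamming distance of zero means both mitotypes were reconstructed
exactly. The same flow is available from the shell:

```sh
Rscript inst/cli/mitophase syndata --out db.empop --seed 3
Rscript inst/cli/mitophase simulate --db db.empop --major HG1_S01 --minor HG2_S01 --ratio 4:1 --out mix.tsv
Rscript inst/cli/mitophase panel --db db.empop --counts mix.tsv --edit-distance 4 --out panel.empop
Rscript inst/cli/mitophase deconvolve --counts mix.tsv --panel panel.empop --seed 5 --out result.json
```

See `vignettes/mixture-deconvolution.Rmd` for the model, the sampler
moves, parameter guidance, and the validation design.

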