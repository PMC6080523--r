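---
title: "Weighted single-step GWAS: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted single-step GWAS: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wssgwas)
```

## The problem

Semen traits (and many other repeated-record traits in animal breeding) are
recorded many times per animal, on a modest number of animals, while genotypes
are available for a partly different — often much larger — set of relatives.
Single-SNP association tests waste most of that information: they need animals
that are both genotyped and phenotyped, or pseudo-phenotypes derived from
them. Single-step GBLUP (ssGBLUP) instead fits one mixed model over *all*
animals, combining pedigree and genomic relationships, and the weighted
single-step GWAS (WssGWAS) converts the resulting genomic breeding values into
SNP effects, iteratively re-weighting SNP variances so large effects are
shrunk less. Results are reported per 0.4 Mb window of consecutive SNPs as the
percentage of additive genetic variance the window explains.

This package implements that pipeline end to end — pedigree relationship
matrices, genotype quality control, REML variance components, the weighting
loop, window variance decomposition, and QTL-region selection — together with
a synthetic-data generator that produces pedigrees, LD-structured genotypes
and repeated-record phenotypes with the statistical structure the analysis
assumes, so every stage is testable without proprietary data.

## The repeatability animal model

For one trait the observation model is

$$ y = X\beta + Za + Wp + e, $$

with $y$ one row per ejaculate record; $\beta$ the fixed effects (an
intercept, contemporary-group factors, and mean-centered covariates for the
collection interval in days and boar age in months); $a \sim N(0, K\sigma^2_a)$
the additive genetic effect of every pedigree animal, with $K$ the pedigree
numerator relationship matrix $A$ or the combined matrix $H$; $p \sim N(0,
I\sigma^2_p)$ a permanent-environment effect per animal with records; and $e
\sim N(0, I\sigma^2_e)$. Heritability is $h^2 = \sigma^2_a / (\sigma^2_a +
\sigma^2_p + \sigma^2_e)$ and repeatability $(\sigma^2_a + \sigma^2_p)$ over
the same total. Counts such as the number of sperm cells per ejaculate are
log-transformed before analysis; the package expects the response already on
the analysis scale.

The single-step relationship structure enters only through its inverse,

$$ H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1} \end{bmatrix}, $$

where $A_{22}$ is the genotyped block of $A$ and $G = Z D Z' \big/ \sum_i
2p_i(1-p_i)$ is the (weighted) VanRaden genomic relationship matrix built
from gene contents centered by twice the allele frequency, with $D$ a
diagonal matrix of SNP variance weights ($D = I$ initially).

## The weighting loop

Each iteration $t$: build $G_{(t)}$ from the current weights; form $H^{-1}$
and solve the mixed-model equations for GEBV; back-solve SNP effects

$$ \hat u_{(t)} = \lambda D_{(t)} Z' G_{(t)}^{-1} \hat a_g,
   \qquad \lambda = \Big(\sum_i 2p_i(1-p_i)\Big)^{-1}, $$

where $\hat a_g$ are the GEBV of the genotyped animals; square them into new
weights $d_{i(t+1)} = \hat u_{i(t)}^2\, 2p_i(1-p_i)$; and rescale so
$\mathrm{tr}(D_{(t+1)}) = M$, the SNP count, keeping the total genetic
variance constant. The loop runs three iterations. Variance components are
estimated once, at $D = I$, and held fixed across iterations. Window
percentages are reported from the final iteration:

$$ \frac{\mathrm{Var}\big(\sum_{j \in \text{window}} Z_j \hat u_j\big)}
        {\sigma^2_a} \times 100\%. $$

The variance is taken across the genotyped animals with denominator $n$
(population variance; an $n-1$ option exists and the difference is
negligible at panel sizes).

Because $Z \hat u = G_{raw} G^{-1} \hat a_g$, the decomposition identity
$Z\hat u = \hat a_g$ holds exactly whenever the same unblended $G$ is used in
the back-solve — the central internal consistency check of the method, and an
automated test in this package.

### Allele frequencies and the singularity of G

With allele frequencies computed from the genotyped animals themselves, the
centered columns of $Z$ sum to zero, so the ones vector is in the null space
of $G$: the unblended $G$ is *always* singular. This is a structural property,
not a numerical accident. The package therefore:

* defaults to observed frequencies (used for MAF filtering, mean imputation
  and centering) **plus** blending, $G \leftarrow (1-\alpha)G + \alpha A_{22}$
  with $\alpha = 0.05$, the standard invertibility device;
* accepts an explicit frequency vector (`freq` in `run_wssgwas()` and
  `center_gene_content()`); base-population frequencies — which the simulator
  records in the panel's `"base_freq"` attribute — are the theoretically
  correct centering for VanRaden's $G$ and make the unblended matrix
  generically invertible, which is how the exact decomposition identity is
  verified with $\alpha = 0$.

No tuning of $G$ to the scale of $A_{22}$ is applied (a flag some ssGBLUP
software exposes); inversion failures raise explicit errors rather than
falling back to pseudo-inverses.

## Relationship matrices

$A$ is built by the tabular method with unknown parents treated as unrelated,
non-inbred base animals; diagonals are $1 + F$. $A^{-1}$ uses Henderson's
rules with Mendelian-sampling variances from the tabular inbreeding
coefficients — at the desk scales this package targets (up to a few thousand
animals) the $O(n^2)$ tabular pass is simpler than Meuwissen–Luo and is
verified against a dense inverse and against gene-drop IBD simulation.
Pedigree pruning retains the phenotyped/genotyped animals plus all their
ancestors (ancestor closure), which is the natural reading of "pruning" for
this analysis; it is idempotent by construction.

## Quality control

Filters run in a fixed, logged order: (1) unmapped or sex-chromosome SNPs,
(2) SNP call rate < 0.95, (3) minor allele frequency < 0.01, (4)
Hardy–Weinberg 1-df goodness-of-fit $\chi^2 > 600$, (5) animals with > 5%
missing genotypes. Thresholds are the standard chip-QC values for pig ssGBLUP
analyses; the $\chi^2$ form is the unbounded 1-df statistic (a bounded exact
test could not exceed 600). Allele frequencies are recomputed on the
survivors and remaining missing genotypes are mean-imputed with $2p$ —
reference-panel imputation is deliberately out of scope, and mean fill only
matters when missingness is injected into simulations. Positions are 1-based
inclusive bp internally and in all reports; BED input/output converts to and
from 0-based half-open coordinates at the boundary.

## REML

`estimate_reml()` maximises the restricted likelihood in
$(\sigma^2_a, \sigma^2_p, \sigma^2_e)$ through the dense-Cholesky
mixed-model-equations identity for the likelihood. The first three updates
are EM-REML (monotone and safe far from the optimum); afterwards
average-information (AI) steps are attempted with step-halving, falling back
to EM whenever an AI candidate leaves the parameter space or lowers the
likelihood. A component that the score pushes against the lower bound
($10^{-10}$ times the phenotypic variance) is pinned there — accepted only if
pinning does not lower the likelihood — and released if its score turns
positive; this is the usual boundary treatment in production AI-REML codes
and prevents the EM tail from stalling on boundary optima. Convergence is a
maximum relative parameter change below $10^{-8}$ (with a small floor in the
denominator so bounded components cannot stall the criterion). Standard
errors come from the inverse AI matrix; $h^2$ and repeatability standard
errors use the delta method. Estimates are invariant to the fixed-effect
constraint (first- vs last-level dropped), which is tested.

Identifiability caveat: with few phenotyped animals and a shallow pedigree,
$\sigma^2_a$ and $\sigma^2_p$ are separated only by relatedness, and the REML
optimum can legitimately sit on the $\sigma^2_p = 0$ boundary even when the
generating value was positive. The fit flags this (`boundary = TRUE`).

## The synthetic-data generator

`sim_config()` defaults describe a desk-scale boar AI population: a few
hundred animals in discrete generations; a genome of 3 chromosomes × 40 Mb
carrying 2000 SNPs — the same ~17 SNPs/Mb density as a 60K chip on a 2.2 Gb
genome, about 7 SNPs per 0.4 Mb window; haplotype blocks of 0.4 Mb, the
average block size in commercial pig lines and the window span used
downstream; heritability defaults in the low-to-moderate range typical of
semen traits (0.10–0.31), repeatability 0.45; 10–50 ejaculate records per
boar with a rounded negative-binomial count distribution (the field reports
only means and SDs, so the count mechanism is a package decision);
contemporary-group fixed effects and two standardized record-level
covariates; and deliberately partial genotyping and phenotyping so the
phenotype/genotype overlap can be made small, as in real AI populations.

Founder haplotypes draw per-SNP frequencies uniform on (0.05, 0.5) — so
default panels rarely lose SNPs to QC; a flag injects QC violations — with a
shared latent uniform per 0.4 Mb block (15% of alleles redrawn
independently), giving strong within-block and no across-block LD. Meiosis
places one crossover per chromosome uniformly over block boundaries: the
simplest mechanism that yields the block structure the window span assumes.
Recombination maps, sex chromosomes and selection are non-goals.

True breeding values are the sum of a few large QTL (SNPs with effects sized
from their base-frequency variance so each explains its configured fraction
of $\sigma^2_a$) and a polygenic background. The background is realized, by
default, as small effects on *all* non-QTL SNPs with equal expected variance
per SNP — the infinitesimal architecture of standard breeding simulators,
transmitted through the pedigree by gene dropping. A SNP-free variant
(`polygene = "pedigree"`), drawn down the pedigree as parent average plus
Mendelian sampling, is retained: it represents genetic variance that the
marker panel cannot tag at all. The choice matters for GWAS calibration:
because the back-solve reproduces $\hat a_g$ exactly in SNP space, any
SNP-orthogonal genetic variance is forcibly redistributed across windows,
and after three weighting iterations the largest window can carry several
times the equal-contribution expectation even when no QTL exists. Passing
tests on the default architecture therefore demonstrate calibration when the
polygene is taggable by the panel; they do not bound the behaviour on traits
whose variance is largely off-chip.

One master seed drives everything; stages consume `seed + 1` … `seed + 5`
(pedigree, genotypes, phenotypes, genotyped subset, gene annotation), so
stages are individually reproducible.

## Window selection and QTL regions

Windows are a greedy non-overlapping partition per chromosome: a window
starts at the first unassigned SNP and absorbs consecutive SNPs strictly
within 0.4 Mb of its start; the midpoint is the mean of the first and last
member positions (sliding windows are deliberately not the default — each
reported dot is one disjoint window). Windows explaining ≥ 1% of the genetic
variance are selected; 1% is 50 times the expected contribution of one
window in a ~4200-window genome (100/4223 ≈ 0.02%). Selected windows merge
into QTL regions by single-linkage clustering of midpoints on the same
chromosome with a *strictly* less-than 0.4 Mb rule — the boundary case (a gap
of exactly 0.4 Mb) does not merge, and chains merge transitively; both
behaviours are unit-tested, since the verbal rule leaves them open. The three
top windows per trait are also reported with 0.4 Mb flanks on either side of
their midpoints (clipped at zero), and gene lookup intersects regions with a
BED/GFF annotation, strand-ignored, 1-based inclusive in reports. Regions
report both the merged window bounds and the flanked bounds, since either
convention is defensible. Cross-population overlap applies the same strict
midpoint rule to the same trait across two analyses; an empty result is a
reportable outcome, not an error.

No significance testing is attached to windows: the method provides variance
percentages, not p-values, and the iteration count is fixed at three rather
than driven by realized accuracies.

## Numerical choices and problem sizes

All factorizations are dense Cholesky with explicit failure modes; the MME
coefficient matrix at the default test scales (≈ 1000–1700 equations) factors
in well under a second. The automated checks run the pipeline at these
sizes: the decomposition identity on 200 animals × 1000 SNPs; REML recovery
at $h^2 = 0.30$, repeatability 0.50, on ~550 phenotyped boars × 10 records
averaged over five replicates; QTL localization and null calibration on 10
replicates each of ~500 genotyped-and-phenotyped boars × 2000 SNPs — sizes
chosen so the entire suite completes in minutes while keeping the Monte
Carlo error of each asserted quantity well inside its assertion band.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7, n_qtl = 1, qtl_variance_fractions = 0.10,
                  h2 = 0.3, rep = 0.5, prop_genotyped = 1, prop_phenotyped = 1)
ds <- simulate_dataset(cfg)
qc <- apply_qc(ds$panel)
model <- build_model(ds$records, ds$ped)
vc <- estimate_reml(model)
tidy(vc)
fit <- run_wssgwas(model, qc$panel, vc)
tidy(fit)                      # one row per 0.4 Mb window
select_windows(tidy(fit), 1)   # windows explaining >= 1%
autoplot(fit)                  # Manhattan-style window plot
```

## Known limitations

* Dense matrices cap practical pedigrees at a few thousand animals; APY-type
  approximations and sparse-inverse-only workflows are out of scope.
* Single-trait models only; genetic correlations between traits are not
  estimated.
* The simulator's LD is block-wise by construction; real chips show decaying
  LD across block boundaries, so simulated windows are slightly cleaner
  units than real ones.
* Reference-panel imputation, GO/KEGG enrichment and literature-based gene
  triage are intentionally outside the package.
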