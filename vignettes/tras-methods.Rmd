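---
title: "Transcriptome-referenced association and eQTL interrelation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-referenced association and eQTL interrelation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Many crops — garlic is the motivating case — have no usable genome assembly
but do have a de novo reference transcriptome and population RNA-seq. SNPs
can then be called against transcript sequences, so every marker is
anchored to a transcript rather than to a chromosome position. A
transcriptome-referenced association study (TRAS) maps quantitative traits
with those markers, and the transcript anchoring buys something a genome
scan does not have: each associated SNP names a candidate gene directly,
and the candidate can be validated on an independent data axis, the
correlation of its *expression* with the trait. `tras` implements that
two-filter design, the downstream eQTL interrelation network, and the
module/GO machinery around it, together with a synthetic cohort generator
that makes every stage testable without any external data.

The intended population is a panel of roughly a hundred clonal landraces.
Clonality matters twice: genotypes do not segregate (heterozygous
accessions stay heterozygous, so no Hardy–Weinberg filtering is applied
anywhere), and the panel carries strong population structure that the
association model must absorb.

# The association model

For one phenotype $y$ (a trait, or one transcript's expression in the eQTL
scans) and one marker dosage vector $x \in \{0,1,2\}^n$:

$$ y = W\alpha + x\beta + u + \varepsilon, \qquad
   u \sim N(0, \sigma_g^2 K), \quad \varepsilon \sim N(0, \sigma_e^2 I) $$

where $W$ is an intercept plus the first three principal components of the
centered dosage matrix (fixed-effect stratification correction) and $K$ is
the VanRaden kinship matrix $ZZ^\top / \sum_j 2p_j(1-p_j)$ computed from
all markers (random-effect relatedness correction). Writing
$\delta = \sigma_e^2/\sigma_g^2$ and eigendecomposing $K = USU^\top$ once
per phenotype, rotation by $U^\top$ diagonalizes the covariance; the
restricted likelihood profiled over $\sigma_g^2$ becomes a one-dimensional
function of $\delta$, which `fit_null()` maximizes on a 100-point log grid
over $[10^{-5}, 10^5]$ with scalar refinement of every local grid maximum.
Markers are then scored by generalized least squares at the null
$\hat\delta$ (the EMMAX approximation), with the Wald statistic
$(\hat\beta/\mathrm{se})^2$ referred to $F(1,\, n - c - 1)$. An
`exact_per_marker` flag re-optimizes $\delta$ with the marker in the model
when exactness matters more than speed.

Numerical choices worth stating:

* REML, not ML, for the variance ratio — conventional for variance
  components, and what the dense-algebra oracle in the test suite checks
  against.
* Kinship eigenvalues are floored at zero and a ridge of $10^{-6}I$ is
  added when the smallest eigenvalue drops below $10^{-8}$, so clone-heavy
  panels (rank-deficient $K$) stay decomposable.
* A marker collinear with the covariates yields $p = 1$ plus a degeneracy
  flag rather than an exception: a transcriptome-wide scan must not abort
  on one bad column.
* PC score signs follow a fixed convention (largest-magnitude loading
  positive) so results are bit-reproducible across BLAS builds.
* With $K = I$ the whole engine reduces exactly to OLS; the suite asserts
  agreement with `lm()` to $10^{-8}$.

# Thresholds

The Bonferroni per-test threshold is $\alpha / m_\mathrm{eff}$. Two modes
exist for the effective marker count $m_\mathrm{eff}$: `total` uses the
raw marker count, which at the published panel size of 19,912 markers and
$\alpha = 0.05$ gives $2.5\times10^{-6}$, matching the convention of
treating all transcriptome SNPs as independent; `li_ji` uses the
eigenvalue-based count
$\sum_i \big[\mathbf{1}(\lambda_i \ge 1) + (\lambda_i - \lfloor\lambda_i\rfloor)\big]$
of the marker correlation matrix, computed block-wise (default 1,000
markers per block, the per-chromosome analogue when there are no
chromosomes). `total` is the default because the $2.5\times10^{-6}$
threshold implies the original analysis effectively used it; `li_ji` is
the principled alternative and is always the smaller count. The suggestive
threshold is $1/N$, i.e. $5\times10^{-5}$ at the published panel size.
The ambiguity in whether the original random effect used the continuous
kinship matrix or discrete kinship-derived groups is resolved toward the
continuous matrix — the standard mixed-model choice, and the only one that
is well-defined without a clustering rule.

# Trait-related transcripts and the interrelation network

A transcript is *trait-related* when it passes two filters: (1) some SNP
physically inside it passes the Bonferroni threshold in the trait scan,
and (2) the Pearson correlation between its expression and the trait has
raw $p < 0.05$. The expression filter is deliberately unadjusted for
multiplicity — that is the published validation rule — and a BH-adjusted
variant sits behind a flag. The regulation direction is the sign of the
expression–trait correlation. Both filters see the same expression scale:
$\log_2(x+1)$ by default, a variance-stabilizing choice the raw abundance
unit (counts, FPKM, TPM) is silent about; the `transformed` flag records
what was applied.

The eQTL stage re-runs the same mixed model with each trait-related
transcript's expression as the phenotype and all SNPs as markers, re-fitting
$\hat\delta$ per expression phenotype (expression heritabilities differ).
A directed edge $B \to A$ enters the interrelation network when three
criteria hold simultaneously: a SNP located in $B$ associates with $A$'s
expression at the eQTL threshold; $A$ and $B$ are trait-related for the
same trait; and the expression of $A$ and $B$ is correlated at $p < 0.05$.
The correlation criterion accepts either sign by default (the operative
definition is two-sided); `require_positive_corr` restricts it. Cis
records ($A = B$) are excluded from the network and reported separately.
Per-target eQTL counts also feed a coarse regulatory-position label:
targets with no eQTL anywhere are upstream candidates, targets with ≥ 50
are downstream candidates.

One behavior to expect on strongly linked architectures: when the cis SNPs
of a regulator and its target are in linkage, the three criteria are close
to symmetric, so reciprocal edges ($A \to B$ alongside $B \to A$) appear.
The rule set has no mediation or causal-direction test — deliberately, as
that is outside what the three criteria can claim.

# Modules and function prediction

Module *detection* is out of scope; labels arrive as input (from WGCNA or
the generator's truth). A module's summary profile is its eigengene — the
first left singular vector of the per-transcript standardized expression
submatrix, sign-fixed to correlate positively with the module's mean
profile; a singleton module falls back to its standardized expression,
flagged. Eigengene–trait coupling is plain Pearson with $p < 0.05$.
Co-expression partners of an lncRNA are the other members of its module
(a correlation-neighborhood alternative exists behind `min_abs_r`), and
their GO over-representation is the hypergeometric upper tail against the
full transcript background with BH $q$-values, terms treated as flat sets
(no ontology-graph propagation — a stated limitation, not an oversight).

# What the generator emulates, and what it does not

`sim_config()` defaults are the desk-scale study conditions: 102
accessions in three Balding–Nichols subpopulations at $F_{st} = 0.15$,
2,000 SNPs anchored on 1,000 transcripts, one diploid dosage draw per
accession (clonal — no recombination, no HWE), three traits affinely
rescaled to bulb-yield-like units ($21.0 \pm 7.4$ g, $41.2 \pm 6.7$ mm,
$12.7 \pm 4.9$) with target pairwise correlations $0.92/0.36/0.23$
achieved through a shared BW/BD genetic core, a pleiotropy leak of the CN
genetic score, a shared polygenic background, and a residual correlation
matrix solved from the targets and projected to the nearest PD matrix.

The planted architecture mirrors the two pathway motifs the network stage
must recover: a single-link cascade $B_1 \to A_1$ and a convergent cascade
$B_2, B_3 \to A_2$ on the CN-analog trait, plus a direct causal SNP
(~30% of BW variance) and one positively and one negatively acting
expression-mediated transcript on BW/BD. Cascade cis SNPs within a motif
are simulated in linkage (dosage correlation 0.85 within the pair, 0.65
within the triple): five mutually independent SNPs cannot each carry the
trait-variance share that makes all five transcripts reliably
Bonferroni-significant at $n = 102$ (marginal variances would sum past 1),
whereas linked cis SNPs — the transcriptome analogue of a pleiotropic
genomic region — share it. Effect sizes were calibrated once, with the
full analysis model in the loop, so that endpoint trait-relatedness lands
near 0.9–1.0 per seed; a first calibration from marginal $F$ statistics
alone overstated power because it ignored the PC + kinship correction,
which costs roughly a factor 2–3 in expected $F$ for structured markers.

Module structure is ten latent factors at signal-to-noise 2, with module 1
coupled to the CN-analog trait at $r = 0.452$ (the effect size scale the
module–trait stage is expected to detect at $n = 102$) and the cascade
transcripts assigned to it, echoing the concentration of trait-related
transcripts in one module. A GO annotation is planted per module (80% of
members carry the module's term), a fraction of transcripts is tagged
lncRNA, and twenty unrelated transcript pairs are recorded for false-edge
scoring. Latent log-scale expression is mapped to non-negative abundance
by $2^z - 1$ with per-transcript location, quantized to three decimals, so
the $\log_2(x+1)$ re-transform recovers the latent scale almost exactly.

What the generator does *not* emulate: realistic linkage-disequilibrium
decay (there is no genetic map to decay along), sequencing noise and
count-model mean–variance coupling, batch effects, replicate structure
across years, and missing-not-at-random genotypes. Passing recovery tests
therefore demonstrates the statistical machinery under the stated
conditions, not robustness to everything real RNA-seq panels do.

# Problem sizes used by the test suite

The suite exercises the oracle checks at $n \le 10$ against dense
explicit-inverse linear algebra; calibration at 102 samples × 200 null
markers × 25 replicates (type-I error within $[0.035, 0.065]$, median
$\chi^2/0.456$ within $[0.85, 1.15]$); recovery at the full desk-scale
defaults over 20 seeds; and the generator's distributional invariants
(trait correlations within ±0.1, $F_{st}$ within ±0.05 of target, 50
seeds) at a reduced marker count with the cohort shape unchanged — sizes
chosen so the whole suite stays deep but quick on one CPU.

# Known limitations

* EMMAX scoring holds $\hat\delta$ fixed across markers; for markers with
  very large effects the exact per-marker fit gives slightly different
  $p$-values (the flag exists, at ~linear extra cost).
* The eQTL threshold is applied per target transcript; a study-wide BH
  alternative across all targets is a one-line change but not the default,
  matching the per-scan convention.
* The three-criterion network is correlational; reciprocal edges under
  strong cis linkage are expected and not resolved.
* GO terms are flat sets; no ontology propagation.
* Locus merging beyond transcript identity is not attempted — on a
  transcriptome reference there is no physical map to merge along, so one
  transcript is one locus and cross-trait overlap is reported as
  pleiotropy.
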