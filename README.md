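# tras — transcriptome-referenced association study and eQTL interrelation networks

`tras` is an R package plus a numbered analysis workflow for association
mapping in crops that have a de novo reference transcriptome but no genome
assembly — the motivating system is a panel of ~100 clonal garlic
landraces scored for bulb-yield traits (bulb weight BW in g, bulb diameter
BD in mm, clove number CN). SNPs are called against transcript sequences,
so every marker is anchored to a transcript; an associated SNP therefore
names a candidate gene directly, and the candidate is validated on a
second axis: the correlation of its expression with the trait.

## The model

Each scan fits the single-variance-component linear mixed model

    y = Wα + xβ + u + ε,   u ~ N(0, σg² K),  ε ~ N(0, σe² I)

with W an intercept plus the first three genotype principal components
and K the VanRaden kinship matrix from all SNPs. The variance ratio
δ = σe²/σg² is estimated once per phenotype by REML on the
kinship-rotated model (exact profile likelihood, grid plus scalar
refinement) and each marker is then scored by GLS at the null δ̂
(EMMAX-style), Wald (β̂/se)² against F(1, n−c−1). Thresholds: Bonferroni
α/m_eff (with m_eff either the raw marker count or a Li–Ji eigenvalue
count) and the suggestive 1/N rule — at the published panel size of
19,912 markers these are 2.5×10⁻⁶ and 5×10⁻⁵.

On top of the scans the package implements:

* **trait-related transcript calling** — a transcript whose SNP passes
  Bonferroni *and* whose expression correlates with the trait (raw
  P < 0.05), with the regulation direction taken from the sign;
* **eQTL scans** — every SNP against each trait-related transcript's
  expression as the phenotype, δ̂ re-fitted per transcript;
* **three-criterion interrelation network** — a directed edge B→A when a
  SNP in B associates with A's expression, both are trait-related for the
  same trait, and their expressions correlate (P < 0.05); edges carry the
  G (eQTL) and E (correlation) P-values;
* **module eigengene–trait correlation** and **hypergeometric GO
  enrichment** (BH FDR) for lncRNA function prediction via co-expression
  partners;
* a **synthetic cohort generator** (Balding–Nichols clonal genotypes,
  planted cascades, module structure, GO truth) so the whole pipeline is
  testable offline, with `evaluate_recovery()` scoring every stage
  against the planted truth.

## Worked example

```r
library(tras)
coh <- simulate_cohort(sim_config(seed = 1))   # 102 x 2000 SNPs / 1000 transcripts
out <- run_full_pipeline(coh)
print(out$phenotype_summary)
print(out$trait_related)
print(out$network$edges)
```

prints (abridged) the population summary

    BW: range 2.4-45.0, mean 21.0 +/- 7.4, fold-range 18.6
    r(BW, BD) = 0.90 (p = 3.1e-38)
    r(BW, CN) = 0.35 (p = 0.00029)

the trait-related transcript calls with their two P-values and direction

      trait transcript_id best_genotype_p expression_r expression_p direction
    1    BW        TR0007         1.7e-06         0.51      4.2e-08         +
    6    CN        TR0004         1.3e-13         0.63      1.5e-12         +
    7    CN        TR0005         3.7e-09         0.69      9.8e-16         +

and the interrelation edges with their G/E annotations

      trait source_id target_id     g_pvalue     e_pvalue   e_r
    1    CN    TR0001    TR0002      3.2e-27      1.1e-38  0.90
    2    CN    TR0003    TR0005      1.0e-17      5.6e-24  0.80

Here TR0001→TR0002 and TR0003/TR0004→TR0005 are exactly the generator's
planted single-link and convergent cascades: a SNP in the source
transcript drives the target's expression, both transcripts pass both
association filters for CN, and their expressions correlate. The
additional reciprocal edges that appear come from cis-SNP linkage within
a cascade (see the methods vignette). The analysis scripts
`analysis/01_simulate.R` … `06_recovery_benchmark.R` run the same
pipeline stage by stage, narrating counts and writing all tables under
`results/`.

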