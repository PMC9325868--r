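# archie

Aggregative trans-association components from trans-eQTL summary statistics.

## The problem

Most trait-associated variants discovered by GWAS are regulatory, and much of
their effect on expression is *trans*: a variant perturbs a nearby (cis) gene
and the perturbation propagates through regulatory networks to genes far away
(at least 5 Mb, or on another chromosome).  Standard trans-eQTL mapping tests
every variant-gene pair separately; after correcting for millions of tests,
the individually weak distal effects that carry most of the signal are lost.

`archie` is for statistical geneticists who have **summary statistics** from a
trans-eQTL scan (Z score and p-value per variant-gene pair, eQTLGen-style),
plus reference panels for linkage disequilibrium (LD) and gene co-expression.
It aggregates many weak trans associations between a trait's variants and
distal genes into a small number of testable *components*, returning sparse
sets of variants and target genes that move together.

## The method

Let `Z` be the p x g matrix of trans-eQTL Z statistics between the p
trait-associated variants and g distal genes.  With an LD matrix
`Sigma_GG` (reference genotypes), a penalized co-expression matrix
`Sigma_EE` (reference expression, shrunk toward the identity), and the
cross-correlation `Sigma_GE` implied by `Z`, form the correlation-adjusted
matrix

```
W = Sigma_EE^(-1/2)  Sigma_GE  Sigma_GG^(-1/2)        (genes x variants)
```

and solve the sparse canonical correlation problem

```
max  v' W u    s.t.  ||u||_2 = ||v||_2 = 1,  ||u||_1 <= c_u,  ||v||_1 <= c_v.
```

The non-zero entries of `u` (variant component) and `v` (gene component)
define the selected variants and target genes; successive components come
from rank-one deflation.  Each pair is summarized by its cc-value

```
q^2 = (v' W u)^2 / sqrt( (u' W' W u) (v' W W' v) )   in [0, 1].
```

Significance is assessed by resampling.  The *competitive null* rebuilds the
matrix from variants associated with **other** traits (one variant per
randomly chosen trait) and freshly sampled genes -- the genome-wide background
of trans signal any GWAS variant set carries -- and asks whether the observed
cc-values exceed that background.  The *global null* draws matrices with the
correct LD/co-expression structure but no variant-gene association
(`vec(Sigma_GE;null) ~ N(0, Sigma_EE (x) Sigma_GG)`).  The p-value of the
k-th component is the fraction of null cc-values at rank k reaching the
observed one, and the number of significant leading components is
`L = min{k : p_k > alpha} - 1`.

The package also includes

* a linear structural-equation simulator of cis/trans regulatory networks
  (40 SNPs in blocks of five, 8 cis genes, 9 downstream genes; sparse,
  dense, master-regulator and global-null presets) with heritabilities
  calibrated analytically by path counting -- average cis heritability
  20-22%, average downstream trans heritability 10-14% -- and a type-I
  error / power harness comparing the component test with per-pair mapping;
* trans-imputed expression scores (TIES), `sum_i Z_ij x_ik / sqrt(2 m_i (1 -
  m_i))`, with a multi-gene phenotype regression and resampling tests for
  enrichment of trait heritability in an independent cohort.

## Worked example

A fully synthetic run: simulate a sparse regulatory network, map trans-eQTLs
in a cohort of 2,000, whiten, extract three components, and test them against
the global null.

```r
library(archie)
net  <- calibrate_effects(build_network("sparse", seed = 2))
geno <- simulate_genotypes(2000, seed = 5)
expr <- simulate_expression(net, geno$dosages, geno$mafs, seed = 6)
sm   <- map_trans_eqtl(geno$dosages, expr, gene_subset = net$downstream)
ld   <- estimate_ld(geno$dosages)
co   <- network_coexpression(net)
W    <- build_w(sm, ld, co, map = "t")
fit  <- fit_components(W, 3)
ens  <- null_ensemble_global(co, ld, K = 3, M = 99,
                             cfg = scca_config(fit$c_u, fit$c_v), seed = 7)
sig  <- component_pvalues(fit$q2, ens)
select_significant(sig, 0.05)
```

Output:

```
archie_network [sparse]: 40 SNPs -> 8 cis genes -> 9 downstream genes (calibrated)
  mean cis h2 = 0.210, mean downstream trans h2 = 0.120
archie_component_set: 3 components (c_u = 2.6, c_v = 1.6)
archie_component (rank 1): q2 = 0.9760, 15 variants / 5 genes selected
archie_component (rank 2): q2 = 0.9728, 25 variants / 5 genes selected
archie_component (rank 3): q2 = 0.9641, 22 variants / 4 genes selected
archie_significance: 3 components, M = 99 resamples
  p-values: < 0.0101, < 0.0101, < 0.0101
L = 3
```

The network genuinely carries SNP-to-downstream-gene signal (average trans
heritability 12%), and all three components beat every one of the 99 global
null draws (`p < 1/99`), so `L = 3` components are declared significant.
Their non-zero loadings name the variants and genes doing the work.  On a
global-null network the same pipeline returns `L = 0` at the nominal rate or
less.

For file-based runs, `run_pipeline()` takes a YAML/list configuration
(summary TSV, annotation, reference panels, trait label, sparsity, resampling
sizes, seeds) and writes component TSVs, a JSON significance report and a
reconstructible log; `make_fixtures()` generates a complete synthetic input
bundle.  A thin command-line front end lives at `inst/cli/archie.R`
(subcommands `run`, `fixtures`, `type1`, `power`).

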