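# ceidca

Inference of miRNA-modulated competing-endogenous-RNA (ceRNA) interactions
by differential correlation analysis.

## The problem

Transcripts that share predicted targeting miRNAs compete for the same
miRNA pool, which couples their expression: a *ce-pair* is two such genes,
and a *ce-triplet* adds one shared (bridging) miRNA. The ceRNA hypothesis
predicts that the coexpression of a ce-pair is not constant but *modulated*
by the abundance of the bridging miRNA. `ceidca` screens sample-paired
miRNA/gene expression matrices (e.g. level-3 tumour array cohorts) for
exactly this signature, at genome scale, and is aimed at systems-biology
groups studying post-transcriptional regulatory networks and
interaction-based prognostic markers.

## The statistic

For each putative triplet (genes *i*, *j*; miRNA *m*), samples are split
into *k* equally-sized strata by the expression of *m* (k = 3 by default:
L/M/H). Within each stratum the Pearson correlation of *i* and *j* is
mapped to the t-domain,

    t = rho * sqrt((N - 2) / (1 - rho^2)),      N = stratum size,

which makes changes comparable across correlation magnitudes. The
interaction score is

    deltaI = max{ t_G : t_G > 0 } - min |t_G|,   deltaI = 0 if no t_G > 0,

the intensification of coexpression in the most-coexpressed stratum (the
*optimized group*, G_opt) relative to the least-coexpressed one. Its null
distribution — *k* independent Student-t(N−2) variates pushed through the
same formula — is simulated once into an empirical lookup table; P-values
are strict tail proportions, Bonferroni-corrected over all putative
triplets. Bonferroni-level cutoffs far beyond Monte-Carlo reach (tail
probabilities around 1e-12) are served by tail-conditioned importance
sampling on the maximal coordinate, cross-checked by closed-form
quadrature.

The package also provides the two mutual-information baselines used for
method comparison (SMI: per-stratum MI in place of t; CMI:
CMI(i; m | j) − MI(i; m), both with permutation inference), ceRNA network
construction with degree/hub/overrepresentation statistics, Kaplan–Meier /
log-rank analysis of interaction-strength signatures including the
seed-then-greedy optimized-subset search, and a synthetic cohort generator
so every stage is testable without downloads.

## Worked example

```r
library(ceidca)

# a 450-sample cohort with one planted miRNA-modulated ce-pair:
# GENE0001-GENE0002 correlate at rho = 0.8 when MIR001 is low, 0 elsewhere
design <- simulation_design(
  n_samples = 450, n_genes = 30, n_mirnas = 3,
  planted = data.frame(gene_i = 1, gene_j = 2, mirna = 1,
                       stratum = "L", rho_opt = 0.8, rho_base = 0),
  seed = 42)
sim <- simulate_cohort(design)

# putative triplets from a target map; null from 10^6 simulated scores
targets  <- cohort_target_map(sim)
triplets <- enumerate_triplets(targets, rownames(sim$genes),
                               rownames(sim$mirnas))
nrow(triplets)
#> [1] 58

null_tab <- build_null_table(df = 148, k = 3, n_draws = 1e6, seed = 1)
delta_threshold(null_tab, 0.01)
#> [1] 2.418113

results <- score_triplets(sim$genes, sim$mirnas, triplets,
                          null_table = null_tab)
subset(results, p_value < 0.01,
       select = c(gene_i, gene_j, mirna, delta_i, p_value, g_opt))
#>     gene_i   gene_j  mirna  delta_i p_value g_opt
#> 1 GENE0001 GENE0002 MIR001 17.77401   1e-06     L

net <- build_network(results, p_cutoff = 0.01)
net
#> ceRNA network: 2 nodes, 1 edges, 1 triplets; connectivity (mean degree) = 1
```

Of the 58 putative triplets, exactly the planted one crosses the 1%
significance threshold (deltaI = 17.8 against a threshold of 2.42 for this
cohort geometry), with the correct optimized group L; its reported P-value
is the 1/n_draws floor of the million-draw table. The 57 null triplets form
no edges.

A shell front end over the same functions lives in `inst/cli/ceidca.R`
(subcommands `run`, `null`, `mi`, `network`, `survival`, `simulate`), e.g.

```sh
Rscript inst/cli/ceidca.R null --df 171 --k 3 --draws 1e6 --seed 1 --out null.tsv
```

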