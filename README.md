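# vprotqtl

Quantitative genetics of cell-to-cell protein expression variability.

`vprotqtl` is an R package for analysts who want to go from raw single-cell
flow-cytometry event tables to the genetic architecture of expression
*noise*: which loci, and which causal paths, make one person's cells more
heterogeneous than another's in how much of a protein they display.

The pipeline has five analytic stages plus a ground-truth simulator:

1. **Cytometry preprocessing** — event-count QC (< 1000 events rejected),
   biexponential (default `asinh`) transform, cross-sample landmark
   normalization, FSC-A/FSC-H doublet removal, rectangular gating,
   cell-volume normalization (volume = log10 of the cubed forward-scatter
   area), and per-(individual, cell type, protein) summaries
   (n ≥ 100 cells, mean, CV² = s²/mean²).
2. **Mean-adjusted variability** — per trait, a local polynomial fit of
   log10 CV² on log10 mean across individuals; the standardized residuals
   η_res (mean 0, variance 1) are the variability phenotype, decoupled
   from mean expression.
3. **Twin ACE decomposition** — Gaussian maximum likelihood with
   covariance σ²_A·K + σ²_C·S + σ²_E·I (K: 1 MZ / 0.5 DZ kinship; S:
   within-pair shared environment), path-coefficient parametrization,
   75%-of-pairs bootstrap SEs, and zygosity-permutation p-values.
4. **Variability-QTL mapping** — MAF/HWE variant QC, GCTA-style
   standardized GRMs with leave-one-chromosome-out versions, REML linear
   mixed model y = α + gγ + Xβ + Zu + ε with per-SNP t-tests, 1 Mb cis
   windows with Beta-approximation permutation adjustment, BH FDR, greedy
   LD clumping (250 kb, r² > 0.5), strand-aware varSNP annotation and
   MAF-matched TSS-proximity enrichment.
5. **Two-sample Mendelian randomization** — instrument selection (200 kb,
   p ≤ 1e-5, cell-type matched), allele harmonization, Wald ratio /
   maximum likelihood / IVW / MR-Egger, Cochran's Q, and an FDR-controlled
   screen over (eGene exposure, variability-trait outcome) pairs.

The `synthgen` module simulates every input with known truth: LD-block
genotypes (Markov copying haplotypes), MZ/DZ twin cohorts with correct
allele sharing, ACE-structured latent expression parameters, single-cell
event tables with doublets, and confounded/pleiotropic causal chains with
two-sample summary statistics.

## Worked example

Simulate a 300-pair twin cohort in which one SNP (`snp0025`) raises the
dispersion of a protein, run the cytometry and variability stages, and ask
whether the heritability and the locus are recovered:

```r
library(vprotqtl)

cfg <- sim_config(seed = 42, n_mz_pairs = 150, n_dz_pairs = 150,
                  n_individuals = 0, n_snps = 200, n_chromosomes = 2,
                  ld_rho = 0.9, ld_block_size = 10,
                  ace_fractions = c(0.5, 0.1, 0.4),
                  qtl_effects = data.frame(snp = 25, beta_mean = 0,
                                           beta_var = 0.4),
                  n_cells_per_individual = 1500, doublet_rate = 0.05)

cohort  <- simulate_twin_cohort(cfg)
truth   <- simulate_latent_traits(cohort$genotypes, cohort$pedigree, cfg)
samples <- setNames(lapply(seq_len(nrow(truth)), function(i)
  simulate_cells(truth[i, ], cfg)), truth$id)

cyt <- process_cytometry(samples, channel = "FL1-A",
                         cell_type = "Tcell", protein = "CD45")
head(cyt$summaries, 3)
#>  individual cell_type protein n_cells      mean        cv2
#>     ind0001     Tcell    CD45    1426 0.1705740 0.01311605
#>     ind0002     Tcell    CD45    1428 0.1803013 0.01981240
#>     ind0003     Tcell    CD45    1427 0.1689888 0.00281859

eta <- eta_res_matrix(cyt$summaries)        # individuals x traits, mean 0 / var 1

ped <- cohort$pedigree[match(rownames(eta), cohort$pedigree$id), ]
ace_fit(eta[, 1], ped)$fractions
#>    a2    c2    e2
#> 0.549 0.094 0.357
```

The generating fractions were (0.5, 0.1, 0.4): about half the variance in
cell-to-cell variability is additive-genetic in this world, and the fit
recovers that through the full measurement layer (cells, doublets, volume
normalization, η_res).

```r
qc <- qc_variants(cohort$genotypes)
sc <- lmm_scan(eta[, 1], NULL,
               qc$genotypes$dosages[match(rownames(eta),
                                          qc$genotypes$individuals), ],
               compute_grm(qc$genotypes))
head(sc[order(sc$p), ], 3)
#>      snp      beta        se        t            p
#>  snp0025 0.3950026 0.1147414 3.442547 0.0006165176
#>  snp0028 0.3668554 0.1130783 3.244261 0.0012432304
#>  snp0024 0.3157386 0.1143592 2.760939 0.0059404342

ld_clump(sc[, c("snp", "p")], qc$genotypes, p_index = 1e-3)
#>  index_snp      index_p n_members members
#>    snp0025 0.0006165176         0
```

The causal variant is the top association (per-allele effect 0.40
simulated, 0.395 ± 0.115 estimated), its LD-block neighbours rank next,
and clumping at a demo-scale index threshold collapses the locus to the
causal SNP. At this small cohort size the effect is far from genome-wide
significance — the acceptance suite demonstrates recovery at p < 5e-8
with n = 800.

A one-call orchestration of all stages, with per-stage outputs and a JSON
manifest, is available as:

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "my_run"))
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the statistical
models, their assumptions, every tunable threshold with its default, what
the simulator does and does not emulate, and the numerical choices made
where the design was genuinely open.
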