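test_that("sim_config validates its invariants", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(sim_config(ace_fractions = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(sim_config(doublet_rate = 1), "doublet_rate")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
})

test_that("genotype simulation is deterministic and respects LD structure", {
  cfg <- sim_config(seed = 42, n_individuals = 300, n_snps = 40,
                    ld_rho = 0, ld_block_size = 10)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  expect_true(all(g1$dosages %in% 0:2))
  expect_equal(dim(g1$dosages), c(300L, 40L))

  # independence case: pairwise genotype correlations near 0
  cors <- stats::cor(g1$dosages)
  off <- cors[upper.tri(cors)]
  expect_gt(mean(abs(off) < 3 / sqrt(300)), 0.95)

  # copying model: stationary adjacent-haplotype correlation ~ ld_rho when
  # allele frequencies are equal
  cfg2 <- sim_config(seed = 7, n_individuals = 1000, n_snps = 40,
                     ld_rho = 0.9, ld_block_size = 10,
                     maf_range = c(0.3, 0.3))
  gs <- simulate_genotypes(cfg2)
  H <- rbind(gs$haplotypes$H1, gs$haplotypes$H2)  # 2000 haplotype pairs
  adj <- sapply(setdiff(2:40, seq(11, 40, by = 10)),
                function(k) stats::cor(H[, k - 1], H[, k]))
  expect_lt(abs(mean(adj) - 0.9), 0.05)
})

test_that("twin cohorts share genotypes per zygosity", {
  cfg <- sim_config(seed = 11, n_individuals = 100, n_mz_pairs = 80,
                    n_dz_pairs = 80, n_snps = 200)
  tc <- simulate_twin_cohort(cfg)
  ped <- tc$pedigree
  expect_true(all(table(ped$family[ped$zygosity != "unrelated"]) == 2))

  # MZ: identical genotype vectors
  for (f in unique(ped$family[ped$zygosity == "MZ"])[1:10]) {
    idx <- which(ped$family == f)
    expect_identical(tc$genotypes$dosages[idx[1], ],
                     tc$genotypes$dosages[idx[2], ])
  }
  # DZ: per-variant co-twin correlation ~ 0.5
  expect_lt(abs(pairwise_geno_cor(tc$genotypes, ped, "DZ") - 0.5), 0.05)
  # unrelated: correlation ~ 0
  G <- tc$genotypes$dosages[ped$zygosity == "unrelated", ]
  cc <- stats::cor(t(scale(G, scale = FALSE)))
  expect_lt(abs(mean(cc[upper.tri(cc)])), 0.05)
})

test_that("latent traits reproduce the ACE twin-correlation identities", {
  # pure noise: within-MZ correlation ~ 0
  cfg0 <- sim_config(seed = 5, n_individuals = 0, n_mz_pairs = 300,
                     n_dz_pairs = 50, n_snps = 20,
                     ace_fractions = c(0, 0, 1))
  tc0 <- simulate_twin_cohort(cfg0)
  lt0 <- simulate_latent_traits(tc0$genotypes, tc0$pedigree, cfg0)
  mz <- tc0$pedigree$zygosity == "MZ"
  fam <- unique(tc0$pedigree$family[mz])
  pairs <- t(sapply(fam, function(f)
    lt0$latent_var[tc0$pedigree$family == f]))
  expect_lt(abs(stats::cor(pairs[, 1], pairs[, 2])), 0.12)

  # a2 = 0.6, c2 = 0: r_MZ ~ 0.6, r_DZ ~ 0.3
  cfg1 <- sim_config(seed = 6, n_individuals = 0, n_mz_pairs = 500,
                     n_dz_pairs = 500, n_snps = 20,
                     ace_fractions = c(0.6, 0, 0.4))
  tc1 <- simulate_twin_cohort(cfg1)
  lt1 <- simulate_latent_traits(tc1$genotypes, tc1$pedigree, cfg1)
  twin_r <- function(z) {
    fams <- unique(tc1$pedigree$family[tc1$pedigree$zygosity == z])
    p <- t(sapply(fams, function(f)
      lt1$latent_var[tc1$pedigree$family == f]))
    stats::cor(c(p[, 1], p[, 2]), c(p[, 2], p[, 1]))
  }
  expect_lt(abs(twin_r("MZ") - 0.6), 0.06)
  expect_lt(abs(twin_r("DZ") - 0.3), 0.06)

  # single QTL of 0.5 on the standardized trait scale: OLS recovery
  cfg2 <- sim_config(seed = 8, n_individuals = 600,
                     n_snps = 30, maf_range = c(0.3, 0.3),
                     ace_fractions = c(0, 0, 1),
                     qtl_effects = data.frame(snp = 4, beta_mean = 0,
                                              beta_var = 0.5))
  g2 <- simulate_genotypes(cfg2)
  lt2 <- simulate_latent_traits(g2, NULL, cfg2)
  f <- summary(stats::lm(lt2$latent_var ~ g2$dosages[, 4]))$coefficients
  expect_lt(abs(f[2, 1] - 0.5), 2 * f[2, 2])

  # referencing an absent variant is an error
  cfg3 <- sim_config(seed = 1, n_snps = 10,
                     qtl_effects = data.frame(snp = 99, beta_mean = 0,
                                              beta_var = 1))
  g3 <- simulate_genotypes(sim_config(seed = 1, n_snps = 10))
  expect_error(simulate_latent_traits(g3, NULL, cfg3), "absent variant")
})

test_that("latent trait variance bookkeeping holds", {
  cfg <- sim_config(seed = 13, n_individuals = 4000, n_snps = 20,
                    maf_range = c(0.3, 0.3), ace_fractions = c(0.4, 0.2, 0.4),
                    qtl_effects = data.frame(snp = 2, beta_mean = 0,
                                             beta_var = 0.4))
  g <- simulate_genotypes(cfg)
  lt <- simulate_latent_traits(g, NULL, cfg)
  expected <- 0.4^2 * 2 * 0.3 * 0.7 + 1  # SNP variance + A + C + E
  expect_lt(abs(stats::var(lt$latent_var) / expected - 1), 0.05)
})

test_that("simulated cells carry the doublet geometry and dispersion", {
  cfg0 <- sim_config(seed = 3, n_cells_per_individual = 2000,
                     doublet_rate = 0)
  prm <- list(id = "ind0001", mu = 2.5, sigma = 0.25, volume_mean = 5e4)
  ev <- simulate_cells(prm, cfg0)
  ratio <- ev[["FSC-A"]] / ev[["FSC-H"]]
  expect_true(all(ratio > 0.8 & ratio < 1.3))

  # doublet fraction shows up in the pulse-shape ratio
  cfg1 <- sim_config(seed = 3, n_cells_per_individual = 10000,
                     doublet_rate = 0.1)
  ev1 <- simulate_cells(prm, cfg1)
  expect_lt(abs(mean(ev1[["FSC-A"]] / ev1[["FSC-H"]] > 1.5) - 0.1), 0.01)

  expect_error(simulate_cells(list(id = "x", mu = 2, sigma = 0,
                                   volume_mean = 5e4), cfg0), "sigma")

  # doubling sigma increases the CV^2 of volume-normalized expression in
  # nearly all replicate individuals (scaled-down replicate count)
  cv2_of <- function(sigma, seed) {
    cfg <- sim_config(seed = seed, n_cells_per_individual = 800)
    e <- simulate_cells(list(id = seed, mu = 2.5, sigma = sigma,
                             volume_mean = 5e4), cfg)
    v <- volume_normalize(e[["FL1-A"]], cell_volume(e[["FSC-A"]]))$values
    stats::var(v) / mean(v)^2
  }
  wins <- sum(vapply(1:40, function(s) cv2_of(0.5, s) > cv2_of(0.25, s),
                     logical(1)))
  expect_gte(wins, 38)
})

test_that("MR chain algebra and two-sample layout are correct", {
  # no pleiotropy/confounding: Wald ratio consistent for beta_causal
  ch <- simulate_mr_chain(5000, beta_gx = 0.5, beta_causal = 0.4, seed = 2)
  expect_lt(abs(ch$outcome$beta / ch$exposure$beta - 0.4), 0.1)
  expect_equal(nrow(ch$data), 10000)

  # beta_gx = 0: exposure p uniform over seeds
  ps <- vapply(1:60, function(s)
    simulate_mr_chain(300, beta_gx = 0, beta_causal = 0.4,
                      seed = s)$exposure$p, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # determinism
  expect_identical(simulate_mr_chain(100, seed = 9)$exposure,
                   simulate_mr_chain(100, seed = 9)$exposure)
})

test_that("genotype writers and readers round-trip", {
  cfg <- sim_config(seed = 21, n_individuals = 25, n_snps = 12)
  gs <- simulate_genotypes(cfg)
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(gs, vcf)
  back <- read_vcf(vcf)
  expect_equal(unname(back$dosages), unname(gs$dosages))
  expect_equal(back$variants$pos, gs$variants$pos)

  tsv <- tempfile(fileext = ".tsv")
  write_dosage_tsv(gs, tsv)
  back2 <- read_dosage_tsv(tsv)
  expect_equal(unname(back2$dosages), unname(gs$dosages))
})
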