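test_that("Hardy-Weinberg chi-squared matches hand computations", {
  expect_equal(hwe_chi2(25, 50, 25)$chi2, 0)
  expect_equal(hwe_chi2(25, 50, 25)$p, 1)
  # counts (30, 30, 40), p_hat = 0.45, expected (20.25, 49.5, 30.25)
  h <- hwe_chi2(30, 30, 40)
  expect_equal(h$chi2,
               9.75^2 / 20.25 + 19.5^2 / 49.5 + 9.75^2 / 30.25)
  expect_equal(round(h$chi2, 2), 15.52)
  expect_equal(hwe_chi2(50, 0, 50)$chi2, 100)
  expect_error(hwe_chi2(10, 0, 0), "monomorphic")
})

test_that("variant QC applies the MAF and HWE rules at their boundaries", {
  # dosage columns engineered to exact frequencies over 200 individuals
  n <- 400
  g_low <- c(rep(1, 2), rep(0, n - 2))            # MAF 0.0025 < 1%
  g_edge <- c(rep(1, 8), rep(0, n - 8))           # MAF 0.01 exactly
  g_hwe <- c(rep(2, n / 2), rep(0, n / 2))        # no hets: chi2 = n, p << 1e-50
  g_ok <- rep(c(0, 1, 1, 2), n / 4)
  G <- cbind(v1 = g_low, v2 = g_edge, v3 = g_hwe, v4 = g_ok)
  gs <- structure(list(
    variants = data.frame(id = colnames(G), chrom = 1L,
                          pos = 1:4 * 1000L, ref = "A", alt = "G",
                          maf = NA),
    dosages = G, individuals = sprintf("i%03d", 1:n)),
    class = "genotype_set")
  res <- qc_variants(gs)
  expect_false("v1" %in% res$genotypes$variants$id)  # MAF < 1% out
  expect_true("v2" %in% res$genotypes$variants$id)   # exactly 1% stays
  expect_false("v3" %in% res$genotypes$variants$id)  # extreme HWE out
  expect_true("v4" %in% res$genotypes$variants$id)
  expect_equal(res$report$reason[1], "maf")
  expect_equal(res$report$reason[3], "hwe")
})

test_that("GRM standardization matches the direct formula", {
  gs <- structure(list(
    variants = data.frame(id = "v1", chrom = 1L, pos = 100L,
                          ref = "A", alt = "G", maf = 0.5),
    dosages = matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "v1")),
    individuals = c("a", "b", "c")), class = "genotype_set")
  grm <- compute_grm(gs)
  # z = (g - 1)/sqrt(0.5): diag entries {2, 0, 2}
  expect_equal(diag(grm$matrix), c(2, 0, 2), ignore_attr = TRUE)
  expect_equal(grm$m, 1)

  # identical genotype rows give off-diagonal equal to diagonal
  cfg <- sim_config(seed = 51, n_individuals = 0, n_mz_pairs = 5,
                    n_dz_pairs = 5, n_snps = 500)
  tc <- simulate_twin_cohort(cfg)
  # tiny cohort: some variants are monomorphic and skipped with a warning
  g <- suppressWarnings(compute_grm(tc$genotypes))
  i <- which(tc$pedigree$family == tc$pedigree$family[1])
  expect_lt(abs(g$matrix[i[1], i[2]] -
                  (g$matrix[i[1], i[1]] + g$matrix[i[2], i[2]]) / 2), 1e-8)

  # unrelated cohort: off-diagonals concentrate near 0, diagonal near 1
  cfg2 <- sim_config(seed = 52, n_individuals = 150, n_snps = 5000)
  gs2 <- simulate_genotypes(cfg2)
  g2 <- compute_grm(gs2)
  off <- g2$matrix[upper.tri(g2$matrix)]
  expect_lt(abs(mean(off)), 0.02)
  expect_lt(abs(mean(diag(g2$matrix)) - 1), 0.1)
})

test_that("leave-one-chromosome-out GRMs satisfy the additivity identity", {
  cfg <- sim_config(seed = 53, n_individuals = 80, n_snps = 60,
                    n_chromosomes = 3)
  gs <- simulate_genotypes(cfg)
  grms <- loco_grms(gs)
  m_all <- grms$all$m
  for (cn in names(grms$per_chromosome)) {
    mc <- grms$per_chromosome[[cn]]$m
    mn <- grms$complement[[cn]]$m
    expect_equal(mc + mn, m_all)
    recon <- (mc * grms$per_chromosome[[cn]]$matrix +
                mn * grms$complement[[cn]]$matrix) / m_all
    expect_lt(max(abs(recon - grms$all$matrix)), 1e-10)
  }
  # single-chromosome genome has no complement
  cfg1 <- sim_config(seed = 54, n_individuals = 20, n_snps = 10,
                     n_chromosomes = 1)
  expect_error(loco_grms(simulate_genotypes(cfg1)), "at least 2")
})

test_that("the scan equals OLS when the relatedness matrix is identity", {
  set.seed(55)
  n <- 200
  X <- cbind(1, age = runif(n, 20, 70))
  G <- matrix(rbinom(n * 30, 2, 0.3), n,
              dimnames = list(NULL, paste0("s", 1:30)))
  y <- X %*% c(1, 0.01) + 0.3 * G[, 5] + rnorm(n)
  # explicit identity GRM exercises the eigendecomposition path too
  id_grm <- structure(list(matrix = diag(n), m = NA), class = "grm")
  for (grm in list(NULL, id_grm)) {
    sc <- lmm_scan(y, X, G, grm)
    for (j in c(1, 5, 18)) {
      o <- summary(stats::lm(y ~ 0 + X + G[, j]))$coefficients
      expect_equal(sc$beta[j], o[3, 1], tolerance = 1e-8)
      expect_equal(sc$se[j], o[3, 2], tolerance = 1e-8)
      expect_equal(sc$p[j], o[3, 4], tolerance = 1e-8)
    }
  }
})

test_that("REML recovers variance components on a structured GRM", {
  cfg <- sim_config(seed = 57, n_individuals = 0, n_mz_pairs = 250,
                    n_dz_pairs = 250, n_snps = 30,
                    ace_fractions = c(0.5, 0, 0.5))
  tc <- simulate_twin_cohort(cfg)
  lt <- simulate_latent_traits(tc$genotypes, tc$pedigree, cfg)
  K <- relatedness_matrices(tc$pedigree)$K
  grm <- structure(list(matrix = K, m = NA), class = "grm")
  null <- fit_lmm_null(lt$latent_var, NULL, grm)
  expect_lt(abs(null$sigma_g2 - 0.5), 0.1)
  expect_lt(abs(null$sigma_e2 - 0.5), 0.1)
  # exact linear trait: both components collapse to zero
  X <- cbind(1, rnorm(nrow(K)))
  null0 <- fit_lmm_null(X %*% c(2, 0.5), X, grm)
  expect_lt(null0$sigma_g2 + null0$sigma_e2, 1e-6)
  # a SNP effect is recovered within 2 SE
  cfg2 <- sim_config(seed = 58, n_individuals = 800, n_snps = 40,
                     maf_range = c(0.3, 0.3), ace_fractions = c(0, 0, 1),
                     qtl_effects = data.frame(snp = 10, beta_mean = 0,
                                              beta_var = 0.5))
  gs2 <- simulate_genotypes(cfg2)
  lt2 <- simulate_latent_traits(gs2, NULL, cfg2)
  sc <- lmm_scan(lt2$latent_var, NULL, gs2$dosages)
  expect_lt(abs(sc$beta[10] - 0.5), 2 * sc$se[10])
})

test_that("a SNP collinear with covariates is flagged with missing p", {
  set.seed(59)
  n <- 100
  x <- rbinom(n, 2, 0.4)
  X <- cbind(1, x)
  G <- cbind(s1 = x, s2 = rbinom(n, 2, 0.4))
  sc <- lmm_scan(rnorm(n), X, G)
  expect_true(is.na(sc$p[1]))
  expect_false(is.na(sc$p[2]))
})

test_that("cis windows are closed 1 Mb intervals on the gene chromosome", {
  gene <- list(chrom = 2L, tss = 10000000L)
  vt <- data.frame(chrom = c(2L, 2L, 2L, 2L, 3L),
                   pos = c(9500000L, 10500000L, 9499999L, 10500001L,
                           10000000L))
  expect_equal(cis_window(gene, vt), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(cis_window(list(chrom = 1, tss = NA), vt), "TSS")
})

test_that("BH adjustment matches the hand computation", {
  out <- fdr_bh(c(0.01, 0.02, 0.04), q = 0.05)
  expect_equal(out$q_value, c(0.03, 0.03, 0.04))
  expect_true(all(out$discovery))
  expect_equal(fdr_bh(0.2)$q_value, 0.2)
  expect_false(any(fdr_bh(rep(1, 5), q = 0.5)$discovery))
})

test_that("greedy clumping matches the hand-worked example", {
  # A (p=1e-6), B (p=1e-5, near A, r2 high), C (p=2e-5, r2 with A low)
  set.seed(61)
  n <- 400
  a <- rbinom(n, 2, 0.4)
  b <- ifelse(runif(n) < 0.93, a, rbinom(n, 2, 0.4))   # r2 > 0.5 with a
  cc <- rbinom(n, 2, 0.4)                               # independent
  G <- cbind(A = a, B = b, C = cc)
  gs <- structure(list(
    variants = data.frame(id = c("A", "B", "C"), chrom = 1L,
                          pos = c(50000L, 60000L, 70000L),
                          ref = "A", alt = "G", maf = 0.4),
    dosages = G, individuals = sprintf("i%03d", 1:n)),
    class = "genotype_set")
  assoc <- data.frame(snp = c("A", "B", "C"), p = c(1e-6, 1e-5, 2e-5))
  cl <- ld_clump(assoc, gs, p_index = 1e-4)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$index_snp, c("A", "C"))
  expect_equal(cl$members[1], "B")
  expect_equal(cl$n_members[2], 0)
  # empty result when nothing passes
  expect_equal(nrow(ld_clump(assoc, gs, p_index = 1e-9)), 0)
})

test_that("clumping is identical to a brute-force greedy reference", {
  for (inst in 1:50) {
    set.seed(700 + inst)
    n <- 60; m <- 200
    cfg <- sim_config(seed = 700 + inst, n_individuals = n, n_snps = m,
                      ld_rho = 0.7, ld_block_size = 8, n_chromosomes = 2)
    gs <- simulate_genotypes(cfg)
    assoc <- data.frame(snp = gs$variants$id, p = runif(m)^4)
    cl <- ld_clump(assoc, gs, p_index = 0.01)
    ref <- brute_clump(assoc, gs$variants, gs$dosages, 0.01, 0.5, 250000)
    expect_equal(nrow(cl), length(ref))
    for (i in seq_len(nrow(cl))) {
      expect_equal(cl$index_snp[i], ref[[i]]$index)
      got <- if (cl$members[i] == "") character(0)
             else strsplit(cl$members[i], ";")[[1]]
      expect_setequal(got, ref[[i]]$members)
    }
    # partition property: nobody assigned twice, everyone accounted for
    all_ids <- c(cl$index_snp,
                 unlist(strsplit(cl$members[cl$members != ""], ";")))
    expect_equal(sort(all_ids), sort(assoc$snp[assoc$p <= 0.01]))
  }
})

test_that("varSNP annotation is strand-aware", {
  gm <- data.frame(gene = c("gplus", "gminus"),
                   chrom = c(1L, 1L),
                   start = c(100000L, 300000L), end = c(120000L, 320000L),
                   tss = c(100000L, 320000L),
                   strand = c("+", "-"))
  snps <- data.frame(snp = c("in_body", "up_plus", "down_plus",
                             "near_minus_tss", "far"),
                     chrom = 1L,
                     pos = c(110000L, 97000L, 123000L, 323000L, 200000L))
  ann <- annotate_varsnps(snps, gm)
  expect_equal(ann$category,
               c("transcribed", "upstream", "downstream", "upstream",
                 "intergenic"))
  # the same offset 3 kb beyond a minus-strand gene's start is downstream
  ann2 <- annotate_varsnps(data.frame(snp = "s", chrom = 1L, pos = 297000L),
                           gm[2, , drop = FALSE])
  expect_equal(ann2$category, "downstream")
  # signed TSS distance respects orientation
  expect_equal(ann$tss_distance[ann$snp == "up_plus"], -3000)
  expect_equal(ann$tss_distance[ann$snp == "near_minus_tss"], -3000)
  expect_warning(
    annotate_varsnps(data.frame(snp = "x", chrom = 9L, pos = 1L), gm),
    "absent")
})

test_that("TSS enrichment reproduces the cross-product odds ratio", {
  set.seed(63)
  gm <- data.frame(chrom = 1L, tss = 0L)
  # cases: 30 of 100 within 100 kb; controls: 20 of 100
  cases <- data.frame(snp = sprintf("c%03d", 1:100), chrom = 1L,
                      pos = c(rep(50000L, 30), rep(500000L, 70)),
                      maf = runif(100, 0.2, 0.25))
  pool <- data.frame(snp = sprintf("p%03d", 1:100), chrom = 1L,
                     pos = c(rep(50000L, 20), rep(500000L, 80)),
                     maf = runif(100, 0.2, 0.25))
  res <- suppressWarnings(
    tss_enrichment(cases, pool, gm, n_controls_per_case = 1, seed = 2))
  # every control is MAF-eligible, so the full pool is sampled
  expect_equal(sum(res$table["control", ]), 100)
  expect_equal(res$table["case", "near_tss"], 30)
  or_hand <- (res$table[1, 1] * res$table[2, 2]) /
    (res$table[1, 2] * res$table[2, 1])
  expect_equal(res$odds_ratio, or_hand)
  # determinism
  res2 <- suppressWarnings(
    tss_enrichment(cases, pool, gm, n_controls_per_case = 1, seed = 2))
  expect_identical(res$table, res2$table)
  # equal proportions give OR 1
  pool_eq <- cases
  pool_eq$snp <- sprintf("q%03d", 1:100)
  res3 <- suppressWarnings(tss_enrichment(cases, pool_eq, gm, seed = 3))
  expect_equal(res3$odds_ratio, 1)
})

test_that("down-sampling recovery is 1 at the full fraction", {
  cfg <- sim_config(seed = 65, n_individuals = 500, n_snps = 30,
                    maf_range = c(0.3, 0.3), ace_fractions = c(0, 0, 1),
                    qtl_effects = data.frame(snp = 3, beta_mean = 0,
                                             beta_var = 0.8))
  gs <- simulate_genotypes(cfg)
  lt <- simulate_latent_traits(gs, NULL, cfg)
  res <- downsample_sensitivity(lt$latent_var, NULL, gs$dosages,
                                fractions = c(0.1, 0.5, 1.0), seed = 1)
  expect_equal(res$recovery[res$fraction == 1.0], 1.0)
  expect_true(all(res$recovery >= 0 & res$recovery <= 1))
  expect_warning(
    downsample_sensitivity(lt$latent_var[1:50], NULL,
                           gs$dosages[1:50, ], fractions = c(0.1, 1.0),
                           seed = 1),
    "skipped")
})
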