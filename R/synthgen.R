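# Synthetic cohort generator: LD-structured genotypes, MZ/DZ twin cohorts,
# latent per-individual expression parameters, single-cell event tables and
# exposure/outcome causal chains, all with known ground truth.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator into a validated list.
#' Defaults describe a modest desk-scale cohort; parameter-recovery tests
#' override individual fields.
#'
#' @param seed integer seed controlling all randomness downstream.
#' @param n_individuals number of unrelated individuals.
#' @param n_mz_pairs,n_dz_pairs numbers of monozygotic / dizygotic twin pairs.
#' @param n_snps total number of biallelic variants.
#' @param n_chromosomes chromosomes over which variants are spread evenly.
#' @param maf_range length-2 vector of minor allele frequency bounds in
#'   (0, 0.5]; per-variant MAFs are drawn uniformly from this interval.
#' @param ld_rho copying probability between adjacent variants within an LD
#'   block, in [0, 1). With equal allele frequencies the stationary
#'   haplotype correlation of adjacent variants equals \code{ld_rho}.
#' @param ld_block_size number of variants per LD block; blocks independent.
#' @param ace_fractions triple (a2, c2, e2) of additive-genetic, common- and
#'   unique-environment variance fractions; must sum to 1.
#' @param qtl_effects data.frame with columns \code{snp} (variant index),
#'   \code{beta_mean}, \code{beta_var}: per-allele effects on the latent
#'   mean-scale and dispersion-scale traits. \code{NULL} for no QTLs.
#' @param n_cells_per_individual singlet events simulated per individual.
#' @param doublet_rate fraction of events that are doublets, in [0, 1).
#' @param confounder_snp optional variant index whose genotype shifts the
#'   latent mean additively (a reagent-interaction stand-in); \code{NA} to
#'   disable.
#' @param confounder_beta additive per-allele effect of the confounder SNP
#'   on the latent mean.
#' @return object of class \code{sim_config} (a named list).
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 200L,
                       n_mz_pairs = 0L,
                       n_dz_pairs = 0L,
                       n_snps = 100L,
                       n_chromosomes = 2L,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0,
                       ld_block_size = 10L,
                       ace_fractions = c(a2 = 0.4, c2 = 0.2, e2 = 0.4),
                       qtl_effects = NULL,
                       n_cells_per_individual = 1000L,
                       doublet_rate = 0,
                       confounder_snp = NA_integer_,
                       confounder_beta = 0) {
  stopifnot(length(maf_range) == 2L, length(ace_fractions) == 3L)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be ordered and within (0, 0.5]")
  if (abs(sum(ace_fractions) - 1) > 1e-12)
    stop("ace_fractions must sum to 1")
  if (any(ace_fractions < 0)) stop("ace_fractions must be non-negative")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (doublet_rate < 0 || doublet_rate >= 1) stop("doublet_rate must be in [0, 1)")
  if (!is.null(qtl_effects)) {
    stopifnot(is.data.frame(qtl_effects),
              all(c("snp", "beta_mean", "beta_var") %in% names(qtl_effects)))
  }
  cfg <- list(seed = as.integer(seed),
              n_individuals = as.integer(n_individuals),
              n_mz_pairs = as.integer(n_mz_pairs),
              n_dz_pairs = as.integer(n_dz_pairs),
              n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              maf_range = as.numeric(maf_range),
              ld_rho = as.numeric(ld_rho),
              ld_block_size = as.integer(ld_block_size),
              ace_fractions = stats::setNames(as.numeric(ace_fractions),
                                              c("a2", "c2", "e2")),
              qtl_effects = qtl_effects,
              n_cells_per_individual = as.integer(n_cells_per_individual),
              doublet_rate = as.numeric(doublet_rate),
              confounder_snp = confounder_snp,
              confounder_beta = confounder_beta)
  class(cfg) <- "sim_config"
  cfg
}

# haplotype block under the first-order copying model: n_hap x m matrix of
# 0/1 alleles; adjacent columns copy with probability rho, else redraw at
# the variant's own frequency.
.sim_hap_block <- function(n_hap, p, rho) {
  m <- length(p)
  H <- matrix(0L, n_hap, m)
  H[, 1] <- stats::rbinom(n_hap, 1L, p[1])
  if (m > 1L) {
    for (k in 2:m) {
      copy <- stats::runif(n_hap) < rho
      fresh <- stats::rbinom(n_hap, 1L, p[k])
      H[, k] <- ifelse(copy, H[, k - 1L], fresh)
    }
  }
  H
}

.sim_haplotypes <- function(n_hap, p, cfg) {
  m <- length(p)
  blocks <- split(seq_len(m), ceiling(seq_len(m) / cfg$ld_block_size))
  H <- matrix(0L, n_hap, m)
  for (idx in blocks) H[, idx] <- .sim_hap_block(n_hap, p[idx], cfg$ld_rho)
  H
}

.variant_table <- function(cfg, p) {
  m <- cfg$n_snps
  chrom <- rep(seq_len(cfg$n_chromosomes), length.out = m)
  chrom <- sort(chrom)
  pos <- integer(m)
  for (c in unique(chrom)) {
    n_c <- sum(chrom == c)
    pos[chrom == c] <- as.integer(seq(10000L, by = 10000L, length.out = n_c))
  }
  data.frame(id = sprintf("snp%04d", seq_len(m)),
             chrom = chrom, pos = pos,
             ref = "A", alt = "G",
             maf = p,
             stringsAsFactors = FALSE)
}

#' Simulate LD-structured biallelic genotypes for unrelated individuals
#'
#' Diploid dosages are sums of two independent haplotypes generated by a
#' first-order Markov copying model within LD blocks; blocks and chromosomes
#' are independent. Variants are evenly spaced along each chromosome.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{genotype_set}: list with \code{variants} (data.frame: id,
#'   chrom, pos, ref, alt, maf), \code{dosages} (individuals x variants
#'   integer matrix in \{0,1,2\}), \code{individuals} (character ids).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_snps >= 1L)
  set.seed(config$seed)
  n <- config$n_individuals
  p <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  H1 <- .sim_haplotypes(n, p, config)
  H2 <- .sim_haplotypes(n, p, config)
  G <- H1 + H2
  ids <- sprintf("ind%04d", seq_len(n))
  rownames(G) <- ids
  vt <- .variant_table(config, p)
  colnames(G) <- vt$id
  structure(list(variants = vt, dosages = G, individuals = ids,
                 haplotypes = list(H1 = H1, H2 = H2)),
            class = "genotype_set")
}

#' Simulate a twin cohort with genotype sharing
#'
#' MZ co-twins receive identical genotypes. DZ co-twins are built from four
#' shared parental haplotypes, each child drawing one haplotype per parent
#' independently per LD block, so each allele is shared with probability 1/2
#' in expectation. Remaining individuals are unrelated.
#'
#' @param config a \code{\link{sim_config}} with
#'   \code{n_mz_pairs + n_dz_pairs >= 1}.
#' @return list with \code{pedigree} (data.frame: id, family, zygosity in
#'   MZ/DZ/unrelated) and \code{genotypes} (a \code{genotype_set} covering
#'   all cohort members).
#' @export
simulate_twin_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"),
            config$n_mz_pairs + config$n_dz_pairs >= 1L)
  set.seed(config$seed + 1L)
  m <- config$n_snps
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  vt <- .variant_table(config, p)
  blocks <- split(seq_len(m), ceiling(seq_len(m) / config$ld_block_size))

  draw_child <- function(pat, mat) {
    # pat, mat: list(h1, h2) parental haplotypes; inherit per LD block
    h_p <- integer(m); h_m <- integer(m)
    for (idx in blocks) {
      h_p[idx] <- if (stats::runif(1) < 0.5) pat$h1[idx] else pat$h2[idx]
      h_m[idx] <- if (stats::runif(1) < 0.5) mat$h1[idx] else mat$h2[idx]
    }
    h_p + h_m
  }

  rows <- list(); fam <- character(); zyg <- character()
  G <- list()
  k <- 0L
  for (i in seq_len(config$n_mz_pairs)) {
    g <- .sim_haplotypes(2L, p, config)  # two haplotypes of one genome
    geno <- g[1, ] + g[2, ]
    for (j in 1:2) {
      k <- k + 1L
      G[[k]] <- geno
      fam[k] <- sprintf("famMZ%03d", i); zyg[k] <- "MZ"
    }
  }
  for (i in seq_len(config$n_dz_pairs)) {
    hp <- .sim_haplotypes(4L, p, config)
    pat <- list(h1 = hp[1, ], h2 = hp[2, ])
    mat <- list(h1 = hp[3, ], h2 = hp[4, ])
    for (j in 1:2) {
      k <- k + 1L
      G[[k]] <- draw_child(pat, mat)
      fam[k] <- sprintf("famDZ%03d", i); zyg[k] <- "DZ"
    }
  }
  for (i in seq_len(config$n_individuals)) {
    h <- .sim_haplotypes(2L, p, config)
    k <- k + 1L
    G[[k]] <- h[1, ] + h[2, ]
    fam[k] <- sprintf("famU%04d", i); zyg[k] <- "unrelated"
  }
  Gm <- do.call(rbind, G)
  ids <- sprintf("ind%04d", seq_len(k))
  rownames(Gm) <- ids; colnames(Gm) <- vt$id
  ped <- data.frame(id = ids, family = fam, zygosity = zyg,
                    stringsAsFactors = FALSE)
  gs <- structure(list(variants = vt, dosages = Gm, individuals = ids),
                  class = "genotype_set")
  list(pedigree = ped, genotypes = gs)
}

#' Simulate latent per-individual expression parameters
#'
#' For each individual a dispersion-scale latent trait is generated as
#' \eqn{s_i = \sum_k \gamma_k g_{ik} + A_i + C_f + E_i}, where A is an
#' additive-genetic deviate shared fully within MZ pairs and with
#' correlation 1/2 within DZ pairs, C is shared within families, and E is
#' independent; variances of (A, C, E) equal \code{ace_fractions} before SNP
#' effects. A mean-scale latent trait is generated analogously with its own
#' SNP effects. Latent traits map to log10-scale location \code{mu} and
#' dispersion \code{sigma} of per-cell fluorescence.
#'
#' @param genotypes a \code{genotype_set}.
#' @param pedigree data.frame (id, family, zygosity); all ids must be
#'   genotyped. Unrelated-only designs may pass \code{NULL}.
#' @param config a \code{\link{sim_config}}.
#' @param mu0,sigma0 baseline log10 location and dispersion.
#' @param mu_scale,sigma_scale how strongly the latent traits move
#'   \code{mu} and \code{log(sigma)}.
#' @return data.frame with one row per individual: id, family, zygosity,
#'   latent_mean, latent_var (the raw latent traits), mu, sigma, volume_mean
#'   (mean forward-scatter area), age, confounder_g.
#' @export
simulate_latent_traits <- function(genotypes, pedigree = NULL, config,
                                   mu0 = 2.5, sigma0 = 0.25,
                                   mu_scale = 0.3, sigma_scale = 0.4) {
  stopifnot(inherits(genotypes, "genotype_set"))
  ids <- genotypes$individuals
  if (is.null(pedigree)) {
    pedigree <- data.frame(id = ids, family = paste0("f", seq_along(ids)),
                           zygosity = "unrelated", stringsAsFactors = FALSE)
  }
  if (!all(pedigree$id %in% ids))
    stop("pedigree individuals must be a subset of genotyped individuals")
  set.seed(config$seed + 2L)
  ped <- pedigree[match(ids, pedigree$id), ]
  n <- length(ids)
  fr <- config$ace_fractions
  a <- sqrt(fr["a2"]); cc <- sqrt(fr["c2"]); e <- sqrt(fr["e2"])

  ace_draw <- function() {
    # additive-genetic deviate: shared in MZ, half-shared in DZ
    A <- numeric(n); C <- numeric(n)
    for (f in unique(ped$family)) {
      idx <- which(ped$family == f)
      z <- ped$zygosity[idx[1]]
      if (z == "MZ" && length(idx) == 2L) {
        A[idx] <- stats::rnorm(1)
      } else if (z == "DZ" && length(idx) == 2L) {
        shared <- stats::rnorm(1)
        A[idx] <- (shared + stats::rnorm(2)) / sqrt(2)
      } else {
        A[idx] <- stats::rnorm(length(idx))
      }
      C[idx] <- stats::rnorm(1)
    }
    E <- stats::rnorm(n)
    a * A + cc * C + e * E
  }

  snp_part <- function(effect_col) {
    s <- numeric(n)
    qe <- config$qtl_effects
    if (!is.null(qe) && nrow(qe) > 0) {
      if (any(qe$snp < 1 | qe$snp > ncol(genotypes$dosages)))
        stop("qtl_effects references an absent variant")
      for (r in seq_len(nrow(qe)))
        s <- s + qe[[effect_col]][r] * genotypes$dosages[, qe$snp[r]]
    }
    s
  }

  latent_var <- snp_part("beta_var") + ace_draw()
  latent_mean <- snp_part("beta_mean") + ace_draw()
  age <- stats::runif(n, 20, 70)
  conf_g <- if (!is.na(config$confounder_snp))
    genotypes$dosages[, config$confounder_snp] else rep(0, n)
  mu <- mu0 + mu_scale * latent_mean + config$confounder_beta * conf_g
  sigma <- sigma0 * exp(sigma_scale * latent_var)
  data.frame(id = ids, family = ped$family, zygosity = ped$zygosity,
             latent_mean = latent_mean, latent_var = latent_var,
             mu = mu, sigma = sigma,
             volume_mean = stats::rlnorm(n, meanlog = log(5e4), sdlog = 0.05),
             age = age, confounder_g = conf_g,
             stringsAsFactors = FALSE)
}

#' Simulate a single-cell event table for one individual
#'
#' Singlet events have forward-scatter area FSC-A log-normally distributed
#' around the individual's mean cell size, FSC-H equal to FSC-A up to small
#' noise, and raw fluorescence F with
#' \code{log10(F) ~ Normal(mu + kappa * (volume - vbar), sigma)} where
#' volume is \code{3 * log10(FSC-A)} and vbar its individual mean, so cell
#' size and fluorescence are positively coupled. A fraction
#' \code{doublet_rate} of events are sums of two singlets' areas and
#' fluorescences with FSC-H close to the larger singlet's height (so
#' FSC-A/FSC-H is near 2).
#'
#' @param params one row of \code{\link{simulate_latent_traits}} output (or
#'   a list with fields mu, sigma, volume_mean, id).
#' @param config a \code{\link{sim_config}}.
#' @param kappa volume-fluorescence coupling on the log10 scale.
#' @param channel fluorescence channel name.
#' @return data.frame event table with columns FSC-A, FSC-H, SSC-A and the
#'   fluorescence channel, plus attribute \code{individual} and a logical
#'   \code{is_doublet} column carrying ground truth.
#' @export
simulate_cells <- function(params, config, kappa = 0.3, channel = "FL1-A") {
  if (params$sigma <= 0) stop("sigma must be positive")
  n <- config$n_cells_per_individual
  stopifnot(n >= 1L)
  set.seed(config$seed + 3L + .id_seed_offset(params$id))
  n_dbl <- stats::rbinom(1L, n, config$doublet_rate)
  n_sgl <- n - n_dbl
  n_pool <- n_sgl + 2L * n_dbl
  fsc_a <- stats::rlnorm(n_pool, meanlog = log(params$volume_mean), sdlog = 0.08)
  vol <- 3 * log10(fsc_a)
  lf <- stats::rnorm(n_pool, params$mu + kappa * (vol - mean(vol)), params$sigma)
  fl <- 10^lf
  ssc <- stats::rlnorm(n_pool, meanlog = log(params$volume_mean * 0.6), sdlog = 0.15)
  fsc_h <- fsc_a * (1 + stats::rnorm(n_pool, 0, 0.02))

  sgl <- seq_len(n_sgl)
  ev <- data.frame(`FSC-A` = fsc_a[sgl], `FSC-H` = fsc_h[sgl],
                   `SSC-A` = ssc[sgl], fl = fl[sgl],
                   is_doublet = FALSE, check.names = FALSE)
  if (n_dbl > 0L) {
    i1 <- n_sgl + seq_len(n_dbl)
    i2 <- n_sgl + n_dbl + seq_len(n_dbl)
    dbl <- data.frame(`FSC-A` = fsc_a[i1] + fsc_a[i2],
                      `FSC-H` = pmax(fsc_h[i1], fsc_h[i2]) *
                        (1 + stats::rnorm(n_dbl, 0, 0.02)),
                      `SSC-A` = ssc[i1] + ssc[i2],
                      fl = fl[i1] + fl[i2],
                      is_doublet = TRUE, check.names = FALSE)
    ev <- rbind(ev, dbl)
    ev <- ev[sample.int(nrow(ev)), , drop = FALSE]
    rownames(ev) <- NULL
  }
  names(ev)[names(ev) == "fl"] <- channel
  attr(ev, "individual") <- params$id
  ev
}

.id_seed_offset <- function(id) {
  if (is.character(id)) sum(utf8ToInt(id)) %% 10000L else as.integer(id) %% 10000L
}

#' Simulate a two-sample exposure/outcome causal chain
#'
#' Individual-level model with a single biallelic instrument G:
#' \code{E = beta_gx * G + confounding * U + noise} and
#' \code{V = beta_causal * E + confounding * U + pleiotropy * G + noise}.
#' Per-SNP summary statistics are OLS estimates computed in two disjoint
#' halves of the sample (exposure in one, outcome in the other), matching
#' the independence assumption of two-sample designs.
#'
#' @param n individuals per half-sample (total simulated is \code{2n}).
#' @param beta_gx instrument-on-exposure effect.
#' @param beta_causal causal exposure-on-outcome effect.
#' @param confounding effect of the shared confounder U on both E and V.
#' @param pleiotropy direct instrument-on-outcome effect.
#' @param seed integer seed.
#' @param maf instrument allele frequency.
#' @param n_snps number of independent instruments to simulate (all with the
#'   same parameter values unless vectors are supplied).
#' @return list with \code{exposure} and \code{outcome} summary-stat
#'   data.frames (snp, effect_allele, other_allele, beta, se, p) and
#'   \code{data} (individual-level data.frame with halves labelled).
#' @export
simulate_mr_chain <- function(n, beta_gx = 0.5, beta_causal = 0.4,
                              confounding = 0, pleiotropy = 0,
                              seed = 1L, maf = 0.3, n_snps = 1L) {
  stopifnot(n >= 10L)
  set.seed(seed)
  beta_gx <- rep_len(beta_gx, n_snps)
  pleiotropy <- rep_len(pleiotropy, n_snps)
  N <- 2L * n
  G <- sapply(seq_len(n_snps), function(j) stats::rbinom(N, 2L, maf))
  U <- stats::rnorm(N)
  E <- G %*% beta_gx + confounding * U + stats::rnorm(N)
  V <- beta_causal * E + confounding * U + G %*% pleiotropy + stats::rnorm(N)
  half1 <- seq_len(n); half2 <- n + seq_len(n)
  ols <- function(y, g) {
    fit <- stats::lm(y ~ g)
    s <- summary(fit)$coefficients["g", ]
    c(beta = unname(s[1]), se = unname(s[2]), p = unname(s[4]))
  }
  exp_stats <- t(sapply(seq_len(n_snps), function(j) ols(E[half1], G[half1, j])))
  out_stats <- t(sapply(seq_len(n_snps), function(j) ols(V[half2], G[half2, j])))
  mk <- function(s) data.frame(snp = sprintf("iv%03d", seq_len(n_snps)),
                               effect_allele = "G", other_allele = "A",
                               beta = s[, "beta"], se = s[, "se"], p = s[, "p"],
                               stringsAsFactors = FALSE)
  list(exposure = mk(exp_stats), outcome = mk(out_stats),
       data = data.frame(half = rep(1:2, each = n), E = as.numeric(E),
                         V = as.numeric(V), U = U))
}

#' Write simulated genotypes as a minimal VCF v4.2 (GT field)
#'
#' @param genotypes a \code{genotype_set}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_vcf <- function(genotypes, path) {
  vt <- genotypes$variants
  G <- genotypes$dosages
  gt <- c("0/0", "0/1", "1/1")[G + 1L]
  dim(gt) <- dim(G)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", genotypes$individuals), collapse = "\t"))
  body <- vapply(seq_len(nrow(vt)), function(i) {
    paste(c(vt$chrom[i], vt$pos[i], vt$id[i], vt$ref[i], vt$alt[i],
            ".", "PASS", ".", "GT", gt[, i]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a dosage-matrix VCF written by \code{\link{write_vcf}} or any
#' VCF v4.2 with diploid GT calls
#'
#' @param path VCF file path (uncompressed).
#' @return a \code{genotype_set}.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  ids <- hdr[-(1:9)]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  vt <- data.frame(
    id = vapply(rows, `[[`, "", 3L),
    chrom = as.integer(vapply(rows, `[[`, "", 1L)),
    pos = as.integer(vapply(rows, `[[`, "", 2L)),
    ref = vapply(rows, `[[`, "", 4L),
    alt = vapply(rows, `[[`, "", 5L),
    stringsAsFactors = FALSE)
  # vapply returns individuals x variants directly
  G <- vapply(rows, function(r) {
    g <- substr(r[-(1:9)], 1, 3)
    as.integer(substr(g, 1, 1) != "0") + as.integer(substr(g, 3, 3) != "0")
  }, integer(length(ids)))
  dim(G) <- c(length(ids), nrow(vt))
  rownames(G) <- ids; colnames(G) <- vt$id
  p <- colMeans(G) / 2
  vt$maf <- pmin(p, 1 - p)
  structure(list(variants = vt, dosages = G, individuals = ids),
            class = "genotype_set")
}

#' Write a dosage matrix TSV (rows = variants, columns = individuals)
#' @param genotypes a \code{genotype_set}.
#' @param path output path.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- cbind(genotypes$variants[, c("id", "chrom", "pos", "ref", "alt")],
              as.data.frame(t(genotypes$dosages)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage matrix TSV written by \code{\link{write_dosage_tsv}}
#' @param path input path.
#' @return a \code{genotype_set}.
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- c("id", "chrom", "pos", "ref", "alt")
  G <- t(as.matrix(df[, setdiff(names(df), meta), drop = FALSE]))
  colnames(G) <- df$id
  vt <- df[, meta]
  p <- colMeans(G) / 2
  vt$maf <- pmin(p, 1 - p)
  structure(list(variants = vt, dosages = G, individuals = rownames(G)),
            class = "genotype_set")
}
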