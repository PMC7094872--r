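# Genotype QC, GRM construction, LMM association scans with
# leave-one-chromosome-out relatedness, cis permutation adjustment,
# LD clumping, varSNP annotation and TSS-proximity enrichment.

#' Hardy-Weinberg equilibrium chi-squared test
#'
#' 1-df goodness-of-fit of observed genotype counts against expectations
#' under the estimated allele frequency \eqn{\hat p = (2 n_{AA} + n_{Aa}) /
#' (2n)}.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return list with \code{chi2} and \code{p} (upper tail of chi-squared
#'   with 1 df).
#' @export
hwe_chi2 <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("empty genotype counts")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p <= 0 || p >= 1) stop("monomorphic variant: HWE undefined")
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Variant quality control: MAF and HWE filters
#'
#' Removes variants with minor allele frequency below \code{maf_min}
#' (strict: exactly \code{maf_min} is retained) or Hardy-Weinberg p-value
#' at or below \code{hwe_p_max}. Monomorphic variants are removed (MAF 0).
#'
#' @param genotypes a \code{genotype_set}.
#' @param maf_min MAF threshold (default 0.01).
#' @param hwe_p_max HWE p-value threshold (default 1e-50); \code{<=} is
#'   exclusionary.
#' @return list with \code{genotypes} (filtered \code{genotype_set}) and
#'   \code{report} (data.frame: id, maf, hwe_p, removed, reason).
#' @export
qc_variants <- function(genotypes, maf_min = 0.01, hwe_p_max = 1e-50) {
  G <- genotypes$dosages
  p_alt <- colMeans(G) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  hwe_p <- vapply(seq_len(ncol(G)), function(k) {
    tab <- tabulate(G[, k] + 1L, nbins = 3L)
    if (maf[k] == 0) return(NA_real_)
    hwe_chi2(tab[3], tab[2], tab[1])$p
  }, numeric(1))
  bad_maf <- maf < maf_min
  bad_hwe <- !is.na(hwe_p) & hwe_p <= hwe_p_max
  removed <- bad_maf | bad_hwe
  report <- data.frame(id = genotypes$variants$id, maf = maf, hwe_p = hwe_p,
                       removed = removed,
                       reason = ifelse(bad_maf, "maf",
                                       ifelse(bad_hwe, "hwe", NA)),
                       stringsAsFactors = FALSE)
  vt <- genotypes$variants[!removed, , drop = FALSE]
  vt$maf <- maf[!removed]
  gs <- structure(list(variants = vt,
                       dosages = G[, !removed, drop = FALSE],
                       individuals = genotypes$individuals),
                  class = "genotype_set")
  list(genotypes = gs, report = report)
}

#' Genetic relationship matrix from standardized genotypes
#'
#' GCTA-style construction: each dosage column is centered and scaled as
#' \eqn{z_{ik} = (g_{ik} - 2 p_k) / \sqrt{2 p_k (1 - p_k)}} using the
#' alternate-allele frequency \eqn{p_k}; the GRM is \eqn{Z Z^\top / m}.
#' Monomorphic variants in the subset are skipped with a warning.
#'
#' @param genotypes a \code{genotype_set}.
#' @param variant_subset optional integer/logical/character index of
#'   variants to use (default all).
#' @return list of class \code{grm} with \code{matrix} (n x n) and \code{m}
#'   (variants used).
#' @export
compute_grm <- function(genotypes, variant_subset = NULL) {
  G <- genotypes$dosages
  if (!is.null(variant_subset)) G <- G[, variant_subset, drop = FALSE]
  if (ncol(G) == 0L) stop("empty variant subset")
  p <- colMeans(G) / 2
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic variant(s) skipped in GRM")
    G <- G[, poly, drop = FALSE]; p <- p[poly]
  }
  Z <- sweep(sweep(G, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  m <- ncol(Z)
  A <- tcrossprod(Z) / m
  dimnames(A) <- list(genotypes$individuals, genotypes$individuals)
  structure(list(matrix = A, m = m), class = "grm")
}

#' Leave-one-chromosome-out GRMs
#'
#' For each chromosome, builds the GRM from all variants not on that
#' chromosome (used when testing variants on it, avoiding proximal
#' contamination), plus the per-chromosome GRMs.
#'
#' @param genotypes a \code{genotype_set} with at least 2 chromosomes.
#' @return list with \code{complement} (chromosome -> \code{grm} of all
#'   other chromosomes), \code{per_chromosome} (chromosome -> \code{grm}),
#'   and \code{all} (whole-genome \code{grm}).
#' @export
loco_grms <- function(genotypes) {
  chroms <- unique(genotypes$variants$chrom)
  if (length(chroms) < 2L)
    stop("leave-one-chromosome-out needs at least 2 chromosomes")
  per <- list(); comp <- list()
  for (c in chroms) {
    on_c <- genotypes$variants$chrom == c
    if (all(on_c)) stop("empty complement for chromosome ", c)
    per[[as.character(c)]] <- compute_grm(genotypes, which(on_c))
    comp[[as.character(c)]] <- compute_grm(genotypes, which(!on_c))
  }
  list(complement = comp, per_chromosome = per,
       all = compute_grm(genotypes))
}

#' Fit the null linear mixed model for one trait
#'
#' Model \eqn{y = X\beta + u + \epsilon} with \eqn{u \sim N(0, \sigma_g^2
#' K)} and \eqn{\epsilon \sim N(0, \sigma_e^2 I)}. Variance components are
#' estimated by REML using a single eigendecomposition of the GRM and a
#' one-dimensional optimization over the log variance ratio; the rotated
#' trait and covariates are cached for fast per-SNP testing.
#'
#' @param y trait values.
#' @param X covariate matrix including intercept (full column rank);
#'   \code{NULL} for intercept only.
#' @param grm a \code{grm} object, or \code{NULL} for an identity
#'   relatedness matrix (equivalent to OLS downstream).
#' @return object of class \code{lmm_null}: sigma_g2, sigma_e2, h2, loglik,
#'   and the spectral cache.
#' @export
fit_lmm_null <- function(y, X = NULL, grm = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  if (is.null(grm)) {
    U <- NULL; d <- rep(1, n)
    ystar <- y; Xstar <- X
  } else {
    K <- grm$matrix
    ee <- eigen(K, symmetric = TRUE)
    if (min(ee$values) < -1e-8 * max(abs(ee$values)))
      stop("GRM is not positive semi-definite")
    d <- pmax(ee$values, 0)
    U <- ee$vectors
    ystar <- crossprod(U, y)
    Xstar <- crossprod(U, X)
  }
  p <- ncol(X)
  reml_nll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- lam * d + 1          # V = sigma_e2 * diag(w) in rotated space
    sw <- 1 / sqrt(w)
    Xw <- Xstar * sw; yw <- ystar * sw
    qrx <- qr(Xw)
    res <- qr.resid(qrx, yw)
    rss <- sum(res^2)
    sigma_e2 <- rss / (n - p)
    R <- qr.R(qrx)
    0.5 * ((n - p) * log(sigma_e2) + sum(log(w)) +
             2 * sum(log(abs(diag(R)))) + (n - p))
  }
  if (is.null(grm) || max(d) - min(d) < 1e-12) {
    # relatedness proportional to identity: ratio not identified
    lam_hat <- 0
  } else {
    opt <- stats::optimize(reml_nll, interval = c(-20, 20), tol = 1e-8)
    lam_hat <- exp(opt$minimum)
  }
  w <- lam_hat * d + 1
  sw <- 1 / sqrt(w)
  Xw <- Xstar * sw; yw <- ystar * sw
  qrx <- qr(Xw)
  rss <- sum(qr.resid(qrx, yw)^2)
  sigma_e2 <- rss / (n - p)
  structure(list(sigma_g2 = lam_hat * sigma_e2, sigma_e2 = sigma_e2,
                 h2 = lam_hat / (1 + lam_hat), lambda = lam_hat,
                 U = U, d = d, w = w, ystar = ystar, Xstar = Xstar,
                 n = n, p = p),
            class = "lmm_null")
}

#' Per-SNP association scan with variance components fixed at the null
#'
#' For each SNP, the per-allele effect \eqn{\gamma} is estimated by
#' generalized least squares with the covariance fixed at the null-model
#' REML estimates (single-decomposition, MLMA-style). The null hypothesis
#' \eqn{\gamma = 0} is assessed with a t-test on
#' \eqn{n - \mathrm{rank}(X) - 1} degrees of freedom. SNPs collinear with
#' the covariates are flagged with missing p. With an identity relatedness
#' matrix the scan reduces exactly to OLS.
#'
#' @param y trait values.
#' @param X covariates including intercept (or \code{NULL}).
#' @param snps dosage matrix, individuals x SNPs.
#' @param grm a \code{grm} or \code{NULL} (identity).
#' @param null optional prefitted \code{\link{fit_lmm_null}} (must match
#'   \code{y}, \code{X}, \code{grm}).
#' @return data.frame: snp, beta, se, t, p.
#' @export
lmm_scan <- function(y, X = NULL, snps, grm = NULL, null = NULL) {
  snps <- as.matrix(snps)
  if (is.null(null)) null <- fit_lmm_null(y, X, grm)
  sw <- 1 / sqrt(null$w)
  Gstar <- if (is.null(null$U)) snps else crossprod(null$U, snps)
  Gw <- Gstar * sw
  Xw <- null$Xstar * sw
  yw <- null$ystar * sw
  qrx <- qr(Xw)
  yr <- qr.resid(qrx, yw)
  Gr <- qr.resid(qrx, Gw)
  gg <- colSums(Gr^2)
  gy <- as.numeric(crossprod(Gr, yr))
  df <- null$n - null$p - 1L
  ok <- gg > 1e-10 * nrow(Gr)
  beta <- ifelse(ok, gy / gg, NA_real_)
  rss <- pmax(sum(yr^2) - beta^2 * gg, 0)
  se <- ifelse(ok, sqrt(rss / df / gg), NA_real_)
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  data.frame(snp = colnames(snps) %||% paste0("snp", seq_len(ncol(snps))),
             beta = beta, se = se, t = tstat, p = pval,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genomic inflation factor
#'
#' Median observed association chi-squared divided by the null median.
#'
#' @param p vector of p-values.
#' @return scalar lambda.
#' @export
lambda_gc <- function(p) {
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE), na.rm = TRUE) /
    stats::qchisq(0.5, df = 1)
}

#' cis window predicate around a gene's TSS
#'
#' Variants on the gene's chromosome within \code{half_width} of the
#' transcription start site (closed interval: the boundary positions are
#' included).
#'
#' @param gene one row of a gene-model table (chrom, tss).
#' @param variants variant data.frame (chrom, pos).
#' @param half_width window half-width in bp (default 5e5, i.e. a 1 Mb
#'   window centered on the TSS).
#' @return logical vector over the variants.
#' @export
cis_window <- function(gene, variants, half_width = 5e5) {
  if (is.null(gene) || is.na(gene$tss)) stop("gene TSS unknown")
  variants$chrom == gene$chrom & abs(variants$pos - gene$tss) <= half_width
}

# ML fit of a Beta(k1, k2) distribution to values in (0, 1)
.fit_beta_ml <- function(x) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  m <- mean(x); v <- stats::var(x)
  if (v <= 0) return(NULL)
  common <- m * (1 - m) / v - 1
  start <- log(pmax(c(m * common, (1 - m) * common), 1e-3))
  nll <- function(lp) -sum(stats::dbeta(x, exp(lp[1]), exp(lp[2]), log = TRUE))
  o <- try(stats::optim(start, nll, method = "BFGS",
                        control = list(maxit = 200)), silent = TRUE)
  if (inherits(o, "try-error")) return(exp(start))
  exp(o$par)
}

#' Beta-approximation permutation adjustment for a cis window
#'
#' Corrects the window's best nominal p-value for the number of correlated
#' variants tested: trait values are permuted in the whitened-residual
#' space of the null model, the minimum p across window SNPs is recorded per
#' permutation, a Beta distribution is fitted to the null minimum-p sample
#' by maximum likelihood, and the adjusted p is the fitted Beta CDF at the
#' observed minimum. Falls back to the empirical rank p if the null sample
#' is degenerate.
#'
#' @param y trait values; @param X covariates; @param snps window dosages;
#' @param grm a \code{grm} or NULL.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list: p_nominal (window min), p_adjusted, best_snp, beta_shape,
#'   null_min_p.
#' @export
cis_empirical_p <- function(y, X = NULL, snps, grm = NULL, n_perm = 1000L,
                            seed = 1L) {
  stopifnot(n_perm >= 100L)
  set.seed(seed)
  snps <- as.matrix(snps)
  null <- fit_lmm_null(y, X, grm)
  scan <- lmm_scan(y, X, snps, grm, null = null)
  p_min <- min(scan$p, na.rm = TRUE)
  best <- scan$snp[which.min(scan$p)]

  # whitened residual space shared by observed and permuted scans
  sw <- 1 / sqrt(null$w)
  Gstar <- if (is.null(null$U)) snps else crossprod(null$U, snps)
  Gw <- Gstar * sw
  Xw <- null$Xstar * sw
  yw <- null$ystar * sw
  qrx <- qr(Xw)
  yr <- qr.resid(qrx, yw)
  Gr <- qr.resid(qrx, Gw)
  gg <- colSums(Gr^2)
  ok <- gg > 1e-10 * nrow(Gr)
  Gr <- Gr[, ok, drop = FALSE]; gg <- gg[ok]
  df <- null$n - null$p - 1L
  n <- length(yr)
  P <- matrix(NA_real_, n_perm, 1)
  yy <- sum(yr^2)
  # all permutations at once: t_j = <g_j, y_perm> / sqrt((yy - b^2 gg) /df /gg) ...
  perm_min_p <- vapply(seq_len(n_perm), function(i) {
    yp <- yr[sample.int(n)]
    gy <- as.numeric(crossprod(Gr, yp))
    b <- gy / gg
    rss <- pmax(yy - b^2 * gg, 1e-300)
    tstat <- b / sqrt(rss / df / gg)
    min(2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE))
  }, numeric(1))
  shape <- .fit_beta_ml(perm_min_p)
  if (is.null(shape)) {
    warning("degenerate permutation null; using empirical rank p")
    p_adj <- (sum(perm_min_p <= p_min) + 1) / (n_perm + 1)
    shape <- c(NA_real_, NA_real_)
  } else {
    p_adj <- stats::pbeta(p_min, shape[1], shape[2])
  }
  list(p_nominal = p_min, p_adjusted = p_adj, best_snp = best,
       beta_shape = shape, null_min_p = perm_min_p)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values (monotone) and discovery flags at level \code{q}.
#'
#' @param p p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return data.frame with p, q_value, discovery.
#' @export
fdr_bh <- function(p, q = 0.05) {
  qv <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q_value = qv, discovery = qv <= q)
}

#' Greedy LD clumping of association records
#'
#' Candidates with p at or below \code{p_index} are sorted by ascending p
#' (ties broken by chromosome, position, id); the best unassigned variant
#' becomes a clump index and absorbs all unassigned variants on the same
#' chromosome within \code{dist} bp and with squared dosage correlation
#' above \code{r2} with the index. Output clumps partition the passing
#' variants.
#'
#' @param assoc data.frame with snp, p columns (one trait's scan).
#' @param genotypes a \code{genotype_set} providing positions and dosages
#'   for r-squared.
#' @param p_index index-variant p threshold (\code{<=} passes).
#' @param r2 LD threshold, membership requires r-squared strictly above it.
#' @param dist distance window in bp (default 250000).
#' @return data.frame: index_snp, index_p, n_members, members
#'   (semicolon-joined ids).
#' @export
ld_clump <- function(assoc, genotypes, p_index = 1e-4, r2 = 0.5,
                     dist = 250000) {
  vt <- genotypes$variants
  cand <- assoc[!is.na(assoc$p) & assoc$p <= p_index, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(index_snp = character(), index_p = numeric(),
                      n_members = integer(), members = character(),
                      stringsAsFactors = FALSE))
  vi <- match(cand$snp, vt$id)
  if (anyNA(vi)) stop("association record for unknown variant")
  cand$chrom <- vt$chrom[vi]; cand$pos <- vt$pos[vi]
  ord <- order(cand$p, cand$chrom, cand$pos, cand$snp)
  cand <- cand[ord, , drop = FALSE]
  G <- genotypes$dosages[, cand$snp, drop = FALSE]
  # mean-impute missing dosages for correlation only
  if (anyNA(G)) G <- apply(G, 2, function(g) {
    g[is.na(g)] <- mean(g, na.rm = TRUE); g })
  assigned <- rep(FALSE, nrow(cand))
  out <- list()
  while (any(!assigned)) {
    i <- which(!assigned)[1]
    assigned[i] <- TRUE
    near <- which(!assigned & cand$chrom == cand$chrom[i] &
                    abs(cand$pos - cand$pos[i]) <= dist)
    memb <- character()
    if (length(near)) {
      r2v <- as.numeric(stats::cor(G[, i], G[, near, drop = FALSE]))^2
      take <- near[!is.na(r2v) & r2v > r2]
      assigned[take] <- TRUE
      memb <- cand$snp[take]
    }
    out[[length(out) + 1L]] <- data.frame(
      index_snp = cand$snp[i], index_p = cand$p[i],
      n_members = length(memb),
      members = paste(memb, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Annotate varSNPs relative to gene models
#'
#' Categories: \code{transcribed} (inside a gene body), \code{upstream}
#' (within \code{flank} bp 5' of the TSS, strand-aware), \code{downstream}
#' (within \code{flank} bp 3' of the gene end, strand-aware), else
#' \code{intergenic}. Also reports the signed distance to the nearest TSS
#' (ties broken toward the lower-coordinate TSS).
#'
#' @param varsnps data.frame with snp, chrom, pos.
#' @param gene_models data.frame with gene, chrom, start, end, tss, strand
#'   ("+"/"-").
#' @param flank upstream/downstream band width in bp (default 5000).
#' @return data.frame: snp, category, nearest_gene, tss_distance (signed:
#'   positive when the SNP is downstream of the TSS in gene orientation).
#' @export
annotate_varsnps <- function(varsnps, gene_models, flank = 5000) {
  res <- lapply(seq_len(nrow(varsnps)), function(i) {
    chrom <- varsnps$chrom[i]; pos <- varsnps$pos[i]
    gm <- gene_models[gene_models$chrom == chrom, , drop = FALSE]
    if (nrow(gm) == 0L) {
      warning("chromosome absent from gene table: ", chrom)
      return(data.frame(snp = varsnps$snp[i], category = "intergenic",
                        nearest_gene = NA_character_,
                        tss_distance = NA_real_, stringsAsFactors = FALSE))
    }
    cat <- "intergenic"
    for (j in seq_len(nrow(gm))) {
      g <- gm[j, ]
      if (pos >= g$start && pos <= g$end) { cat <- "transcribed"; break }
      plus <- g$strand == "+"
      up <- if (plus) pos < g$tss && g$tss - pos <= flank
            else pos > g$tss && pos - g$tss <= flank
      gene_end <- if (plus) g$end else g$start
      down <- if (plus) pos > gene_end && pos - gene_end <= flank
              else pos < gene_end && gene_end - pos <= flank
      if (up) cat <- "upstream"
      else if (down && cat == "intergenic") cat <- "downstream"
    }
    dists <- pos - gm$tss
    best <- order(abs(dists), gm$tss)[1]
    signed <- if (gm$strand[best] == "+") dists[best] else -dists[best]
    data.frame(snp = varsnps$snp[i], category = cat,
               nearest_gene = gm$gene[best], tss_distance = signed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' TSS-proximity enrichment of varSNPs against MAF-matched controls
#'
#' Samples \code{n_controls_per_case} control SNPs per varSNP from the
#' genome-wide pool, matched on MAF in bins of width \code{maf_bin} (the
#' bin is doubled with a warning if a bin lacks controls), then compares the
#' proportions of case and control SNPs lying within \code{threshold} bp of
#' their nearest TSS in a 2x2 table (odds ratio, Fisher exact p).
#'
#' @param varsnps data.frame: snp, chrom, pos, maf.
#' @param all_snps control pool with the same columns.
#' @param gene_models gene-model data.frame (chrom, tss).
#' @param threshold proximity threshold in bp (default 1e5).
#' @param n_controls_per_case controls sampled per case (default 1).
#' @param maf_bin MAF bin width for matching (default 0.05).
#' @param seed integer seed.
#' @return list: odds_ratio, p, table (2x2 matrix).
#' @export
tss_enrichment <- function(varsnps, all_snps, gene_models, threshold = 1e5,
                           n_controls_per_case = 1L, maf_bin = 0.05,
                           seed = 1L) {
  set.seed(seed)
  pool <- all_snps[!all_snps$snp %in% varsnps$snp, , drop = FALSE]
  controls <- list()
  for (i in seq_len(nrow(varsnps))) {
    bw <- maf_bin
    repeat {
      inbin <- which(abs(pool$maf - varsnps$maf[i]) <= bw / 2)
      inbin <- setdiff(inbin, unlist(controls))
      if (length(inbin) >= n_controls_per_case) break
      bw <- bw * 2
      warning("insufficient controls in MAF bin; widening to ", bw)
      if (bw > 1) break
    }
    controls[[i]] <- inbin[sample.int(length(inbin),
                                      min(n_controls_per_case, length(inbin)))]
  }
  ctrl <- pool[unlist(controls), , drop = FALSE]
  near_tss <- function(df) {
    vapply(seq_len(nrow(df)), function(i) {
      tss <- gene_models$tss[gene_models$chrom == df$chrom[i]]
      length(tss) > 0 && min(abs(df$pos[i] - tss)) <= threshold
    }, logical(1))
  }
  a <- sum(near_tss(varsnps)); b <- nrow(varsnps) - a
  c_ <- sum(near_tss(ctrl)); d <- nrow(ctrl) - c_
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("case", "control"),
                                c("near_tss", "far")))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = (a * d) / (b * c_), p = ft$p.value, table = tab,
       fisher_or = unname(ft$estimate))
}

#' Down-sampling sensitivity of a QTL scan
#'
#' Re-runs the association scan on random subsets of individuals at the
#' given fractions and reports, per fraction, the proportion of
#' full-sample QTLs (SNPs significant at \code{p_sig}) recovered.
#'
#' @param y trait values; @param X covariates; @param snps dosage matrix;
#' @param grm a \code{grm} or NULL (the GRM is subset per fraction).
#' @param fractions vector of fractions in (0, 1] (default seq(0.1, 1, 0.1)).
#' @param p_sig significance threshold defining a QTL (default 5e-8).
#' @param min_n fractions yielding fewer individuals are skipped with a
#'   warning (default 30).
#' @param seed integer seed.
#' @return data.frame: fraction, n, n_full_qtls, n_recovered, recovery.
#' @export
downsample_sensitivity <- function(y, X = NULL, snps, grm = NULL,
                                   fractions = seq(0.1, 1, by = 0.1),
                                   p_sig = 5e-8, min_n = 30L, seed = 1L) {
  set.seed(seed)
  full <- lmm_scan(y, X, snps, grm)
  qtls <- full$snp[!is.na(full$p) & full$p <= p_sig]
  n <- length(y)
  rows <- list()
  for (f in fractions) {
    ns <- round(f * n)
    if (ns < min_n) { warning("fraction ", f, " yields < ", min_n,
                              " individuals; skipped"); next }
    idx <- if (ns == n) seq_len(n) else sample.int(n, ns)
    g_sub <- if (is.null(grm)) NULL else
      structure(list(matrix = grm$matrix[idx, idx], m = grm$m), class = "grm")
    sc <- lmm_scan(y[idx], if (is.null(X)) NULL else X[idx, , drop = FALSE],
                   snps[idx, , drop = FALSE], g_sub)
    rec <- sc$snp[!is.na(sc$p) & sc$p <= p_sig]
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = f, n = ns, n_full_qtls = length(qtls),
      n_recovered = length(intersect(rec, qtls)),
      recovery = if (length(qtls)) length(intersect(rec, qtls)) / length(qtls)
                 else NA_real_)
  }
  do.call(rbind, rows)
}
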