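# Shared fixtures and independent oracles, built in code at test time.

# per-variant correlation of co-twin genotypes, averaged over variants
# (column-centering removes the allele-frequency component that would
# otherwise inflate an across-variant correlation)
pairwise_geno_cor <- function(genotypes, pedigree, zygosity) {
  fams <- unique(pedigree$family[pedigree$zygosity == zygosity])
  G <- scale(genotypes$dosages, center = TRUE, scale = FALSE)
  twin1 <- t(vapply(fams, function(f) G[which(pedigree$family == f)[1], ],
                    numeric(ncol(G))))
  twin2 <- t(vapply(fams, function(f) G[which(pedigree$family == f)[2], ],
                    numeric(ncol(G))))
  cors <- vapply(seq_len(ncol(G)), function(k) {
    if (stats::sd(twin1[, k]) == 0 || stats::sd(twin2[, k]) == 0) NA_real_
    else stats::cor(twin1[, k], twin2[, k])
  }, numeric(1))
  mean(cors, na.rm = TRUE)
}

# simulated mean/cv2 cloud with a known log-log trend curve
make_cv2_cloud <- function(n, curve = function(lm) -1 - lm, noise_sd = 0.2,
                           seed = 1) {
  set.seed(seed)
  mu <- runif(n, 1, 3)
  lcv2 <- curve(log10(mu)) + rnorm(n, 0, noise_sd)
  data.frame(individual = sprintf("i%04d", seq_len(n)),
             mean = mu, cv2 = 10^lcv2)
}

# independent brute-force greedy clumping reference (plain loops; no shared
# code with ld_clump)
brute_clump <- function(assoc, variants, dosages, p_index, r2, dist) {
  keep <- which(!is.na(assoc$p) & assoc$p <= p_index)
  if (!length(keep)) return(NULL)
  df <- assoc[keep, ]
  vi <- match(df$snp, variants$id)
  df$chrom <- variants$chrom[vi]; df$pos <- variants$pos[vi]
  df <- df[order(df$p, df$chrom, df$pos, df$snp), ]
  done <- rep(FALSE, nrow(df))
  res <- list()
  for (i in seq_len(nrow(df))) {
    if (done[i]) next
    done[i] <- TRUE
    members <- character(0)
    for (j in seq_len(nrow(df))) {
      if (done[j]) next
      if (df$chrom[j] != df$chrom[i]) next
      if (abs(df$pos[j] - df$pos[i]) > dist) next
      r <- suppressWarnings(stats::cor(dosages[, df$snp[i]],
                                       dosages[, df$snp[j]]))
      if (!is.na(r) && r^2 > r2) {
        done[j] <- TRUE
        members <- c(members, df$snp[j])
      }
    }
    res[[length(res) + 1L]] <- list(index = df$snp[i], members = members)
  }
  res
}

# homogeneous instrument summary statistics for a fixed causal effect
make_instruments <- function(J, beta = 0.4, bx0 = 0.5, se_x = 0.001,
                             se_y = 0.05, seed = 1) {
  set.seed(seed)
  bx <- rnorm(J, bx0, se_x)
  by <- rnorm(J, beta * bx0, se_y)
  data.frame(snp = sprintf("iv%02d", seq_len(J)),
             effect_allele = "G", other_allele = "A",
             b_x = bx, se_x = se_x, b_y = by, se_y = se_y,
             stringsAsFactors = FALSE)
}
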