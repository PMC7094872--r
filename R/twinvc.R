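# ACE variance decomposition in twin cohorts: Gaussian maximum likelihood
# with path-coefficient (Cholesky-style) parametrization, pair bootstrap
# SEs and zygosity-permutation p-values.

#' Expected relatedness matrices from twin zygosity
#'
#' The genetic matrix K has 1 for MZ co-twins, 0.5 for DZ co-twins and 0 for
#' unrelated individuals (1 on the diagonal); the shared-environment matrix
#' S has 1 within twin pairs and on the diagonal, 0 otherwise. Both are
#' block-diagonal by family.
#'
#' @param pedigree data.frame with columns id, family, zygosity
#'   (MZ/DZ/unrelated); MZ/DZ families must have exactly 2 members.
#' @return list with matrices \code{K} and \code{S} (dimnames = ids).
#' @export
relatedness_matrices <- function(pedigree) {
  n <- nrow(pedigree)
  K <- diag(n); S <- diag(n)
  dimnames(K) <- dimnames(S) <- list(pedigree$id, pedigree$id)
  for (f in unique(pedigree$family)) {
    idx <- which(pedigree$family == f)
    if (length(idx) == 1L) next
    z <- pedigree$zygosity[idx[1]]
    if (z %in% c("MZ", "DZ") && length(idx) != 2L)
      stop("MZ/DZ family must have exactly 2 members: ", f)
    off <- switch(z, MZ = 1, DZ = 0.5, 0)
    K[idx[1], idx[2]] <- K[idx[2], idx[1]] <- off
    if (z %in% c("MZ", "DZ"))
      S[idx[1], idx[2]] <- S[idx[2], idx[1]] <- 1
  }
  list(K = K, S = S)
}

# family blocks in a vectorized layout: pair index vectors with their
# kinship (k) and shared-environment (s) coefficients, plus singletons
.ace_blocks <- function(pedigree) {
  fam <- split(seq_len(nrow(pedigree)), pedigree$family)
  sizes <- lengths(fam)
  pairs <- fam[sizes == 2L]
  singles <- unlist(fam[sizes == 1L], use.names = FALSE)
  if (any(sizes > 2L))
    stop("families with more than 2 members are not supported")
  i1 <- vapply(pairs, `[[`, 0L, 1L)
  i2 <- vapply(pairs, `[[`, 0L, 2L)
  z <- pedigree$zygosity[i1]
  list(i1 = i1, i2 = i2,
       k = ifelse(z == "MZ", 1, ifelse(z == "DZ", 0.5, 0)),
       s = as.numeric(z %in% c("MZ", "DZ")),
       singles = singles)
}

# negative log-likelihood of centered y under path coefficients (a, c, e);
# exploits the 2x2 block structure for O(n) vectorized evaluation
.ace_negll <- function(par, y, blocks) {
  a2 <- par[1]^2; c2 <- par[2]^2; e2 <- par[3]^2
  v <- a2 + c2 + e2
  if (v <= 0 || e2 < 1e-10) return(1e10)
  nll <- 0
  if (length(blocks$singles))
    nll <- nll + 0.5 * sum(log(2 * pi * v) + y[blocks$singles]^2 / v)
  if (length(blocks$i1)) {
    y1 <- y[blocks$i1]; y2 <- y[blocks$i2]
    cv <- a2 * blocks$k + c2 * blocks$s
    det2 <- v^2 - cv^2
    if (any(det2 <= 0)) return(1e10)
    q <- (v * (y1^2 + y2^2) - 2 * cv * y1 * y2) / det2
    nll <- nll + 0.5 * sum(2 * log(2 * pi) + log(det2) + q)
  }
  nll
}

#' Fit the ACE model to a twin-cohort trait by maximum likelihood
#'
#' Partitions trait variance into additive-genetic (A), common-environment
#' (C) and unique-environment (E) components by maximizing the Gaussian
#' log-likelihood with covariance \eqn{\sigma_A^2 K + \sigma_C^2 S +
#' \sigma_E^2 I}. Components are parametrized by path coefficients
#' (a, c, e), so \eqn{a^2, c^2, e^2} are non-negative by construction.
#' Optimization uses quasi-Newton iterations from several restarts. The
#' trait is centered internally; optionally residualized on covariates
#' (e.g. age) first.
#'
#' @param y numeric trait values, one per pedigree row.
#' @param pedigree data.frame (id, family, zygosity).
#' @param covariates optional numeric matrix/data.frame regressed out of
#'   \code{y} before fitting.
#' @param n_restarts random restarts for the optimizer (default 5).
#' @param min_pairs minimum number of complete twin pairs (default 20).
#' @return object of class \code{ace_fit}: list with \code{components}
#'   (sigma_A2, sigma_C2, sigma_E2), \code{fractions} (a2, c2, e2 of the
#'   total), \code{loglik}, \code{n_pairs}.
#' @export
ace_fit <- function(y, pedigree, covariates = NULL, n_restarts = 5L,
                    min_pairs = 20L) {
  stopifnot(length(y) == nrow(pedigree))
  zyg_pairs <- table(pedigree$zygosity[!duplicated(pedigree$family)])
  n_mz <- if ("MZ" %in% names(zyg_pairs)) zyg_pairs[["MZ"]] else 0L
  n_dz <- if ("DZ" %in% names(zyg_pairs)) zyg_pairs[["DZ"]] else 0L
  if (n_mz + n_dz < min_pairs)
    stop(sprintf("need at least %d complete twin pairs", min_pairs))
  if (n_mz == 0L || n_dz == 0L)
    stop("A and C not separately identifiable: cohort must contain both MZ and DZ pairs")
  if (!is.null(covariates))
    y <- stats::resid(stats::lm(y ~ ., data = as.data.frame(covariates)))
  y <- y - mean(y)
  if (stats::sd(y) == 0) stop("constant trait: variance components undefined")
  blocks <- .ace_blocks(pedigree)
  vy <- stats::var(y)
  best <- NULL
  starts <- rbind(sqrt(vy * c(1, 1, 1) / 3),
                  sqrt(vy * c(0.6, 0.1, 0.3)),
                  sqrt(vy * c(0.05, 0.05, 0.9)))
  extra <- max(0L, n_restarts - nrow(starts))
  if (extra > 0L) {
    fr <- matrix(stats::runif(extra * 3, 0.05, 1), extra)
    fr <- fr / rowSums(fr)
    starts <- rbind(starts, sqrt(vy * fr))
  }
  for (i in seq_len(min(n_restarts, nrow(starts)))) {
    o <- try(stats::optim(starts[i, ], .ace_negll, y = y, blocks = blocks,
                          method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("ACE optimizer failed to converge from all restarts")
  comp <- best$par^2
  tot <- sum(comp)
  structure(list(components = stats::setNames(comp, c("sigma_A2", "sigma_C2", "sigma_E2")),
                 fractions = stats::setNames(comp / tot, c("a2", "c2", "e2")),
                 loglik = -best$value, n_pairs = n_mz + n_dz,
                 n_mz = n_mz, n_dz = n_dz),
            class = "ace_fit")
}

#' Falconer closed-form ACE estimate (oracle / sanity check)
#'
#' From empirical MZ and DZ twin correlations: a2 = 2 (r_MZ - r_DZ),
#' c2 = 2 r_DZ - r_MZ, e2 = 1 - r_MZ; values are truncated at 0.
#'
#' @param y trait values; @param pedigree pedigree data.frame.
#' @return named vector (a2, c2, e2) and attributes r_mz, r_dz.
#' @export
ace_falconer <- function(y, pedigree) {
  pair_cor <- function(z) {
    fams <- unique(pedigree$family[pedigree$zygosity == z])
    pairs <- t(vapply(fams, function(f) y[pedigree$family == f][1:2],
                      numeric(2)))
    # double-entered correlation (symmetric in twin order)
    stats::cor(c(pairs[, 1], pairs[, 2]), c(pairs[, 2], pairs[, 1]))
  }
  r_mz <- pair_cor("MZ"); r_dz <- pair_cor("DZ")
  a2 <- max(0, 2 * (r_mz - r_dz))
  c2 <- max(0, 2 * r_dz - r_mz)
  e2 <- max(0, 1 - r_mz)
  out <- c(a2 = a2, c2 = c2, e2 = e2)
  attr(out, "r_mz") <- r_mz; attr(out, "r_dz") <- r_dz
  out
}

#' Bootstrap standard errors for ACE fractions
#'
#' Refits the model on random samples of a fraction (default 75%) of twin
#' pairs drawn without replacement; unrelated individuals are always kept.
#' Resampling is by pair, never splitting co-twins. The SE of each fraction
#' is the standard deviation of the replicate estimates.
#'
#' @param y,pedigree,covariates as in \code{\link{ace_fit}}.
#' @param n_boot number of replicates (>= 50).
#' @param pair_fraction fraction of pairs per replicate (default 0.75).
#' @param seed integer seed.
#' @return list with \code{se} (named vector over a2, c2, e2),
#'   \code{replicates} (matrix) and \code{n_failed}.
#' @export
ace_bootstrap <- function(y, pedigree, covariates = NULL, n_boot = 100L,
                          pair_fraction = 0.75, seed = 1L) {
  stopifnot(n_boot >= 50L)
  set.seed(seed)
  fam_first <- !duplicated(pedigree$family)
  twin_fams <- pedigree$family[fam_first][
    pedigree$zygosity[fam_first] %in% c("MZ", "DZ")]
  other_idx <- which(!pedigree$family %in% twin_fams)
  n_take <- max(1L, round(pair_fraction * length(twin_fams)))
  reps <- matrix(NA_real_, n_boot, 3, dimnames = list(NULL, c("a2", "c2", "e2")))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    fams <- sample(twin_fams, n_take)
    idx <- c(which(pedigree$family %in% fams), other_idx)
    fit <- try(ace_fit(y[idx], pedigree[idx, , drop = FALSE],
                       covariates = if (is.null(covariates)) NULL else
                         covariates[idx, , drop = FALSE],
                       min_pairs = 2L),
               silent = TRUE)
    if (inherits(fit, "try-error")) { n_failed <- n_failed + 1L; next }
    reps[b, ] <- fit$fractions
  }
  if (n_failed > 0.2 * n_boot)
    stop(sprintf("%d of %d bootstrap replicates failed", n_failed, n_boot))
  if (n_failed > 0L)
    warning(sprintf("%d bootstrap replicate(s) failed and were dropped", n_failed))
  list(se = apply(reps, 2, stats::sd, na.rm = TRUE),
       replicates = reps, n_failed = n_failed)
}

#' Zygosity-permutation p-values for ACE components
#'
#' Builds a null distribution of each variance fraction by permuting the
#' zygosity labels across families (pair structure preserved) and refitting.
#' The default p-value follows the formula
#' \eqn{p = 1 - (\#\{test > null\} + 1) / (n_{perm} + 1)}, which equals
#' \eqn{\#\{null \ge test\} / (n_{perm} + 1)} and can reach exactly 0; the
#' conventional permutation form
#' \eqn{p = (\#\{null \ge test\} + 1) / (n_{perm} + 1)} is available via
#' \code{formula = "standard"}.
#'
#' @param y,pedigree,covariates as in \code{\link{ace_fit}}.
#' @param n_perm number of label permutations (default 100).
#' @param seed integer seed.
#' @param formula \code{"as_printed"} (default) or \code{"standard"}.
#' @return list with \code{p} (named vector over a2, c2, e2), \code{observed}
#'   fractions and the \code{null} matrix.
#' @export
ace_permutation_p <- function(y, pedigree, covariates = NULL, n_perm = 100L,
                              seed = 1L, formula = c("as_printed", "standard")) {
  formula <- match.arg(formula)
  stopifnot(n_perm >= 1L)
  set.seed(seed)
  obs <- ace_fit(y, pedigree, covariates = covariates)$fractions
  fam_first <- !duplicated(pedigree$family)
  fams <- pedigree$family[fam_first]
  zyg <- pedigree$zygosity[fam_first]
  null_mat <- matrix(NA_real_, n_perm, 3,
                     dimnames = list(NULL, c("a2", "c2", "e2")))
  for (i in seq_len(n_perm)) {
    perm_zyg <- sample(zyg)
    ped_p <- pedigree
    ped_p$zygosity <- perm_zyg[match(pedigree$family, fams)]
    fit <- try(ace_fit(y, ped_p, covariates = covariates), silent = TRUE)
    if (!inherits(fit, "try-error")) null_mat[i, ] <- fit$fractions
  }
  p <- vapply(c("a2", "c2", "e2"), function(k) {
    null <- null_mat[, k][is.finite(null_mat[, k])]
    permutation_p(obs[[k]], null, formula = formula)
  }, numeric(1))
  list(p = p, observed = obs, null = null_mat)
}

#' Permutation p-value formula
#'
#' \code{"as_printed"}: \eqn{p = 1 - (\#\{test > null\} + 1)/(n + 1)};
#' \code{"standard"}: \eqn{p = (\#\{null \ge test\} + 1)/(n + 1)}.
#'
#' @param test observed statistic; @param null numeric null sample;
#' @param formula which convention.
#' @return scalar p-value.
#' @export
permutation_p <- function(test, null, formula = c("as_printed", "standard")) {
  formula <- match.arg(formula)
  n <- length(null)
  if (formula == "as_printed") 1 - (sum(test > null) + 1) / (n + 1)
  else (sum(null >= test) + 1) / (n + 1)
}
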