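# Two-sample Mendelian randomization from summary statistics: instrument
# selection and harmonization, Wald ratio, maximum likelihood, IVW,
# MR-Egger regression, Cochran's Q and pairwise screening with FDR control.

.palindromic <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  toupper(a2) == comp[toupper(a1)]
}

#' Harmonize one exposure/outcome summary-statistic pair
#'
#' Aligns the outcome row to the exposure row's effect allele: if the
#' effect/other alleles are swapped the outcome beta's sign is flipped;
#' strand-ambiguous palindromic variants (A/T, C/G) are rejected by default
#' since their orientation cannot be verified without allele frequencies.
#'
#' @param exposure,outcome single-row data.frames with columns snp,
#'   effect_allele, other_allele, beta, se (and optionally p).
#' @param drop_palindromic reject A/T and C/G variants (default TRUE).
#' @return list with \code{instrument} (harmonized row: snp, b_x, se_x,
#'   b_y, se_y) or \code{NULL}, \code{rejected}, \code{reason}.
#' @export
harmonize <- function(exposure, outcome, drop_palindromic = TRUE) {
  stopifnot(exposure$snp == outcome$snp)
  ea_x <- toupper(exposure$effect_allele); oa_x <- toupper(exposure$other_allele)
  ea_y <- toupper(outcome$effect_allele); oa_y <- toupper(outcome$other_allele)
  if (drop_palindromic && .palindromic(ea_x, oa_x))
    return(list(instrument = NULL, rejected = TRUE,
                reason = "palindromic variant"))
  if (ea_x == ea_y && oa_x == oa_y) {
    b_y <- outcome$beta
  } else if (ea_x == oa_y && oa_x == ea_y) {
    b_y <- -outcome$beta
  } else {
    return(list(instrument = NULL, rejected = TRUE,
                reason = "incompatible allele pairs"))
  }
  list(instrument = data.frame(snp = exposure$snp,
                               effect_allele = ea_x, other_allele = oa_x,
                               b_x = exposure$beta, se_x = exposure$se,
                               b_y = b_y, se_y = outcome$se,
                               stringsAsFactors = FALSE),
       rejected = FALSE, reason = NA_character_)
}

#' Select candidate instruments for a varSNP / eGene pair
#'
#' Extracts cis-eQTL records within a 200 kb window centered on the varSNP
#' (i.e. within \code{window/2} bp), with eQTL p-value at or below
#' \code{p_max} and a matching cell type, then intersects with the variants
#' present in the outcome (variability) summary statistics and harmonizes
#' alleles.
#'
#' @param varsnp list/row with chrom, pos (the clump index variant).
#' @param eqtl_stats exposure summary table: snp, chrom, pos, effect_allele,
#'   other_allele, beta, se, p, cell_type.
#' @param outcome_stats outcome summary table with the same columns.
#' @param cell_type_map character vector of exposure cell types considered
#'   a match for the outcome trait's cell type.
#' @param window total window width in bp (default 2e5).
#' @param p_max eQTL p-value threshold (default 1e-5, inclusive).
#' @return data.frame of harmonized instruments (possibly 0 rows), with
#'   attribute \code{n_rejected}.
#' @export
select_instruments <- function(varsnp, eqtl_stats, outcome_stats,
                               cell_type_map = NULL, window = 2e5,
                               p_max = 1e-5) {
  half <- window / 2
  sel <- eqtl_stats$chrom == varsnp$chrom &
    abs(eqtl_stats$pos - varsnp$pos) <= half &
    eqtl_stats$p <= p_max
  if (!is.null(cell_type_map) && "cell_type" %in% names(eqtl_stats))
    sel <- sel & eqtl_stats$cell_type %in% cell_type_map
  cand <- eqtl_stats[sel, , drop = FALSE]
  cand <- cand[cand$snp %in% outcome_stats$snp, , drop = FALSE]
  out <- list(); n_rej <- 0L
  for (i in seq_len(nrow(cand))) {
    orow <- outcome_stats[match(cand$snp[i], outcome_stats$snp), ]
    h <- harmonize(cand[i, ], orow)
    if (h$rejected) n_rej <- n_rej + 1L else out[[length(out) + 1L]] <- h$instrument
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(snp = character(), effect_allele = character(),
               other_allele = character(), b_x = numeric(), se_x = numeric(),
               b_y = numeric(), se_y = numeric(), stringsAsFactors = FALSE)
  attr(res, "n_rejected") <- n_rej
  res
}

#' Wald ratio causal-effect estimate for a single instrument
#'
#' \eqn{\beta_{causal} = b_y / b_x} with first-order delta-method standard
#' error \eqn{\sqrt{se_y^2 / b_x^2 + b_y^2 se_x^2 / b_x^4}} and a normal
#' approximation for the p-value.
#'
#' @param b_x,se_x exposure effect and SE; @param b_y,se_y outcome effect
#'   and SE.
#' @return data.frame row: method, beta, se, p, n_instruments.
#' @export
mr_ratio <- function(b_x, se_x, b_y, se_y) {
  if (b_x == 0) stop("weak/null instrument: exposure effect is zero")
  beta <- b_y / b_x
  se <- sqrt(se_y^2 / b_x^2 + b_y^2 * se_x^2 / b_x^4)
  data.frame(method = "ratio", beta = beta, se = se,
             p = 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE),
             n_instruments = 1L, stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted combination of Wald ratios
#'
#' \eqn{\beta_{IVW} = \sum w_j r_j / \sum w_j} with \eqn{r_j = b_{y,j} /
#' b_{x,j}} and first-order weights \eqn{w_j = b_{x,j}^2 / se_{y,j}^2}.
#'
#' @param instruments harmonized instrument data.frame (b_x, se_x, b_y,
#'   se_y).
#' @return data.frame row: method, beta, se, p, n_instruments.
#' @export
mr_ivw <- function(instruments) {
  stopifnot(nrow(instruments) >= 1L)
  w <- instruments$b_x^2 / instruments$se_y^2
  r <- instruments$b_y / instruments$b_x
  beta <- sum(w * r) / sum(w)
  se <- sqrt(1 / sum(w))
  data.frame(method = "ivw", beta = beta, se = se,
             p = 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE),
             n_instruments = nrow(instruments), stringsAsFactors = FALSE)
}

#' Maximum-likelihood causal-effect estimate
#'
#' Maximizes the joint normal likelihood \eqn{b_{x,j} \sim N(\xi_j,
#' se_{x,j}^2)}, \eqn{b_{y,j} \sim N(\beta \xi_j, se_{y,j}^2)} over the
#' per-instrument true exposure effects \eqn{\xi_j} and a single causal
#' \eqn{\beta}, by profiling \eqn{\xi_j} out in closed form. The SE comes
#' from the curvature of the profile likelihood (observed information).
#' With a single instrument this reduces to the Wald ratio.
#'
#' @param instruments harmonized instrument data.frame.
#' @return data.frame row: method, beta, se, p, n_instruments.
#' @export
mr_ml <- function(instruments) {
  J <- nrow(instruments)
  stopifnot(J >= 1L)
  bx <- instruments$b_x; sx2 <- instruments$se_x^2
  by <- instruments$b_y; sy2 <- instruments$se_y^2
  prof_nll <- function(beta) {
    xi <- (bx / sx2 + beta * by / sy2) / (1 / sx2 + beta^2 / sy2)
    sum((bx - xi)^2 / sx2 + (by - beta * xi)^2 / sy2) / 2
  }
  start <- mr_ivw(instruments)$beta
  o <- stats::optim(start, prof_nll, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-12))
  if (o$convergence != 0) stop("ML estimator failed to converge: code ",
                               o$convergence)
  beta <- o$par
  h <- 1e-4 * max(1, abs(beta))
  info <- (prof_nll(beta + h) - 2 * prof_nll(beta) + prof_nll(beta - h)) / h^2
  if (!is.finite(info) || info <= 0) stop("singular information at the ML optimum")
  se <- sqrt(1 / info)
  data.frame(method = "ml", beta = beta, se = se,
             p = 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE),
             n_instruments = J, stringsAsFactors = FALSE)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a
#' free intercept (weights \eqn{1/se_y^2}); exposure effects are oriented
#' non-negative first. The slope estimates the causal effect under the
#' InSIDE assumption; a non-zero intercept indicates directional
#' pleiotropy. Requires at least 3 instruments.
#'
#' @param instruments harmonized instrument data.frame.
#' @return data.frame row: method, beta, se, p, n_instruments,
#'   egger_intercept, egger_intercept_se, egger_intercept_p.
#' @export
mr_egger <- function(instruments) {
  J <- nrow(instruments)
  if (J < 3L) stop("Egger underdetermined: need at least 3 instruments")
  flip <- sign(instruments$b_x)
  flip[flip == 0] <- 1
  bx <- instruments$b_x * flip
  by <- instruments$b_y * flip
  w <- 1 / instruments$se_y^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)$coefficients
  data.frame(method = "egger",
             beta = sm["bx", "Estimate"], se = sm["bx", "Std. Error"],
             p = sm["bx", "Pr(>|t|)"],
             n_instruments = J,
             egger_intercept = sm["(Intercept)", "Estimate"],
             egger_intercept_se = sm["(Intercept)", "Std. Error"],
             egger_intercept_p = sm["(Intercept)", "Pr(>|t|)"],
             stringsAsFactors = FALSE)
}

#' Cochran's Q heterogeneity statistic over Wald ratios
#'
#' \eqn{Q = \sum_j w_j (r_j - \beta_{IVW})^2} with first-order
#' delta-method weights \eqn{w_j = 1/\mathrm{var}(r_j)}; p from chi-squared
#' with J-1 df. Second-order weights (adding the \eqn{b_y^2 se_x^2 /
#' b_x^4} term) behind \code{weights = "second"}.
#'
#' @param instruments harmonized instrument data.frame (>= 2 rows).
#' @param weights \code{"first"} (default) or \code{"second"} order.
#' @return list: Q, df, p.
#' @export
cochran_q <- function(instruments, weights = c("first", "second")) {
  weights <- match.arg(weights)
  J <- nrow(instruments)
  if (J < 2L) return(list(Q = NA_real_, df = NA_integer_, p = NA_real_))
  r <- instruments$b_y / instruments$b_x
  v <- instruments$se_y^2 / instruments$b_x^2
  if (weights == "second")
    v <- v + instruments$b_y^2 * instruments$se_x^2 / instruments$b_x^4
  w <- 1 / v
  beta <- sum(w * r) / sum(w)
  Q <- sum(w * (r - beta)^2)
  list(Q = Q, df = J - 1L,
       p = stats::pchisq(Q, df = J - 1L, lower.tail = FALSE))
}

#' Screen (exposure, outcome) pairs with FDR control
#'
#' For each pair: single-instrument pairs use the Wald ratio (equivalently
#' ML); pairs with 2 instruments use ML; pairs with 3 or more use MR-Egger
#' (slope) when \code{multi_method = "egger"} or ML otherwise, with
#' Cochran's Q reported whenever 2 or more instruments are available.
#' Benjamini-Hochberg FDR is applied across all tested pairs; pairs with
#' empty instrument sets are excluded from the FDR denominator. A pair is
#' flagged "explained" when it passes the FDR threshold.
#'
#' @param pairs named list of harmonized instrument data.frames (one per
#'   (exposure, outcome) pair).
#' @param fdr FDR level (default 0.10).
#' @param multi_method \code{"ml"} (default) or \code{"egger"} for pairs
#'   with >= 3 instruments.
#' @return data.frame: pair, method, n_snps, beta, se, p, q_fdr, explained,
#'   egger_intercept(_se), Q, Q_df, Q_p.
#' @export
mr_screen <- function(pairs, fdr = 0.10, multi_method = c("ml", "egger")) {
  multi_method <- match.arg(multi_method)
  stopifnot(length(pairs) >= 1L)
  nm <- names(pairs) %||% paste0("pair", seq_along(pairs))
  rows <- list()
  for (i in seq_along(pairs)) {
    ins <- pairs[[i]]
    if (is.null(ins) || nrow(ins) == 0L) next
    est <- if (nrow(ins) == 1L)
      mr_ratio(ins$b_x, ins$se_x, ins$b_y, ins$se_y)
    else if (nrow(ins) >= 3L && multi_method == "egger") mr_egger(ins)
    else mr_ml(ins)
    q <- cochran_q(ins)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = nm[i], method = est$method, n_snps = nrow(ins),
      beta = est$beta, se = est$se, p = est$p,
      egger_intercept = if ("egger_intercept" %in% names(est))
        est$egger_intercept else NA_real_,
      egger_intercept_se = if ("egger_intercept_se" %in% names(est))
        est$egger_intercept_se else NA_real_,
      Q = q$Q, Q_df = q$df, Q_p = q$p,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out$q_fdr <- stats::p.adjust(out$p, method = "BH")
  out$explained <- out$q_fdr <= fdr
  out
}
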