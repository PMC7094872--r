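# Mean-adjusted variability statistic: local polynomial fit of log10 CV^2
# on log10 mean across individuals, standardized residuals (eta_res).

#' Fit the mean-CV^2 relationship for one trait across individuals
#'
#' Cell-to-cell variability (CV^2) is strongly and inversely coupled to mean
#' expression; a locally weighted polynomial regression of log10(CV^2) on
#' log10(mean) across individuals captures this trend so it can be removed.
#' Uses tricube-weighted local regression (degree 2, span 0.75 by default)
#' with robustness iterations and exact (direct-surface) prediction.
#' Fitting is done within a single cohort; pooling cohorts is refused
#' upstream.
#'
#' @param summaries data.frame with columns \code{mean} and \code{cv2} (one
#'   row per individual) for a single (cell type, protein) trait.
#' @param span loess span (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @return object of class \code{mean_cv2_fit}: list with \code{predict}
#'   (function of log10 mean, clamped to the observed range at the
#'   boundaries), \code{range} (observed log10-mean range), \code{n} and
#'   fit metadata.
#' @export
fit_mean_cv2 <- function(summaries, span = 0.75, degree = 2L) {
  stopifnot(all(c("mean", "cv2") %in% names(summaries)))
  n <- nrow(summaries)
  if (n < max(10L, degree + 2L))
    stop(sprintf("need at least %d individuals to fit the mean-CV2 curve",
                 max(10L, degree + 2L)))
  if (any(summaries$mean <= 0)) stop("means must be positive for the log fit")
  cv2 <- summaries$cv2
  if (any(cv2 < 0)) stop("cv2 must be non-negative")
  if (any(cv2 == 0)) {
    offset <- min(cv2[cv2 > 0]) * 1e-3
    cv2[cv2 == 0] <- offset
    warning("zero cv2 values offset by smallest positive cv2 x 1e-3")
  }
  lx <- log10(summaries$mean)
  ly <- log10(cv2)
  fit <- stats::loess(ly ~ lx, span = span, degree = degree,
                      family = "symmetric",
                      control = stats::loess.control(surface = "direct"))
  rng <- range(lx)
  pred <- function(x) {
    clamped <- pmin(pmax(x, rng[1]), rng[2])
    if (any(x < rng[1] | x > rng[2]))
      warning("extrapolation at boundary: using nearest fitted value")
    as.numeric(stats::predict(fit, data.frame(lx = clamped)))
  }
  structure(list(predict = pred, range = rng, n = n,
                 span = span, degree = degree, loess = fit),
            class = "mean_cv2_fit")
}

#' Mean-adjusted variability (eta_res) for one trait
#'
#' Residuals of log10(CV^2) from the fitted mean-CV^2 curve are standardized
#' across individuals to zero mean and unit variance (n-1 sample standard
#' deviation), giving the per-individual mean-adjusted variability in units
#' of residual standard deviations.
#'
#' @param summaries data.frame with \code{mean} and \code{cv2} columns (and
#'   optionally \code{individual}).
#' @param fit a \code{\link{fit_mean_cv2}} object for the same trait.
#' @return numeric vector of eta_res values (named by individual when
#'   available), mean 0 and variance 1.
#' @export
eta_res <- function(summaries, fit) {
  stopifnot(inherits(fit, "mean_cv2_fit"))
  r <- log10(summaries$cv2) - fit$predict(log10(summaries$mean))
  s <- stats::sd(r)
  if (!is.finite(s) || s == 0) stop("degenerate trait: all residuals identical")
  out <- (r - mean(r)) / s
  if ("individual" %in% names(summaries)) names(out) <- summaries$individual
  out
}

#' Build an individuals-by-traits eta_res matrix
#'
#' Fits the mean-CV^2 curve and computes eta_res separately for every
#' (cell type, protein) trait present in a cohort's trait summary table.
#'
#' @param summaries data.frame with columns individual, cell_type, protein,
#'   mean, cv2 for one cohort.
#' @param span,degree passed to \code{\link{fit_mean_cv2}}.
#' @return numeric matrix, rows = individuals, columns = traits named
#'   "cell_type:protein"; missing combinations are NA.
#' @export
eta_res_matrix <- function(summaries, span = 0.75, degree = 2L) {
  key <- paste(summaries$cell_type, summaries$protein, sep = ":")
  inds <- sort(unique(summaries$individual))
  traits <- unique(key)
  M <- matrix(NA_real_, length(inds), length(traits),
              dimnames = list(inds, traits))
  for (tr in traits) {
    sub <- summaries[key == tr, , drop = FALSE]
    f <- fit_mean_cv2(sub, span = span, degree = degree)
    M[match(sub$individual, inds), tr] <- eta_res(sub, f)
  }
  M
}
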