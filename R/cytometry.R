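# Flow-cytometry event preprocessing: sample-level QC, biexponential
# transform, cross-sample landmark normalization, doublet removal,
# rectangular gating, cell-volume normalization and per-trait summaries.

#' Biexponential transform parameters
#'
#' The forward map is \eqn{y(x) = a e^{bx} - c e^{-dx} + f}; the transform
#' applied to fluorescence data is its inverse. Defaults (a = c = 0.5,
#' b = d = 1, f = 0) make the transform identical to asinh.
#'
#' @param a,b,c,d,f real parameters; the forward map must be strictly
#'   increasing, which holds whenever a, b, d > 0 and c >= 0.
#' @return object of class \code{biexp_params}.
#' @export
biexp_params <- function(a = 0.5, b = 1, c = 0.5, d = 1, f = 0) {
  if (a <= 0 || b <= 0 || d <= 0 || c < 0)
    stop("non-monotone biexponential parameter set: need a,b,d > 0 and c >= 0")
  structure(list(a = a, b = b, c = c, d = d, f = f), class = "biexp_params")
}

.biexp_forward <- function(x, p) p$a * exp(p$b * x) - p$c * exp(-p$d * x) + p$f

#' Inverse biexponential transform
#'
#' Returns x such that \eqn{a e^{bx} - c e^{-dx} + f = v} for each value v,
#' by monotone bisection to a relative tolerance of 1e-9. With default
#' parameters this equals \code{asinh(v)}. Intended for non-scatter
#' (fluorescence) channels only.
#'
#' @param values numeric vector of raw channel values.
#' @param params a \code{\link{biexp_params}}.
#' @return numeric vector of transformed values.
#' @export
biexp_transform <- function(values, params = biexp_params()) {
  stopifnot(inherits(params, "biexp_params"))
  vapply(values, function(v) {
    if (!is.finite(v)) return(NA_real_)
    tol <- 1e-9 * max(1, abs(v))
    # bracket the root
    lo <- -1; hi <- 1
    while (.biexp_forward(lo, params) > v) lo <- lo * 2
    while (.biexp_forward(hi, params) < v) hi <- hi * 2
    stats::uniroot(function(x) .biexp_forward(x, params) - v,
                   lower = lo, upper = hi,
                   tol = .Machine$double.eps^0.75)$root
  }, numeric(1))
}

#' Reject event tables with too few recorded events
#'
#' Samples with fewer than \code{min_events} total events are rejected;
#' the boundary is strict (exactly \code{min_events} events pass).
#'
#' @param events event data.frame (one row per event).
#' @param min_events minimum total events (default 1000).
#' @return list with \code{events} (the table, or \code{NULL} if rejected),
#'   \code{rejected} (logical) and \code{reason}.
#' @export
filter_low_event_samples <- function(events, min_events = 1000L) {
  n <- nrow(events)
  if (n < min_events) {
    list(events = NULL, rejected = TRUE,
         reason = sprintf("sample has %d events (< %d)", n, min_events))
  } else {
    list(events = events, rejected = FALSE, reason = NA_character_)
  }
}

# kernel-density landmark positions: locations of the top-k modes
.find_landmarks <- function(x, peakNr, bwFac) {
  bw <- bwFac * stats::bw.nrd0(x)
  d <- stats::density(x, bw = bw, n = 512)
  y <- d$y
  is_peak <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] > y[3:length(y)], FALSE)
  px <- d$x[is_peak]; ph <- y[is_peak]
  if (length(px) == 0L) { px <- d$x[which.max(y)]; ph <- max(y) }
  ord <- order(ph, decreasing = TRUE)
  k <- min(peakNr, length(px))
  sort(px[ord][seq_len(k)])
}

#' Align landmark positions of a channel across samples
#'
#' For each sample the top-\code{peakNr} density modes (bandwidth =
#' \code{bwFac} times Silverman's rule) are located; a strictly increasing
#' piecewise-linear warp maps each sample's landmarks to the cross-sample
#' median landmark positions. Samples in which fewer than \code{peakNr}
#' peaks are detected are matched on the highest-ranked peaks with a
#' warning. Values outside the landmark range are shifted by the boundary
#' segment's affine map, so the warp is increasing on the whole line and
#' value ranks are preserved.
#'
#' @param samples list of event data.frames.
#' @param channel channel to normalize.
#' @param peakNr number of principal landmarks (default 2).
#' @param nbreaks number of spline/segment sections (retained for interface
#'   compatibility; the piecewise-linear warp uses the landmarks as breaks).
#' @param bwFac density bandwidth factor (default 2).
#' @return list of event data.frames with the channel warped.
#' @export
landmark_normalize <- function(samples, channel, peakNr = 2L, nbreaks = 11L,
                               bwFac = 2) {
  stopifnot(length(samples) >= 2L, peakNr >= 1L, bwFac > 0)
  lms <- lapply(samples, function(s) {
    if (!channel %in% names(s)) stop("channel absent from a sample: ", channel)
    .find_landmarks(s[[channel]], peakNr, bwFac)
  })
  k_min <- min(lengths(lms))
  if (k_min < peakNr)
    warning(sprintf("only %d peak(s) detected in some sample; matching top %d by rank",
                    k_min, k_min))
  lms <- lapply(lms, function(l) sort(l)[seq_len(k_min)])
  target <- apply(do.call(rbind, lms), 2, stats::median)
  lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    src <- lms[[i]]
    x <- s[[channel]]
    if (k_min == 1L) {
      s[[channel]] <- x + (target - src)
    } else {
      # piecewise linear through (src, target); affine continuation outside
      w <- stats::approx(src, target, xout = pmin(pmax(x, src[1]), src[k_min]),
                         ties = "ordered")$y
      below <- x < src[1]; above <- x > src[k_min]
      slope_lo <- (target[2] - target[1]) / (src[2] - src[1])
      slope_hi <- (target[k_min] - target[k_min - 1]) /
        (src[k_min] - src[k_min - 1])
      w[below] <- target[1] + slope_lo * (x[below] - src[1])
      w[above] <- target[k_min] + slope_hi * (x[above] - src[k_min])
      s[[channel]] <- w
    }
    s
  })
}

#' Remove doublets by the FSC-A/FSC-H pulse-shape ratio
#'
#' Events whose forward-scatter area-to-height ratio falls outside
#' \code{ratio_band} are discarded; a doublet formed by two coincident cells
#' has roughly double area at similar height, so its ratio is near 2.
#' Events with non-positive FSC-H are dropped and counted.
#'
#' @param events event data.frame with FSC-A and FSC-H columns.
#' @param ratio_band length-2 numeric band (default \code{c(0.8, 1.3)}).
#' @return list with \code{events} (singlets), \code{removed_fraction} and
#'   \code{n_invalid} (non-positive FSC-H).
#' @export
remove_doublets <- function(events, ratio_band = c(0.8, 1.3)) {
  stopifnot(all(c("FSC-A", "FSC-H") %in% names(events)))
  n0 <- nrow(events)
  invalid <- events[["FSC-H"]] <= 0
  ev <- events[!invalid, , drop = FALSE]
  ratio <- ev[["FSC-A"]] / ev[["FSC-H"]]
  keep <- ratio >= ratio_band[1] & ratio <= ratio_band[2]
  list(events = ev[keep, , drop = FALSE],
       removed_fraction = if (n0 > 0) (n0 - sum(keep)) / n0 else 0,
       n_invalid = sum(invalid))
}

#' Build a rectangular gate tree
#'
#' Each gate is a rectangle on two channels with a population label;
#' gates are applied sequentially so populations are nested along the list.
#'
#' @param gates list of lists with fields \code{x}, \code{y} (channel
#'   names), \code{xlim}, \code{ylim} (length-2 bounds) and \code{label}.
#' @return object of class \code{gate_tree}.
#' @export
gate_tree <- function(gates) {
  for (g in gates) {
    stopifnot(all(c("x", "y", "xlim", "ylim", "label") %in% names(g)))
    if (g$xlim[1] > g$xlim[2] || g$ylim[1] > g$ylim[2])
      stop("gate bounds must be ordered")
  }
  labs <- vapply(gates, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("gate labels must be unique")
  structure(gates, class = "gate_tree")
}

#' Assign events to gated populations
#'
#' Applies the gates of a \code{\link{gate_tree}} in order, each gate
#' subsetting the previous population, and returns the event subset at each
#' node keyed by its label.
#'
#' @param events event data.frame.
#' @param gates a \code{\link{gate_tree}}.
#' @return named list mapping population label to event data.frame.
#' @export
gate_population <- function(events, gates) {
  stopifnot(inherits(gates, "gate_tree"))
  out <- list()
  current <- events
  for (g in gates) {
    if (!g$x %in% names(current) || !g$y %in% names(current))
      stop("gate on missing channel: ", g$x, "/", g$y)
    inside <- current[[g$x]] >= g$xlim[1] & current[[g$x]] <= g$xlim[2] &
      current[[g$y]] >= g$ylim[1] & current[[g$y]] <= g$ylim[2]
    current <- current[inside, , drop = FALSE]
    out[[g$label]] <- current
  }
  out
}

#' Cell volume from forward-scatter area
#'
#' Volume is the log10 of the cubed forward-scatter area, i.e.
#' \code{3 * log10(fsc_a)}.
#'
#' @param fsc_a positive forward-scatter area values.
#' @return numeric volumes.
#' @export
cell_volume <- function(fsc_a) {
  if (any(fsc_a <= 0)) stop("forward-scatter area must be positive")
  3 * log10(fsc_a)
}

#' Normalize log10 fluorescence to cell volume
#'
#' The default mode divides log10 fluorescence by cell volume. The
#' \code{"residual"} mode instead returns residuals of log10 fluorescence
#' regressed on volume (an alternative reading of volume normalization).
#' Events with non-positive fluorescence cannot be logged and are dropped.
#'
#' @param fluor raw fluorescence values.
#' @param volumes per-event cell volumes (positive).
#' @param mode \code{"divide"} (default) or \code{"residual"}.
#' @return list with \code{values} (normalized), \code{kept} (logical index
#'   of retained events) and \code{n_dropped}.
#' @export
volume_normalize <- function(fluor, volumes, mode = c("divide", "residual")) {
  mode <- match.arg(mode)
  stopifnot(length(fluor) == length(volumes))
  if (any(volumes <= 0)) stop("volumes must be positive")
  keep <- fluor > 0
  lf <- log10(fluor[keep])
  v <- volumes[keep]
  vals <- if (mode == "divide") lf / v else stats::resid(stats::lm(lf ~ v))
  list(values = as.numeric(vals), kept = keep, n_dropped = sum(!keep))
}

#' Summarize a gated population into a trait record
#'
#' Computes the per-individual mean and squared coefficient of variation
#' (sample variance with n-1 denominator divided by the squared mean) of
#' volume-normalized expression. Populations with fewer than
#' \code{min_cells} cells, or with zero mean (CV-squared undefined), are
#' rejected.
#'
#' @param values normalized expression values for one population.
#' @param individual,cell_type,protein identifiers.
#' @param min_cells minimum population size (default 100).
#' @return list with \code{summary} (data.frame row: individual, cell_type,
#'   protein, n_cells, mean, cv2; or \code{NULL}), \code{rejected},
#'   \code{reason}.
#' @export
summarize_trait <- function(values, individual, cell_type, protein,
                            min_cells = 100L) {
  n <- length(values)
  if (n < min_cells)
    return(list(summary = NULL, rejected = TRUE,
                reason = sprintf("%d cells (< %d)", n, min_cells)))
  m <- mean(values)
  if (m == 0)
    return(list(summary = NULL, rejected = TRUE,
                reason = "zero mean: cv2 undefined"))
  list(summary = data.frame(individual = individual, cell_type = cell_type,
                            protein = protein, n_cells = n,
                            mean = m, cv2 = stats::var(values) / m^2,
                            stringsAsFactors = FALSE),
       rejected = FALSE, reason = NA_character_)
}

#' Run the full cytometry preprocessing pipeline over a cohort
#'
#' Fixed stage order: sample event-count filter, biexponential transform of
#' fluorescence channels, cross-sample landmark normalization, doublet
#' removal, gating, volume normalization, trait summarization. Every
#' rejection is recorded in the QC report.
#'
#' @param samples named list (by individual id) of raw event data.frames.
#' @param channel fluorescence channel carrying the protein signal.
#' @param gates optional \code{\link{gate_tree}} applied after doublet
#'   removal; \code{NULL} keeps all singlets as one population.
#' @param cell_type,protein labels for the summarized trait.
#' @param min_events,min_cells QC thresholds.
#' @param doublet_band FSC-A/FSC-H singlet band.
#' @param biexp \code{\link{biexp_params}} for the fluorescence transform;
#'   \code{NULL} skips the transform (synthetic linear-scale data).
#' @param normalize_landmarks logical; warp the fluorescence channel across
#'   samples before gating.
#' @param volume_mode passed to \code{\link{volume_normalize}}.
#' @return list with \code{summaries} (data.frame of retained traits) and
#'   \code{qc} (per-sample record of events in/out and rejections).
#' @export
process_cytometry <- function(samples, channel, gates = NULL,
                              cell_type = "all", protein = channel,
                              min_events = 1000L, min_cells = 100L,
                              doublet_band = c(0.8, 1.3),
                              biexp = NULL, normalize_landmarks = FALSE,
                              volume_mode = "divide") {
  qc <- list(); out <- list()
  kept <- list()
  for (id in names(samples)) {
    f <- filter_low_event_samples(samples[[id]], min_events)
    if (f$rejected) {
      qc[[id]] <- list(stage = "event_filter", reason = f$reason)
      next
    }
    ev <- f$events
    if (!is.null(biexp)) ev[[channel]] <- biexp_transform(ev[[channel]], biexp)
    kept[[id]] <- ev
  }
  if (normalize_landmarks && length(kept) >= 2L)
    kept <- stats::setNames(landmark_normalize(kept, channel), names(kept))
  for (id in names(kept)) {
    ev <- kept[[id]]
    dd <- remove_doublets(ev, doublet_band)
    ev <- dd$events
    pops <- if (is.null(gates)) list(all = ev) else gate_population(ev, gates)
    pop <- pops[[length(pops)]]
    vols <- cell_volume(pop[["FSC-A"]])
    vn <- volume_normalize(pop[[channel]], vols, mode = volume_mode)
    s <- summarize_trait(vn$values, id, cell_type, protein, min_cells)
    if (s$rejected) {
      qc[[id]] <- list(stage = "summarize", reason = s$reason,
                       doublets_removed = dd$removed_fraction)
    } else {
      out[[id]] <- s$summary
      qc[[id]] <- list(stage = "pass", reason = NA_character_,
                       doublets_removed = dd$removed_fraction,
                       n_nonpositive = vn$n_dropped)
    }
  }
  list(summaries = if (length(out)) do.call(rbind, out) else NULL, qc = qc)
}
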