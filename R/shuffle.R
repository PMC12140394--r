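# The shuffle player. It builds surrogate window ensembles that destroy the
# temporal (or, in static mode, cross-channel) structure of the data, then
# importance-resamples them so that the distribution of surrogate filtering
# errors matches the data's. The resampling function zeta is the ratio of
# the two projected error densities, estimated with a shared-support
# histogram; surrogates whose error falls in a bin carrying zero data mass
# get weight zero, which blocks "constraint detector" artefact solutions.

#' Build an unconstrained surrogate ensemble
#'
#' In `"tail"` mode (the dynamic-regulation null) each surrogate keeps a
#' verbatim length-`T` history prefix taken from a uniformly drawn data
#' window and replaces the final sample with an observation drawn uniformly
#' (with replacement) from the pooled marginal over all series, detaching
#' the predicted sample from its history. In `"channel"` mode (the
#' fixed-set-point null used by the static reduction) every sample of the
#' surrogate window is rebuilt with each channel drawn independently from
#' that channel's pooled marginal, destroying the co-variation between
#' channels instead of the temporal link.
#'
#' @param we a `window_ensemble` from [build_windows()].
#' @param ts the [ts_set()] the windows came from (source of the pooled
#'   marginal).
#' @param count number of surrogates to draw.
#' @param mode `"tail"` or `"channel"`.
#' @return a `surrogate_ensemble`: array `Z` (`count x (T+1) x n`),
#'   provenance vectors `prefix_source` (window index; `NA` in channel mode)
#'   and `tail_source` (pooled-sample row index of the final sample),
#'   `constrained = FALSE`.
#' @export
make_unconstrained_surrogates <- function(we, ts, count,
                                          mode = c("tail", "channel")) {
  mode <- match.arg(mode)
  stopifnot(inherits(we, "window_ensemble"), inherits(ts, "ts_set"))
  count <- as.integer(count)
  if (count < 1L) stop("count must be >= 1", call. = FALSE)
  B <- dim(we$Z)[1L]
  if (B == 0L) stop("empty window ensemble", call. = FALSE)
  pool <- pooled_samples(ts)
  Tp1 <- we$T + 1L
  n <- dim(we$Z)[3L]
  if (mode == "tail") {
    pre <- sample.int(B, count, replace = TRUE)
    tail_idx <- sample.int(nrow(pool), count, replace = TRUE)
    Z <- we$Z[pre, , , drop = FALSE]
    Z[, Tp1, ] <- pool[tail_idx, , drop = FALSE]
    prefix_source <- pre
  } else {
    # every (sample, channel) cell drawn independently from that channel's
    # pooled marginal
    Z <- array(NA_real_, dim = c(count, Tp1, n))
    for (ch in seq_len(n)) {
      idx <- sample.int(nrow(pool), count * Tp1, replace = TRUE)
      Z[, , ch] <- matrix(pool[idx, ch], count, Tp1)
    }
    prefix_source <- rep(NA_integer_, count)
    tail_idx <- rep(NA_integer_, count)
  }
  structure(list(Z = Z, T = we$T, prefix_source = prefix_source,
                 tail_source = tail_idx, weights = NULL,
                 constrained = FALSE, mode = mode),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat("<surrogate_ensemble> ", dim(x$Z)[1L], " surrogates (", x$mode,
      " shuffle), ", if (x$constrained) "constrained" else "unconstrained",
      "\n", sep = "")
  invisible(x)
}

#' Histogram estimate of an error density
#'
#' Empirical per-bin probability masses of a scalar error sample over shared
#' bin edges. Both players only ever see these one-dimensional projected
#' densities, never a density in window space.
#'
#' @param errors numeric vector.
#' @param bins numeric vector of bin edges (length >= 3, strictly
#'   increasing), spanning all values of `errors`.
#' @return numeric vector of `length(bins) - 1` masses summing to 1.
#' @export
estimate_error_density <- function(errors, bins) {
  if (length(errors) == 0L) stop("no errors supplied", call. = FALSE)
  if (length(bins) < 3L) stop("need at least 2 bins", call. = FALSE)
  idx <- bin_index(errors, bins)
  tabulate(idx, nbins = length(bins) - 1L) / length(errors)
}

# Shared bin edges spanning the union range of two samples. Edges are
# placed at quantiles of the pooled sample (equal-mass bins): when the data
# errors are far more concentrated than the surrogate errors, equal-width
# bins would lump most of the data into one or two bins and the resampled
# match would be poor exactly where it matters; equal-mass bins keep the
# histogram resolution proportional to where either sample has mass.
shared_bins <- function(a, b, n_bins = 50L) {
  x <- c(a, b)
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                               names = FALSE, type = 8))
  if (length(qs) < 3L) {
    lo <- min(x); hi <- max(x)
    if (hi <= lo) { lo <- lo - 0.5; hi <- hi + 0.5 }
    qs <- seq(lo, hi, length.out = 3L)
  }
  pad <- (qs[length(qs)] - qs[1L]) * 1e-9 + 1e-300
  qs[1L] <- qs[1L] - pad
  qs[length(qs)] <- qs[length(qs)] + pad
  qs
}

bin_index <- function(x, bins) {
  idx <- findInterval(x, bins, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), length(bins) - 1L)
}

#' Constrain a surrogate ensemble by zeta-resampling
#'
#' Computes the filtering error of every surrogate under the current model,
#' weights each surrogate by the ratio of the data-error density to the
#' surrogate-error density at its own error (zero where the data density is
#' zero), and importance-resamples with replacement down to
#' `target_count` windows. After resampling the surrogate error
#' distribution matches the data error distribution (up to histogram and
#' Monte-Carlo resolution), which resets the variance ratio to ~1 and makes
#' the ensemble adversarial for the combination player.
#'
#' @param se an unconstrained `surrogate_ensemble`.
#' @param model the current [model_state()].
#' @param data_errors filtering errors of the real data windows under the
#'   same model (and the same gauge).
#' @param n_bins number of shared histogram bins.
#' @param target_count size of the resampled ensemble (default: number of
#'   data errors, keeping the two variance estimates comparable).
#' @param gauge gauge (mean/scale of c) under which the surrogate errors are
#'   evaluated; must be the one used for `data_errors`.
#' @return a constrained `surrogate_ensemble` with normalised `weights`
#'   (the zeta weights of the unconstrained draw) and resampled windows.
#' @export
resample_surrogates <- function(se, model, data_errors, n_bins = 50L,
                                target_count = length(data_errors),
                                gauge = NULL) {
  stopifnot(inherits(se, "surrogate_ensemble"))
  if (isTRUE(se$constrained))
    stop("surrogate ensemble is already constrained", call. = FALSE)
  surr_errors <- errors_forward(model, se$Z,
                                gauge = gauge %||% gauge_identity())$e
  bins <- shared_bins(data_errors, surr_errors, n_bins)
  f_data <- estimate_error_density(data_errors, bins)
  f_surr <- estimate_error_density(surr_errors, bins)
  zeta <- ifelse(f_surr > 0, f_data / f_surr, 0)
  w <- zeta[bin_index(surr_errors, bins)]
  # zero branch, enforced at the sample level: surrogates whose error lies
  # outside the observed data-error support can never be selected
  w[surr_errors < min(data_errors) | surr_errors > max(data_errors)] <- 0
  if (!any(w > 0))
    stop("degenerate zeta: data and surrogate filtering errors share no ",
         "histogram support; try wider bins or re-initialising the model",
         call. = FALSE)
  w <- w / sum(w)
  pick <- sample.int(length(w), target_count, replace = TRUE, prob = w)
  structure(list(Z = se$Z[pick, , , drop = FALSE], T = se$T,
                 prefix_source = se$prefix_source[pick],
                 tail_source = se$tail_source[pick],
                 weights = w, picked = pick,
                 constrained = TRUE, mode = se$mode,
                 bins = bins, f_data = f_data, f_surr = f_surr),
            class = "surrogate_ensemble")
}

# Two-sample Kolmogorov-Smirnov statistic (no ties handling needed for the
# continuous errors used here); kept internal, diagnostics only.
ks_stat <- function(a, b) {
  all_v <- sort(c(a, b))
  Fa <- stats::ecdf(a)(all_v)
  Fb <- stats::ecdf(b)(all_v)
  max(abs(Fa - Fb))
}
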