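# Metrics for scoring a fit against a known control objective, plus the
# closed-form reference quantities of the bacterial model.

#' Sign-aligned Pearson correlation
#'
#' The learned combination is identifiable only up to sign/affine gauge, so
#' correlations are reported after multiplying `c` by the sign of its
#' covariance with the reference - equivalently, the absolute correlation.
#' With a `group` vector (e.g. series ids), both inputs are standardised
#' within each group before pooling, so slow between-series offsets do not
#' inflate the score.
#'
#' @param c_star reference (ground-truth) values.
#' @param c learned values, same length.
#' @param group optional grouping vector for per-group standardisation.
#' @return correlation in `[0, 1]`.
#' @export
pearson_aligned <- function(c_star, c, group = NULL) {
  if (length(c_star) != length(c))
    stop("length mismatch: reference has ", length(c_star),
         " values, learned series has ", length(c), call. = FALSE)
  if (length(c) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (!is.null(group)) {
    std <- function(x) {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
      (x - mean(x)) / s
    }
    c_star <- unlist(tapply(c_star, group, std, simplify = FALSE),
                     use.names = FALSE)
    c <- unlist(tapply(c, group, std, simplify = FALSE), use.names = FALSE)
    keep <- is.finite(c_star) & is.finite(c)
    c_star <- c_star[keep]; c <- c[keep]
  }
  if (stats::sd(c_star) == 0 || stats::sd(c) == 0)
    stop("correlation undefined for a constant input", call. = FALSE)
  abs(stats::cor(c_star, c))
}

#' Normalised mean-square error
#'
#' `var(c - c_hat) / var(c)` (population variances): 0 is perfect one-step
#' prediction, 1 is no better than predicting the mean.
#'
#' @param c realised values.
#' @param c_hat predictions, same length.
#' @return a non-negative scalar.
#' @export
nmse <- function(c, c_hat) {
  if (length(c) != length(c_hat))
    stop("length mismatch: ", length(c), " vs ", length(c_hat), call. = FALSE)
  if (length(c) < 2L) stop("need at least 2 values", call. = FALSE)
  vc <- pop_var(c)
  if (vc <= 0) stop("var(c) must be positive", call. = FALSE)
  pop_var(c - c_hat) / vc
}

#' Sizer / adder / timer reference indicators
#'
#' The three candidate division rules evaluated on lineage records: sizer
#' `x_b * exp(alpha * T)` (the size at division), adder
#' `x_b * (exp(alpha * T) - 1)` (the added size), timer `T`.
#'
#' @param records lineage records with columns `x_b`, `alpha`, `T` (as from
#'   [simulate_lineages()]).
#' @return tibble with columns `sizer`, `adder`, `timer`.
#' @export
reference_indicators <- function(records) {
  stopifnot(all(c("x_b", "alpha", "T") %in% names(records)))
  gr <- exp(records$alpha * records$T)
  tibble::tibble(sizer = records$x_b * gr,
                 adder = records$x_b * (gr - 1),
                 timer = records$T)
}

#' Sizer-threshold residual mixture
#'
#' `x_b * exp(alpha * T) - 2 * x_b`: the division size minus twice the
#' birth size. When the threshold drifts slowly relative to a cycle the
#' birth size is about half the local threshold, so this mixture hovers
#' near zero - it is the static combination a fixed-set-point search tends
#' to report on sizer data with a drifting threshold.
#'
#' @inheritParams reference_indicators
#' @return numeric vector, one value per cycle.
#' @export
eq_sizer_mixture <- function(records) {
  stopifnot(all(c("x_b", "alpha", "T") %in% names(records)))
  records$x_b * exp(records$alpha * records$T) - 2 * records$x_b
}

#' Closed-form prediction floor of the threshold model
#'
#' For a mean cycle duration `T_bar` and threshold timescale `tau_u`, the
#' best achievable normalised mean-square error of a one-cycle-ahead
#' prediction of the division size is `1 - exp(-2 * T_bar / tau_u)` (the
#' fraction of the threshold's stationary variance renewed per cycle).
#'
#' @param T_bar mean cycle duration.
#' @param tau_u threshold timescale (> 0).
#' @return value in `[0, 1)`.
#' @export
expected_ou_nmse <- function(T_bar, tau_u) {
  stopifnot(tau_u > 0, T_bar >= 0)
  1 - exp(-2 * T_bar / tau_u)
}

#' Mean cycle duration implied by the growth-rate distribution
#'
#' A cell doubling at the mean growth rate `alpha_bar = shape * scale`
#' takes `log(2) / alpha_bar`.
#'
#' @param gamma_shape,gamma_scale Gamma parameters of the growth rate.
#' @return mean cycle duration `T_bar`.
#' @export
mean_cycle <- function(gamma_shape, gamma_scale) {
  stopifnot(gamma_shape > 0, gamma_scale > 0)
  log(2) / (gamma_shape * gamma_scale)
}

#' Monte-Carlo NMSE of the optimal one-cycle threshold predictor
#'
#' Predicts each division size from the previous one with the exact
#' conditional mean of the threshold process over the realised cycle gap,
#' and returns the NMSE of that predictor over all simulated cycles. This
#' is the empirical counterpart of [expected_ou_nmse()] - the floor any
#' trained filter is judged against.
#'
#' @param sim output of [simulate_lineages()].
#' @return a scalar NMSE.
#' @export
ou_conditional_nmse <- function(sim) {
  p <- sim$params
  per <- dplyr::group_by(sim$records, .data$lineage_id)
  per <- dplyr::mutate(per,
    gap = .data$t_d - dplyr::lag(.data$t_d),
    pred = p$mu_u + (dplyr::lag(.data$x_d) - p$mu_u) *
      exp(-.data$gap / p$tau_u))
  per <- dplyr::ungroup(per)
  keep <- !is.na(per$pred)
  nmse(per$x_d[keep], per$pred[keep])
}

#' Score a fit against ground truth
#'
#' Joins the fit's per-sample predictions with a ground-truth table and
#' reports sign-aligned correlations (with per-series standardisation) and
#' the filter's prediction NMSE. For lineage ground truth
#' (columns `x_b`, `alpha`, `T` present), correlations against the sizer,
#' adder and timer indicators are reported.
#'
#' @param fit an `idras_fit`.
#' @param truth a data frame with `series_id`, `time_index` and either a
#'   `c_star` column (generic reference) or lineage record columns.
#' @return a one-row tibble (class `eval_report` attributes preserved):
#'   `rho` (against `c_star` when present), `nmse`, and
#'   `rho_sizer`/`rho_adder`/`rho_timer` when lineage columns are present.
#' @export
evaluate_fit <- function(fit, truth) {
  stopifnot(inherits(fit, "idras_fit"), is.data.frame(truth))
  preds <- fit$predictions
  key <- c("series_id", "time_index")
  if (!all(key %in% names(truth))) {
    if (all(c("lineage_id", "cycle") %in% names(truth))) {
      truth <- dplyr::rename(truth, series_id = "lineage_id")
      truth$time_index <- truth$cycle - 1L
    } else {
      stop("truth needs series_id/time_index (or lineage_id/cycle) columns",
           call. = FALSE)
    }
  }
  j <- dplyr::inner_join(preds, truth, by = key)
  if (nrow(j) == 0L) stop("no overlapping samples between fit and truth",
                          call. = FALSE)
  out <- tibble::tibble(.rows = 1L)
  if ("c_star" %in% names(j))
    out$rho <- pearson_aligned(j$c_star, j$c, group = j$series_id)
  if (all(c("x_b", "alpha", "T") %in% names(j))) {
    ind <- reference_indicators(j)
    out$rho_sizer <- pearson_aligned(ind$sizer, j$c, group = j$series_id)
    out$rho_adder <- pearson_aligned(ind$adder, j$c, group = j$series_id)
    out$rho_timer <- pearson_aligned(ind$timer, j$c, group = j$series_id)
  }
  jp <- j[!is.na(j$c_hat), ]
  out$nmse <- if (nrow(jp) >= 2L && pop_var(jp$c) > 0)
    nmse(jp$c, jp$c_hat) else NA_real_
  out
}
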