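#' Predicted charge of an intact/deacylated RNA mixture
#'
#' Mixing a fraction p (percent) of intact RNA A with (100 - p) percent
#' deacylated RNA B, where transcript i is present in B at a concentration
#' F_i relative to A, gives the predicted measured charge
#' \deqn{T_i^{AB}(p) = \frac{p\,T_i^A + (100-p)\,T_i^B F_i}{p + (100-p)F_i}}
#' with T_i^A, T_i^B the replicate-averaged measured charges of pure intact
#' and pure deacylated RNA. At p = 100 this returns T_A exactly and at
#' p = 0 it returns T_B, for any F. With F = 1 it reduces to the linear
#' mixture (p T_A + (100-p) T_B) / 100.
#'
#' @param p percent intact RNA in the mixture (0-100), vectorized.
#' @param T_A,T_B mean measured charge (percent) of intact / deacylated RNA.
#' @param F_i concentration correction factor (dimensionless).
#' @return predicted charge in percent.
#' @export
predict_titration_charge <- function(p, T_A, T_B, F_i) {
  denom <- p + (100 - p) * F_i
  if (any(denom <= 0)) stop("non-positive denominator: p + (100 - p) * F must be > 0")
  (p * T_A + (100 - p) * T_B * F_i) / denom
}

# Bounded 1-D least-squares fit of F for one transcript; multi-start L-BFGS-B.
.fit_F_one <- function(p, measured, T_A, T_B, lower = 0.25, upper = 4) {
  obj <- function(f) sum((predict_titration_charge(p, T_A, T_B, f) - measured)^2)
  starts <- c(1, (lower + upper) / 2, 0.5, 2)
  best <- NULL
  for (s in starts) {
    fit <- suppressWarnings(
      optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e4, maxit = 500)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(F_i = best$par, rss = best$value,
       converged = best$convergence == 0,
       at_bound = best$par <= lower + 1e-9 || best$par >= upper - 1e-9)
}

#' Fit per-transcript concentration correction factors from a titration
#'
#' From a charge-titration series (mixtures of intact and deacylated RNA at
#' known percentages), fits for each transcript the factor F_i by
#' bound-constrained quasi-Newton minimization (L-BFGS-B, bounds 0.25-4) of
#' the sum of squared differences between [predict_titration_charge()] and
#' the measured charges. The two endpoint ratios (p = 100 and p = 0) define
#' T_A and T_B as replicate means and are excluded from the residuals;
#' interior ratios with all their replicates are pooled into the fit.
#'
#' @param data data.frame with columns `transcript`, `ratio_p` (percent
#'   intact), `replicate`, `measured_charge` (percent), and optionally
#'   `adapter`.
#' @param lower,upper bounds on F.
#' @return object of class `titration_fit`: data.frame with `transcript`,
#'   `F_i`, `rss`, `n_points`, `T_A`, `T_B`, `converged`, `at_bound`.
#' @export
fit_correction_factors <- function(data, lower = 0.25, upper = 4) {
  stopifnot(all(c("transcript", "ratio_p", "measured_charge") %in% names(data)))
  interior <- data$ratio_p > 0 & data$ratio_p < 100
  if (!any(interior)) stop("need at least one interior mixing ratio (0 < p < 100)")
  rows <- lapply(unique(data$transcript), function(tid) {
    d <- data[data$transcript == tid, , drop = FALSE]
    T_A <- mean(d$measured_charge[d$ratio_p == 100])
    T_B <- mean(d$measured_charge[d$ratio_p == 0])
    di <- d[d$ratio_p > 0 & d$ratio_p < 100, , drop = FALSE]
    if (nrow(di) == 0 || !is.finite(T_A) || !is.finite(T_B))
      stop("transcript ", tid, " lacks endpoint or interior measurements")
    f <- .fit_F_one(di$ratio_p, di$measured_charge, T_A, T_B, lower, upper)
    data.frame(transcript = tid, F_i = f$F_i, rss = f$rss,
               n_points = nrow(di), T_A = T_A, T_B = T_B,
               converged = f$converged, at_bound = f$at_bound,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("titration_fit", "data.frame")
  out
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("Titration correction-factor fit: %d transcript(s)\n", nrow(x)))
  cat(sprintf("  F range %.3f-%.3f; %d at bounds; %d non-converged\n",
              min(x$F_i), max(x$F_i), sum(x$at_bound), sum(!x$converged)))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' @method coef titration_fit
#' @export
coef.titration_fit <- function(object, ...) setNames(object$F_i, object$transcript)

#' @export
predict.titration_fit <- function(object, newdata, ...) {
  i <- match(newdata$transcript, object$transcript)
  if (anyNA(i)) stop("unknown transcript(s) in newdata")
  predict_titration_charge(newdata$ratio_p, object$T_A[i], object$T_B[i],
                           object$F_i[i])
}

#' Prediction-error report for a titration fit
#'
#' Bins the percentage-point differences between measured and predicted
#' charge by adapter barcode, mixing ratio or sequencing run, to expose
#' systematic biases such as adapter ligation bias. Bins partition all
#' interior measurements.
#'
#' @param fit a `titration_fit`.
#' @param data the titration data used for the fit.
#' @param grouping column to bin by: `"adapter"`, `"ratio_p"` or another
#'   column of `data`.
#' @return data.frame per bin: `bin`, `n`, `median_err`, `mean_err`,
#'   `sd_err` (errors are measured - predicted, percentage points).
#' @export
titration_error_report <- function(fit, data, grouping = "adapter") {
  stopifnot(grouping %in% names(data))
  di <- data[data$ratio_p > 0 & data$ratio_p < 100, , drop = FALSE]
  err <- di$measured_charge - predict(fit, di)
  bins <- sort(unique(as.character(di[[grouping]])))
  out <- do.call(rbind, lapply(bins, function(b) {
    e <- err[as.character(di[[grouping]]) == b]
    data.frame(bin = b, n = length(e), median_err = median(e),
               mean_err = mean(e), sd_err = if (length(e) > 1) sd(e) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' First-order aminoacylation decay curve
#'
#' \deqn{N(t) = N_0 \left(\tfrac12\right)^{t/t_{1/2}} + N_\infty}
#' where N(t) is the measured charge (percent) at time t (minutes), N_0 the
#' decaying amplitude, t_half the deacylation half-life and N_inf the lower
#' asymptote accommodating the small fraction of molecules still presenting
#' a CCA end after full deacylation. The model value at t = 0 is
#' N_0 + N_inf.
#'
#' @param t time in minutes (vectorized).
#' @param N0 amplitude in percent (0-100).
#' @param t_half half-life in minutes (1-1e5).
#' @param N_inf asymptote in percent (0-3.5).
#' @return charge in percent.
#' @export
decay_value <- function(t, N0, t_half, N_inf) {
  N0 * 0.5^(t / t_half) + N_inf
}

.decay_bounds <- list(lower = c(N0 = 0, t_half = 1, N_inf = 0),
                      upper = c(N0 = 100, t_half = 1e5, N_inf = 3.5))

.fit_decay_one <- function(time_min, charge, starts = NULL) {
  obj <- function(par) sum((decay_value(time_min, par[1], par[2], par[3]) - charge)^2)
  lo <- .decay_bounds$lower; up <- .decay_bounds$upper
  if (is.null(starts)) {
    mt <- tapply(charge, time_min, mean)
    tt <- as.numeric(names(mt))
    n_inf0 <- min(max(mt[which.max(tt)], lo["N_inf"]), up["N_inf"])
    n0_0 <- min(max(mt[which.min(tt)] - n_inf0, 1), 100)
    half_level <- n_inf0 + n0_0 / 2
    below <- which(mt <= half_level & tt > 0)
    t0 <- if (length(below)) max(min(tt[below]), 1) else exp(mean(log(pmax(tt, 1))))
    starts <- rbind(c(n0_0, t0, n_inf0),
                    c(50, sqrt(1 * 1e5), 1.75),       # bounds midpoint-ish
                    c(min(n0_0 * 1.5, 100), t0 * 3, n_inf0),
                    c(max(n0_0 * 0.5, 1), max(t0 / 3, 1), 0))
  } else if (!is.matrix(starts)) starts <- matrix(starts, nrow = 1)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- suppressWarnings(
      optim(pmin(pmax(starts[s, ], lo), up), obj, method = "L-BFGS-B",
            lower = lo, upper = up, control = list(factr = 1e2, maxit = 500)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(N0 = best$par[1], t_half = best$par[2], N_inf = best$par[3],
       rss = best$value, converged = best$convergence == 0,
       t_half_at_bound = best$par[2] <= lo[2] + 1e-6 || best$par[2] >= up[2] - 1e-3)
}

#' Fit the aminoacylation decay model per group
#'
#' Fits [decay_value()] to each group's pooled timepoints x replicates by
#' bound-constrained quasi-Newton least squares (L-BFGS-B; N_0 in [0, 100]
#' percent, t_half in [1, 1e5] minutes, N_inf in [0, 3.5] percent), with
#' multiple starts to guard against local minima. A degenerate
#' (non-decaying) series pins t_half at a bound and is flagged.
#'
#' @param series data.frame with columns `group`, `time_min`, `replicate`,
#'   `charge` (percent).
#' @return object of class `decay_fit`: data.frame with `group`, `N0`,
#'   `t_half`, `N_inf`, `charge_t0` (= N0 + N_inf), `rss`, `converged`,
#'   `t_half_at_bound`.
#' @export
fit_decay <- function(series) {
  stopifnot(all(c("group", "time_min", "charge") %in% names(series)))
  rows <- lapply(unique(series$group), function(g) {
    d <- series[series$group == g, , drop = FALSE]
    if (length(unique(d$time_min)) < 3)
      stop("group ", g, ": need at least 3 distinct timepoints")
    f <- .fit_decay_one(d$time_min, d$charge)
    data.frame(group = g, N0 = f$N0, t_half = f$t_half, N_inf = f$N_inf,
               charge_t0 = f$N0 + f$N_inf, rss = f$rss,
               converged = f$converged, t_half_at_bound = f$t_half_at_bound,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("decay_fit", "data.frame")
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Aminoacylation decay fit: %d group(s)\n", nrow(x)))
  cat(sprintf("  t_half range %.1f-%.1f min (%.1f-fold)\n",
              min(x$t_half), max(x$t_half), max(x$t_half) / min(x$t_half)))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' @method coef decay_fit
#' @export
coef.decay_fit <- function(object, ...) {
  m <- as.matrix(object[, c("N0", "t_half", "N_inf")])
  rownames(m) <- object$group
  m
}

#' @export
predict.decay_fit <- function(object, newdata, ...) {
  i <- match(newdata$group, object$group)
  if (anyNA(i)) stop("unknown group(s) in newdata")
  decay_value(newdata$time_min, object$N0[i], object$t_half[i], object$N_inf[i])
}

#' Bootstrap confidence intervals for decay parameters
#'
#' Each of `n_boot` bootstrap iterates builds a single time-series by
#' drawing, independently per timepoint, one replicate value at random
#' (with replacement across iterates), refits the decay model, and records
#' the parameters. The 95% CI is the 2.5/97.5 percentile of the bootstrap
#' distribution. This resamples replicate noise at fixed design points, not
#' the design itself.
#'
#' @param series data.frame as for [fit_decay()].
#' @param n_boot number of bootstrap iterates (default 1000).
#' @param seed RNG seed (results are reproducible for a fixed seed).
#' @return data.frame per group: `group`, then `<param>_lo` / `<param>_hi`
#'   for N0, t_half, N_inf.
#' @export
bootstrap_decay_ci <- function(series, n_boot = 1000L, seed = 1L) {
  stopifnot(all(c("group", "time_min", "charge") %in% names(series)))
  with_seed(seed, {
    rows <- lapply(unique(series$group), function(g) {
      d <- series[series$group == g, , drop = FALSE]
      tps <- sort(unique(d$time_min))
      vals <- lapply(tps, function(tp) d$charge[d$time_min == tp])
      if (any(lengths(vals) < 2))
        warning("group ", g, ": fewer than 2 replicates at some timepoint")
      # bootstrap refits start from the group's point estimate (the
      # resampled series is a perturbation of the fitted one)
      pt <- .fit_decay_one(tps, vapply(vals, mean, numeric(1)))
      start <- c(pt$N0, pt$t_half, pt$N_inf)
      boots <- matrix(NA_real_, n_boot, 3,
                      dimnames = list(NULL, c("N0", "t_half", "N_inf")))
      for (b in seq_len(n_boot)) {
        ch <- vapply(vals, function(v) v[sample.int(length(v), 1L)], numeric(1))
        f <- .fit_decay_one(tps, ch, starts = start)
        boots[b, ] <- c(f$N0, f$t_half, f$N_inf)
      }
      q <- apply(boots, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
      data.frame(group = g,
                 N0_lo = q[1, 1], N0_hi = q[2, 1],
                 t_half_lo = q[1, 2], t_half_hi = q[2, 2],
                 N_inf_lo = q[1, 3], N_inf_hi = q[2, 3],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
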