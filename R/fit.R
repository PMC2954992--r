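#' Ordinary least-squares line fit
#'
#' Closed-form OLS of labelling index on exposure time. The coefficient of
#' determination is defined as 1 when the residual sum of squares is zero
#' or the total sum of squares is zero (noiseless and constant fixtures are
#' both exact fits of their respective models).
#'
#' @param t Numeric vector of times.
#' @param li Numeric vector of responses, same length.
#' @return A list with `slope`, `intercept`, `r_squared`, `sse`,
#'   `slope_se` (standard error of the slope; `NA` when df < 1) and `n`.
#' @export
fit_line <- function(t, li) {
  stopifnot(is.numeric(t), is.numeric(li), length(t) == length(li))
  n <- length(t)
  if (n < 2L) stop("insufficient data: need at least 2 points for a line fit")
  sxx <- sum((t - mean(t))^2)
  if (sxx == 0) stop("insufficient data: all times equal")
  slope <- sum((t - mean(t)) * (li - mean(li))) / sxx
  intercept <- mean(li) - slope * mean(t)
  fitted <- intercept + slope * t
  sse <- sum((li - fitted)^2)
  sst <- sum((li - mean(li))^2)
  r2 <- if (sst <= 0 || sse <= 1e-300) 1 else 1 - sse / sst
  slope_se <- if (n > 2L) sqrt(sse / (n - 2L) / sxx) else NA_real_
  list(slope = slope, intercept = intercept, r_squared = r2,
       sse = sse, slope_se = slope_se, n = n)
}

# One-sided test of H0: slope <= 0 on a candidate plateau segment.
# Returns TRUE if the segment's slope is significantly positive, i.e. the
# segment is still rising and must not be treated as a plateau. An exactly
# positive slope with no residual degrees of freedom (2 points, or a
# zero-residual fit) is treated as significant: the data are literally on a
# rising line.
plateau_slope_significant <- function(t, li, alpha) {
  f <- fit_line(t, li)
  if (f$slope <= 0) return(FALSE)
  df <- f$n - 2L
  if (df < 1L || !is.na(f$slope_se) && f$slope_se == 0) return(TRUE)
  p <- stats::pt(f$slope / f$slope_se, df = df, lower.tail = FALSE)
  p < alpha
}

#' Detect the plateau of a cumulative-labelling series
#'
#' Segments an ordered labelling-index series into a rising linear segment
#' followed by a constant plateau. All splits with at least 2 rising and
#' 2 plateau points are scored by the total sum of squared errors of a
#' line-on-rising plus constant-on-plateau model; the minimising split is
#' selected (ties broken toward the larger plateau). The winning split is
#' accepted only if the plateau segment's own fitted slope is not
#' significantly positive at level `alpha` (one-sided t test); otherwise no
#' plateau is declared and `NULL` is returned — the series is still rising
#' at the last observation.
#'
#' @param series A data frame with columns `time_h` and `li` (e.g. from
#'   [labelling_index()]), times strictly increasing.
#' @param alpha Significance level of the plateau slope test; default 0.05.
#' @return `NULL` if no plateau, else a list with integer index vectors
#'   `rising` and `plateau` and the achieved `sse`.
#' @export
detect_plateau <- function(series, alpha = 0.05) {
  series <- as_li_points(series)
  n <- nrow(series)
  if (n < 3L) stop("insufficient data: need at least 3 points")
  ks <- seq.int(2L, n - 2L)
  if (length(ks) == 0L || ks[1] > n - 2L) return(NULL)
  sse <- vapply(ks, function(k) {
    r <- fit_line(series$time_h[1:k], series$li[1:k])
    p <- series$li[(k + 1L):n]
    r$sse + sum((p - mean(p))^2)
  }, numeric(1))
  best <- min(sse)
  # ties toward the larger plateau = smaller k
  k <- ks[which(sse <= best + 1e-12)[1L]]
  pl <- (k + 1L):n
  if (plateau_slope_significant(series$time_h[pl], series$li[pl], alpha))
    return(NULL)
  list(rising = 1:k, plateau = pl, sse = sse[match(k, ks)])
}

#' Fit the cumulative-labelling model and estimate cell-cycle parameters
#'
#' Estimates the growth fraction GF, S-phase duration Ts and total
#' cell-cycle time Tc from a cumulative-labelling series under
#' single-population kinetics.
#'
#' If [detect_plateau()] finds a plateau (`mode = "plateau_reached"`), the
#' rising segment is fit by OLS, the plateau level `lim` is the mean of the
#' plateau-segment labelling indices, the plateau time is the intersection
#' `t_plateau = (lim - li0) / slope`, and
#' `tc = lim / slope`, `ts = li0 / slope`, `gf = lim`.
#'
#' If the series never plateaus (`mode = "minimum_estimate"`), all points
#' are fit by one line, the growth fraction is bounded below by the fitted
#' value at the last sampled time, `lim = li0 + slope * T_last`, and the
#' same identities give a *minimum* estimate of Tc: labelling would have
#' had to continue past `T_last` to see the true plateau.
#'
#' @param series Data frame with columns `time_h`, `li` (a single group).
#' @param alpha Plateau-test significance level, passed to
#'   [detect_plateau()].
#' @return An object of class `cumulative_fit`: list with `mode`, `li0`,
#'   `slope`, `lim`, `t_plateau`, `tc`, `ts`, `gf`, `r_squared`,
#'   `n_rising`, `n_plateau`, `li0_clamped`.
#' @examples
#' p <- kinetic_params(10.5, 5, 0.11)
#' tt <- c(0.5, 2.5, 4.5, 6.5, 8.5, 10.5)
#' fit_cumulative(data.frame(time_h = tt, li = expected_li(p, tt)))
#' @export
fit_cumulative <- function(series, alpha = 0.05) {
  series <- as_li_points(series)
  n <- nrow(series)
  if (n < 3L) stop("insufficient data: need at least 3 points")
  if (any(series$li < 0 | series$li > 1))
    stop("labelling indices must lie in [0, 1]")

  seg <- detect_plateau(series, alpha = alpha)
  if (!is.null(seg)) {
    mode <- "plateau_reached"
    f <- fit_line(series$time_h[seg$rising], series$li[seg$rising])
    lim <- mean(series$li[seg$plateau])
    n_rising <- length(seg$rising)
    n_plateau <- length(seg$plateau)
  } else {
    mode <- "minimum_estimate"
    f <- fit_line(series$time_h, series$li)
    lim <- f$intercept + f$slope * series$time_h[n]
    n_rising <- n
    n_plateau <- 0L
  }
  if (f$slope <= 0)
    stop("no estimate: fitted rising slope is not positive, ",
         "cycle time undefined")
  li0 <- f$intercept
  li0_clamped <- FALSE
  if (li0 < 0) {
    warning("fitted intercept li0 < 0; clamped to 0")
    li0 <- 0
    li0_clamped <- TRUE
  }
  if (li0 >= lim)
    stop("non-physical fit: intercept li0 >= plateau lim")
  t_plateau <- if (mode == "plateau_reached")
    (lim - li0) / f$slope else series$time_h[n]
  res <- list(mode = mode, li0 = li0, slope = f$slope, lim = lim,
              t_plateau = t_plateau, tc = lim / f$slope,
              ts = li0 / f$slope, gf = lim, r_squared = f$r_squared,
              n_rising = n_rising, n_plateau = n_plateau,
              li0_clamped = li0_clamped)
  class(res) <- "cumulative_fit"
  res
}

#' @export
print.cumulative_fit <- function(x, ...) {
  lab <- if (x$mode == "plateau_reached") "Tc" else "Tc (minimum estimate)"
  cat("Cumulative-labelling fit [", x$mode, "]\n", sep = "")
  cat(sprintf("  rising: LI = %.5f + %.6f * T  (R^2 = %.4f, n = %d)\n",
              x$li0, x$slope, x$r_squared, x$n_rising))
  cat(sprintf("  plateau LI_m = %.4f (growth fraction), reached at %.2f h\n",
              x$lim, x$t_plateau))
  cat(sprintf("  %s = %.2f h, Ts = %.2f h\n", lab, x$tc, x$ts))
  invisible(x)
}

# Coerce/validate (time_h, li) points for the fitters.
as_li_points <- function(series) {
  if (inherits(series, "li_series"))
    series <- as.data.frame(series)
  stopifnot(is.data.frame(series),
            all(c("time_h", "li") %in% names(series)))
  if (length(unique(series$group %||% "g")) > 1L)
    stop("fit one group at a time; got multiple groups")
  series <- series[order(series$time_h), c("time_h", "li")]
  if (any(diff(series$time_h) <= 0))
    stop("times must be strictly increasing (duplicate time points?)")
  series
}

`%||%` <- function(a, b) if (is.null(a)) b else a
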