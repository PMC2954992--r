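#' Group summary (mean, SD, n)
#'
#' Container for a group's printed or computed summary statistics. The
#' `+/-` convention is standard deviation, not standard error.
#'
#' @param label Group label.
#' @param mean Group mean, measurement units.
#' @param sd Standard deviation, same units (>= 0).
#' @param n Group size.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(label, mean, sd, n) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0,
            is.numeric(n), n >= 1, n == round(n))
  structure(list(label = as.character(label), mean = mean, sd = sd,
                 n = as.integer(n)), class = "group_summary")
}

summarize_group <- function(label, values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  group_summary(label, mean(values), stats::sd(values), length(values))
}

#' Normalize an area measurement by body length
#'
#' Cross-sectional areas of embryos that differ in overall size are made
#' comparable by dividing by the embryo's body length; the result has units
#' of length (um).
#'
#' @param area Area in um^2.
#' @param length Body length in um (> 0).
#' @return `area / length`, in um.
#' @export
normalize_area <- function(area, length) {
  stopifnot(is.numeric(area), is.numeric(length))
  if (any(length <= 0)) stop("length must be positive")
  area / length
}

#' Percent reduction relative to a reference
#'
#' @param reference Reference measurement (> 0).
#' @param observed Observed measurement.
#' @return `100 * (reference - observed) / reference`.
#' @examples
#' percent_reduction(6700, 3350) # 50
#' @export
percent_reduction <- function(reference, observed) {
  stopifnot(is.numeric(reference), is.numeric(observed))
  if (any(reference <= 0)) stop("reference must be positive")
  100 * (reference - observed) / reference
}

#' Two-sample t test from summary statistics
#'
#' Student's pooled-variance two-sample t test computed from
#' (mean, SD, n) triples, the only route available when a study prints
#' summaries but not raw values:
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` and
#' `t = (mean_b - mean_a) / (sp * sqrt(1/n1 + 1/n2))`, two-sided p from
#' the t distribution with `n1 + n2 - 2` df. `var_equal = FALSE` gives the
#' Welch statistic with Satterthwaite df instead.
#'
#' Degenerate inputs: both SDs zero with equal means gives `t = 0, p = 1`;
#' with unequal means the statistic is infinite and flagged.
#'
#' @param a,b [group_summary()] objects (each `n >= 2`).
#' @param var_equal Pooled (Student, default) or Welch.
#' @return An object of class `ttest_result`: `t`, `df`, `p`, `method`,
#'   `infinite` flag.
#' @examples
#' t_test_from_summary(group_summary("control", 15.3, 4.7, 3),
#'                     group_summary("morphant", 28.0, 3.4, 3))
#' @export
t_test_from_summary <- function(a, b, var_equal = TRUE) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$n < 2 || b$n < 2) stop("need n >= 2 in both groups")
  diff <- b$mean - a$mean
  if (var_equal) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    method <- "pooled"
  } else {
    v1 <- a$sd^2 / a$n
    v2 <- b$sd^2 / b$n
    se <- sqrt(v1 + v2)
    df <- if (se == 0) a$n + b$n - 2 else
      (v1 + v2)^2 / (v1^2 / (a$n - 1) + v2^2 / (b$n - 1))
    method <- "welch"
  }
  if (se == 0) {
    if (diff == 0) {
      res <- list(t = 0, df = df, p = 1, method = method, infinite = FALSE)
    } else {
      res <- list(t = sign(diff) * Inf, df = df, p = 0, method = method,
                  infinite = TRUE)
    }
  } else {
    t <- diff / se
    res <- list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                method = method, infinite = FALSE)
  }
  class(res) <- "ttest_result"
  res
}

#' Two-sample t test from raw values
#'
#' Summarizes each group and delegates to [t_test_from_summary()], so the
#' two routes agree exactly by construction.
#'
#' @param a,b Numeric vectors (each >= 2 values).
#' @param var_equal Pooled (default) or Welch.
#' @inherit t_test_from_summary return
#' @export
t_test_from_values <- function(a, b, var_equal = TRUE) {
  t_test_from_summary(summarize_group("a", a), summarize_group("b", b),
                      var_equal = var_equal)
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("two-sample t test (%s): t = %.3f, df = %.2f, p = %.4g%s\n",
              x$method, x$t, x$df, x$p,
              if (x$infinite) " [zero-variance, infinite statistic]" else ""))
  invisible(x)
}
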