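#' Cell-cycle kinetic parameters
#'
#' Constructs and validates the parameter set of the single-population
#' cell-cycle model: all cycling cells share one cycle time `tc`, of which
#' `ts` hours are S phase, and a fraction `gf` of the population is cycling
#' at all (the growth fraction). An optional phase partition
#' `tg1 + ts + tg2m = tc` places S within the cycle; it is needed for
#' DNA-content simulation and true phase fractions, not for labelling
#' kinetics (under uniform cycle-position occupancy the labelled fraction
#' depends only on `ts` and `tc`).
#'
#' If only one of `tg1`, `tg2m` is supplied the other is completed from
#' `tc - ts`. If neither is supplied the partition is left unset; consumers
#' that need it ([phase_fractions_true()]) error, while the simulator falls
#' back to `tg2m = 0`, `tg1 = tc - ts`.
#'
#' @param tc Total cell-cycle time, hours. Must be positive.
#' @param ts S-phase duration, hours; `0 < ts < tc`.
#' @param gf Growth fraction, in `[0, 1]`.
#' @param tg1,tg2m Optional G1 and combined G2+M durations, hours.
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(tc = 10.5, ts = 5, gf = 0.11)
#' @export
kinetic_params <- function(tc, ts, gf, tg1 = NULL, tg2m = NULL) {
  stopifnot(is.numeric(tc), length(tc) == 1L, is.finite(tc),
            is.numeric(ts), length(ts) == 1L, is.finite(ts),
            is.numeric(gf), length(gf) == 1L, is.finite(gf))
  if (!(ts > 0 && ts < tc))
    stop("invalid kinetic parameters: need 0 < ts < tc (got ts = ",
         ts, ", tc = ", tc, ")")
  if (gf < 0 || gf > 1)
    stop("growth fraction gf must lie in [0, 1], got ", gf)
  if (is.null(tg1) && !is.null(tg2m)) tg1 <- tc - ts - tg2m
  if (!is.null(tg1) && is.null(tg2m)) tg2m <- tc - ts - tg1
  if (!is.null(tg1)) {
    if (tg1 < 0 || tg2m < 0)
      stop("phase partition inconsistent: tg1 and tg2m must be non-negative")
    if (abs(tg1 + ts + tg2m - tc) > 1e-9 * tc)
      stop("phase partition inconsistent: tg1 + ts + tg2m must equal tc")
  }
  structure(list(tc = tc, ts = ts, gf = gf, tg1 = tg1, tg2m = tg2m),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("kinetic_params: Tc = %g h, Ts = %g h, GF = %g", x$tc, x$ts, x$gf))
  if (!is.null(x$tg1))
    cat(sprintf(" (G1 %g h, G2+M %g h)", x$tg1, x$tg2m))
  cat("\n")
  invisible(x)
}

# Complete a missing phase partition: all non-S time assigned to G1.
complete_partition <- function(params) {
  if (is.null(params$tg1)) {
    params$tg1 <- params$tc - params$ts
    params$tg2m <- 0
  }
  params
}

#' Preset kinetic parameters for the zebrafish retinal progenitor groups
#'
#' Convenience constructors for the two groups whose cumulative-labelling
#' and DNA-content readouts the synthetic generator emulates: an un-injected
#' control retina (Tc 10.5 h, GF 0.11) and a slow-cycling double-morphant
#' retina (minimum Tc 50.6 h, GF 0.35). S-phase durations (5.44 h and
#' 39.47 h) and G2+M durations (0.67 h and 1.0 h) are back-solved so that
#' the true S and G2-M occupancy fractions under uniform cycle-position
#' occupancy concord with DNA-content phase fractions of roughly 5.7% /
#' 27.3% S; they are derived quantities, not measured ones.
#'
#' @param group `"control"` or `"morphant"`.
#' @return A [kinetic_params()] object with full phase partition.
#' @examples
#' phase_fractions_true(preset_kinetics("control"))
#' @export
preset_kinetics <- function(group = c("control", "morphant")) {
  group <- match.arg(group)
  switch(group,
    control  = kinetic_params(tc = 10.5, ts = 5.44, gf = 0.11, tg2m = 0.67),
    morphant = kinetic_params(tc = 50.6, ts = 39.47, gf = 0.35, tg2m = 1.0))
}

#' Expected labelling index under cumulative labelling
#'
#' The forward single-population model: with continuous label availability
#' over `[0, T]`, a cycling cell is labelled iff it spends any time in
#' S phase during the window, so the expected labelled fraction is
#' `LI(T) = min(GF * (Ts + T) / Tc, GF)` — linear with intercept
#' `GF * Ts / Tc` (cells already in S) and plateau `GF` reached at
#' `T = Tc - Ts`.
#'
#' @param params A [kinetic_params()] object.
#' @param T Exposure time(s) in hours since the first label delivery;
#'   vectorised, must be non-negative.
#' @return Expected labelling index, same length as `T`.
#' @examples
#' p <- kinetic_params(10.5, 5, 0.11)
#' expected_li(p, c(0, 5.5, 10.5))
#' @export
expected_li <- function(params, T) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(T))
  if (any(!is.finite(T)) || any(T < 0))
    stop("exposure time T must be finite and non-negative")
  pmin(params$gf * (params$ts + T) / params$tc, params$gf)
}

#' True cell-cycle phase fractions of the population
#'
#' Under uniform cycle-position occupancy, a cycling cell is in phase X
#' with probability `T_X / Tc`, so the population fraction in phase X is
#' `GF * T_X / Tc`. Non-cycling (G0) cells carry 2C DNA content and are
#' pooled with G1, mirroring their indistinguishability by DNA-content
#' staining.
#'
#' @param params A [kinetic_params()] object with phase partition set.
#' @return An object of class `phase_fractions` with fields `g1` (includes
#'   G0), `s` and `g2m`, summing to 1.
#' @examples
#' phase_fractions_true(kinetic_params(10.5, 5.44, 0.11, tg2m = 0.67))
#' @export
phase_fractions_true <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (is.null(params$tg1))
    stop("phase_fractions_true needs the phase partition (tg1, tg2m) set")
  s <- params$gf * params$ts / params$tc
  g2m <- params$gf * params$tg2m / params$tc
  phase_fractions(g1 = 1 - s - g2m, s = s, g2m = g2m)
}

#' Phase-fraction container
#'
#' @param g1 Proportion of events/cells in G1 (pooled with G0).
#' @param s Proportion in S phase.
#' @param g2m Proportion in G2 + M.
#' @return An object of class `phase_fractions`.
#' @export
phase_fractions <- function(g1, s, g2m) {
  v <- c(g1 = g1, s = s, g2m = g2m)
  stopifnot(is.numeric(v), all(is.finite(v)))
  if (any(v < -1e-12) || any(v > 1 + 1e-12))
    stop("phase fractions must lie in [0, 1]")
  if (sum(v) > 1 + 1e-9)
    stop("phase fractions must sum to at most 1")
  structure(list(g1 = unname(v[1]), s = unname(v[2]), g2m = unname(v[3])),
            class = "phase_fractions")
}

#' @export
print.phase_fractions <- function(x, ...) {
  cat(sprintf("phase fractions: G1(+G0) %.1f%%  S %.1f%%  G2-M %.1f%%\n",
              100 * x$g1, 100 * x$s, 100 * x$g2m))
  invisible(x)
}

#' Invert the cumulative-labelling identities for the total cycle time
#'
#' From the plateau of a cumulative-labelling curve: the plateau is reached
#' at `t_plateau = Tc - Ts`, and the intercept/plateau ratio gives
#' `LI_0 / LI_m = Ts / Tc`. Jointly these give
#' `Tc = LI_m * t_plateau / (LI_m - LI_0)` and `Ts = Tc * LI_0 / LI_m`.
#'
#' @param li0 Labelling index at zero exposure (regression intercept).
#' @param lim Plateau labelling index (growth fraction).
#' @param t_plateau Time at which the plateau is reached, hours.
#' @return Estimated total cycle time `Tc`, hours.
#' @examples
#' invert_tc(0.0524, 0.11, 5.5)   # ~10.5 h
#' invert_tc(0.2774, 0.35, 10.5)  # ~50.6 h
#' @export
invert_tc <- function(li0, lim, t_plateau) {
  stopifnot(is.numeric(li0), is.numeric(lim), is.numeric(t_plateau))
  if (lim <= 0) stop("plateau labelling index lim must be positive")
  if (li0 < 0 || lim > 1) stop("labelling indices must lie in [0, 1]")
  if (li0 >= lim)
    stop("non-physical input: intercept li0 must be below plateau lim")
  if (t_plateau <= 0) stop("t_plateau must be positive")
  lim * t_plateau / (lim - li0)
}
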