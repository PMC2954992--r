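# Derived substream seeds: one user-facing seed, deterministic per-stage
# offsets, kept below 2^31 - 1.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  as.integer((as.double(seed) + 1000003 * stream) %% 2147483647)
}

# Evaluate expr under a fixed seed without touching the caller's RNG state;
# seed = NULL means use the current RNG stream.
with_sim_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

#' Simulate an asynchronously cycling cell population
#'
#' Each cell is cycling with probability `gf`; cycling cells occupy cycle
#' positions drawn uniformly on `[0, Tc)` (non-expanding steady state, the
#' occupancy under which the cumulative labelling index is exactly linear).
#' Phase is assigned from the position against the partition
#' `[0, Tg1) = G1`, `[Tg1, Tg1 + Ts) = S`, rest `G2M`; non-cycling cells
#' are recorded as G1 (they carry 2C DNA and are indistinguishable from G1
#' by DNA content). If the partition is unset, `tg2m = 0` is assumed.
#'
#' @param n Number of cells (>= 0).
#' @param params A [kinetic_params()] object.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A data frame of class `cell_population` with columns `cycling`
#'   (logical), `cycle_position` (hours, `NA` for non-cycling cells),
#'   `phase` (`"G1"`, `"S"`, `"G2M"`), `s_progress` (fractional S-phase
#'   progress in `[0, 1)`, `NA` outside S) and `labelled` (all `FALSE`;
#'   see [label_cumulative()]).
#' @examples
#' pop <- simulate_population(1000, preset_kinetics("control"), seed = 1)
#' table(pop$phase)
#' @export
simulate_population <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "kinetic_params"),
            is.numeric(n), length(n) == 1L, n >= 0)
  n <- as.integer(n)
  params <- complete_partition(params)
  with_sim_seed(seed, {
    cycling <- stats::runif(n) < params$gf
    pos <- rep(NA_real_, n)
    pos[cycling] <- stats::runif(sum(cycling), 0, params$tc)
    phase <- rep("G1", n)
    in_s <- cycling & pos >= params$tg1 & pos < params$tg1 + params$ts
    in_g2m <- cycling & pos >= params$tg1 + params$ts
    phase[which(in_s)] <- "S"
    phase[which(in_g2m)] <- "G2M"
    s_progress <- rep(NA_real_, n)
    s_progress[which(in_s)] <- (pos[which(in_s)] - params$tg1) / params$ts
    structure(
      data.frame(cycling = cycling, cycle_position = pos, phase = phase,
                 s_progress = s_progress, labelled = logical(n)),
      class = c("cell_population", "data.frame"))
  })
}

#' Apply cumulative labelling to a simulated population
#'
#' Label is modelled as continuously available over the window `[0, T]`
#' (repeated 2-hourly boluses with an S phase longer than the interval
#' never miss an S-phase transit). A cycling cell at initial position `a`
#' becomes labelled iff some `t` in `[0, T]` places `(a + t) mod Tc` inside
#' the S interval — i.e. it is in S now, or enters S within `T` hours.
#' Labelled cells stay labelled (no dilution within the window);
#' non-cycling cells are never labelled. The expected labelled fraction is
#' exactly [expected_li()]`(params, T)`.
#'
#' @param population A `cell_population` from [simulate_population()].
#' @param params The same [kinetic_params()] used to build the population.
#' @param T Exposure time in hours, `>= 0`.
#' @return The population with the `labelled` flags set.
#' @export
label_cumulative <- function(population, params, T) {
  stopifnot(inherits(population, "cell_population"),
            inherits(params, "kinetic_params"),
            is.numeric(T), length(T) == 1L, T >= 0)
  params <- complete_partition(params)
  a <- population$cycle_position
  in_s <- population$cycling &
    a >= params$tg1 & a < params$tg1 + params$ts
  wait <- (params$tg1 - a) %% params$tc  # hours until next S entry
  population$labelled <- population$cycling & (in_s | wait <= T)
  population
}

#' Turn labelled populations into per-section count records
#'
#' For each exposure time and each retina, a section of `cells_per_section`
#' cells is sampled without replacement and its labelled cells counted.
#' `populations` gives, per time, either a single population (retinas then
#' draw disjoint cell samples from it) or a list of `n_retinas` independent
#' populations (the default produced by [simulate_experiment()]; retinas
#' are different animals). Nuclear density and section area are drawn with
#' multiplicative Gaussian noise of coefficient `noise_cv` around their
#' means, then jointly rescaled so `density * area` equals the sampled cell
#' total exactly — the density-based total-nuclei estimate downstream then
#' reproduces the true denominator up to rounding.
#'
#' @param populations List over exposure times; each element a
#'   `cell_population` or a list of `n_retinas` of them, already labelled.
#' @param times Numeric vector of exposure times (hours), one per element
#'   of `populations`.
#' @param cells_per_section Cells counted per section (>= 1).
#' @param n_retinas Retinas per time point (>= 1).
#' @param density_mean Mean nuclear density, nuclei per um^2.
#' @param area_mean Mean section area, um^2.
#' @param noise_cv Coefficient of variation of the multiplicative noise on
#'   density and area (0 disables noise).
#' @param group Group label stamped on every record.
#' @param seed Optional integer seed.
#' @return Data frame with columns `group`, `time_h`, `retina_id`,
#'   `section_id`, `brdu_pos`, `dapi_density_per_um2`, `section_area_um2`.
#' @export
simulate_sections <- function(populations, times, cells_per_section,
                              n_retinas, density_mean = 0.025,
                              area_mean = 20000, noise_cv = 0.05,
                              group = "control", seed = NULL) {
  stopifnot(is.list(populations), length(populations) == length(times),
            cells_per_section >= 1, n_retinas >= 1, noise_cv >= 0,
            density_mean > 0, area_mean > 0)
  with_sim_seed(seed, {
    rows <- list()
    for (i in seq_along(times)) {
      pt <- populations[[i]]
      shared <- inherits(pt, "cell_population")
      if (shared) {
        if (cells_per_section * n_retinas > nrow(pt))
          stop("cells_per_section * n_retinas exceeds the population size")
        pool <- sample.int(nrow(pt))  # disjoint sections from one pool
      } else {
        stopifnot(length(pt) == n_retinas)
      }
      for (r in seq_len(n_retinas)) {
        if (shared) {
          idx <- pool[((r - 1) * cells_per_section + 1):(r * cells_per_section)]
          sec <- pt[idx, ]
        } else {
          pop_r <- pt[[r]]
          if (cells_per_section > nrow(pop_r))
            stop("cells_per_section exceeds the population size")
          sec <- pop_r[sample.int(nrow(pop_r), cells_per_section), ]
        }
        d <- density_mean * (1 + noise_cv * stats::rnorm(1))
        a <- area_mean * (1 + noise_cv * stats::rnorm(1))
        if (d <= 0 || a <= 0)
          stop("noise_cv too large: drew a non-positive density or area")
        sc <- sqrt(cells_per_section / (d * a))
        rows[[length(rows) + 1L]] <- data.frame(
          group = group, time_h = times[i], retina_id = r, section_id = 1L,
          brdu_pos = sum(sec$labelled),
          dapi_density_per_um2 = d * sc, section_area_um2 = a * sc)
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a full cumulative-labelling experiment
#'
#' The default geometry mirrors the source experiment: exposure times 0.5
#' to 10.5 h in 2-h steps, 3 retinas per time, ~500 cells counted per
#' section. An independent population is generated per (time, retina) —
#' retinas are separate animals — labelled for its exposure time, and one
#' section sampled per retina.
#'
#' @param params A [kinetic_params()] object (the generative truth).
#' @param times Exposure times, hours.
#' @param n_retinas Retinas per time point.
#' @param cells_per_section Cells counted per section.
#' @param cells_per_retina Population size per retina (>=
#'   `cells_per_section`; default 4x).
#' @param group Group label.
#' @param seed Integer seed for the whole experiment.
#' @inheritParams simulate_sections
#' @return Section-count data frame as in [simulate_sections()].
#' @examples
#' sec <- simulate_experiment(preset_kinetics("control"), seed = 1)
#' labelling_index(sec)
#' @export
simulate_experiment <- function(params,
                                times = c(0.5, 2.5, 4.5, 6.5, 8.5, 10.5),
                                n_retinas = 3, cells_per_section = 500,
                                cells_per_retina = 4 * cells_per_section,
                                density_mean = 0.025, area_mean = 20000,
                                noise_cv = 0.05, group = "control",
                                seed = NULL) {
  stopifnot(cells_per_retina >= cells_per_section)
  pops <- vector("list", length(times))
  for (i in seq_along(times)) {
    pops[[i]] <- lapply(seq_len(n_retinas), function(r) {
      s <- if (is.null(seed)) NULL
           else substream_seed(seed, 100L * i + r)
      pop <- simulate_population(cells_per_retina, params, seed = s)
      label_cumulative(pop, params, times[i])
    })
  }
  simulate_sections(pops, times, cells_per_section, n_retinas,
                    density_mean, area_mean, noise_cv, group = group,
                    seed = if (is.null(seed)) NULL
                           else substream_seed(seed, 99L))
}

#' Simulate DNA-content fluorescence events
#'
#' Propidium-iodide style readout: nominal content is `c2_level` for
#' G1/G0 cells, `2 * c2_level` for G2/M, and `c2_level * (1 + s)` for an
#' S-phase cell with fractional progress `s` (replication doubles content
#' linearly across S). Observed fluorescence multiplies the nominal level
#' by `1 + N(0, cv)` — measurement CV constant across the scale, as for a
#' linear-area PI signal.
#'
#' @param population A `cell_population`.
#' @param c2_level Nominal 2C fluorescence, arbitrary units.
#' @param cv Multiplicative measurement coefficient of variation.
#' @param n_events Events to record (sampled without replacement; default
#'   the whole population, must not exceed it).
#' @param seed Optional integer seed.
#' @return Numeric vector of fluorescence values, length `n_events`.
#' @export
simulate_dna_content <- function(population, c2_level = 50, cv = 0.03,
                                 n_events = nrow(population), seed = NULL) {
  stopifnot(inherits(population, "cell_population"), cv >= 0, c2_level > 0)
  if (n_events > nrow(population))
    stop("n_events exceeds the population size")
  with_sim_seed(seed, {
    idx <- if (n_events == nrow(population)) seq_len(n_events)
           else sample.int(nrow(population), n_events)
    nominal <- rep(c2_level, length(idx))
    ph <- population$phase[idx]
    nominal[ph == "G2M"] <- 2 * c2_level
    is_s <- ph == "S"
    nominal[is_s] <- c2_level * (1 + population$s_progress[idx][is_s])
    nominal * (1 + cv * stats::rnorm(length(idx)))
  })
}

#' Simulate per-embryo morphometric groups
#'
#' Independent Gaussian draws per group, for fixtures of the
#' group-comparison statistics (e.g. mitotic-figure counts, normalized
#' areas, body lengths).
#'
#' @param group_specs Data frame with columns `label`, `mean`, `sd`, `n`.
#' @param seed Optional integer seed.
#' @return Data frame with columns `group`, `embryo_id`, `value`.
#' @examples
#' simulate_morphometry(data.frame(label = c("control", "morphant"),
#'                                 mean = c(15.3, 28.0),
#'                                 sd = c(4.7, 3.4), n = c(3, 3)), seed = 1)
#' @export
simulate_morphometry <- function(group_specs, seed = NULL) {
  stopifnot(is.data.frame(group_specs),
            all(c("label", "mean", "sd", "n") %in% names(group_specs)),
            all(group_specs$sd >= 0), all(group_specs$n >= 1))
  with_sim_seed(seed, {
    rows <- lapply(seq_len(nrow(group_specs)), function(i) {
      g <- group_specs[i, ]
      data.frame(group = g$label, embryo_id = seq_len(g$n),
                 value = stats::rnorm(g$n, g$mean, g$sd))
    })
    do.call(rbind, rows)
  })
}
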