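#' Labelling-index series from per-section counts
#'
#' Reproduces the counting arithmetic of a density-based cumulative
#' labelling assay: total nuclei per section are estimated as
#' `round(dapi_density_per_um2 * section_area_um2)`, the per-section
#' labelling index is `brdu_pos / total`, sections are averaged within
#' each retina first, and the group labelling index at each time is the
#' unweighted mean of the per-retina means — so a retina contributing more
#' sections does not dominate its group.
#'
#' @param sections Data frame with columns `group`, `time_h`, `retina_id`,
#'   `section_id`, `brdu_pos`, `dapi_density_per_um2`, `section_area_um2`
#'   (as written by [simulate_experiment()] or read from `counts.csv`).
#' @param min_retinas Warn if any (group, time) has fewer retinas.
#' @return A data frame of class `li_series`, columns `group`, `time_h`,
#'   `li`, `n_retinas`, sorted by group then time.
#' @export
labelling_index <- function(sections, min_retinas = 3) {
  stopifnot(is.data.frame(sections),
            all(c("group", "time_h", "retina_id", "section_id", "brdu_pos",
                  "dapi_density_per_um2", "section_area_um2")
                %in% names(sections)))
  total <- round(sections$dapi_density_per_um2 * sections$section_area_um2)
  bad <- which(total <= 0)
  if (length(bad))
    stop("zero estimated nuclei in section (group=", sections$group[bad[1]],
         ", time_h=", sections$time_h[bad[1]],
         ", retina=", sections$retina_id[bad[1]],
         ", section=", sections$section_id[bad[1]], ")")
  if (any(sections$brdu_pos > total))
    stop("brdu_pos exceeds the estimated total nuclei in some section")
  sections$li_section <- sections$brdu_pos / total

  per_retina <- stats::aggregate(
    li_section ~ group + time_h + retina_id, data = sections, FUN = mean)
  out <- stats::aggregate(li_section ~ group + time_h, data = per_retina,
                          FUN = mean)
  names(out)[names(out) == "li_section"] <- "li"
  nr <- stats::aggregate(retina_id ~ group + time_h, data = per_retina,
                         FUN = length)
  out$n_retinas <- nr$retina_id[match(paste(out$group, out$time_h),
                                      paste(nr$group, nr$time_h))]
  out <- out[order(out$group, out$time_h), c("group", "time_h", "li",
                                             "n_retinas")]
  rownames(out) <- NULL
  if (any(out$n_retinas < min_retinas))
    warning("some (group, time) points have fewer than ", min_retinas,
            " retinas")
  class(out) <- c("li_series", "data.frame")
  out
}

# Locate the G1 (2C) peak of a DNA-content histogram: modal bin of an
# equal-width histogram spanning the data range (explicit breaks keep the
# estimate equivariant under rescaling of the fluorescence axis), refined
# to the median of the events inside the modal bin.
find_g1_peak <- function(values, nbins = 256L) {
  rng <- range(values)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- graphics::hist(values, breaks = br, plot = FALSE,
                      include.lowest = TRUE)
  if (max(h$counts) < 2 * mean(h$counts))
    stop("no detectable G1 peak: DNA-content histogram is flat")
  i <- which.max(h$counts)
  inb <- values >= br[i] & values <= br[i + 1L]
  stats::median(values[inb])
}

#' Estimate cell-cycle phase fractions from DNA-content values
#'
#' Deterministic histogram gating (no mixture-model deconvolution): the G1
#' (2C) peak is the histogram mode; the G2/M reference sits at twice the
#' peak; the G1 gate is `peak +/- k_sigma * sigma_G1` and the G2-M gate
#' `2 * peak +/- k_sigma * sigma_G2`, with `sigma_G1` the robust spread
#' (1.4826 x median absolute deviation) of events within 10% of the peak —
#' robust to the S-phase shoulder — and `sigma_G2 = 2 * sigma_G1` (the
#' measurement CV is constant on a multiplicative scale). S-phase events
#' are those strictly between the gates; fractions are relative to all
#' in-gate events (anything from the lower G1 bound to the upper G2-M
#' bound).
#'
#' @param values Numeric vector of fluorescence values (>= 1000 events).
#' @param k_sigma Gate half-width in units of the peak spread; default 2.
#' @return A [phase_fractions()] object (fractions sum to 1).
#' @examples
#' pop <- simulate_population(5e4, preset_kinetics("control"), seed = 1)
#' x <- simulate_dna_content(pop, c2_level = 50, cv = 0.03, seed = 2)
#' estimate_phase_fractions(x)
#' @export
estimate_phase_fractions <- function(values, k_sigma = 2) {
  stopifnot(is.numeric(values), k_sigma > 0)
  if (length(values) < 1000L)
    stop("need at least 1000 events to gate a DNA-content histogram")
  peak <- find_g1_peak(values)
  near <- values[abs(values - peak) <= 0.1 * peak]
  sigma1 <- 1.4826 * stats::median(abs(near - peak))
  sigma2 <- 2 * sigma1
  g1_lo <- peak - k_sigma * sigma1
  g1_hi <- peak + k_sigma * sigma1
  g2_lo <- 2 * peak - k_sigma * sigma2
  g2_hi <- 2 * peak + k_sigma * sigma2
  in_g1 <- values >= g1_lo & values <= g1_hi
  in_g2 <- values >= g2_lo & values <= g2_hi & !in_g1
  in_s <- values > g1_hi & values < g2_lo
  n <- sum(in_g1) + sum(in_g2) + sum(in_s)
  if (n == 0L) stop("no events fall inside the gates")
  phase_fractions(g1 = sum(in_g1) / n, s = sum(in_s) / n,
                  g2m = sum(in_g2) / n)
}

#' Fold change of a proportion
#'
#' @param reference Reference proportion (> 0).
#' @param observed Observed proportion.
#' @return `observed / reference`.
#' @examples
#' fold_change(0.07, 0.47) # ~6.7
#' @export
fold_change <- function(reference, observed) {
  stopifnot(is.numeric(reference), is.numeric(observed))
  if (any(reference <= 0))
    stop("undefined ratio: reference proportion must be positive")
  observed / reference
}
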