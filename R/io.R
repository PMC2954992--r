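# Column schemas for the pipeline's CSV tables. Every quantity carries its
# unit in the column name to keep hours/um/um^2 unambiguous.
table_schemas <- list(
  counts = list(
    columns = c("group", "time_h", "retina_id", "section_id", "brdu_pos",
                "dapi_density_per_um2", "section_area_um2"),
    numeric = c("time_h", "retina_id", "section_id", "brdu_pos",
                "dapi_density_per_um2", "section_area_um2"),
    range = list(time_h = c(0, Inf), brdu_pos = c(0, Inf),
                 dapi_density_per_um2 = c(0, Inf),
                 section_area_um2 = c(0, Inf))),
  li = list(
    columns = c("group", "time_h", "li"),
    numeric = c("time_h", "li"),
    range = list(time_h = c(0, Inf), li = c(0, 1))),
  fluor = list(
    columns = c("group", "event_id", "fluorescence_au"),
    numeric = c("event_id", "fluorescence_au"),
    range = list(fluorescence_au = c(0, Inf))),
  morpho = list(
    columns = c("group", "embryo_id", "value"),
    numeric = c("embryo_id", "value"),
    range = list()))

validate_table <- function(df, schema_name, where = "table") {
  sch <- table_schemas[[schema_name]]
  if (is.null(sch)) stop("unknown schema: ", schema_name)
  missing <- setdiff(sch$columns, names(df))
  if (length(missing))
    stop("schema '", schema_name, "': ", where, " is missing column(s) ",
         paste(missing, collapse = ", "))
  df <- df[sch$columns]
  for (col in sch$numeric) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("schema '", schema_name, "': non-numeric value in column '",
           col, "', row ", bad[1])
    if (anyNA(v))
      stop("schema '", schema_name, "': missing value in column '", col,
           "', row ", which(is.na(v))[1])
    df[[col]] <- v
  }
  for (col in names(sch$range)) {
    r <- sch$range[[col]]
    bad <- which(df[[col]] < r[1] | df[[col]] > r[2])
    if (length(bad))
      stop("schema '", schema_name, "': value out of range [", r[1], ", ",
           r[2], "] in column '", col, "', row ", bad[1])
  }
  df
}

#' Read a validated pipeline table
#'
#' Reads one of the pipeline's CSV schemas (`counts`, `li`, `fluor`,
#' `morpho`) and validates column presence, types and ranges; errors name
#' the offending row and column.
#'
#' @param path CSV file path.
#' @param schema_name One of `"counts"`, `"li"`, `"fluor"`, `"morpho"`.
#' @return A validated data frame with the schema's columns.
#' @export
read_table <- function(path, schema_name) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(df, schema_name, where = path)
}

#' Write a validated pipeline table
#'
#' @param df Data frame conforming to the schema.
#' @param path Output CSV path.
#' @param schema_name Schema to validate against before writing.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema_name) {
  df <- validate_table(df, schema_name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' The stated world of the synthetic experiment: control and morphant
#' kinetics, six exposure times 0.5-10.5 h in 2-h steps, 3 retinas per
#' time, ~500 cells per section, 2e6 flow events per group at 3%
#' measurement CV, and the printed mitotic-count morphometry summaries.
#'
#' @param seed Integer seed for the whole run.
#' @return A nested list (class `run_config`), serialisable to JSON via
#'   [write_run_config()].
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    groups = list(
      control  = list(tc = 10.5, ts = 5.44, gf = 0.11, tg2m = 0.67),
      morphant = list(tc = 50.6, ts = 39.47, gf = 0.35, tg2m = 1.0)),
    reference_group = "control",
    times = c(0.5, 2.5, 4.5, 6.5, 8.5, 10.5),
    n_retinas = 3,
    cells_per_section = 500,
    cells_per_retina = 2000,
    density_mean = 0.025,
    area_mean = 20000,
    counting_cv = 0.05,
    flow_events = 2e6,
    flow_cv = 0.03,
    c2_level = 50,
    alpha = 0.05,
    k_sigma = 2,
    min_retinas = 3,
    morpho_groups = data.frame(
      label = c("control", "morphant"),
      mean = c(15.3, 28.0), sd = c(4.7, 3.4), n = c(3L, 3L)),
    seed = seed), class = "run_config")
}

#' Read / write a pipeline configuration (JSON)
#'
#' @param path JSON file path.
#' @return For `read_run_config`, a `run_config` list; for
#'   `write_run_config`, `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg$groups <- lapply(cfg$groups, as.list)
  validate_run_config(structure(cfg, class = "run_config"))
}

#' @rdname read_run_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

validate_run_config <- function(config) {
  if (length(config$groups) == 0) stop("config defines zero groups")
  if (!is.null(config$reference_group) &&
      !(config$reference_group %in% names(config$groups)))
    stop("reference_group '", config$reference_group, "' is not defined")
  if (any(diff(config$times) <= 0))
    stop("config times must be strictly increasing")
  if (is.null(config$seed) || config$seed < 0 ||
      config$seed != round(config$seed))
    stop("config seed must be a non-negative integer")
  defaults <- default_run_config()
  for (f in setdiff(names(defaults), names(config)))
    config[[f]] <- defaults[[f]]
  config
}

config_params <- function(config, group) {
  g <- config$groups[[group]]
  kinetic_params(tc = g$tc, ts = g$ts, gf = g$gf,
                 tg1 = g$tg1 %||% NULL, tg2m = g$tg2m %||% NULL)
}

#' Run the full synthetic analysis pipeline
#'
#' For each configured group: simulate a cumulative-labelling experiment,
#' compute the labelling-index series, fit the rise/plateau model; simulate
#' a DNA-content readout and gate its phase fractions. Then compute phase
#' fold changes of each group against the reference group and the
#' morphometric t test. The report payload is a pure function of
#' (config, seed); any stage failure is rethrown with the stage name.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out Optional path; when given the report is written there as
#'   JSON.
#' @return The report, a nested list.
#' @export
run_pipeline <- function(config, out = NULL) {
  config <- validate_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  report <- list(config_seed = config$seed, groups = list())
  gi <- 0L
  for (g in names(config$groups)) {
    gi <- gi + 1L
    params <- stage("config", config_params(config, g))
    sec <- stage("simulate", simulate_experiment(
      params, times = config$times, n_retinas = config$n_retinas,
      cells_per_section = config$cells_per_section,
      cells_per_retina = config$cells_per_retina,
      density_mean = config$density_mean, area_mean = config$area_mean,
      noise_cv = config$counting_cv, group = g,
      seed = substream_seed(config$seed, 10L * gi)))
    li <- stage("index", labelling_index(sec,
                                         min_retinas = config$min_retinas))
    fit <- stage("fit", fit_cumulative(li, alpha = config$alpha))
    flowpop <- stage("flow", simulate_population(
      config$flow_events, params,
      seed = substream_seed(config$seed, 10L * gi + 1L)))
    fluor <- stage("flow", simulate_dna_content(
      flowpop, c2_level = config$c2_level, cv = config$flow_cv,
      seed = substream_seed(config$seed, 10L * gi + 2L)))
    phases <- stage("flow", estimate_phase_fractions(
      fluor, k_sigma = config$k_sigma))
    report$groups[[g]] <- list(
      params = unclass(params)[!vapply(unclass(params), is.null,
                                       logical(1))],
      fit = unclass(fit),
      phase_fractions = unclass(phases),
      phase_fractions_true = unclass(phase_fractions_true(
        complete_partition(params))))
  }
  ref <- config$reference_group %||% names(config$groups)[1]
  report$fold_changes <- list()
  for (g in setdiff(names(config$groups), ref)) {
    pr <- report$groups[[ref]]$phase_fractions
    pg <- report$groups[[g]]$phase_fractions
    report$fold_changes[[g]] <- list(
      vs = ref,
      s = stage("fold", fold_change(pr$s, pg$s)),
      g2m = if (pr$g2m > 0) fold_change(pr$g2m, pg$g2m) else NA)
  }
  mg <- config$morpho_groups
  if (!is.null(mg) && nrow(mg) >= 2) {
    report$morpho <- stage("morpho", {
      sums <- lapply(seq_len(nrow(mg)), function(i)
        group_summary(mg$label[i], mg$mean[i], mg$sd[i], mg$n[i]))
      names(sums) <- mg$label
      refs <- if (ref %in% mg$label) ref else mg$label[1]
      lapply(setdiff(mg$label, refs), function(g)
        c(list(group = g, vs = refs),
          unclass(t_test_from_summary(sums[[refs]], sums[[g]]))))
    })
  }
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}
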