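# Readers, writers and the end-to-end report runner.

.trace_csv_cols <- c("trace_id", "time_s", "value")

#' Read fluorescence traces from long CSV
#'
#' Expects the long dialect written by [write_traces()] /
#' [generate_uptake_traces()]: one row per sample with columns `trace_id`,
#' `time_s`, `value`, an exposure time (column `exposure_time_s` or the
#' `exposure_time` argument), and optional metadata columns (`kind`,
#' `cell_line`, `ca_mM`, `field_level`, `replicate_id`). Rows are sorted by
#' time within each trace; duplicate time stamps and non-numeric values are
#' reported with their row numbers.
#'
#' @param path CSV file path.
#' @param exposure_time Exposure time in seconds, used when the file carries
#'   no `exposure_time_s` column.
#' @return Named list of [fluorescence_trace()] objects.
#' @export
read_traces <- function(path, exposure_time = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(.trace_csv_cols, names(df))
  if (length(missing))
    stop("trace CSV is missing column(s): ", paste(missing, collapse = ", "))
  if (!"exposure_time_s" %in% names(df)) {
    if (is.null(exposure_time))
      stop("no 'exposure_time_s' column; supply 'exposure_time'")
    df$exposure_time_s <- exposure_time
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$value))))
  if (length(bad))
    stop("non-numeric 'value' at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  dup <- duplicated(df[, c("trace_id", "time_s")])
  if (any(dup))
    stop("duplicate (trace_id, time_s) at row(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "))
  traces_from_table(df)
}

#' Write a long trace table (or any data frame) with a provenance header
#'
#' Prepends a `#`-comment line recording the package version and a content
#' hash of the run configuration, then writes standard CSV. Files written
#' this way are read back with `comment.char = "#"` (as [read_traces()]
#' does).
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param config_hash Optional provenance string (e.g. from
#'   [config_hash()]).
#' @return Invisibly, `path`.
#' @export
write_traces <- function(df, path, config_hash = NULL) {
  hdr <- sprintf("# nspef %s%s",
                 as.character(utils::packageVersion("nspef")),
                 if (is.null(config_hash)) "" else paste0("; config ", config_hash))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Hash a run configuration for provenance headers
#'
#' @param config Any serializable R object.
#' @return A short hexadecimal digest string.
#' @export
config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  # small rolling hash; provenance marker, not cryptographic
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2^28
  sprintf("%07x", h)
}

#' Run the configured analysis stages end to end
#'
#' Executes the requested stages on generated data and writes their outputs
#' under `out_dir`: `simulate` (uptake trace CSV), `fit` (per-trace
#' exponential fits and AUC CSV), `stats` (Welch ANOVA + Dunnett T3 of the
#' AUC by cell line, JSON), `threshold` (threshold-field table CSV), and
#' `field` (per-subROI field CSV). A manifest JSON records the
#' configuration, seed and produced files.
#'
#' @param config Either a named list or a path to a YAML file with any of
#'   the keys `seed`, `out_dir`, `stages`, `n_per_group`, `groups`
#'   (cell-line subset), `diameters_um`, `durations_s`. Unknown keys are
#'   rejected.
#' @return Invisibly, the manifest list.
#' @export
run_report <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  known <- c("seed", "out_dir", "stages", "n_per_group", "groups",
             "diameters_um", "durations_s")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% tempfile("nspef_report_")
  stages <- config$stages %||% c("simulate", "fit", "stats", "threshold")
  if (length(stages) == 0L) {
    warning("empty stage list; nothing to do")
    return(invisible(list(stages = character(0))))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # hash the scientific configuration only, so the same analysis written to
  # two directories carries the same provenance mark
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  files <- character(0)
  gdef <- uptake_group_defaults()
  if (!is.null(config$groups)) gdef <- gdef[gdef$cell_line %in% config$groups, ]

  traces_df <- NULL
  if ("simulate" %in% stages || "fit" %in% stages || "stats" %in% stages) {
    traces_df <- generate_uptake_traces(gdef,
                                        n_per_group = config$n_per_group %||% 20,
                                        seed = seed)
    f <- file.path(out_dir, "uptake_traces.csv")
    write_traces(traces_df, f, hash); files <- c(files, f)
  }
  fits_df <- NULL
  if ("fit" %in% stages || "stats" %in% stages) {
    traces <- traces_from_table(traces_df)
    fits <- lapply(traces, fit_uptake)
    fits_df <- data.frame(
      trace_id = names(fits),
      cell_line = vapply(traces, function(tr) tr$meta$cell_line, character(1)),
      ca_mM = vapply(traces, function(tr) tr$meta$ca_mM, numeric(1)),
      amplitude = vapply(fits, `[[`, numeric(1), "amplitude"),
      tau_s = vapply(fits, `[[`, numeric(1), "tau_reseal"),
      r2 = vapply(fits, `[[`, numeric(1), "r_squared"),
      converged = vapply(fits, `[[`, logical(1), "converged"),
      auc = vapply(traces, trace_auc, numeric(1)))
    f <- file.path(out_dir, "uptake_fits.csv")
    write_traces(fits_df, f, hash); files <- c(files, f)
  }
  if ("stats" %in% stages) {
    res <- lapply(split(fits_df, fits_df$ca_mM), function(d) {
      gr <- split(d$auc, d$cell_line)
      list(ca_mM = d$ca_mM[1],
           welch = unclass(welch_anova(gr))[c("w_statistic", "df_num",
                                              "df_den", "p_value")],
           dunnett_t3 = as.data.frame(dunnett_t3(gr)))
    })
    f <- file.path(out_dir, "auc_stats.json")
    jsonlite::write_json(res, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  if ("threshold" %in% stages) {
    f <- file.path(out_dir, "threshold_curve.csv")
    threshold_curve(config$diameters_um %||% seq(10, 40, by = 5),
                    config$durations_s %||% 10^seq(-7, -5, length.out = 25),
                    file = f)
    files <- c(files, f)
  }
  if ("field" %in% stages) {
    f <- file.path(out_dir, "subroi_fields.csv")
    assign_subroi_fields(electrode_geometry(), roi_spec(), file = f)
    files <- c(files, f)
  }
  manifest <- list(package = "nspef",
                   version = as.character(utils::packageVersion("nspef")),
                   seed = seed, config_hash = hash, stages = stages,
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(manifest, list(out_dir = out_dir)))
}
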