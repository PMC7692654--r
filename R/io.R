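# Schema-validated CSV I/O, report rendering, run logging, and access
# to the bundled reference kinetic-parameter tables.

# One canonical CSV dialect everywhere: UTF-8, comma, header, '.' decimal.
read_csv_strict <- function(path) {
  if (!file.exists(path)) {
    stop("validation error: file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0L) {
    stop("empty input: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    stop("empty input: ", path, " has a header but no rows", call. = FALSE)
  }
  df
}

check_columns <- function(df, cols, path) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("validation error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
}

check_numeric <- function(df, cols, path) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(v_num <- as.numeric(v))
      bad <- which(is.na(v_num) & !is.na(v))
      if (length(bad)) {
        stop(sprintf(
          "validation error in %s, line %d: non-numeric value '%s' in column %s",
          path, bad[1] + 1L, v[bad[1]], cl), call. = FALSE)
      }
      df[[cl]] <- v_num
    }
    bad <- which(!is.finite(df[[cl]]))
    if (length(bad)) {
      stop(sprintf("validation error in %s, line %d: non-finite value in column %s",
                   path, bad[1] + 1L, cl), call. = FALSE)
    }
  }
  df
}

#' Read a decay-series CSV
#'
#' Schema: `temperature_c, time_min, value, replicate` (replicate
#' optional). Each (temperature, replicate) group must form a valid
#' decay series: times starting at 0, strictly increasing, positive
#' initial value. Diagnostics name the offending line.
#'
#' @param path Path to the CSV file.
#' @return A list of [decay_series()].
#' @export
read_decay_csv <- function(path) {
  df <- read_csv_strict(path)
  check_columns(df, c("temperature_c", "time_min", "value"), path)
  df <- check_numeric(df, c("temperature_c", "time_min", "value"), path)
  bad <- which(df$time_min < 0)
  if (length(bad)) {
    stop(sprintf("validation error in %s, line %d: negative time",
                 path, bad[1] + 1L), call. = FALSE)
  }
  if (is.null(df$replicate)) df$replicate <- 1L
  groups <- split(df, list(df$temperature_c, df$replicate), drop = TRUE)
  lapply(unname(groups), function(g) {
    g <- g[order(g$time_min), ]
    decay_series(g$temperature_c[1], g$time_min, g$value,
                 replicate_id = as.character(g$replicate[1]))
  })
}

#' Read a pH-differential assay CSV
#'
#' Schema: `sample_id, replicate, a520_ph1, a700_ph1, a520_ph45,
#' a700_ph45, dilution_factor, final_volume_ml, dry_mass_mg`.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame ready for [quantify_assay_table()].
#' @export
read_assay_csv <- function(path) {
  df <- read_csv_strict(path)
  cols <- c("sample_id", "replicate", "a520_ph1", "a700_ph1",
            "a520_ph45", "a700_ph45", "dilution_factor",
            "final_volume_ml", "dry_mass_mg")
  check_columns(df, cols, path)
  check_numeric(df, cols[-1], path)
}

#' Read a Trolox standards CSV
#'
#' Schema: `concentration_mmol, response`.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_trolox_csv <- function(path) {
  df <- read_csv_strict(path)
  check_columns(df, c("concentration_mmol", "response"), path)
  check_numeric(df, c("concentration_mmol", "response"), path)
}

#' Read a digestion time-course CSV
#'
#' Schema: `pretreatment, phase, time_min, tac_value, dpph_value`.
#'
#' @param path Path to the CSV file.
#' @return A list of [digestion_course()], one per
#'   (pretreatment, phase).
#' @export
read_digestion_csv <- function(path) {
  df <- read_csv_strict(path)
  check_columns(df, c("pretreatment", "phase", "time_min", "tac_value",
                      "dpph_value"), path)
  df <- check_numeric(df, c("time_min", "tac_value", "dpph_value"), path)
  groups <- split(df, list(df$pretreatment, df$phase), drop = TRUE)
  lapply(unname(groups), function(g) {
    g <- g[order(g$time_min), ]
    digestion_course(g$pretreatment[1], g$phase[1], g$time_min,
                     g$tac_value, g$dpph_value)
  })
}

#' Write decay series to the canonical CSV schema
#'
#' @param series_list List of [decay_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decay_csv <- function(series_list, path) {
  df <- do.call(rbind, lapply(series_list, function(s)
    data.frame(temperature_c = s$temperature, time_min = s$times,
               value = s$values,
               replicate = if (is.null(s$replicate_id)) "1"
                           else s$replicate_id)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a thermal summary as a report artifact
#'
#' Produces the conventional kinetic-parameter table layout: one row
#' per temperature with k, D and t1/2, then an Ea/z footer. The CSV
#' form round-trips through [utils::read.csv()]; the JSON form carries
#' identical values. Unavailable Ea/z are explicit nulls, never blanks.
#'
#' @param summary A `thermal_summary` from [summarize_kinetics()].
#' @param format `"csv"` or `"json"`.
#' @param path Optional output file; when `NULL` the rendering is
#'   returned as a character string.
#' @return The rendered report (character), invisibly when written.
#' @export
render_report <- function(summary, format = c("csv", "json"), path = NULL) {
  stopifnot(inherits(summary, "thermal_summary"))
  format <- match.arg(format)
  rows <- summary$rows[, c("temperature_c", "k_per_min", "k_se",
                           "d_value_min", "half_life_min", "significant")]
  footer <- list(
    ea_kj_mol = if (is.null(summary$arrhenius)) NULL else summary$arrhenius$ea,
    ea_se = if (is.null(summary$arrhenius)) NULL else summary$arrhenius$ea_se,
    ea_r2 = if (is.null(summary$arrhenius)) NULL
            else summary$arrhenius$r_squared,
    z_c = if (is.null(summary$z)) NULL else summary$z$z_value,
    z_se = if (is.null(summary$z)) NULL else summary$z$z_se,
    z_r2 = if (is.null(summary$z)) NULL else summary$z$r_squared,
    thermostable_c = summary$thermostable)
  footer[vapply(footer, is.null, logical(1))] <- list(NA_real_)

  if (format == "json") {
    out <- jsonlite::toJSON(list(rows = rows, footer = footer),
                            auto_unbox = TRUE, digits = NA, null = "null",
                            na = "null", pretty = TRUE)
    out <- as.character(out)
  } else {
    con <- textConnection("csv_lines", "w", local = TRUE)
    utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
    close(con)
    footer_line <- paste0(
      "# ", paste(names(footer),
                  vapply(footer, function(x)
                    paste(format(x, digits = 15), collapse = ";"),
                    character(1)),
                  sep = "=", collapse = ","))
    out <- paste(c(csv_lines, footer_line), collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Write a reproducibility log for a run
#'
#' Records the configuration (as a digest-free JSON echo), seed,
#' package version and R version — enough to reproduce the outputs.
#'
#' @param config A named list describing the run configuration.
#' @param seed The seed used.
#' @param path Output path for the JSON log.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(config, seed, path) {
  log <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    package_version = as.character(utils::packageVersion("thermokin")),
    r_version = R.version.string)
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Published reference kinetic-parameter tables
#'
#' Returns the bundled published kinetic parameters for the thermal
#' degradation of purple maize flour extract: per-temperature
#' first-order rate constants, decimal reduction times and half-lives,
#' for total monomeric anthocyanins (120-180 degrees C) or antioxidant
#' activity (80-180 degrees C). These printed values serve as fixed
#' inputs for cross-temperature regressions (Ea, z) and as test
#' anchors.
#'
#' @param which `"anthocyanin"` or `"antioxidant"`.
#' @return Data frame `temperature_c, k_per_min, k_sd, d_value_min,
#'   d_sd, half_life_min, half_life_sd`.
#' @export
reference_kinetics <- function(which = c("anthocyanin", "antioxidant")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0(which, "_kinetics_published.csv"),
                      package = "thermokin", mustWork = TRUE)
  utils::read.csv(path)
}
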