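#' Replicate kinetic time series
#'
#' A `kinetic_series` holds the concentration-versus-time observations for a
#' single replicate of one storage condition: one analyte (the pigment, lipid
#' hydroperoxides, or a volatile aldehyde) followed over storage days in one
#' emulsion at a given pH and extract dose.
#'
#' @param day Numeric vector of sampling times in days, non-negative and
#'   strictly increasing. Unsorted input is sorted (with `value`).
#' @param value Numeric vector of concentrations in micromolar, same length as
#'   `day`, all non-negative.
#' @param analyte One of `"anthocyanin"`, `"LOOH"`, `"propanal"`, `"hexanal"`.
#' @param sample_id Character label of the emulsion sample.
#' @param pH Numeric pH of the aqueous phase, in `[0, 14]`.
#' @param extract_dose Black carrot extract dose in g/L, `>= 0`.
#' @param replicate Integer replicate index, `>= 1`.
#' @param meta Optional named list of further metadata (e.g. oil fraction,
#'   surfactant concentration, preparation index).
#'
#' @return An object of class `kinetic_series`: a list with elements `day`,
#'   `value`, `analyte` and `meta`.
#' @examples
#' s <- kinetic_series(day = 0:4, value = 24 * exp(-1.44 * 0:4),
#'                     analyte = "anthocyanin", pH = 2, replicate = 1)
#' s
#' @export
kinetic_series <- function(day, value,
                           analyte = c("anthocyanin", "LOOH", "propanal", "hexanal"),
                           sample_id = "sample", pH = NA_real_,
                           extract_dose = 0, replicate = 1L, meta = list()) {
  analyte <- match.arg(analyte)
  day <- as.numeric(day)
  value <- as.numeric(value)
  if (length(day) != length(value))
    stop("`day` and `value` must have the same length", call. = FALSE)
  if (anyNA(day) || anyNA(value))
    stop("`day` and `value` must not contain missing values", call. = FALSE)
  ord <- order(day)
  day <- day[ord]; value <- value[ord]
  if (any(day < 0)) stop("days must be non-negative", call. = FALSE)
  if (anyDuplicated(day))
    stop("duplicated day within a replicate: ",
         paste(unique(day[duplicated(day)]), collapse = ", "), call. = FALSE)
  if (any(value < 0)) stop("values must be non-negative (µM)", call. = FALSE)
  if (!is.na(pH) && (pH < 0 || pH > 14)) stop("pH must lie in [0, 14]", call. = FALSE)
  if (!is.na(extract_dose) && extract_dose < 0)
    stop("extract_dose must be >= 0", call. = FALSE)
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L) stop("replicate must be >= 1", call. = FALSE)
  structure(list(
    day = day, value = value, analyte = analyte,
    meta = c(list(sample_id = as.character(sample_id), pH = pH,
                  extract_dose = extract_dose, replicate = replicate), meta)
  ), class = "kinetic_series")
}

#' @export
print.kinetic_series <- function(x, ...) {
  cat(sprintf("<kinetic_series> %s, sample %s, pH %s, dose %s g/L, replicate %d\n",
              x$analyte, x$meta$sample_id, format(x$meta$pH),
              format(x$meta$extract_dose), x$meta$replicate))
  print(data.frame(day = x$day, value_uM = x$value), row.names = FALSE)
  invisible(x)
}

#' @export
length.kinetic_series <- function(x) length(x$day)

#' @export
as.data.frame.kinetic_series <- function(x, ...) {
  data.frame(sample_id = x$meta$sample_id, pH = x$meta$pH,
             extract_dose = x$meta$extract_dose, replicate = x$meta$replicate,
             analyte = x$analyte, day = x$day, value = x$value)
}

# condition key used to decide whether two series/fits are comparable
condition_key <- function(x) {
  m <- if (inherits(x, "kinetic_series")) x$meta else x$meta
  paste(m$sample_id, format(m$pH), format(m$extract_dose),
        if (inherits(x, "kinetic_series")) x$analyte else x$analyte,
        sep = "|")
}

#' Read kinetic time series from a long-format CSV file
#'
#' The file must carry the columns `sample_id, pH, extract_dose, replicate,
#' analyte, day, value` (header required, any column order, extra columns
#' ignored). One [kinetic_series] is returned per
#' `(sample_id, analyte, replicate)` group, rows sorted by day. Units are
#' fixed: days for `day`, micromolar for `value`. Rows with an empty `value`
#' cell are dropped with a message giving the count.
#'
#' @param path Path to a CSV file (RFC 4180, UTF-8, header row).
#' @return A list of [kinetic_series] objects; an empty list (with a warning)
#'   for a file with no data rows.
#' @export
read_kinetic_csv <- function(path) {
  required <- c("sample_id", "pH", "extract_dose", "replicate",
                "analyte", "day", "value")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) {
    warning("no data rows in ", path, call. = FALSE)
    return(list())
  }
  blank <- !nzchar(trimws(df$value))
  if (any(blank)) {
    message(sum(blank), " row(s) with empty value dropped")
    df <- df[!blank, , drop = FALSE]
  }
  num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & nzchar(trimws(df[[col]])))
    if (length(bad))
      stop(sprintf("non-numeric %s at data row %d: '%s'",
                   col, bad[1], df[[col]][bad[1]]), call. = FALSE)
    x
  }
  df$day <- num("day"); df$value <- num("value")
  df$pH <- num("pH"); df$extract_dose <- num("extract_dose")
  df$replicate <- as.integer(num("replicate"))
  key <- interaction(df$sample_id, df$analyte, df$replicate, drop = TRUE)
  lapply(split(df, key), function(g) {
    kinetic_series(day = g$day, value = g$value, analyte = g$analyte[1],
                   sample_id = g$sample_id[1], pH = g$pH[1],
                   extract_dose = g$extract_dose[1],
                   replicate = g$replicate[1])
  })
}

#' Write a CSV report of fitted kinetic models
#'
#' Serializes a list of [fit_decay()] / [fit_sigmoid()] results to a CSV file
#' with one row per fit (condition keys, parameter estimates, derived
#' statistics, residual sum of squares, convergence flag). Mixed fit kinds
#' produce the union of columns with empty cells where a statistic does not
#' apply; an absent induction time is written as `"—"`. A JSON sidecar
#' `<path>.json` records the call configuration and seed.
#'
#' @param fits Non-empty list of `decay_fit` and/or `sigmoid_fit` objects.
#' @param path Output CSV path.
#' @param config Optional list stored in the JSON sidecar.
#' @param seed Optional integer seed stored in the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fits, path, config = list(), seed = NULL) {
  if (!length(fits)) stop("`fits` must be non-empty", call. = FALSE)
  if (inherits(fits, "kinetic_fit")) fits <- list(fits)
  rows <- lapply(fits, fit_report_row)
  cols <- unique(unlist(lapply(rows, names)))
  tab <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    as.data.frame(r[cols], stringsAsFactors = FALSE)
  }))
  if ("t_ind" %in% names(tab))
    tab$t_ind <- ifelse(is.na(tab$t_ind_raw), "—",
                        formatC(tab$t_ind_raw, digits = 15, format = "g"))
  tab$t_ind_raw <- NULL
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  jsonlite::write_json(list(config = config, seed = seed,
                            n_fits = length(fits),
                            written = format(Sys.time(), tz = "UTC")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

fit_report_row <- function(f) {
  m <- f$meta
  base <- list(sample_id = m$sample_id, pH = m$pH,
               extract_dose = m$extract_dose, replicate = m$replicate,
               analyte = f$analyte, model = class(f)[1],
               rss = f$rss, n_obs = f$n_obs, converged = f$converged)
  if (inherits(f, "decay_fit")) {
    c(base, list(C0 = unname(coef(f)["C0"]), k = unname(coef(f)["k"]),
                 t_half = f$t_half))
  } else {
    c(base, list(c0 = unname(coef(f)["c0"]), cmax = unname(coef(f)["cmax"]),
                 k = unname(coef(f)["k"]), t_star = f$t_star,
                 t_ind = NA, t_ind_raw = f$t_ind))
  }
}

#' Read fitted-parameter report back from CSV
#'
#' Inverse of [write_fit_report()] at the table level: returns the data frame
#' with numeric columns restored (`"—"` mapped back to `NA`).
#'
#' @param path CSV path written by [write_fit_report()].
#' @return A data frame.
#' @export
read_fit_report <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("t_ind" %in% names(tab)) {
    tab$t_ind[tab$t_ind == "—"] <- NA
    tab$t_ind <- as.numeric(tab$t_ind)
  }
  tab
}
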