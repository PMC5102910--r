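#' Read a multi-ROI recording table
#'
#' Reads a spreadsheet (`.xlsx`, first worksheet) or `.csv` in the standard
#' layout: column 1 holds the sample times, every following column one
#' region-of-interest (ROI) trace. A header row is auto-detected (a first row
#' whose cells are not numeric is treated as column names). Rows with a
#' non-numeric cell in a given ROI column are dropped for that column only.
#'
#' @param path Path to an `.xlsx` or `.csv` file.
#' @param config Optional [catrace_config()]; `time_scale` converts the time
#'   column to seconds and `trim_before` drops early samples.
#'
#' @return A tibble in long form with columns `trace_id` (the ROI column
#'   name), `time` (seconds, strictly increasing within each trace) and
#'   `value` (fluorescence ratio, a.u.).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(t = 0:29 / 2, roi1 = rnorm(30, 1), roi2 = rnorm(30, 1)),
#'           tf, row.names = FALSE)
#' read_recordings(tf)
read_recordings <- function(path, config = NULL) {
  cfg <- as_catrace_config(config)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "xlsx" = ,
    "xls" = as.data.frame(readxl::read_excel(path, sheet = 1, col_names = FALSE,
                                             col_types = "text",
                                             .name_repair = "minimal")),
    "csv" = utils::read.csv(path, header = FALSE, colClasses = "character",
                            check.names = FALSE),
    stop("unsupported file extension: .", ext)
  )
  if (ncol(raw) < 2L) stop("need at least 2 columns (time + one ROI)")

  first_row <- suppressWarnings(as.numeric(unlist(raw[1L, ])))
  has_header <- any(is.na(first_row))
  if (has_header) {
    nms <- as.character(unlist(raw[1L, ]))
    raw <- raw[-1L, , drop = FALSE]
  } else {
    nms <- c("time", paste0("roi", seq_len(ncol(raw) - 1L)))
  }
  nms[nms == "" | is.na(nms)] <- paste0("col", which(nms == "" | is.na(nms)))
  names(raw) <- make.unique(nms)

  num <- as.data.frame(lapply(raw, function(x) suppressWarnings(as.numeric(x))))
  tvec <- num[[1L]] * cfg$time_scale
  keep_t <- !is.na(tvec)
  num <- num[keep_t, , drop = FALSE]
  tvec <- tvec[keep_t]
  if (length(tvec) == 0L || any(diff(tvec) <= 0)) {
    stop("time column must be strictly increasing")
  }

  out <- purrr::map_dfr(seq.int(2L, ncol(num)), function(jcol) {
    v <- num[[jcol]]
    ok <- !is.na(v)
    if (!is.null(cfg$trim_before)) ok <- ok & tvec >= cfg$trim_before
    tibble::tibble(trace_id = names(num)[jcol], time = tvec[ok], value = v[ok])
  })
  # ROI columns with no usable rows still count in a batch (flagged rows)
  attr(out, "all_ids") <- names(num)[-1L]
  out
}

#' Assemble a single trace tibble
#'
#' @param time Sample times (s), strictly increasing.
#' @param value Signal values (a.u.), same length.
#' @param trace_id Label.
#' @return A tibble with columns `trace_id`, `time`, `value`.
#' @export
as_trace <- function(time, value, trace_id = "trace") {
  stopifnot(length(time) == length(value))
  if (anyNA(time) || anyNA(value)) stop("trace contains missing values")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  tibble::tibble(trace_id = trace_id, time = as.numeric(time),
                 value = as.numeric(value))
}

#' Characterize every trace in a recording file or tibble
#'
#' Runs the full pipeline (total-variation denoising, drift delimitation and
#' fitting, transient detection and fitting, multi-peaked-response analysis)
#' on each ROI and collects one report row per trace. A failing trace is
#' reported as a flagged row; it never aborts the batch.
#'
#' @param x Path to a recordings file (see [read_recordings()]) or a long
#'   tibble with columns `trace_id`, `time`, `value`.
#' @param config Optional [catrace_config()].
#' @param plots Optional directory; when given, a per-trace diagnostic figure
#'   (data, drift, fitted model) is written as `<trace_id>.png`.
#' @param keep_fits Keep the full fitted objects in a `fit` list-column
#'   (default `TRUE`).
#'
#' @return A tibble with one row per input ROI column: `trace_id`,
#'   `detected`, the transient parameters (`t_onset`, `t_10_90`, `amplitude`,
#'   `auc`, `fwhm`, `rho`, `tau_decay`), the two oscillation blocks
#'   (`mpr_all_*`, `mpr_coh_*`), a collapsed `flags` string and (optionally)
#'   the `fit` objects.
#' @export
characterize_document <- function(x, config = NULL, plots = NULL,
                                  keep_fits = TRUE) {
  cfg <- as_catrace_config(config)
  data <- if (is.character(x)) read_recordings(x, cfg) else tibble::as_tibble(x)
  stopifnot(all(c("trace_id", "time", "value") %in% names(data)))
  ids <- attr(data, "all_ids") %||% unique(data$trace_id)

  rows <- purrr::map(ids, function(id) {
    d <- data[data$trace_id == id, ]
    fit <- tryCatch(
      characterize_trace(d, config = cfg),
      error = function(e) {
        structure(list(trace_id = id, error = conditionMessage(e),
                       flags = paste0("error: ", conditionMessage(e)),
                       detected = NA),
                  class = "trace_fit")
      }
    )
    if (!is.null(plots) && is.null(fit$error)) {
      dir.create(plots, showWarnings = FALSE, recursive = TRUE)
      p <- try(autoplot(fit), silent = TRUE)
      if (!inherits(p, "try-error")) {
        suppressMessages(ggplot2::ggsave(
          file.path(plots, paste0(gsub("[^A-Za-z0-9_.-]", "_", id), ".png")),
          p, width = 7, height = 4, dpi = 120))
      }
    }
    fit
  })

  report <- purrr::map_dfr(rows, glance)
  if (keep_fits) report$fit <- rows
  report
}

#' Write characterization results to disk
#'
#' Writes the report tibble as a CSV (one row per trace) and a
#' machine-readable JSON file next to it.
#'
#' @param report Tibble from [characterize_document()].
#' @param path Output CSV path; the JSON is written with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_results <- function(report, path) {
  tab <- report[setdiff(names(report), "fit")]
  utils::write.csv(tab, path, row.names = FALSE)
  jsonlite::write_json(tab, sub("\\.[Cc][Ss][Vv]$", ".json", path),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
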