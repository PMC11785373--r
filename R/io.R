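#' Write an experiment to a directory of CSV files
#'
#' Canonical on-disk layout: one CSV per sweep (`time_ms`, `value_mv`) and
#' per linescan (`time_ms`, `green`, `red`, `artifact`), a `manifest.csv`
#' indexing every record with its condition, location count, cycle and
#' onset times, a `params.json` sidecar holding the protocol and generator
#' parameters, and `ground_truth.csv` when ground truth is present.
#' Numeric values are written with full round-trip precision, so
#' write/read/write is byte-identical.
#'
#' @param experiment An `uncaging_experiment` (see [generate_experiment()]).
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_experiment <- function(experiment, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fs <- experiment$protocol$sampling_rate_hz

  man <- list()
  add_record <- function(type, obj, i) {
    file <- sprintf("%s_%03d.csv", type, i)
    # numeric channels are formatted with %.17g so that parse(write(x))
    # restores every double bit for bit
    if (type == "voltage") {
      tbl <- tibble::tibble(
        time_ms = (seq_along(obj$samples) - 1) * 1000 / fs,
        value_mv = sprintf("%.17g", obj$samples)
      )
    } else {
      tbl <- tibble::tibble(
        time_ms = linescan_times(obj),
        green = sprintf("%.17g", obj$green),
        red = sprintf("%.17g", obj$red),
        artifact = as.integer(obj$artifact_mask)
      )
    }
    readr::write_csv(tbl, file.path(path, file), progress = FALSE)
    man[[length(man) + 1]] <<- tibble::tibble(
      file = file,
      type = type,
      condition = obj$condition,
      k_active = obj$k_active,
      cycle = obj$meta$cycle %||% NA_integer_,
      onsets = paste(sprintf("%.17g", obj$onset_times_ms), collapse = ";"),
      line_period_ms = if (type == "linescan") obj$line_period_ms else NA_real_
    )
  }
  for (i in seq_along(experiment$sweeps)) {
    add_record("voltage", experiment$sweeps[[i]], i)
  }
  for (i in seq_along(experiment$linescans %||% list())) {
    add_record("linescan", experiment$linescans[[i]], i)
  }
  readr::write_csv(dplyr::bind_rows(man), file.path(path, "manifest.csv"),
                   progress = FALSE)

  # numeric parameters go out as %.17g strings: jsonlite's own double
  # serialization is not round-trip exact
  stringify <- function(lst) {
    lapply(lst, function(x) if (is.numeric(x)) sprintf("%.17g", x) else x)
  }
  pars <- list(
    dendrite_id = experiment$dendrite_id,
    drug_condition = experiment$drug_condition,
    n_cycles = experiment$n_cycles,
    protocol = stringify(unclass(experiment$protocol)),
    gain_params = stringify(unclass(experiment$gain_params)),
    calcium_params = if (!is.null(experiment$calcium_params)) {
      stringify(unclass(experiment$calcium_params))
    }
  )
  jsonlite::write_json(pars, file.path(path, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (!is.null(experiment$ground_truth)) {
    gt <- experiment$ground_truth
    readr::write_csv(
      tibble::tibble(quantity = c("amp_nonlinearity_pct",
                                  "int_nonlinearity_pct",
                                  "ca_nonlinearity_pct"),
                     value = c(gt$amp_nonlinearity_pct,
                               gt$int_nonlinearity_pct,
                               gt$ca_nonlinearity_pct %||% NA_real_)),
      file.path(path, "ground_truth.csv"), progress = FALSE)
    readr::write_csv(gt$series, file.path(path, "ground_truth_series.csv"),
                     progress = FALSE)
  }
  invisible(path)
}

#' Read an experiment from its CSV directory layout
#'
#' Inverse of [write_experiment()]: reconstructs the protocol, every sweep
#' and linescan (with onset times and artifact masks) and the ground-truth
#' table when present.
#'
#' @param path Directory written by [write_experiment()].
#' @param calcium Require linescan records with both channels; when `TRUE`
#'   and a linescan file lacks its red channel a descriptive error is
#'   raised.  Default `TRUE` when the manifest lists linescans.
#' @return An `uncaging_experiment`.
#' @export
read_experiment <- function(path, calcium = NULL) {
  manifest_file <- file.path(path, "manifest.csv")
  if (!file.exists(manifest_file)) {
    stop(sprintf("no manifest.csv under '%s'", path), call. = FALSE)
  }
  # base R's strtod parsing is correctly rounded, which the bitwise
  # round-trip guarantee relies on
  man <- utils::read.csv(manifest_file, colClasses = c(onsets = "character"))
  pars <- jsonlite::read_json(file.path(path, "params.json"),
                              simplifyVector = TRUE)
  numify <- function(lst) lapply(lst, function(x) {
    if (is.character(x)) as.numeric(x) else x
  })
  protocol <- do.call(uncaging_protocol, numify(pars$protocol))
  gp <- do.call(gain_params, numify(pars$gain_params))
  cp <- if (!is.null(pars$calcium_params)) {
    do.call(calcium_params, numify(pars$calcium_params))
  }
  if (is.null(calcium)) calcium <- any(man$type == "linescan")
  fs <- protocol$sampling_rate_hz
  base_meta <- list(dendrite_id = pars$dendrite_id,
                    drug_condition = pars$drug_condition)

  parse_onsets <- function(s) {
    if (is.na(s) || !nzchar(s)) numeric() else
      as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  }
  sweeps <- list()
  linescans <- list()
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    tbl <- utils::read.csv(file.path(path, row$file))
    meta <- c(base_meta, list(cycle = row$cycle))
    if (row$type == "voltage") {
      if (!"value_mv" %in% names(tbl)) {
        stop(sprintf("file '%s': missing column 'value_mv'", row$file),
             call. = FALSE)
      }
      sweeps[[length(sweeps) + 1]] <-
        voltage_sweep(tbl$value_mv, fs, condition = row$condition,
                      onset_times_ms = parse_onsets(row$onsets),
                      k_active = row$k_active, meta = meta)
    } else {
      if (!"green" %in% names(tbl)) {
        stop(sprintf("file '%s': missing column 'green'", row$file),
             call. = FALSE)
      }
      if (!"red" %in% names(tbl)) {
        if (calcium) {
          stop(sprintf(
            "file '%s': missing column 'red' (required for calcium analysis)",
            row$file), call. = FALSE)
        }
        next
      }
      linescans[[length(linescans) + 1]] <-
        linescan(tbl$green, tbl$red, row$line_period_ms,
                 onset_times_ms = parse_onsets(row$onsets),
                 artifact_mask = as.logical(tbl$artifact),
                 condition = row$condition, k_active = row$k_active,
                 meta = meta)
    }
  }
  gt <- NULL
  gt_file <- file.path(path, "ground_truth.csv")
  if (file.exists(gt_file)) {
    g <- utils::read.csv(gt_file)
    vals <- stats::setNames(g$value, g$quantity)
    gt <- list(amp_nonlinearity_pct = vals[["amp_nonlinearity_pct"]],
               int_nonlinearity_pct = vals[["int_nonlinearity_pct"]],
               ca_nonlinearity_pct = vals[["ca_nonlinearity_pct"]],
               series = tibble::as_tibble(utils::read.csv(
                 file.path(path, "ground_truth_series.csv"))))
  }
  structure(
    list(
      protocol = protocol,
      gain_params = gp,
      calcium_params = cp,
      n_cycles = pars$n_cycles,
      dendrite_id = pars$dendrite_id,
      drug_condition = pars$drug_condition,
      sweeps = sweeps,
      linescans = if (length(linescans)) linescans else NULL,
      noiseless_sweeps = NULL,
      noiseless_linescans = NULL,
      ground_truth = gt
    ),
    class = "uncaging_experiment"
  )
}
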