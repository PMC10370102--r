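# File formats: wide reads TSV (one row per read, columns read_id then
# ch{c}_t{t} channel-major), schema-versioned fit/bootstrap JSON, and a
# YAML/JSON run configuration.

FIT_SCHEMA_VERSION <- 1L

#' Read a wide reads TSV
#'
#' @param path TSV file with header `read_id` followed by `ch{c}_t{t}`
#'   columns (tab separated, `.` decimal).
#' @param design Optional [peptide_design()]; when given, the presence of
#'   every expected column is checked and the result validated.
#' @return A wide reads tibble.
#' @export
read_reads_tsv <- function(path, design = NULL) {
  reads <- readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    locale = readr::locale(decimal_mark = ".")
  )
  if (!"read_id" %in% names(reads)) {
    stop("reads file lacks a 'read_id' column", call. = FALSE)
  }
  if (!is.null(design)) {
    missing <- setdiff(reads_colnames(design), names(reads))
    if (length(missing)) {
      stop("reads file is missing column(s): ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    val_cols <- reads_colnames(design)
    for (col in val_cols) {
      bad <- which(!is.finite(as.numeric(reads[[col]])))
      if (length(bad)) {
        stop("non-numeric intensity in column ", col, ", row ", bad[1],
          call. = FALSE
        )
      }
    }
  }
  reads
}

#' Write a wide reads TSV
#'
#' @param reads Wide reads tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  readr::write_tsv(reads, path, progress = FALSE)
  invisible(path)
}

params_as_list <- function(params) {
  list(
    edman_failure = params$edman_failure, detach = params$detach,
    initial_block = params$initial_block, cyclic_block = params$cyclic_block,
    dye_loss = params$dye_loss, dud = params$dud,
    mu = params$mu, sigma = params$sigma,
    bg_mu = params$bg_mu, bg_sigma = params$bg_sigma
  )
}

params_from_list <- function(x) {
  do.call(seq_params, x[intersect(names(x), names(formals(seq_params)))])
}

#' Write a fit or bootstrap summary to JSON
#'
#' Serializes estimates, objective traces, constraints, and settings in a
#' schema-versioned machine-readable form.
#'
#' @param x A `fluorfit_fit` or `fluorfit_boot` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  if (inherits(x, "fluorfit_fit")) {
    out <- list(
      schema_version = FIT_SCHEMA_VERSION,
      kind = "fit",
      method = x$method,
      params = params_as_list(x$params),
      estimates = as.list(rates_as_vector(x$params)),
      objective = if (!is.null(x$loglik)) {
        list(type = "loglik", value = x$loglik, trace = x$loglik_trace)
      } else {
        list(type = "rmse", value = x$rmse)
      },
      n_iterations = x$n_iterations,
      converged = x$converged,
      constraints = as.list(x$constraints),
      n_reads = x$n_reads,
      settings = x$settings
    )
  } else if (inherits(x, "fluorfit_boot")) {
    out <- list(
      schema_version = FIT_SCHEMA_VERSION,
      kind = "bootstrap",
      ci_level = x$ci_level,
      n_boot = x$n_boot,
      n_failed = x$n_failed,
      seed = x$seed,
      ci = x$ci,
      replicates = x$replicates
    )
  } else {
    stop("unsupported object for write_fit_json", call. = FALSE)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a fit JSON written by [write_fit_json()]
#'
#' @param path JSON path.
#' @return A list mirroring the serialized fields, with `params` restored to
#'   a [seq_params()].
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema_version)) {
    stop("not a fluorfit JSON (no schema_version)", call. = FALSE)
  }
  if (identical(x$kind, "fit")) x$params <- params_from_list(x$params)
  x
}

#' Read a run configuration (YAML or JSON)
#'
#' The configuration bundles a peptide description, cycle count, intensity
#' model, optional intensity filter, and fitter settings. Peptides are given
#' either as `peptide:` (notation string, with optional `label_rules:`) or
#' as `labels:` (list of per-channel position lists).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON path.
#' @return A list with `design` ([peptide_design()]), `params`
#'   ([seq_params()]), `filter` ([intensity_filter()] or `NULL`), and
#'   `settings` (remaining fields).
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  n_cycles <- cfg$n_cycles %||% 10L
  design <- if (!is.null(cfg$peptide)) {
    parse_peptide_notation(cfg$peptide, cfg$label_rules, n_cycles = n_cycles)
  } else if (!is.null(cfg$labels)) {
    peptide_design(cfg$labels, n_cycles = n_cycles)
  } else {
    stop("config needs 'peptide' or 'labels'", call. = FALSE)
  }
  params <- params_from_list(cfg$params %||% list())
  filt <- if (!is.null(cfg$filter)) {
    do.call(intensity_filter, lapply(cfg$filter, function(ch) {
      lapply(ch$allowed, unlist)
    }))
  } else {
    NULL
  }
  known <- c("peptide", "label_rules", "labels", "n_cycles", "params", "filter")
  list(
    design = design, params = params, filter = filt,
    settings = cfg[setdiff(names(cfg), known)]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
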