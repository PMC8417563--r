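#' Read a flow trace from a delimited text file
#'
#' Accepts a one-column file of flow values (ml/s) at a known sampling
#' rate, or a two-column file of time (s) and flow. The delimiter (comma,
#' tab or whitespace) is auto-detected and a single header line is allowed.
#' Two-column input is validated for uniform sample spacing to within
#' 1e-6 s; the rate is then inferred from the spacing.
#'
#' @param path Path to the file.
#' @param rate Sampling rate (samples/s); required for one-column input,
#'   cross-checked (if given) against two-column input.
#' @param subject_id Subject identifier to attach.
#' @param periods Optional period table (see [flow_trace()]), or a path to
#'   a JSON/YAML sidecar file with fields `label`, `start_s`, `end_s`.
#' @return A [flow_trace()].
#' @export
read_flow_trace <- function(path, rate = NULL, subject_id = NULL,
                            periods = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- detect_sep(first)
  has_header <- !is_numeric_row(strsplit(trimws(first), sep)[[1]])
  dat <- tryCatch(
    utils::read.table(path, sep = if (sep == "[[:space:]]+") "" else sep,
                      header = has_header, colClasses = "numeric",
                      comment.char = "#"),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(dat)) {
    bad <- find_bad_line(path, sep, has_header)
    stop(sprintf("non-numeric data in '%s' at line %d", path, bad),
         call. = FALSE)
  }
  if (ncol(dat) == 1) {
    if (is.null(rate)) stop("rate is required for one-column input",
                            call. = FALSE)
    flow <- dat[[1]]
  } else if (ncol(dat) == 2) {
    tt <- dat[[1]]
    flow <- dat[[2]]
    dt <- diff(tt)
    if (length(dt) < 1 || any(dt <= 0) || max(dt) - min(dt) > 1e-6)
      stop("time column is not uniformly spaced (tolerance 1e-6 s)",
           call. = FALSE)
    inferred <- 1 / mean(dt)
    if (!is.null(rate) && abs(inferred - rate) / rate > 1e-4)
      stop(sprintf("given rate %g disagrees with time column (%g)",
                   rate, inferred), call. = FALSE)
    rate <- if (is.null(rate)) inferred else rate
  } else {
    stop("expected a one- or two-column file, got ", ncol(dat), " columns",
         call. = FALSE)
  }
  if (is.character(periods) && length(periods) == 1)
    periods <- read_periods(periods)
  flow_trace(flow, rate = rate,
             subject_id = if (is.null(subject_id)) tools::file_path_sans_ext(basename(path)) else subject_id,
             periods = periods)
}

detect_sep <- function(line) {
  if (grepl(",", line)) "," else if (grepl("\t", line)) "\t" else "[[:space:]]+"
}

is_numeric_row <- function(fields) {
  fields <- fields[nzchar(fields)]
  length(fields) > 0 && !anyNA(suppressWarnings(as.numeric(fields)))
}

find_bad_line <- function(path, sep, has_header) {
  lines <- readLines(path)
  start <- if (has_header) 2L else 1L
  for (i in seq(start, length(lines))) {
    f <- strsplit(trimws(lines[i]), sep)[[1]]
    if (!is_numeric_row(f) && nzchar(trimws(lines[i]))) return(i)
  }
  NA_integer_
}

#' Write a flow trace to a two-column CSV (time_s, flow_ml_s)
#'
#' Values are written with enough digits for a bit-faithful round-trip via
#' [read_flow_trace()].
#'
#' @param trace A [flow_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flow_trace <- function(trace, path) {
  tt <- trace_times(trace)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,flow_ml_s", con)
  writeLines(paste(sprintf("%.9f", tt), sprintf("%.17g", trace$samples),
                   sep = ","), con)
  invisible(path)
}

#' Read a period sidecar file (JSON or YAML)
#'
#' @param path Path to a JSON (or YAML, if the `yaml` package is available)
#'   file holding a list/array of records with `label`, `start_s`, `end_s`.
#' @return A `data.frame` suitable for [flow_trace()]'s `periods`.
#' @export
read_periods <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML period files",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  p <- as.data.frame(raw)
  stopifnot(all(c("label", "start_s", "end_s") %in% names(p)))
  p[, c("label", "start_s", "end_s")]
}

#' Write a per-breath result table
#'
#' One row per breath, ordered by onset, with columns `onset_s`,
#' `raw_onset_s`, `duration_s`, `domain_id`, `cluster_id`, `v_t_ml`,
#' `t_e_s`, `period_label`, `subject_id`.
#'
#' @param breaths A breath table as returned by [segment_breaths()]
#'   (the `samples` list column is dropped on write).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_breath_table <- function(breaths, path) {
  if (nrow(breaths) > 0 &&
      (anyNA(breaths$onset_s) || any(!is.finite(breaths$onset_s))))
    stop("breath onsets contain NA/NaN; cannot order table", call. = FALSE)
  cols <- c("onset_s", "raw_onset_s", "duration_s", "domain_id",
            "cluster_id", "v_t_ml", "t_e_s", "period_label", "subject_id")
  out <- as.data.frame(breaths)[, intersect(cols, names(breaths)),
                                drop = FALSE]
  if ("duration_s" %in% names(out) == FALSE && "t_tot_s" %in% names(breaths))
    out$duration_s <- breaths$t_tot_s
  out <- out[order(out$onset_s), , drop = FALSE]
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' Read a per-breath result table written by [write_breath_table()]
#'
#' @param path CSV path.
#' @return A `data.frame`, ordered by onset.
#' @export
read_breath_table <- function(path) {
  out <- utils::read.table(path, sep = ",", header = TRUE,
                           stringsAsFactors = FALSE)
  out[order(out$onset_s), , drop = FALSE]
}

# ---- cluster model persistence -------------------------------------------

model_schema_version <- "1.0"

#' Save a fitted cluster model to a JSON archive
#'
#' The archive is plain text with an explicit schema version; numeric
#' values are written at full precision so that `load(save(m))` reproduces
#' eigenvectors, centroids and cluster counts to well within 1e-12.
#'
#' @param model A fitted `cluster_model` (see [fit_waveform_clusters()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_cluster_model <- function(model, path) {
  if (!inherits(model, "cluster_model"))
    stop("not a cluster_model", call. = FALSE)
  if (length(model$domains) == 0)
    stop("model is unfitted: no domains", call. = FALSE)
  for (d in model$domains) {
    if (is.null(d$centroids_wave) || is.null(d$eigenvectors))
      stop("model is unfitted: missing centroids or eigenvectors",
           call. = FALSE)
  }
  ser <- list(
    schema_version = model_schema_version,
    rate = model$rate,
    variance_target = model$variance_target,
    domain_edges_s = model$domain_edges_s,
    domains = lapply(model$domains, serialize_domain)
  )
  json <- jsonlite::toJSON(ser, digits = NA, auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

serialize_domain <- function(d) {
  list(
    domain_id = d$domain_id,
    n = d$n,
    row_length = d$row_length,
    col_means = d$col_means,
    eigenvectors = mat_ser(d$eigenvectors),
    explained = d$explained,
    n_retained = d$n_retained,
    merge = mat_ser(d$merge),
    height = d$height,
    k = d$k,
    scan_d = d$scan_d,
    global_offset = d$global_offset,
    cluster_ids = d$cluster_ids,
    centroids_wave = mat_ser(d$centroids_wave),
    centroids_pc = mat_ser(d$centroids_pc),
    display_length = d$display_length
  )
}

mat_ser <- function(m) {
  if (is.null(m)) return(NULL)
  list(dim = dim(m), data = as.vector(m))
}

mat_deser <- function(s) {
  if (is.null(s)) return(NULL)
  matrix(unlist(s$data), nrow = s$dim[1], ncol = s$dim[2])
}

#' Load a cluster model saved by [save_cluster_model()]
#'
#' @param path Path to the JSON archive.
#' @return A `cluster_model`.
#' @export
load_cluster_model <- function(path) {
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE),
                  error = function(e)
                    stop("model-format error: ", conditionMessage(e),
                         call. = FALSE))
  req <- c("schema_version", "rate", "variance_target", "domain_edges_s",
           "domains")
  if (!all(req %in% names(raw)))
    stop("model-format error: missing fields ",
         paste(setdiff(req, names(raw)), collapse = ", "), call. = FALSE)
  if (!identical(as.character(raw$schema_version), model_schema_version))
    stop("model-format error: unsupported schema version '",
         raw$schema_version, "'", call. = FALSE)
  domains <- lapply(raw$domains, function(d) {
    d$eigenvectors <- mat_deser(d$eigenvectors)
    d$merge <- mat_deser(d$merge)
    d$centroids_wave <- mat_deser(d$centroids_wave)
    d$centroids_pc <- mat_deser(d$centroids_pc)
    d$col_means <- as.numeric(unlist(d$col_means))
    d$explained <- as.numeric(unlist(d$explained))
    d$height <- as.numeric(unlist(d$height))
    d$scan_d <- as.numeric(unlist(d$scan_d))
    d$display_length <- as.numeric(unlist(d$display_length))
    d$cluster_ids <- as.integer(unlist(d$cluster_ids))
    d
  })
  structure(list(rate = raw$rate, variance_target = raw$variance_target,
                 domain_edges_s = as.numeric(unlist(raw$domain_edges_s)),
                 domains = domains, assignments = NULL),
            class = "cluster_model")
}
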