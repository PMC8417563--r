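#' Run the full WBP analysis pipeline
#'
#' Orchestrates simulate/read -> preprocess -> detect -> segment ->
#' cluster -> annotate -> report, writing every artifact (breath table,
#' cluster model, annotation track, prevalence table, raster, ventilation
#' summary, run manifest) into a fresh output directory. The output
#' directory must not already contain files: one directory per run, never
#' overwriting.
#'
#' @param config Either a list or a path to a JSON (or YAML) config file.
#'   Recognized fields: any [run_config()] parameter; `input` (trace file
#'   path) with `rate` and optional `periods` (sidecar path); or
#'   `simulate = TRUE` with optional `sim_baseline_s`, `sim_depressed_s`,
#'   `sim_noise_sd`; `baseline_label` (default "baseline");
#'   `augmented_templates` ignored when not simulating.
#' @param out_dir Output directory (created; must be empty or absent).
#' @param seed Integer seed for stochastic stages (overrides the config's
#'   `rng_seed`).
#' @return Invisibly, a list with the in-memory results (`breaths`,
#'   `model`, `annotation`, `prevalence`, `summary`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- read_config_file(config)
  stopifnot(is.list(config))
  cfg_args <- config[intersect(names(config), names(formals(run_config)))]
  cfg <- do.call(run_config, cfg_args)       # validates before any work
  if (!is.null(seed)) cfg$rng_seed <- as.integer(seed)

  if (dir.exists(out_dir) && length(dir(out_dir, all.files = FALSE)) > 0)
    stop("output directory '", out_dir, "' is not empty; refusing to ",
         "overwrite", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  input_hash <- NULL
  truth <- NULL
  if (isTRUE(config$simulate)) {
    sched <- two_state_schedule(
      baseline_s = config$sim_baseline_s %||% 600,
      depressed_s = config$sim_depressed_s %||% 600)
    sim <- generate_trace(sched, rate = 500,
                          noise_sd = config$sim_noise_sd %||% 0.05,
                          seed = cfg$rng_seed)
    raw <- sim$trace
    truth <- sim$truth
    utils::write.table(truth, file.path(out_dir, "ground_truth.csv"),
                       sep = ",", row.names = FALSE)
  } else {
    if (is.null(config$input))
      stop("config needs either simulate = TRUE or an 'input' trace path",
           call. = FALSE)
    raw <- read_flow_trace(config$input, rate = config$rate,
                           periods = config$periods)
    input_hash <- unname(tools::md5sum(config$input))
  }

  pre <- preprocess_trace(raw, cfg)
  onsets <- detect_onsets(pre, cfg$detect_threshold_mls)
  breaths <- segment_breaths(pre, onsets, cfg)
  if (nrow(breaths) == 0) stop("no breaths detected", call. = FALSE)

  model <- fit_waveform_clusters(breaths, cfg)
  breaths$cluster_id <- model$assignments
  save_cluster_model(model, file.path(out_dir, "cluster_model.json"))
  write_breath_table(breaths, file.path(out_dir, "breaths.csv"))

  baseline_label <- config$baseline_label %||% "baseline"
  categories <- build_categories(model, breaths, baseline_label)
  annotation <- annotate_windows(breaths, categories,
                                 cfg$window_breaths, cfg$majority_pct)
  utils::write.table(annotation, file.path(out_dir, "annotation.csv"),
                     sep = ",", row.names = FALSE)

  prev <- prevalence_table(breaths)
  utils::write.table(cbind(group = rownames(prev), as.data.frame(prev)),
                     file.path(out_dir, "prevalence.csv"),
                     sep = ",", row.names = FALSE)

  vsum <- ventilation_summary(
    breaths, pre$periods %||% data.frame(
      label = "all", start_s = 0, end_s = trace_duration(pre)),
    cfg$metric_window_s,
    normalize_to = if (!is.null(pre$periods) &&
                       baseline_label %in% pre$periods$label)
      baseline_label else NULL)
  utils::write.table(vsum, file.path(out_dir, "summary.csv"), sep = ",",
                     row.names = FALSE)

  manifest <- list(
    tool = "plethyclust",
    version = as.character(utils::packageVersion("plethyclust")),
    seed = cfg$rng_seed,
    config = unclass(cfg),
    input_md5 = input_hash,
    counts = list(
      breaths_detected = length(onsets),
      breaths_segmented = nrow(breaths),
      per_domain = as.list(table(factor(
        breaths$domain_id,
        levels = seq_len(length(cfg$domain_edges_s) - 1)))),
      out_of_range = sum(is.na(breaths$domain_id)),
      k_per_domain = lapply(model$domains, function(d) d$k)
    ))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             file.path(out_dir, "manifest.json"))

  invisible(list(breaths = breaths, model = model, truth = truth,
                 annotation = annotation, prevalence = prev,
                 summary = vsum, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs",
           call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# default behavioral category map: sniffing = all domain-1 clusters,
# common/uncommon tidal by the above-average baseline rule over domains
# 2-3, augmented = all domain-4 clusters.
build_categories <- function(model, breaths, baseline_label) {
  dom_of <- function(ids) {
    unlist(lapply(model$domains[vapply(model$domains,
                                       function(d) d$domain_id,
                                       integer(1)) %in% ids],
                  function(d) seq(d$global_offset,
                                  d$global_offset + d$k - 1)))
  }
  categories <- list()
  sniff <- dom_of(1)
  if (length(sniff) > 0) categories$sniffing <- sniff
  tidal <- dom_of(c(2, 3))
  if (length(tidal) > 0 &&
      any(breaths$period_label == baseline_label, na.rm = TRUE)) {
    ct <- tryCatch(derive_common_tidal(breaths, tidal, baseline_label),
                   error = function(e) NULL)
    if (!is.null(ct)) {
      if (length(ct$common) > 0) categories$common_tidal <- ct$common
      if (length(ct$uncommon) > 0) categories$uncommon_tidal <- ct$uncommon
    } else categories$tidal <- tidal
  } else if (length(tidal) > 0) categories$tidal <- tidal
  aug <- dom_of(4)
  if (length(aug) > 0) categories$augmented <- aug
  categories
}
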