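#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline with the experiment
#' defaults. The configuration round-trips through a YAML file
#' ([read_pipeline_config()] / [write_pipeline_config()]).
#'
#' @param seed Master seed; every random draw descends from it via named
#'   substreams (`stimulus`, `cohort`, `behavior`, `permutation`).
#' @param protocol A [block_protocol()].
#' @param stimulus A [glass_spec()].
#' @param areas Area labels to simulate (with built-in
#'   [area_profile()]s).
#' @param n_participants,nodes_per_hemi,null_nodes_per_hemi,amp_jitter_sd,baseline
#'   Cohort settings; see [simulate_cohort()].
#' @param fdr_q FDR level for node selection.
#' @param n_permutations Permutation iterations for the trend tests.
#' @param lags Behavioral response lags (seconds).
#' @param output_dir Directory for the report bundle.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            protocol = block_protocol(),
                            stimulus = glass_spec(coherence = 1),
                            areas = c("V1", "V2", "V3", "hMT+", "DRA", "VRA"),
                            n_participants = 6,
                            nodes_per_hemi = 50,
                            null_nodes_per_hemi = 10,
                            amp_jitter_sd = 0.08,
                            baseline = 1000,
                            fdr_q = 0.001,
                            n_permutations = 1e4,
                            lags = seq(0, 1.4, by = 0.1),
                            output_dir = "glasscoh-output") {
  structure(list(seed = as.integer(seed), protocol = protocol,
                 stimulus = stimulus, areas = areas,
                 n_participants = n_participants,
                 nodes_per_hemi = nodes_per_hemi,
                 null_nodes_per_hemi = null_nodes_per_hemi,
                 amp_jitter_sd = amp_jitter_sd, baseline = baseline,
                 fdr_q = fdr_q, n_permutations = n_permutations,
                 lags = lags, output_dir = output_dir),
            class = "pipeline_config")
}

# deterministic substream seed derived from the master seed and a name;
# kept below 2^31
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- config
  plain$protocol <- unclass(config$protocol)
  plain$stimulus <- unclass(config$stimulus)
  yaml::write_yaml(unclass(plain), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    seed = raw$seed,
    protocol = do.call(block_protocol, raw$protocol),
    stimulus = do.call(glass_spec, raw$stimulus),
    areas = raw$areas,
    n_participants = raw$n_participants,
    nodes_per_hemi = raw$nodes_per_hemi,
    null_nodes_per_hemi = raw$null_nodes_per_hemi,
    amp_jitter_sd = raw$amp_jitter_sd,
    baseline = raw$baseline,
    fdr_q = raw$fdr_q,
    n_permutations = raw$n_permutations,
    lags = raw$lags,
    output_dir = raw$output_dir)
}

#' Run the end-to-end pipeline
#'
#' Executes design construction, stimulus rendering, cohort simulation,
#' the GLM/psc/selection analysis, the trend permutation tests and the
#' behavioral analysis, writing a report bundle (events TSVs, one example
#' stimulus PNG and dipole TSV, the area response matrices, the trend
#' table, the behavioral ANOVA, and a JSON report with design dimensions
#' and seeds) into `config$output_dir`. Deterministic given the config.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out)) stop("cannot create output directory: ", out,
                             call. = FALSE)
  write_pipeline_config(config, file.path(out, "config.yaml"))

  say("[stimulus] rendering example pattern")
  set.seed(substream_seed(config$seed, "stimulus"))
  field <- sample_dipole_field(config$stimulus)
  img <- render_pattern(field, config$stimulus)
  write_pattern_png(img, file.path(out, "example_pattern.png"))
  write_dipole_tsv(field, file.path(out, "example_dipoles.tsv"))

  say("[cohort] simulating %d participants x %d runs, %d areas",
      config$n_participants, config$protocol$n_runs, length(config$areas))
  set.seed(substream_seed(config$seed, "cohort"))
  cohort <- simulate_cohort(
    protocol = config$protocol,
    profiles = lapply(config$areas, area_profile),
    n_participants = config$n_participants,
    nodes_per_hemi = config$nodes_per_hemi,
    null_nodes_per_hemi = config$null_nodes_per_hemi,
    amp_jitter_sd = config$amp_jitter_sd,
    baseline = config$baseline)
  for (r in seq_len(config$protocol$n_runs)) {
    write_events_tsv(cohort$participants[[1]]$timelines[[r]],
                     file.path(out, sprintf("events_p01_run%02d.tsv", r)))
  }

  say("[glm] fitting prewhitened GLMs and selecting responsive nodes")
  fit <- analyze_cohort(cohort, whiten = TRUE, fdr_q = config$fdr_q)
  for (a in fit$areas) {
    utils::write.table(
      data.frame(participant = seq_len(nrow(fit$responses[[a]])),
                 round(unclass(fit$responses[[a]]), 6)),
      file.path(out, sprintf("area_response_%s.tsv", gsub("\\+", "p", a))),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  say("[inference] permutation trend tests (%d iterations)",
      config$n_permutations)
  set.seed(substream_seed(config$seed, "permutation"))
  trends <- trend_table(fit, n_iterations = config$n_permutations)
  utils::write.table(trends, file.path(out, "trend_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("[behavior] fixation-task analysis")
  set.seed(substream_seed(config$seed, "behavior"))
  trains <- lapply(seq_len(config$n_participants), function(p) {
    lapply(cohort$participants[[p]]$timelines, simulate_behavior_run)
  })
  behav <- behavior_analysis(trains, lags = config$lags)
  utils::write.table(behav$correlations,
                     file.path(out, "behavior_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    seed = config$seed,
    substream_seeds = list(
      stimulus = substream_seed(config$seed, "stimulus"),
      cohort = substream_seed(config$seed, "cohort"),
      permutation = substream_seed(config$seed, "permutation"),
      behavior = substream_seed(config$seed, "behavior")),
    design_matrix_dim = fit$design_dim,
    n_dipoles = nrow(field),
    trend_table = trends,
    anova = list(standard = behav$anova$table, pooled = behav$anova$pooled),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] report written to %s (%.1f s)", out, report$elapsed_s)
  invisible(report)
}
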