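#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration (the shipped default if `path` is `NULL`),
#' fills unset keys from the defaults, and rejects unknown keys so typos
#' fail loudly rather than silently reverting to defaults.
#'
#' @param path YAML config path, or `NULL` for the shipped defaults.
#' @return Nested list of class `pipeline_config` with sections `io`,
#'   `burst`, `measures`, `stats`, `simulate`.
#' @examples
#' cfg <- load_config()
#' cfg$burst$min_spikes_per_channel
#' @export
load_config <- function(path = NULL) {
  defaults <- yaml::read_yaml(default_config_path())
  cfg <- if (is.null(path)) defaults else {
    user <- yaml::read_yaml(path)
    bad_sections <- setdiff(names(user), names(defaults))
    if (length(bad_sections))
      stop("unknown config section(s): ",
           paste(bad_sections, collapse = ", "), call. = FALSE)
    for (s in names(user)) {
      bad <- setdiff(names(user[[s]]), names(defaults[[s]]))
      if (length(bad))
        stop("unknown key(s) in [", s, "]: ", paste(bad, collapse = ", "),
             call. = FALSE)
    }
    utils::modifyList(defaults, user)
  }
  structure(cfg, class = "pipeline_config")
}

#' Path of the shipped default configuration
#' @return File path of the default YAML config.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "meaburst",
              mustWork = TRUE)
}

config_criteria <- function(cfg) {
  burst_criteria(cfg$burst$min_spikes_per_channel,
                 cfg$burst$channel_window_s,
                 cfg$burst$min_channels,
                 cfg$burst$overlap_window_s)
}

#' Simulate an experiment to disk
#'
#' Writes one spike table, metadata sidecar and ground-truth annotation
#' table per culture under `out_dir/<condition>/`.
#'
#' @param config a `pipeline_config` (default: shipped defaults).
#' @param preset generator preset (see [simulation_presets()]).
#' @param transform drug transform for the paired condition; `"none"`
#'   writes only control recordings.
#' @param n_cultures paired cultures to simulate (default from config).
#' @param seed experiment seed.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the list of written spike-table paths.
#' @export
run_simulate <- function(config = load_config(), preset = NULL,
                         transform = "none", n_cultures = NULL, seed = 1L,
                         out_dir = ".") {
  preset <- preset %||% config$simulate$preset
  n_cultures <- n_cultures %||% config$simulate$n_cultures
  base <- simulation_presets(preset, duration = config$simulate$duration_s)
  exp <- make_paired_experiment(base, transform, n_cultures, seed)
  written <- character()
  emit <- function(sims, condition) {
    dir <- file.path(out_dir, condition)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in sims) {
      stem <- file.path(dir, s$recording$culture_id)
      write_spike_table(s$recording, paste0(stem, ".csv"))
      write_ground_truth(s$ground_truth, paste0(stem, "_truth.csv"))
      written <<- c(written, paste0(stem, ".csv"))
    }
  }
  emit(exp$control, "control")
  if (transform != "none") emit(exp$drug, transform)
  invisible(written)
}

#' Analyze a directory of spike tables
#'
#' For every `*.csv` spike table (with YAML sidecar) in `dir`: filters
#' artifacts, detects bursts, applies the inclusion gate, computes the
#' measure suite and the peak-aligned profile. Per-recording burst and
#' measure tables are written next to a `gate` log; recordings failing the
#' gate are flagged (`included = FALSE`) and excluded from group-level
#' summaries, but their per-recording outputs are still produced.
#'
#' @param config a `pipeline_config`.
#' @param dir directory of spike tables (ground-truth annotation files
#'   `*_truth.csv` are ignored).
#' @param out_dir where to write tables (default `dir`); `NULL` disables
#'   writing.
#' @param apply_gate apply the early-incidence inclusion gate
#'   (default TRUE).
#' @return Invisibly, a list per recording: `recording`, `bursts`,
#'   `measures`, `profile` (or `NULL` if burst-free), `included`,
#'   `incidence_hz`; plus attribute `gate_log` (data frame).
#' @export
run_analyze <- function(config = load_config(), dir, out_dir = dir,
                        apply_gate = TRUE) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[!grepl("_truth\\.csv$", files)]
  files <- files[!grepl("_(bursts|measures|profile)\\.csv$", files)]
  files <- files[basename(files) != "gate_log.csv"]
  if (!length(files)) stop("no spike tables found in ", dir, call. = FALSE)
  criteria <- config_criteria(config)
  results <- list()
  log_rows <- list()
  for (f in files) {
    rec <- read_spike_table(f)
    n_in <- nrow(rec$events)
    rec <- filter_artifacts(rec, config$io$artifact_max_positive_uv)
    bursts <- detect_bursts(rec, criteria)
    gate <- if (rec$duration >= config$io$inclusion_window_s) {
      check_inclusion(rec, bursts$global_bursts,
                      window = config$io$inclusion_window_s,
                      threshold_hz = config$io$inclusion_threshold_hz)
    } else structure(NA, incidence_hz = NA_real_)
    included <- if (apply_gate && !is.na(gate)) isTRUE(gate[1]) else TRUE
    ms <- burst_measures(rec, bursts,
                         active_channel_rule = config$measures$active_channel_rule)
    prof <- if (nrow(bursts$global_bursts) > 0L)
      network_spike_profile(rec, bursts,
                            bin_width = config$measures$bin_width_s,
                            window = config$measures$profile_window_s)
    else NULL
    if (!is.null(out_dir)) {
      stem <- sub("\\.csv$", "", file.path(out_dir, basename(f)))
      write_burst_table(bursts$global_bursts, paste0(stem, "_bursts.csv"))
      write_measure_table(ms, paste0(stem, "_measures.csv"))
      if (!is.null(prof))
        utils::write.csv(prof$profile[c("offset_ms", "mean_rate")],
                         paste0(stem, "_profile.csv"), row.names = FALSE)
    }
    message(sprintf(
      "%s: %d events in, %d after artifact filter, %d global bursts, incidence %.3g Hz -> %s",
      basename(f), n_in, nrow(rec$events), nrow(bursts$global_bursts),
      attr(gate, "incidence_hz"),
      if (included) "included" else "excluded"))
    log_rows[[f]] <- data.frame(
      file = basename(f), culture_id = rec$culture_id,
      condition = rec$condition, events = nrow(rec$events),
      n_bursts = nrow(bursts$global_bursts),
      incidence_hz = attr(gate, "incidence_hz"), included = included)
    results[[rec$culture_id]] <- list(
      recording = rec, bursts = bursts, measures = ms, profile = prof,
      included = included, incidence_hz = attr(gate, "incidence_hz"))
  }
  gate_log <- do.call(rbind, unname(log_rows))
  if (!is.null(out_dir))
    utils::write.csv(gate_log, file.path(out_dir, "gate_log.csv"),
                     row.names = FALSE)
  attr(results, "gate_log") <- gate_log
  invisible(results)
}

#' Compare analyzed control and drug directories
#'
#' Pairs cultures by `culture_id` across two analyzed directories, then
#' produces the summary comparison table (measure, median percentage
#' change, signed-rank p, family-wise significance, direction marker), the
#' two-way profile ANOVA, and per-measure histogram-change tables for the
#' inter-burst interval and spikes-per-channel distributions.
#'
#' @param config a `pipeline_config`.
#' @param control_dir,drug_dir directories of spike tables.
#' @param out_dir where to write the summary tables; `NULL` disables
#'   writing.
#' @return List with `comparison` (a [compare_conditions()] result),
#'   `anova` (profile ANOVA table, or `NULL` if either side lacks
#'   profiles), `ibi_histogram_change`, `spikes_per_channel_change`.
#' @export
run_compare <- function(config = load_config(), control_dir, drug_dir,
                        out_dir = NULL) {
  ctl <- run_analyze(config, control_dir, out_dir = NULL)
  drg <- run_analyze(config, drug_dir, out_dir = NULL)
  cmp <- compare_conditions(
    lapply(ctl, `[[`, "measures"), lapply(drg, `[[`, "measures"),
    family_size = config$stats$family_size,
    direction_alpha = config$stats$direction_alpha)
  prof_c <- Filter(Negate(is.null), lapply(ctl, `[[`, "profile"))
  prof_d <- Filter(Negate(is.null), lapply(drg, `[[`, "profile"))
  anova <- if (length(prof_c) >= 2L && length(prof_d) >= 2L)
    profile_anova(prof_c, prof_d, alpha = config$stats$anova_alpha)
  else NULL
  pool <- function(res, field) unlist(lapply(res, function(r)
    r$measures$raw[[field]]), use.names = FALSE)
  ibi_edges <- seq(0, 30, by = 2.5)
  spc_edges <- seq(0, 50, by = 5)
  ibi_chg <- histogram_change(
    measure_histogram(pool(ctl, "ibi"), ibi_edges),
    measure_histogram(pool(drg, "ibi"), ibi_edges))
  spc_chg <- histogram_change(
    measure_histogram(pool(ctl, "spikes_per_channel"), spc_edges),
    measure_histogram(pool(drg, "spikes_per_channel"), spc_edges))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cmp$table, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    if (!is.null(anova))
      utils::write.csv(anova, file.path(out_dir, "profile_anova.csv"),
                       row.names = FALSE)
    utils::write.csv(ibi_chg, file.path(out_dir, "ibi_histogram_change.csv"),
                     row.names = FALSE)
    utils::write.csv(spc_chg,
                     file.path(out_dir, "spikes_per_channel_change.csv"),
                     row.names = FALSE)
  }
  list(comparison = cmp, anova = anova, ibi_histogram_change = ibi_chg,
       spikes_per_channel_change = spc_chg)
}

#' Simulate, analyze and compare in one call
#'
#' @param config a `pipeline_config`.
#' @param preset,transform,n_cultures,seed passed to [run_simulate()].
#' @param out_dir working directory for all stages.
#' @return The [run_compare()] result.
#' @export
run_all <- function(config = load_config(), preset = NULL,
                    transform = "atropine_like", n_cultures = NULL,
                    seed = 1L, out_dir = tempfile("meaburst_run")) {
  run_simulate(config, preset, transform, n_cultures, seed, out_dir)
  run_analyze(config, file.path(out_dir, "control"))
  run_analyze(config, file.path(out_dir, transform))
  run_compare(config, file.path(out_dir, "control"),
              file.path(out_dir, transform),
              out_dir = file.path(out_dir, "comparison"))
}
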