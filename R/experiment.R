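# End-to-end experiment runner: N simulated subjects through both
# pipelines, cross-pipeline component comparison, DICS evaluation and
# group statistics.

#' Experiment configuration
#'
#' @param n_subjects Number of simulated subjects (seeded re-simulations
#'   sharing one sensor layout and source grid).
#' @param master_seed Base seed; subject s uses `master_seed + s`.
#' @param sim Base [sim_config()] (its `rng_seed` is overridden per
#'   subject).
#' @param bands Named band list for the evaluation.
#' @param grid_spacing,grid_radius Source-grid geometry (m).
#' @param top_k Localization points per component.
#' @param amica_max_iter Iteration cap for the adaptive-mixture fit.
#' @param thresholds From [identify_thresholds()].
#' @return Named list, class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 12, master_seed = 1L,
                              sim = sim_config(), bands = ocubss_bands(),
                              grid_spacing = 0.007, grid_radius = 0.082,
                              top_k = 500, amica_max_iter = 2000,
                              thresholds = identify_thresholds()) {
  structure(list(n_subjects = n_subjects,
                 master_seed = as.integer(master_seed), sim = sim,
                 bands = bands, grid_spacing = grid_spacing,
                 grid_radius = grid_radius, top_k = top_k,
                 amica_max_iter = amica_max_iter, thresholds = thresholds),
            class = "experiment_config")
}

#' Run the full simulated comparison experiment
#'
#' For every simulated subject: simulate, preprocess, run both pipelines,
#' identify components, clean, and evaluate with the common-filter
#' beamformer; then aggregate component counts, cross-pipeline component
#' topography correlations, and parcel-level group tests of the
#' power-reduction difference maps.  A subject whose processing fails is
#' logged and skipped; the others continue.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory for JSON/CSV artifacts.
#' @param verbose Print per-stage progress.
#' @return Object of class `experiment_report`: per-subject results,
#'   aggregate tables, group test output, the config and seed.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           verbose = FALSE) {
  sens <- sensor_layout(config$sim$n_sensor_sites)
  grid <- make_forward_grid(sens, spacing = config$grid_spacing,
                            radius = config$grid_radius)
  parc <- default_parcellation(grid)
  say <- function(...) if (verbose) message(sprintf(...))

  subjects <- list()
  diff_maps <- lapply(config$bands, function(b) NULL)
  for (s in seq_len(config$n_subjects)) {
    res <- tryCatch({
      cfg <- config$sim
      cfg$rng_seed <- config$master_seed + s
      say("subject %d: simulate (seed %d)", s, cfg$rng_seed)
      sim <- simulate_reading_dataset(cfg)
      say("subject %d: pipeline sobi_fastica", s)
      p1 <- run_pipeline(sim$recording, "sobi_fastica", grid = grid,
                         thresholds = config$thresholds,
                         top_k = config$top_k, seed = cfg$rng_seed)
      say("subject %d: pipeline amica", s)
      p2 <- run_pipeline(sim$recording, "amica", grid = grid,
                         thresholds = config$thresholds,
                         top_k = config$top_k,
                         amica_max_iter = config$amica_max_iter,
                         seed = cfg$rng_seed)
      say("subject %d: dics", s)
      ev <- dics_evaluate(demean_pages(sim$recording), p1$recording,
                          p2$recording, grid, bands = config$bands)
      list(sim_config = cfg, pipeline1 = p1, pipeline2 = p2, dics = ev,
           comparison = compare_pipelines(p1, p2))
    }, error = function(e) {
      warning(sprintf("subject %d failed: %s", s, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    subjects[[length(subjects) + 1L]] <- res
    for (b in names(config$bands))
      diff_maps[[b]] <- cbind(diff_maps[[b]], res$dics[[b]]$maps$difference)
  }
  if (!length(subjects)) stop("all subjects failed")

  comp_tab <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    cmp <- subjects[[i]]$comparison
    data.frame(subject = i, n_saccade_p1 = cmp$n_saccade_p1,
               n_saccade_p2 = cmp$n_saccade_p2,
               n_blink_p1 = cmp$n_blink_p1, n_blink_p2 = cmp$n_blink_p2,
               saccade_topo_cor = cmp$saccade_topo_cor,
               blink_topo_cor = cmp$blink_topo_cor)
  }))
  group <- if (length(subjects) >= 3) {
    parcel_and_test(diff_maps, parc)
  } else NULL

  report <- structure(list(subjects = subjects, component_table = comp_tab,
                           group_tests = group, config = config,
                           parcellation = parc,
                           config_hash = config_hash(config)),
                      class = "experiment_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(comp_tab, file.path(out_dir, "components.csv"),
                     row.names = FALSE)
    if (!is.null(group$parcel_table))
      utils::write.csv(group$parcel_table,
                       file.path(out_dir, "parcel_table.csv"),
                       row.names = FALSE)
    write_report_json(list(config_hash = report$config_hash,
                           master_seed = config$master_seed,
                           n_subjects = length(subjects),
                           component_table = comp_tab),
                      file.path(out_dir, "report.json"))
  }
  report
}

# cross-pipeline comparison of the identified artifact components
compare_pipelines <- function(p1, p2) {
  rep_sac_1 <- p1$reports$sobi
  rep_blk_1 <- p1$reports$fastica
  # amica: use the report of the model that supplied each artifact
  rep2 <- p2$reports
  h_s <- p2$provenance$model_saccade
  h_b <- p2$provenance$model_blink
  topo_cor <- function(repA, decA_topo, repB, decB_topo, lab) {
    ia <- labelled_components(repA, lab, primary_only = TRUE)
    ib <- labelled_components(repB, lab, primary_only = TRUE)
    if (!length(ia) || !length(ib)) return(NA_real_)
    cor(decA_topo[, ia], decB_topo[, ib])
  }
  t_sac_1 <- attr(rep_sac_1, "topographies")
  t_blk_1 <- attr(rep_blk_1, "topographies")
  t_sac_2 <- if (!is.na(h_s)) attr(rep2[[h_s]], "topographies") else NULL
  t_blk_2 <- if (!is.na(h_b)) attr(rep2[[h_b]], "topographies") else NULL
  list(
    n_saccade_p1 = length(labelled_components(rep_sac_1, "saccade")),
    n_blink_p1 = length(labelled_components(rep_blk_1, "blink")),
    n_saccade_p2 = if (!is.na(h_s))
      length(labelled_components(rep2[[h_s]], "saccade")) else 0L,
    n_blink_p2 = if (!is.na(h_b))
      length(labelled_components(rep2[[h_b]], "blink")) else 0L,
    saccade_topo_cor = if (!is.null(t_sac_2))
      topo_cor(rep_sac_1, t_sac_1, rep2[[h_s]], t_sac_2, "saccade")
      else NA_real_,
    blink_topo_cor = if (!is.null(t_blk_2))
      topo_cor(rep_blk_1, t_blk_1, rep2[[h_b]], t_blk_2, "blink")
      else NA_real_)
}

# deterministic hash of a config (serialization-based, no extra deps)
config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  sum(as.integer(raw) * (seq_along(raw) %% 251 + 1)) %% 1e9
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d subjects, config hash %d\n",
              length(x$subjects), x$config_hash))
  print(x$component_table)
  invisible(x)
}
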