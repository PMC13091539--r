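#' Configuration for a full simulate-analyze-report run
#'
#' Assembles and validates every knob of the pipeline in one list: the
#' global seed (fanned out to per-modality seeds as `seed + offset`, with
#' offsets cm = 100, syph = 200, fusion = 300, em = 400, so any modality
#' can be re-run in isolation), the modalities to run, and per-modality
#' sample sizes. The resolved configuration is written beside the outputs
#' of every run, so a run is reproducible from its output directory alone.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory (created if needed).
#' @param modalities Subset of `c("cm", "syph", "fusion", "em")`.
#' @param n_cm_traces,n_syph_experiments,n_fusion_cells,n_spots_per_cell
#'   Cohort sizes per modality.
#' @param syph_window_s SypH decay-window length (s).
#' @return A list of class `endokin_config`.
#' @export
pipeline_config <- function(seed = 1,
                            out_dir = tempfile("endokin_run_"),
                            modalities = c("cm", "syph", "fusion", "em"),
                            n_cm_traces = 11,
                            n_syph_experiments = 20,
                            n_fusion_cells = 4,
                            n_spots_per_cell = 6,
                            syph_window_s = 6) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    modalities = modalities,
    n_cm_traces = as.integer(n_cm_traces),
    n_syph_experiments = as.integer(n_syph_experiments),
    n_fusion_cells = as.integer(n_fusion_cells),
    n_spots_per_cell = as.integer(n_spots_per_cell),
    syph_window_s = syph_window_s,
    package_version = as.character(utils::packageVersion("endokin"))
  )
  class(cfg) <- "endokin_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config An `endokin_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the `endokin_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg[setdiff(names(cfg), "package_version")])
}

# Per-modality seed fan-out (documented in pipeline_config).
module_seed <- function(config, modality) {
  config$seed + c(cm = 100L, syph = 200L, fusion = 300L, em = 400L)[[modality]]
}

#' Run the full simulate-analyze-report pipeline
#'
#' Simulates every selected modality at control-like parameters, runs the
#' corresponding analyzers, and writes tidy CSV results plus the resolved
#' configuration to `config$out_dir`. Identical configuration and seed
#' reproduce byte-identical outputs. Each stage runs inside an error
#' barrier: a failing stage raises an error naming the stage while the
#' outputs of completed stages remain on disk.
#'
#' @param config An [pipeline_config()] object.
#' @return Invisibly, a list with the result tibbles and the written file
#'   paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "endokin_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  results <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "endokin_stage_error", parent = e)
    })
  }
  emit <- function(df, file) {
    p <- file.path(config$out_dir, file)
    readr::write_csv(df, p)
    paths <<- c(paths, p)
    p
  }

  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  paths <- c(paths, cfg_path)

  if ("cm" %in% config$modalities) {
    results$cm <- stage("cm", {
      truth <- cm_truth(jump_fF = 531, decay_model = "mono", tau_s = 10.2,
                        noise_sd_fF = 10)
      recs <- simulate_cm_cohort(config$n_cm_traces, truth,
                                 cm_protocol("depol_20ms"),
                                 seed = module_seed(config, "cm"))
      kin <- dplyr::bind_rows(lapply(recs, analyze_cm))
      emit(kin, "cm_kinetics.csv")
      summary <- describe_values(kin$tau_s) |>
        dplyr::mutate(metric = "tau_s", .before = 1) |>
        dplyr::bind_rows(
          describe_values(kin$delta_cm_peak_fF) |>
            dplyr::mutate(metric = "delta_cm_peak_fF", .before = 1),
          describe_values(kin$rate_decay_n_per_s) |>
            dplyr::mutate(metric = "rate_decay_n_per_s", .before = 1)
        )
      emit(summary, "cm_summary.csv")
      list(kinetics = kin, summary = summary)
    })
  }

  if ("syph" %in% config$modalities) {
    results$syph <- stage("syph", {
      base_seed <- module_seed(config, "syph")
      rows <- lapply(seq_len(config$n_syph_experiments), function(i) {
        b <- simulate_syph_experiment(
          seed = base_seed + i - 1,
          experiment_id = sprintf("syph_%02d", i)
        )
        analyze_syph(b, window_s = config$syph_window_s)
      })
      res <- dplyr::bind_rows(rows)
      emit(res, "syph_experiments.csv")
      res
    })
  }

  if ("fusion" %in% config$modalities) {
    results$fusion <- stage("fusion", {
      base_seed <- module_seed(config, "fusion")
      modes <- c("close_fusion", "stay_fusion", "shrink_fusion")
      spots <- list()
      k <- 0L
      for (ci in seq_len(config$n_fusion_cells)) {
        for (si in seq_len(config$n_spots_per_cell)) {
          k <- k + 1L
          tr <- simulate_spot_trace(
            spot_truth(mode = modes[(k %% 3L) + 1L], noise_sd = 5,
                       seed = base_seed + k),
            spot_id = sprintf("spot_%02d", si),
            cell_id = sprintf("cell_%02d", ci)
          )
          spots[[k]] <- tr
        }
        k <- k + 1L
        spots[[k]] <- simulate_spot_trace(
          spot_truth(mode = "pre_close", noise_sd = 5, seed = base_seed + k),
          spot_id = "pre_01", cell_id = sprintf("cell_%02d", ci)
        )
      }
      tab <- dplyr::bind_rows(spots)
      emit(tab, "fusion_spots.csv")
      cls <- classify_fusion_table(tab)
      emit(cls$events, "fusion_events.csv")
      cells <- summarize_fusion_cells(cls$events, cls$pre_spots)
      emit(cells, "fusion_cells.csv")
      list(events = cls$events, cells = cells)
    })
  }

  if ("em" %in% config$modalities) {
    results$em <- stage("em", {
      groups <- tidyr::expand_grid(
        condition = c("control", "perturbed"),
        timepoint = c("rest", "0min", "3min", "10min")
      ) |>
        dplyr::mutate(
          n_profiles = 40L,
          hrp_pos_rate_per_um2 = dplyr::case_when(
            .data$timepoint == "rest" ~ 0.3,
            .data$condition == "control" ~ 2,
            TRUE ~ 0.8
          ),
          bulk_rate_per_um2 = dplyr::case_when(
            .data$timepoint == "rest" ~ 0.05,
            .data$timepoint == "0min" ~ 0.6,
            TRUE ~ 0.3
          ) * ifelse(.data$condition == "control", 1, 0.4)
        )
      tabs <- simulate_em_tables(groups, seed = module_seed(config, "em"))
      emit(tabs$vesicles, "em_vesicles.csv")
      emit(tabs$profiles, "em_profiles.csv")
      dens <- em_profile_densities(tabs$vesicles, tabs$profiles)
      emit(dens, "em_profile_densities.csv")
      agg <- em_group_densities(dens)
      emit(agg, "em_group_densities.csv")
      list(densities = dens, groups = agg)
    })
  }

  invisible(list(results = results, paths = paths, config = config))
}
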