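.pipeline_stages <- c("model_predict", "simulate", "quantify_ds",
                      "mt_analysis", "fisher")

#' Default pipeline configuration
#'
#' All defaults mirror the imaging and analysis protocol: 10 lines of 4 um,
#' 4-degree rose bins, 90-degree quadrants, 22.5-degree sectors, 10000
#' bootstrap resamples, alpha 0.05, 5.16 s frame interval. Simulation sizes
#' are kept at desk scale (number of images and comets per cell) and are
#' ordinary config entries.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    scenario = "wild_type",
    stages = .pipeline_stages,
    simulate = list(
      seed = 1,
      n_images = 4,
      n_cells = 4,
      comets_per_cell = 80,
      mixture = list(means_deg = c(100, 280), kappas = c(2, 2),
                     weights = c(0.5, 0.5), uniform_weight = 0),
      frame_interval = 5.16,
      predenticles = list(n_cells = 40,
                          p_anterior = c("T1" = 0.9, "row 2" = 0.1),
                          p_unclear = 0.1)
    ),
    quantify_ds = list(seed = 2, n_lines = 10, width_um = 4,
                       min_prominence = 0.1, alpha = 0.05),
    mt_analysis = list(seed = 3, B = 10000, bin_width = 4,
                       sector_width = 22.5, alpha = 0.05, n_restarts = 20),
    fisher = list(policy = "split_equally")
  )
}

.validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (st in intersect(names(config), c("simulate", "quantify_ds",
                                        "mt_analysis", "fisher"))) {
    bad <- setdiff(names(config[[st]]), names(base[[st]]))
    if (length(bad) > 0) {
      stop("unknown key(s) in stage ", st, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    # a stage configured by the user must pin its own seed: stochastic
    # stages never inherit one silently
    if (st != "fisher" && is.null(config[[st]]$seed)) {
      stop("stage ", st, " is stochastic: its configuration must include a seed",
           call. = FALSE)
    }
  }
  merged <- utils::modifyList(base, config)
  bad_stage <- setdiff(merged$stages, .pipeline_stages)
  if (length(bad_stage) > 0) {
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "), call. = FALSE)
  }
  merged
}

#' Run the analysis pipeline end to end
#'
#' Executes the selected stages in dependency order — model prediction,
#' synthetic data generation, Ds quantification, microtubule statistics,
#' exact tests — writing each stage's results as CSV under `out_dir`
#' together with a JSON run report (package version, configuration, seeds,
#' summary statistics). Runs are idempotent for fixed seeds: identical
#' configurations produce byte-identical result files.
#'
#' @param config Configuration list, or path to a YAML/JSON file; see
#'   [default_config()] for the schema. Unknown keys are rejected.
#' @param out_dir Output directory (created if needed).
#' @return The run report, invisibly.
#' @export
#' @examples
#' \donttest{
#' out <- tempfile("pcp_run_")
#' rep <- run_pipeline(list(stages = c("model_predict", "fisher")), out, quiet = TRUE)
#' rep$results$fisher$table1$p_value
#' }
#' @param quiet Suppress per-stage progress messages (written to stderr).
run_pipeline <- function(config = list(), out_dir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  cfg <- .validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  t_all <- Sys.time()
  report <- list(
    package = "larvalpcp",
    version = as.character(utils::packageVersion("larvalpcp")),
    config = cfg,
    results = list()
  )
  wcsv <- function(d, name) {
    utils::write.csv(d, file.path(out_dir, name), row.names = FALSE)
  }
  state <- list()

  if ("model_predict" %in% cfg$stages) {
    say("model_predict: ", cfg$scenario)
    land <- build_landscape(cfg$scenario)
    calls <- predict_polarity(land)
    wcsv(as.data.frame(land), "landscape.csv")
    wcsv(calls, "polarity_calls.csv")
    state$landscape <- land
    report$results$model_predict <- list(
      n_rows = nrow(land),
      directions = as.list(table(calls$direction))
    )
  }

  if ("simulate" %in% cfg$stages) {
    sim <- cfg$simulate
    say("simulate: ", sim$n_images, " images, ", sim$n_cells, " cells")
    specs <- image_spec()
    state$images <- lapply(seq_len(sim$n_images), function(i) {
      gen_segment_image(specs, seed = (as.numeric(sim$seed) * 100 + i) %% 2147483647)
    })
    mx <- do.call(circular_mixture, as.list(sim$mixture))
    state$tracks <- gen_comet_dataset(
      mx, n_cells = sim$n_cells, comets_per_cell = sim$comets_per_cell,
      frame_interval = sim$frame_interval, seed = sim$seed)
    wcsv(state$tracks, "tracks.csv")
    pd <- sim$predenticles
    state$predenticles <- gen_predenticles(
      pd$n_cells, p_anterior = unlist(pd$p_anterior),
      p_unclear = pd$p_unclear, seed = sim$seed)
    wcsv(state$predenticles, "predenticles.csv")
    report$results$simulate <- list(
      n_images = sim$n_images,
      n_tracks = length(unique(state$tracks$track_id)),
      n_predenticles = nrow(state$predenticles)
    )
  }

  if ("quantify_ds" %in% cfg$stages) {
    if (is.null(state$images)) {
      stop("stage quantify_ds needs images from stage simulate", call. = FALSE)
    }
    q <- cfg$quantify_ds
    say("quantify_ds: ", length(state$images), " images x ", q$n_lines, " lines")
    summaries <- do.call(rbind, lapply(seq_along(state$images), function(i) {
      quantify_image(state$images[[i]], image_id = sprintf("image_%02d", i),
                     n_lines = q$n_lines, width_um = q$width_um,
                     min_prominence = q$min_prominence,
                     seed = (as.numeric(q$seed) * 100 + i) %% 2147483647)
    }))
    wcsv(summaries, "interface_summaries.csv")
    tk <- tukey_compare(summaries, alpha = q$alpha)
    wcsv(tk$tukey, "tukey_pairs.csv")
    wcsv(tk$letters, "tukey_letters.csv")
    ra <- row_asymmetry(summaries, alpha = q$alpha)
    wcsv(ra, "row_asymmetry.csv")
    report$results$quantify_ds <- list(
      n_interfaces = nrow(tk$letters),
      significant_rows = ra$row_id[ra$significant]
    )
  }

  if ("mt_analysis" %in% cfg$stages) {
    if (is.null(state$tracks)) {
      stop("stage mt_analysis needs tracks from stage simulate", call. = FALSE)
    }
    mt <- cfg$mt_analysis
    say("mt_analysis: B = ", mt$B)
    ang <- track_to_angle(state$tracks)
    wcsv(ang, "angles.csv")
    wcsv(rose_bins(ang$angle_deg, mt$bin_width), "rose_bins.csv")
    qc <- quadrant_counts(ang$angle_deg)
    ci <- sison_glaz_ci(qc, alpha = mt$alpha)
    wcsv(ci, "quadrant_ci.csv")
    fr <- cell_quadrant_fractions(ang)
    wcsv(fr, "cell_fractions.csv")
    bm <- lapply(c("anterior_posterior", "medial_lateral"), function(p) {
      b <- bootstrap_md(fr, pair = p, B = mt$B, seed = mt$seed)
      data.frame(pair = p, md = b$md, ci_lower = b$ci[1], ci_upper = b$ci[2],
                 p_literal = b$p_literal, p_sign = b$p_sign)
    })
    bm <- do.call(rbind, bm)
    wcsv(bm, "bootstrap_md.csv")
    wcsv(sector_scan(ang$angle_deg, mt$sector_width), "sector_scan.csv")
    fits <- fit_circular_models(ang$angle_deg, n_restarts = mt$n_restarts,
                                seed = mt$seed)
    wcsv(as.data.frame(fits), "model_fits.csv")
    report$results$mt_analysis <- list(
      n_angles = nrow(ang),
      quadrant_ci = ci,
      best_model = fits$model[1],
      bootstrap = bm
    )
  }

  if ("fisher" %in% cfg$stages) {
    say("fisher: published tables + simulated observations")
    t1 <- table1_report()
    wcsv(t1, "table1_report.csv")
    report$results$fisher <- list(table1 = t1)
    if (!is.null(state$predenticles)) {
      pol <- allocation_policy(cfg$fisher$policy)
      classes <- names(cfg$simulate$predenticles$p_anterior)
      tb <- build_table(state$predenticles, classes, pol)
      ft <- fisher_exact_2x2(tb)
      sim_fisher <- data.frame(
        class_1 = classes[1], class_2 = classes[2],
        a11 = tb[1, 1], a12 = tb[1, 2], a21 = tb[2, 1], a22 = tb[2, 2],
        p_value = ft$p_value, odds_ratio = ft$odds_ratio
      )
      wcsv(sim_fisher, "simulated_fisher.csv")
      report$results$fisher$simulated <- sim_fisher
    }
  }

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  say(sprintf("done in %.1f s -> %s", report$elapsed_s, out_dir))
  invisible(report)
}
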