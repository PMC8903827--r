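#' Pipeline configuration
#'
#' Assembles the explicit, fully seeded configuration of an end-to-end run:
#' stimulus rendering, trial scheduling, response simulation and mixed-model
#' analysis. All randomness derives from the named seeds; nothing is seeded
#' from the wall clock.
#'
#' @param design One of `"study1-exp1"`, `"study1-exp2"`, `"study2"`.
#' @param preset Observer preset name (see [observer_presets()]).
#' @param n_participants Simulated participants (Study 1 designs) or sessions
#'   (Study 2).
#' @param seeds Named list/vector with integer seeds `schedule`, `simulation`,
#'   `bootstrap`.
#' @param out_dir Output directory for artifacts.
#' @param alpha Significance level for term tests.
#' @param bonferroni_k Divisor applied to alpha (e.g. 3 when analysing three
#'   individuals separately).
#' @param first_species First-block species.
#' @param level,polarity Study 2 session parameters (ignored otherwise).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(design = c("study1-exp1", "study1-exp2", "study2"),
                            preset = "full", n_participants = 25L,
                            seeds = list(schedule = 1L, simulation = 2L,
                                         bootstrap = 3L),
                            out_dir = tempfile("gazevis-run-"),
                            alpha = 0.05, bonferroni_k = 1L,
                            first_species = "chimpanzee",
                            level = 3, polarity = "normal") {
  design <- match.arg(design)
  need <- c("schedule", "simulation", "bootstrap")
  if (!all(need %in% names(seeds)))
    stop("seeds must name: ", paste(need, collapse = ", "))
  structure(list(design = design, preset = preset,
                 n_participants = as.integer(n_participants),
                 seeds = lapply(seeds[need], as.integer),
                 out_dir = out_dir, alpha = alpha,
                 bonferroni_k = as.integer(bonferroni_k),
                 first_species = first_species,
                 level = level, polarity = polarity),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the fields of `pipeline_config()`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

log_stage <- function(log_con, stage, ...) {
  msg <- sprintf("[gazevis] %-10s %s", stage, sprintf(...))
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
}

#' Run the full stimuli -> schedule -> simulate -> analyze pipeline
#'
#' Executes every stage for the configured design, writes all intermediate
#' artifacts (stimulus PNGs and colorimetry CSV, trial-plan CSV, response
#' CSV, analysis JSON) under `config$out_dir`, and returns a manifest with
#' the configuration, seeds and an MD5 hash of every artifact. Identical
#' configurations produce identical artifact hashes.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list), also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(log_con))

  # -- stimuli ---------------------------------------------------------------
  log_stage(log_con, "stimuli", "rendering species presets + polarity pair")
  stim_rows <- list()
  for (sp in c("chimpanzee", "human")) {
    stim <- render_eye_stimulus(geometry_preset(sp), appearance_preset(sp))
    rev <- reverse_polarity(stim$image, stim$masks$eyeball_mask)
    write_image_png(stim$image,
                    file.path(config$out_dir, paste0(sp, "_normal.png")))
    write_image_png(rev,
                    file.path(config$out_dir, paste0(sp, "_reversed.png")))
    for (pol in c("normal", "reversed")) {
      img <- if (pol == "normal") stim$image else rev
      row <- colorimetry_as_row(measure_colorimetry(img, stim$masks))
      row <- cbind(data.frame(species = sp, polarity = pol), row)
      stim_rows[[length(stim_rows) + 1L]] <- row
    }
  }
  colorimetry <- do.call(rbind, stim_rows)
  utils::write.csv(colorimetry, file.path(config$out_dir, "colorimetry.csv"),
                   row.names = FALSE)

  # -- schedule --------------------------------------------------------------
  log_stage(log_con, "schedule", "design %s, seed %d", config$design,
            config$seeds$schedule)
  plan <- switch(config$design,
    "study1-exp1" = build_study1_exp1(config$seeds$schedule,
                                      config$first_species),
    "study1-exp2" = build_study1_exp2(config$seeds$schedule,
                                      config$first_species),
    "study2" = build_study2_session(config$seeds$schedule, config$level,
                                    config$polarity, config$first_species))
  validate_plan(plan)
  utils::write.csv(plan, file.path(config$out_dir, "plan.csv"),
                   row.names = FALSE)

  # -- simulate --------------------------------------------------------------
  log_stage(log_con, "simulate", "%d participants, preset '%s', seed %d",
            config$n_participants, config$preset, config$seeds$simulation)
  params <- observer_presets(config$preset)
  responses <- simulate_responses(plan, params, config$n_participants,
                                  config$seeds$simulation)
  utils::write.csv(responses, file.path(config$out_dir, "responses.csv"),
                   row.names = FALSE)

  # -- analyze ---------------------------------------------------------------
  alpha <- config$alpha / config$bonferroni_k
  log_stage(log_con, "analyze", "GLMM term tests at alpha = %.4f", alpha)
  spec <- switch(config$design,
    "study1-exp1" = spec_study1_exp1(),
    "study1-exp2" = spec_study1_exp2(),
    "study2" = model_spec("species", random = "stimulus_id"))
  pruned <- prune_and_test(responses, spec, alpha = alpha)
  unit <- if (config$design == "study2") "session_id" else "participant_id"
  if (config$design == "study2") responses$session_id <- responses$participant_id
  ci <- bootstrap_ci(responses, unit, seed = config$seeds$bootstrap)
  analysis <- list(
    design = config$design, alpha = alpha,
    tests = lapply(pruned$tests, function(t)
      list(term = t$term, chisq = t$chisq, df = t$df, p = t$p,
           action = t$action)),
    final_terms = pruned$final_terms,
    simple_effects_needed = pruned$simple_effects_needed,
    dispersion = pruned$final_fit$dispersion,
    overall_ci = list(estimate = ci$estimate, lower = ci$lower,
                      upper = ci$upper))
  jsonlite::write_json(analysis, file.path(config$out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- manifest --------------------------------------------------------------
  arts <- sort(setdiff(list.files(config$out_dir), c("manifest.json", "run.log")))
  manifest <- list(
    config = unclass(config),
    n_trials = nrow(plan), n_responses = nrow(responses),
    artifacts = as.list(tools::md5sum(file.path(config$out_dir, arts))))
  names(manifest$artifacts) <- arts
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage(log_con, "done", "%d artifacts in %s", length(arts),
            config$out_dir)
  invisible(manifest)
}

#' Generate the canned fixture set used by the test suite
#'
#' Writes a small, fully regenerable fixture bundle: one stimulus per species
#' x polarity at levels 1 and 4, a Study-1 plan, and a matching response
#' table (one row per plan trial), plus a manifest recording the seed and
#' file hashes.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return The fixture manifest (list), invisibly.
#' @export
make_fixtures <- function(seed, dir = tempfile("gazevis-fixtures-")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (sp in c("chimpanzee", "human")) {
    stim <- render_eye_stimulus(geometry_preset(sp), appearance_preset(sp))
    for (pol in c("normal", "reversed")) {
      img <- if (pol == "normal") stim$image
             else reverse_polarity(stim$image, stim$masks$eyeball_mask)
      for (lv in c(1, 4)) {
        f <- sprintf("%s_%s_L%d.png", sp, pol, lv)
        write_image_png(apply_level(img, lv), file.path(dir, f))
        entries[[length(entries) + 1L]] <-
          list(file = f, species = sp, polarity = pol, level = lv)
      }
    }
  }
  plan <- build_study1_exp1(seed)
  utils::write.csv(plan, file.path(dir, "plan.csv"), row.names = FALSE)
  resp <- simulate_responses(plan, observer_presets("full"), 1L,
                             seed = seed + 1L)
  utils::write.csv(resp, file.path(dir, "responses.csv"), row.names = FALSE)
  files <- sort(setdiff(list.files(dir), "manifest.json"))
  manifest <- list(seed = seed, stimuli = entries,
                   hashes = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Plot accuracy by condition with bootstrap confidence intervals
#'
#' Mean proportion correct per species x level (x polarity when present),
#' with percentile bootstrap CIs over the resampling unit. Requires ggplot2.
#'
#' @param responses Trial-level response data frame.
#' @param unit Resampling-unit column for the CIs.
#' @param n_resamples Bootstrap resamples per cell.
#' @param seed Integer seed.
#' @return A ggplot object.
#' @export
plot_accuracy <- function(responses, unit = "participant_id",
                          n_resamples = 500L, seed = 1L) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_accuracy requires the ggplot2 package")
  d <- as.data.frame(responses)
  has_pol <- "polarity" %in% names(d) && length(unique(d$polarity)) > 1L
  cells <- if (has_pol) c("species", "level", "polarity")
           else c("species", "level")
  groups <- unique(d[cells])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- rep(TRUE, nrow(d))
    for (f in cells) sel <- sel & d[[f]] == groups[i, f]
    ci <- bootstrap_ci(d[sel, ], unit, n_resamples = n_resamples,
                       seed = seed + i)
    cbind(groups[i, , drop = FALSE],
          data.frame(accuracy = ci$estimate, lower = ci$lower,
                     upper = ci$upper))
  })
  s <- do.call(rbind, rows)
  s$level <- factor(s$level)
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$level, y = .data$accuracy,
                                       fill = .data$species)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.25) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "stimulus level", y = "proportion correct")
  if (has_pol) p <- p + ggplot2::facet_wrap(~polarity)
  p
}
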