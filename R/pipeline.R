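#' Configuration for the end-to-end study emulation
#'
#' Bundles the stage configurations of the full pipeline: staircase
#' titration, schedule generation, behavioral simulation, group BOLD
#' generation, model inversion over the whole motif space, and
#' random-effects BMS.
#'
#' @param out_dir output directory for the report bundle.
#' @param master_seed master seed; every stage derives its own seed from
#'   it.
#' @param titration_trials number of titration trials.
#' @param observer_sd perceptual SD of the simulated titration observer
#'   (Hz).
#' @param observer an [observer_params()] for the behavioral stage.
#' @param group a [group_config()] for the BOLD stage.
#' @param fit a [fit_control()] for the inversions.
#' @param models model names to invert (default: the full space).
#' @param stages character vector of stages to run, in order; any of
#'   `"titration"`, `"behavior"`, `"bold"`, `"inversion"`, `"bms"`.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, master_seed = 1L,
                            titration_trials = 400L, observer_sd = 1.5,
                            observer = observer_params(),
                            group = group_config(n_subjects = 2L,
                                                 session_length = 240),
                            fit = fit_control(),
                            models = NULL,
                            stages = c("titration", "behavior", "bold",
                                       "inversion", "bms")) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  structure(list(out_dir = out_dir, master_seed = master_seed,
                 titration_trials = titration_trials,
                 observer_sd = observer_sd, observer = observer,
                 group = group, fit = fit, models = models,
                 stages = stages),
            class = "pipeline_config")
}

provenance_block <- function(config_path, master_seed) {
  list(package = "precistim",
       version = as.character(packageVersion("precistim")),
       master_seed = master_seed,
       config_md5 = unname(tools::md5sum(config_path)),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

pipeline_log <- function(stage, msg, t0) {
  message(sprintf("[precistim:%s] %s (%.1f s elapsed)", stage, msg,
                  as.numeric(Sys.time()) - t0))
}

#' Run the end-to-end study emulation
#'
#' Stages, in order: titrate the easy/hard staircases against a simulated
#' observer and derive the medium difficulty; generate trial schedules and
#' simulate behavior (accuracy cells, d'); generate a synthetic BOLD group
#' from the configured motif; invert every motif per subject; run
#' random-effects BMS. Each stage writes its outputs (CSV/TSV/JSON) under
#' `out_dir` together with a provenance block (package version, config
#' hash, master seed), and the returned report aggregates them. A stage
#' failure aborts with a stage-named diagnostic; outputs of completed
#' stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @param model_space result of [build_model_space()] (rebuilt if `NULL`).
#' @return a `pipeline_report` list with per-stage results.
#' @export
run_pipeline <- function(config, model_space = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  config_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config[setdiff(names(config), "observer")],
                       config_path, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  prov <- provenance_block(config_path, config$master_seed)
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  model_space <- model_space %||% build_model_space()
  report <- list(provenance = prov)
  run_stage <- function(stage, fun) {
    if (!stage %in% config$stages) return(invisible(NULL))
    pipeline_log(stage, "start", t0)
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
    pipeline_log(stage, "done", t0)
    out
  }

  report$titration <- run_stage("titration", function() {
    tit <- run_titration(make_gaussian_observer(config$observer_sd),
                         n_trials = config$titration_trials,
                         seed = derive_seed(config$master_seed, 1L))
    write_titration_csv(tit, file.path(config$out_dir, "titration.csv"))
    tit
  })
  if (!is.null(report$titration)) {
    config$group$schedule$delta <- report$titration$medium_delta
  }

  report$behavior <- run_stage("behavior", function() {
    n_trials <- 400L
    sched_sd <- generate_schedule(n_trials, config$group$schedule,
                                  seed = derive_seed(config$master_seed,
                                                     2L))
    cfg_fs <- config$group$schedule
    cfg_fs$context <- "fast-slow"
    sched_fs <- generate_schedule(n_trials, cfg_fs,
                                  seed = derive_seed(config$master_seed,
                                                     3L))
    trials <- rbind(
      simulate_session(sched_sd, config$observer,
                       seed = derive_seed(config$master_seed, 4L)),
      simulate_session(sched_fs, config$observer,
                       seed = derive_seed(config$master_seed, 5L)))
    acc <- cell_accuracies(trials)
    write_events_tsv(sched_sd, file.path(config$out_dir, "events_sd.tsv"))
    write_events_tsv(sched_fs, file.path(config$out_dir, "events_fs.tsv"))
    write.csv(trials, file.path(config$out_dir, "trials.csv"),
              row.names = FALSE)
    write_accuracy_csv(acc, file.path(config$out_dir, "accuracy.csv"))
    list(trials = trials, accuracy = acc)
  })

  report$group <- run_stage("bold", function() {
    grp <- generate_group(config$group, model_space,
                          observer = config$observer)
    write_group_dataset(grp, file.path(config$out_dir, "group"))
    grp
  })

  report$F_matrix <- run_stage("inversion", function() {
    grp <- report$group
    if (is.null(grp)) stop("inversion requires the bold stage")
    models <- config$models %||% names(model_space)
    Fmat <- matrix(NA_real_, length(grp$subjects), length(models),
                   dimnames = list(NULL, models))
    for (s in seq_along(grp$subjects)) {
      for (mn in models) {
        fit <- fit_model(model_space[[mn]], grp$subjects[[s]]$bold,
                         grp$subjects[[s]]$inputs, control = config$fit)
        Fmat[s, mn] <- fit$F
      }
    }
    write.csv(data.frame(subject = seq_len(nrow(Fmat)), Fmat),
              file.path(config$out_dir, "F_matrix.csv"),
              row.names = FALSE)
    Fmat
  })

  report$bms <- run_stage("bms", function() {
    if (is.null(report$F_matrix)) stop("bms requires the inversion stage")
    bms <- rfx_bms(report$F_matrix,
                   seed = derive_seed(config$master_seed, 6L))
    write_bms_csv(bms, file.path(config$out_dir, "bms.csv"))
    jsonlite::write_json(
      list(winner = names(which.max(bms$exceedance)),
           exceedance = as.list(bms$exceedance),
           generating = config$group$model),
      file.path(config$out_dir, "bms.json"), auto_unbox = TRUE,
      digits = NA)
    bms
  })
  if (!is.null(report$bms))
    report$winner <- names(which.max(report$bms$exceedance))
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$titration))
    cat(sprintf("  titration: medium delta %.3f Hz\n",
                x$titration$medium_delta))
  if (!is.null(x$behavior))
    cat(sprintf("  behavior: interaction %.3f, d' fast-slow %.2f vs same-different %.2f\n",
                x$behavior$accuracy$interaction,
                x$behavior$accuracy$dprime_fast_slow,
                x$behavior$accuracy$dprime_same_different))
  if (!is.null(x$winner))
    cat(sprintf("  BMS winner: %s (generated from %s)\n", x$winner,
                attr(x, "generating") %||% ""))
  invisible(x)
}
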