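# Output CSVs carry a comment header recording provenance; readr skips
# lines starting with '#" on the way back in.
.write_output_csv <- function(df, path, seed = NA) {
  header <- sprintf("# audiencesync %s | seed: %s | written: %s",
                    as.character(utils::packageVersion("audiencesync")),
                    as.character(seed), format(Sys.time(), "%Y-%m-%d"))
  cat(header, "\n", readr::format_csv(df, na = ""), sep = "", file = path)
  invisible(path)
}

#' Write a simulated audience to the three recording CSV formats
#'
#' Runs [simulate_recording()] and writes `expressions.csv`,
#' `participants.csv`, `script.csv` and a `ground_truth.csv` (per-frame
#' engagement, gain and shared signals plus per-participant coupling
#' weights in long form) to a directory.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list returned by [simulate_recording()].
#' @export
simulate_to_csv <- function(config, out_dir) {
  sim <- simulate_recording(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_table(sim$recording$tracks,
                         file.path(out_dir, "expressions.csv"))
  write_participant_table(sim$recording$info,
                          file.path(out_dir, "participants.csv"))
  write_engagement_script(config$script, file.path(out_dir, "script.csv"))
  gt <- dplyr::bind_rows(
    tibble::tibble(quantity = "engagement",
                   index = seq_along(sim$truth$engagement) - 1L,
                   value = sim$truth$engagement),
    tibble::tibble(quantity = "gain",
                   index = seq_along(sim$truth$gain) - 1L,
                   value = sim$truth$gain),
    tibble::tibble(quantity = "coupling_weight",
                   index = seq_along(sim$truth$coupling_weight) - 1L,
                   value = sim$truth$coupling_weight))
  readr::write_csv(gt, file.path(out_dir, "ground_truth.csv"),
                   progress = FALSE)
  invisible(sim)
}

#' Run the full synchrony analysis pipeline
#'
#' Orchestrates inclusion filtering, descriptives, sliding-window and
#' pair-level ISC, engagement correlation/regression (when a script is
#' supplied), proximity permutation inference and the pair-characteristic
#' analyses, and optionally writes every stage's CSV to `out_dir`.
#'
#' @param recording An [audience_recording()].
#' @param script Optional [engagement_script()] for the engagement stage.
#' @param spec A [window_spec()].
#' @param min_valid,require_questionnaires Inclusion thresholds passed to
#'   [apply_inclusion()].
#' @param pair_mode Pair-level ISC mode passed to [pairwise_isc()].
#' @param n_perm,perm_seed,alternative,p_rule Permutation settings passed
#'   to [permutation_test_proximity()].
#' @param bayes A [bayes_spec()].
#' @param out_dir Optional output directory for the stage CSVs.
#' @return Object of class `audience_analysis`: list with elements
#'   `inclusion_log`, `n_before`, `n_after`, `summaries`,
#'   `within_between`, `within_between_bf`, `isc`, `pair_isc`,
#'   `engagement` (`NULL` without a script), `proximity`, `features`,
#'   `gender` and `settings`.
#' @export
run_analysis <- function(recording, script = NULL, spec = window_spec(),
                         min_valid = 0.9, require_questionnaires = TRUE,
                         pair_mode = c("whole_series", "window_mean"),
                         n_perm = 10000L, perm_seed = 1L,
                         alternative = "negative", p_rule = "plain",
                         bayes = bayes_spec(), out_dir = NULL) {
  pair_mode <- match.arg(pair_mode)
  stopifnot(inherits(recording, "audience_recording"))
  n_before <- n_participants(recording)
  included <- apply_inclusion(recording, min_valid = min_valid,
                              require_questionnaires = require_questionnaires)
  n_after <- n_participants(included)
  if (n_after < 2L) {
    stop(sprintf(
      "performance '%s' excluded: %d of %d participants eligible (need more than one)",
      recording$performance_id, n_after, n_before), call. = FALSE)
  }

  summaries <- dplyr::bind_rows(purrr::imap(included$tracks, function(tr, id) {
    dplyr::mutate(expression_summary(tr), participant_id = id,
                  .before = 1)
  }))
  ivr <- purrr::map(participant_ids(included),
                    function(id) individual_vs_rest_matrix(included, id))
  wb <- within_between_contrast(ivr)
  wb_bf <- bf_paired_ttest(wb$individual$contrast, bayes)

  isc <- sliding_window_isc(included, spec)
  pair_isc <- pairwise_isc(included, mode = pair_mode, spec = spec)

  engagement <- NULL
  if (!is.null(script)) {
    nf <- n_frames(included$tracks[[1]])
    course <- resample_engagement(script, spec,
                                  included$tracks[[1]]$frame_rate, nf)
    engagement <- list(
      course = course,
      correlation = isc_engagement_correlation(isc, course, bayes),
      regression = engagement_regression(isc, course))
  }

  proximity <- dplyr::bind_rows(purrr::map(.channels(), function(ch) {
    res <- tryCatch(
      tidy(permutation_test_proximity(pair_isc, ch, n_perm = n_perm,
                                      seed = perm_seed,
                                      alternative = alternative,
                                      p_rule = p_rule)),
      error = function(e) tibble::tibble(
        r_obs = NA_real_, p = NA_real_, n_perm = as.integer(n_perm),
        n_pairs = NA_integer_, alternative = alternative, p_rule = p_rule,
        seed = as.integer(perm_seed)))
    dplyr::mutate(res, expression = ch, .before = 1)
  }))

  features <- dplyr::bind_rows(purrr::map(.channels(), function(ch) {
    purrr::map(c("total_age", "total_empathy"), function(f) {
      tryCatch(
        suppressWarnings(
          feature_association(pair_isc, f, ch, bayes)$correlation),
        error = function(e) NULL)
    }) |> dplyr::bind_rows()
  }))

  gender <- purrr::map(.channels(), function(ch) {
    tryCatch(group_contrast(pair_isc, ch), error = function(e) NULL)
  })
  names(gender) <- .channels()

  out <- structure(list(
    performance_id = recording$performance_id,
    inclusion_log = attr(included, "exclusion_log"),
    n_before = n_before, n_after = n_after,
    summaries = summaries, within_between = wb, within_between_bf = wb_bf,
    isc = isc, pair_isc = pair_isc, engagement = engagement,
    proximity = proximity, features = features, gender = gender,
    settings = list(spec = spec, min_valid = min_valid,
                    pair_mode = pair_mode, n_perm = n_perm,
                    perm_seed = perm_seed, alternative = alternative,
                    p_rule = p_rule, bayes = bayes)),
    class = "audience_analysis")
  if (!is.null(out_dir)) write_analysis_csvs(out, out_dir)
  out
}

#' @export
print.audience_analysis <- function(x, ...) {
  cat(sprintf(
    "<audience_analysis> '%s': %d/%d participants included, %d windows per channel\n",
    x$performance_id, x$n_after, x$n_before,
    sum(x$isc$expression == "happy")))
  invisible(x)
}

#' Write every stage of an analysis to CSV
#'
#' @param analysis An [run_analysis()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_analysis_csvs <- function(analysis, out_dir) {
  stopifnot(inherits(analysis, "audience_analysis"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- analysis$settings$perm_seed
  paths <- c(
    summaries = file.path(out_dir, "expression_summaries.csv"),
    isc = file.path(out_dir, "isc_timecourse.csv"),
    pairs = file.path(out_dir, "pair_isc.csv"),
    prox = file.path(out_dir, "proximity_permutation.csv"),
    feats = file.path(out_dir, "pair_analysis.csv"))
  .write_output_csv(analysis$summaries, paths["summaries"], seed)
  .write_output_csv(tibble::as_tibble(analysis$isc), paths["isc"], seed)
  .write_output_csv(tibble::as_tibble(analysis$pair_isc), paths["pairs"],
                    seed)
  .write_output_csv(analysis$proximity, paths["prox"], seed)
  .write_output_csv(analysis$features, paths["feats"], seed)
  if (!is.null(analysis$engagement)) {
    p <- file.path(out_dir, "engagement_fit.csv")
    .write_output_csv(analysis$engagement$correlation, p, seed)
    .write_output_csv(tidy(analysis$engagement$regression),
                      file.path(out_dir, "engagement_models.csv"), seed)
    paths <- c(paths, engagement = p)
  }
  cells <- purrr::imap(analysis$gender, function(g, ch) {
    if (is.null(g)) return(NULL)
    dplyr::mutate(g$cell_means, expression = ch, .before = 1)
  })
  cells <- dplyr::bind_rows(cells)
  if (nrow(cells)) {
    .write_output_csv(cells, file.path(out_dir, "group_means.csv"), seed)
  }
  invisible(paths)
}

#' Render a human-readable analysis report
#'
#' Summarizes an analysis directory (as written by
#' [write_analysis_csvs()]) into one markdown report: expression
#' descriptives, ISC levels, engagement fit, proximity permutation
#' results and pair-characteristic associations, each tagged with the
#' method that produced it.
#'
#' @param out_dir Directory holding the analysis CSVs.
#' @param file Report path (default `report.md` inside `out_dir`).
#' @return The report path, invisibly.
#' @export
write_report <- function(out_dir, file = file.path(out_dir, "report.md")) {
  need <- c("expression_summaries.csv", "isc_timecourse.csv",
            "pair_isc.csv", "proximity_permutation.csv",
            "pair_analysis.csv")
  for (f in need) {
    if (!file.exists(file.path(out_dir, f))) {
      stop("missing analysis output: ", f, call. = FALSE)
    }
  }
  rd <- function(f) readr::read_csv(file.path(out_dir, f), comment = "#",
                                    show_col_types = FALSE, progress = FALSE)
  summaries <- rd("expression_summaries.csv")
  isc <- rd("isc_timecourse.csv")
  prox <- rd("proximity_permutation.csv")
  feats <- rd("pair_analysis.csv")
  lines <- c(
    "# Audience synchrony report", "",
    sprintf("Participants summarized: %d; expression channels: %s.",
            length(unique(summaries$participant_id)),
            paste(.channels(), collapse = ", ")), "",
    "## Expression descriptives (mean over valid frames)", "")
  desc <- dplyr::summarise(
    dplyr::group_by(summaries, .data$expression),
    mean = mean(.data$mean), sd = mean(.data$sd))
  lines <- c(lines, "| expression | mean | sd |", "|---|---|---|",
             sprintf("| %s | %.3f | %.3f |", desc$expression, desc$mean,
                     desc$sd), "",
             "## Sliding-window ISC (mean pairwise r per channel)", "")
  isc_mean <- dplyr::summarise(
    dplyr::group_by(isc, .data$expression),
    mean_r = mean(.data$mean_r, na.rm = TRUE),
    max_r = max(.data$mean_r, na.rm = TRUE))
  lines <- c(lines, "| expression | mean r | max r |", "|---|---|---|",
             sprintf("| %s | %.3f | %.3f |", isc_mean$expression,
                     isc_mean$mean_r, isc_mean$max_r), "")
  eng_path <- file.path(out_dir, "engagement_fit.csv")
  if (file.exists(eng_path)) {
    eng <- rd("engagement_fit.csv")
    mods <- rd("engagement_models.csv")
    lines <- c(lines, "## Engagement (JZS correlation BF; BIC model proxy)",
               "", "| expression | r | BF10 |", "|---|---|---|",
               sprintf("| %s | %.3f | %.3g |", eng$expression, eng$r,
                       eng$bf10), "",
               sprintf("Best regression model: `%s` (R^2 = %.3f).",
                       mods$model[1], mods$r_squared[1]), "")
  }
  lines <- c(lines, "## Proximity permutation test (one-sided)", "",
             "| expression | r_obs | p | n_perm |", "|---|---|---|---|",
             sprintf("| %s | %.3f | %.4g | %d |", prox$expression,
                     prox$r_obs, prox$p, prox$n_perm), "",
             "## Pair characteristics (JZS correlation BF)", "",
             "| expression | feature | r | BF10 |", "|---|---|---|---|",
             sprintf("| %s | %s | %.3f | %.3g |", feats$expression,
                     feats$feature, feats$r, feats$bf10), "")
  writeLines(lines, file)
  invisible(file)
}

# ---- configuration + command-line front end ------------------------------

#' Read a run configuration from a YAML file
#'
#' Recognized keys (all optional): `expressions`, `participants`,
#' `script` (input CSV paths), `out_dir`, `frame_rate`, `window_len`,
#' `step`, `min_valid_fraction`, `min_valid`, `pair_mode`, `n_perm`,
#' `seed`, `alternative`, `p_rule`, `bayes_scale`, `two_sided`, and for
#' simulation `n_participants`, `n_frames`, `grid_rows`, `grid_seats`,
#' `coupling`, `engagement_exponent`, `spatial_length`, `beta_age`,
#' `beta_empathy`, `beta_gender`, `noise_sd`, `dropout`.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  yaml::read_yaml(path)
}

.cfg <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

.config_to_simulation <- function(config) {
  simulation_config(
    n_participants = .cfg(config, "n_participants", 20),
    n_frames = .cfg(config, "n_frames", 6000),
    frame_rate = .cfg(config, "frame_rate", 50),
    grid = if (!is.null(config$grid_rows)) {
      c(config$grid_rows, config$grid_seats)
    } else NULL,
    coupling = .cfg(config, "coupling", 1),
    engagement_exponent = .cfg(config, "engagement_exponent", 1),
    spatial_length = .cfg(config, "spatial_length", 3),
    beta_age = .cfg(config, "beta_age", -0.5),
    beta_empathy = .cfg(config, "beta_empathy", 0.5),
    beta_gender = .cfg(config, "beta_gender", 0.5),
    noise_sd = .cfg(config, "noise_sd", 0.05),
    dropout = .cfg(config, "dropout", 0.05),
    seed = .cfg(config, "seed", 1L))
}

.load_recording <- function(config) {
  tracks <- read_expression_table(config$expressions,
                                  frame_rate = .cfg(config, "frame_rate", 50))
  info <- read_participant_table(config$participants)
  audience_recording(.cfg(config, "performance_id", "performance"),
                     tracks, info)
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `audiencesync` command-line script
#' (installed at `system.file("cli", "audiencesync.R", package =
#' "audiencesync")`). Subcommands: `simulate`, `describe`, `isc`,
#' `engagement`, `pairs`, `analyze`, `report`. The first argument is the
#' subcommand; `--config <file>` names a YAML configuration and
#' `--out <dir>` the output directory, and `--seed`, `--n-perm`,
#' `--pair-mode`, `--p-rule`, `--two-sided`, `--bayes-scale` override
#' config keys.
#'
#' @param args Character vector of command-line arguments (for the
#'   script, `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly (0 on success).
#' @export
cli_main <- function(args) {
  status <- tryCatch({
    if (length(args) < 1L) {
      stop("usage: audiencesync <simulate|describe|isc|engagement|pairs|analyze|report> [--config file] [--out dir] [options]",
           call. = FALSE)
    }
    cmd <- args[1]
    opt <- list()
    rest <- args[-1]
    i <- 1L
    while (i <= length(rest)) {
      a <- rest[i]
      if (a == "--two-sided") {
        opt$two_sided <- TRUE; i <- i + 1L
      } else if (startsWith(a, "--")) {
        key <- gsub("-", "_", substring(a, 3))
        if (i == length(rest)) stop("missing value for ", a, call. = FALSE)
        opt[[key]] <- rest[i + 1L]; i <- i + 2L
      } else {
        stop("unexpected argument: ", a, call. = FALSE)
      }
    }
    config <- if (!is.null(opt$config)) read_run_config(opt$config) else
      list()
    for (key in setdiff(names(opt), "config")) config[[key]] <- opt[[key]]
    for (key in c("seed", "n_perm", "n_participants", "n_frames",
                  "grid_rows", "grid_seats", "window_len", "step")) {
      if (!is.null(config[[key]])) config[[key]] <- as.integer(config[[key]])
    }
    for (key in c("noise_sd", "dropout", "spatial_length", "bayes_scale",
                  "engagement_exponent", "coupling", "beta_age",
                  "beta_empathy", "beta_gender", "min_valid")) {
      if (!is.null(config[[key]])) config[[key]] <- as.numeric(config[[key]])
    }
    out_dir <- .cfg(config, "out", .cfg(config, "out_dir", "."))
    bayes <- bayes_spec(
      cauchy_scale = .cfg(config, "bayes_scale", 0.5),
      one_sided_positive = !isTRUE(config$two_sided))
    spec <- window_spec(
      window_len = as.integer(.cfg(config, "window_len", 3000)),
      step = as.integer(.cfg(config, "step", 100)),
      min_valid_fraction = as.numeric(.cfg(config, "min_valid_fraction",
                                           0.5)))

    if (cmd == "simulate") {
      simulate_to_csv(.config_to_simulation(config), out_dir)
      message("wrote simulated recording to ", out_dir)
    } else if (cmd %in% c("describe", "isc", "engagement", "pairs",
                          "analyze")) {
      recording <- .load_recording(config)
      script <- if (!is.null(config$script)) {
        read_engagement_script(config$script)
      } else NULL
      if (cmd == "engagement" && is.null(script)) {
        stop("engagement stage needs a script CSV (--script)",
             call. = FALSE)
      }
      analysis <- run_analysis(
        recording, script = script, spec = spec,
        min_valid = .cfg(config, "min_valid", 0.9),
        pair_mode = .cfg(config, "pair_mode", "whole_series"),
        n_perm = .cfg(config, "n_perm", 10000L),
        perm_seed = .cfg(config, "seed", 1L),
        alternative = .cfg(config, "alternative", "negative"),
        p_rule = .cfg(config, "p_rule", "plain"),
        bayes = bayes, out_dir = out_dir)
      message(sprintf("analyzed '%s': %d of %d participants included",
                      analysis$performance_id, analysis$n_after,
                      analysis$n_before))
    } else if (cmd == "report") {
      write_report(out_dir)
      message("wrote ", file.path(out_dir, "report.md"))
    } else {
      stop("unknown subcommand: ", cmd, call. = FALSE)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
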