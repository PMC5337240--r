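#' Per-observer study metrics
#'
#' Scores every response and computes the per-observer figure of merit,
#' point- and event-based sensitivity and scene-based specificity — one row
#' per observer/session, the long-format table all group summaries and tests
#' are built from.
#'
#' @param scene_set a [scene_set()].
#' @param responses list of [observer_response()] objects.
#' @param variant FOM variant, see [rating_data()].
#' @return data.frame with columns `observer_id`, `group_label`,
#'   `session_label`, `fom`, `sensitivity_points`, `sensitivity_events`
#'   (NA when the scene set has no events), `specificity`, `tp_count`,
#'   `fp_count`. Fractions are unrounded proportions in \[0, 1\].
#' @export
study_metrics <- function(scene_set, responses, variant = c("normal_only", "all_scenes")) {
  variant <- match.arg(variant)
  if (inherits(responses, "observer_response")) responses <- list(responses)
  rows <- lapply(responses, function(r) {
    sc <- score_response(scene_set, r)
    data.frame(
      observer_id = r$observer_id,
      group_label = r$group_label,
      session_label = r$session_label,
      fom = afroc_fom(rating_data(sc, scene_set, variant)),
      sensitivity_points = sensitivity_points(sc, scene_set),
      sensitivity_events = if (scene_set$n_events > 0) {
        sensitivity_events(sc, scene_set)
      } else {
        NA_real_
      },
      specificity = specificity_scenes(sc, scene_set),
      tp_count = sc$tp_count,
      fp_count = sc$fp_count,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Score a study from files
#'
#' File-level pipeline: read the scene set and responses, refuse to proceed
#' on any [validate_study()] hard error, then write `scored_marks.csv` (one
#' row per mark with its TP/FP/suppressed label) and `metrics.csv` (one row
#' per observer/session from [study_metrics()]) to `out_dir`. Numbers in the
#' CSVs are unrounded; rounding is a presentation step.
#'
#' @param scene_set_path path to a scene-set JSON file.
#' @param responses_path path to a response CSV file.
#' @param out_dir output directory (created if missing).
#' @param variant FOM variant, see [rating_data()].
#' @return The metrics data.frame, invisibly.
#' @export
run_scoring <- function(scene_set_path, responses_path, out_dir = ".",
                        variant = c("normal_only", "all_scenes")) {
  variant <- match.arg(variant)
  ss <- read_scene_set(scene_set_path)
  responses <- read_responses(responses_path)
  report <- validate_study(ss, responses)
  if (nrow(report)) {
    print(report)
    stop("refusing to score: ", nrow(report), " validation hard error(s)", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scored <- lapply(responses, function(r) score_response(ss, r))
  write_scored_marks(scored, file.path(out_dir, "scored_marks.csv"))
  metrics <- study_metrics(ss, responses, variant)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  invisible(metrics)
}

#' Group comparison of reader figures of merit
#'
#' Summarizes per-observer metrics by group and runs unpaired t tests on the
#' FOMs of every pair of groups with at least two members each (groups with a
#' single member are skipped with a warning). When more than one test is run
#' a note reminds the reader that p values are not adjusted for multiple
#' comparisons.
#'
#' @param metrics data.frame from [study_metrics()].
#' @param by grouping column, default `"group_label"`.
#' @param alpha significance level.
#' @param var_equal pooled (default) or Welch unpaired test.
#' @return list with `summary` (one row per group: n and metric means) and
#'   `tests` (one row per group pair; zero rows when no test could run).
#' @export
compare_groups <- function(metrics, by = "group_label", alpha = 0.05, var_equal = TRUE) {
  stopifnot(by %in% names(metrics))
  groups <- split(metrics, metrics[[by]])
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    s <- summarize_group(groups[[g]], g)
    cbind(
      data.frame(group = g, n = s$n, stringsAsFactors = FALSE),
      as.data.frame(as.list(s$means))
    )
  }))
  tests <- list()
  nm <- names(groups)
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (i >= j) next
      a <- groups[[nm[i]]]$fom
      b <- groups[[nm[j]]]$fom
      if (length(a) < 2 || length(b) < 2) {
        warning(sprintf(
          "skipping t test %s vs %s: a group has fewer than 2 members",
          nm[i], nm[j]
        ), call. = FALSE)
        next
      }
      tt <- fom_t_test(a, b, kind = "unpaired", var_equal = var_equal, alpha = alpha)
      tests[[length(tests) + 1]] <- data.frame(
        group_a = nm[i], group_b = nm[j],
        t = tt$statistic, df = tt$df, p_value = tt$p_value,
        significant = tt$significant, stringsAsFactors = FALSE
      )
    }
  }
  tests <- if (length(tests)) {
    do.call(rbind, tests)
  } else {
    data.frame(
      group_a = character(), group_b = character(), t = numeric(),
      df = numeric(), p_value = numeric(), significant = logical(),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(tests) > 1) {
    message(
      "note: ", nrow(tests),
      " t tests were run; p values are not adjusted for multiple comparisons"
    )
  }
  list(summary = summary, tests = tests)
}

#' Before/after session comparison
#'
#' Builds the per-observer before/after table (FOM, delta FOM = after -
#' before, sensitivities and specificities per session) for observers present
#' in both sessions, with average rows over all observers, and runs the
#' paired t test on the FOMs.
#'
#' @param metrics data.frame from [study_metrics()].
#' @param before,after the two `session_label` values, in order.
#' @param alpha significance level.
#' @return list with `table` (one row per observer plus an `"Average"` row)
#'   and `test` (a [fom_t_test()] result, `NULL` with a warning when fewer
#'   than two observers appear in both sessions).
#' @export
compare_sessions <- function(metrics, before = "before", after = "after", alpha = 0.05) {
  mb <- metrics[metrics$session_label == before, ]
  ma <- metrics[metrics$session_label == after, ]
  ids <- intersect(mb$observer_id, ma$observer_id)
  if (!length(ids)) stop("no observer appears in both sessions", call. = FALSE)
  mb <- mb[match(ids, mb$observer_id), ]
  ma <- ma[match(ids, ma$observer_id), ]
  tab <- data.frame(
    observer_id = ids,
    fom_before = mb$fom, fom_after = ma$fom, delta_fom = ma$fom - mb$fom,
    sensitivity_before = mb$sensitivity_points, sensitivity_after = ma$sensitivity_points,
    specificity_before = mb$specificity, specificity_after = ma$specificity,
    stringsAsFactors = FALSE
  )
  avg <- tab[1, ]
  avg$observer_id <- "Average"
  for (col in names(tab)[-1]) avg[[col]] <- mean(tab[[col]])
  test <- NULL
  if (length(ids) >= 2) {
    test <- fom_t_test(tab$fom_before, tab$fom_after, kind = "paired", alpha = alpha)
  } else {
    warning("paired t test skipped: fewer than 2 observers in both sessions",
      call. = FALSE
    )
  }
  list(table = rbind(tab, avg), test = test)
}

#' Render a before/after table with study-style rounding
#'
#' Applies the reporting convention — FOMs half-up to 3 decimals,
#' sensitivity/specificity as percentages half-up to 1 decimal — to a
#' [compare_sessions()] table.
#'
#' @param comparison a [compare_sessions()] result.
#' @return data.frame with rounded columns.
#' @export
format_session_table <- function(comparison) {
  tab <- comparison$table
  data.frame(
    observer_id = tab$observer_id,
    fom_before = round_half_up(tab$fom_before, 3),
    fom_after = round_half_up(tab$fom_after, 3),
    delta_fom = round_half_up(tab$delta_fom, 3),
    sensitivity_before = round_half_up(100 * tab$sensitivity_before, 1),
    sensitivity_after = round_half_up(100 * tab$sensitivity_after, 1),
    specificity_before = round_half_up(100 * tab$specificity_before, 1),
    specificity_after = round_half_up(100 * tab$specificity_after, 1),
    stringsAsFactors = FALSE
  )
}

#' Group-averaged AFROC curves
#'
#' Computes each observer's empirical AFROC curve and the vertical average
#' per group.
#'
#' @param scene_set a [scene_set()].
#' @param responses list of [observer_response()] objects.
#' @param by grouping field of the responses: `"group_label"` (default) or
#'   `"session_label"`.
#' @param variant FOM variant, see [rating_data()].
#' @param grid_size averaging grid, see [average_afroc_curves()].
#' @return named list of [average_afroc_curves()] results, one per group.
#' @export
group_afroc_curves <- function(scene_set, responses, by = "group_label",
                               variant = c("normal_only", "all_scenes"),
                               grid_size = 100) {
  variant <- match.arg(variant)
  stopifnot(by %in% c("group_label", "session_label"))
  if (inherits(responses, "observer_response")) responses <- list(responses)
  labels <- vapply(responses, function(r) r[[by]], character(1))
  curves <- lapply(responses, function(r) {
    afroc_curve(rating_data(score_response(scene_set, r), scene_set, variant))
  })
  lapply(split(curves, labels), average_afroc_curves, grid_size = grid_size)
}

#' Compare groups from files
#'
#' File-level pipeline over [compare_groups()], [compare_sessions()] and
#' [group_afroc_curves()]: writes `group_summary.csv`, `group_tests.csv`,
#' `afroc_curves.csv` (the averaged polylines, long format) and a vector-plot
#' of the averaged curves to `out_dir`. When `before` and `after` are given
#' and both sessions are present, also writes `session_table.csv` and
#' `session_test.csv`.
#'
#' @inheritParams run_scoring
#' @param by grouping field, `"group_label"` (default) or `"session_label"`.
#' @param before,after optional session labels for a paired comparison.
#' @param alpha significance level.
#' @param grid_size curve-averaging grid.
#' @param plot_file name of the plot file written into `out_dir`; the
#'   extension selects the device (`.svg` needs cairo support, `.pdf` always
#'   works).
#' @return list with `summary`, `tests`, `curves` and (if requested)
#'   `sessions`, invisibly.
#' @export
run_comparison <- function(scene_set_path, responses_path, out_dir = ".",
                           by = "group_label", before = NULL, after = NULL,
                           variant = c("normal_only", "all_scenes"),
                           alpha = 0.05, grid_size = 100,
                           plot_file = "afroc_curves.pdf") {
  variant <- match.arg(variant)
  ss <- read_scene_set(scene_set_path)
  responses <- read_responses(responses_path)
  report <- validate_study(ss, responses)
  if (nrow(report)) {
    print(report)
    stop("refusing to compare: ", nrow(report), " validation hard error(s)", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- study_metrics(ss, responses, variant)
  cg <- compare_groups(metrics, by = by, alpha = alpha)
  utils::write.csv(cg$summary, file.path(out_dir, "group_summary.csv"), row.names = FALSE)
  utils::write.csv(cg$tests, file.path(out_dir, "group_tests.csv"), row.names = FALSE)
  curves <- group_afroc_curves(ss, responses, by = by, variant = variant, grid_size = grid_size)
  curve_df <- do.call(rbind, lapply(names(curves), function(g) {
    cbind(data.frame(group = g, stringsAsFactors = FALSE), curves[[g]]$points)
  }))
  utils::write.csv(curve_df, file.path(out_dir, "afroc_curves.csv"), row.names = FALSE)
  p <- plot_afroc(curves, title = "Group-averaged AFROC curves")
  ggplot2::ggsave(file.path(out_dir, plot_file), p, width = 6, height = 6)
  out <- list(summary = cg$summary, tests = cg$tests, curves = curves, metrics = metrics)
  if (!is.null(before) && !is.null(after)) {
    cs <- compare_sessions(metrics, before = before, after = after, alpha = alpha)
    utils::write.csv(format_session_table(cs), file.path(out_dir, "session_table.csv"),
      row.names = FALSE
    )
    if (!is.null(cs$test)) {
      utils::write.csv(
        data.frame(
          kind = cs$test$kind, t = cs$test$statistic, df = cs$test$df,
          p_value = cs$test$p_value, significant = cs$test$significant
        ),
        file.path(out_dir, "session_test.csv"),
        row.names = FALSE
      )
    }
    out$sessions <- cs
  }
  invisible(out)
}

#' Simulate a study to files
#'
#' Generates a scene set and a panel of simulated observers and writes them
#' in the standard interchange formats (`scene_set.json`, `responses.csv`) so
#' the scoring pipeline consumes them unchanged. Identical seeds give
#' byte-identical files.
#'
#' @param out_dir output directory (created if missing).
#' @param config a [scene_set_config()].
#' @param models list of [observer_model()] objects, one per observer;
#'   a single model is recycled `n_observers` times.
#' @param n_observers number of observers when `models` is a single model.
#' @param sessions character vector of session labels; every observer is
#'   simulated once per session (fresh seed each time).
#' @param group_labels optional per-observer group labels (recycled).
#' @param seed master seed; per-response seeds are derived from it.
#' @return invisibly, list with the paths written.
#' @export
run_simulation <- function(out_dir = ".", config = scene_set_config(),
                           models = kyt_observer_model(), n_observers = 6,
                           sessions = "", group_labels = "simulated", seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ss <- generate_scene_set(config, seed = seed)
  ss_path <- file.path(out_dir, "scene_set.json")
  write_scene_set(ss, ss_path)
  if (inherits(models, "observer_model")) {
    models <- rep(list(models), n_observers)
  }
  group_labels <- rep_len(group_labels, length(models))
  responses <- list()
  k <- 0L
  for (s in seq_along(sessions)) {
    for (i in seq_along(models)) {
      k <- k + 1L
      responses[[k]] <- simulate_response(
        ss, models[[i]],
        observer_id = sprintf("sim%02d", i),
        group_label = group_labels[i],
        session_label = sessions[s],
        seed = as.integer((as.numeric(seed) * 10000 + k) %% .Machine$integer.max)
      )
    }
  }
  resp_path <- file.path(out_dir, "responses.csv")
  write_responses(responses, resp_path)
  invisible(list(scene_set = ss_path, responses = resp_path))
}
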