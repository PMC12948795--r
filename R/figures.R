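# Report outputs: group activity summaries, model-implied reaction-time
# trajectories, and a reproducibility manifest.

#' Model-implied outcome trajectories by chronotype group
#'
#' Evaluates the fitted fixed effects over a time-of-day grid at
#' group-representative chronotype scores (the group means observed in
#' `rows`), holding covariates at their sample means/modes. This is the
#' numeric backbone of the trajectory figure: converging lines indicate that
#' group differences shrink towards the evening.
#'
#' @param result an `lmm_result` from [fit_lmm()].
#' @param rows the analysis table the model was fitted on.
#' @param hours time-of-day grid (default 7..23).
#' @return tibble: `chronotype_group`, `chronotype_score`, `time_of_day_h`,
#'   `predicted`.
#' @export
predict_trajectories <- function(result, rows, hours = seq(7, 23, by = 0.5)) {
  d <- rows[rows$outcome_name == result$outcome, , drop = FALSE]
  if (!is.null(result$task)) d <- d[d$task == result$task, , drop = FALSE]
  groups <- d |>
    dplyr::distinct(.data$participant_id, .data$chronotype_group,
      .data$chronotype_score
    ) |>
    dplyr::group_by(.data$chronotype_group) |>
    dplyr::summarise(chronotype_score = mean(.data$chronotype_score), .groups = "drop")
  est <- stats::setNames(result$terms$estimate, result$terms$term)
  grid <- tidyr::expand_grid(groups, time_of_day_h = hours)
  grid$predicted <- est[["(Intercept)"]] +
    est[["time_of_day_h"]] * grid$time_of_day_h +
    est[["chronotype_score"]] * grid$chronotype_score +
    est[["time_of_day_h:chronotype_score"]] * grid$chronotype_score *
      grid$time_of_day_h +
    est[["age"]] * mean(d$age) +
    est[["sexmale"]] * mean(d$sex == "male") +
    est[["caffeine_flagTRUE"]] * mean(d$caffeine_flag) +
    est[["activity_prior_60min"]] * mean(d$activity_prior_60min)
  grid
}

#' Emit report figures and a run manifest
#'
#' Writes (i) a bar chart of total 7-day activity by chronotype group, (ii) a
#' mean peak-activity-time chart, (iii) model-implied outcome trajectories per
#' fitted model, and (iv) `manifest.json` recording the seed, configuration
#' hash and exclusion counts -- enough to reproduce the run. The manifest is
#' byte-identical across runs with the same inputs.
#'
#' @param fits named list of `lmm_result` objects.
#' @param rows the analysis table used for fitting.
#' @param features output of [activity_summary()] rows.
#' @param assignments output of [assign_quintiles()].
#' @param out_dir output directory.
#' @param seed,config_hash,drop_log provenance fields for the manifest.
#' @return invisible character vector of files written.
#' @export
report_figures <- function(fits, rows, features, assignments, out_dir,
                           seed = NA_integer_, config_hash = NA_character_,
                           drop_log = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)

  feat <- dplyr::inner_join(features, assignments, by = "participant_id")
  p1 <- feat |>
    dplyr::filter(.data$included) |>
    dplyr::group_by(.data$chronotype_group) |>
    dplyr::summarise(total = mean(.data$total_auc_7day), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$chronotype_group, y = .data$total)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = NULL, y = "Mean 7-day total AUC (arbitrary units)",
      title = "Total activity by chronotype group"
    )
  f <- file.path(out_dir, "activity_by_group.png")
  ggplot2::ggsave(f, p1, width = 6, height = 4, dpi = 120)
  written <- c(written, f)

  p2 <- feat |>
    dplyr::filter(.data$included) |>
    dplyr::group_by(.data$chronotype_group) |>
    dplyr::summarise(
      peak = circular_mean_hours(.data$mean_peak_time_h), .groups = "drop"
    ) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$chronotype_group, y = .data$peak)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = NULL, y = "Mean daily peak activity time (h)",
      title = "Peak activity timing by chronotype group"
    )
  f <- file.path(out_dir, "peak_time_by_group.png")
  ggplot2::ggsave(f, p2, width = 6, height = 4, dpi = 120)
  written <- c(written, f)

  for (nm in names(fits)) {
    traj <- predict_trajectories(fits[[nm]], rows)
    p3 <- ggplot2::ggplot(traj, ggplot2::aes(
      x = .data$time_of_day_h, y = .data$predicted,
      colour = .data$chronotype_group
    )) +
      ggplot2::geom_line(linewidth = 0.8) +
      ggplot2::labs(
        x = "Time of day (h)", y = fits[[nm]]$outcome,
        colour = "Chronotype", title = paste("Model-implied trajectories:", nm)
      )
    f <- file.path(out_dir, paste0("trajectories_", nm, ".png"))
    ggplot2::ggsave(f, p3, width = 6, height = 4, dpi = 120)
    written <- c(written, f)
  }

  manifest <- list(
    seed = seed,
    config_hash = config_hash,
    n_participants_included = sum(features$included),
    n_participants_excluded = sum(!features$included),
    dropped_rows = as.list(drop_log %||% list()),
    models = names(fits)
  )
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  written <- c(written, f)
  invisible(written)
}
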