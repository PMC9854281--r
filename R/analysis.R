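# Per-participant cell means: the participant x (block, trial_type)
# building block of all aggregation.  Trial 1 of each session has an
# undefined trial type and is excluded; censored trials are excluded from
# RT means but keep their recorded response in the error denominator.
.participant_cells <- function(trials) {
  dt <- data.table::as.data.table(trials)
  dt <- dt[trial_type != "undefined"]
  dt[, list(
    mean_rt_s = {
      ok <- correct & !censored
      if (any(ok)) mean(rt_s[ok]) else NA_real_
    },
    error_rate = mean(!correct),
    n_trials = .N,
    n_rt = sum(correct & !censored)
  ), by = list(dataset, participant, block, trial_type)]
}

# Grand summary over participants (each participant weighted equally,
# pooled across datasets), with 95% within-subject CIs computed across
# the 2 (measures kept separate) x blocks x trial-types cell grid.
.summarise_cells <- function(cells, conf_level = 0.95) {
  cells <- data.table::as.data.table(cells)
  cells[, cell := paste(block, trial_type, sep = ".")]
  cells[, subject := paste(dataset, participant, sep = ".")]
  cell_levels <- unique(cells[order(block, match(trial_type, trial_types())),
                              cell])
  wide_rt <- .cells_to_matrix(cells, "mean_rt_s", cell_levels)
  wide_err <- .cells_to_matrix(cells, "error_rate", cell_levels)
  if (nrow(wide_rt) >= 2L) {
    ci_rt <- within_subject_ci(wide_rt, conf_level)
    ci_err <- within_subject_ci(wide_err, conf_level)
  } else {
    ci_rt <- ci_err <- stats::setNames(rep(NA_real_, length(cell_levels)),
                                       cell_levels)
  }
  summary <- cells[, list(
    mean_rt_s = mean(mean_rt_s, na.rm = TRUE),
    error_rate = mean(error_rate),
    n_trials = sum(n_trials),
    n_participants = .N
  ), by = list(block, trial_type)]
  summary[, trial_type := factor(trial_type, levels = trial_types())]
  data.table::setorder(summary, block, trial_type)
  summary[, ci_halfwidth_rt := ci_rt[paste(block, trial_type, sep = ".")]]
  summary[, ci_halfwidth_error := ci_err[paste(block, trial_type, sep = ".")]]
  data.table::setcolorder(summary, c("block", "trial_type", "mean_rt_s",
                                     "error_rate", "ci_halfwidth_rt",
                                     "ci_halfwidth_error", "n_trials",
                                     "n_participants"))
  cells[, c("cell", "subject") := NULL]
  structure(list(summary = summary[], cells = cells[],
                 conf_level = conf_level),
            class = "srt_summary")
}

.cells_to_matrix <- function(cells, value_col, cell_levels) {
  wide <- data.table::dcast(cells, subject ~ cell,
                            value.var = value_col)
  m <- as.matrix(wide[, -1L])
  rownames(m) <- wide$subject
  m[, cell_levels, drop = FALSE]
}

#' Aggregate trial records into the block x trial-type summary
#'
#' Computes, per participant and cell (block x trial type), the mean
#' response time over correct, non-censored trials and the proportion of
#' erroneous responses; participant cell means are then averaged with
#' equal weight per participant (pooled across datasets), and 95%
#' within-subject confidence intervals are attached.  The first trial of
#' each session (undefined trial type) is excluded.
#'
#' @param trials A trial table from [run_participant()],
#'   [run_dataset()]`$trials` or [run_experiment()]`$trials`.
#' @param conf_level Confidence level for the within-subject intervals.
#' @return An object of class `srt_summary`: a list with `summary` (one
#'   row per block x trial type: `mean_rt_s`, `error_rate`,
#'   `ci_halfwidth_rt`, `ci_halfwidth_error`, `n_trials`,
#'   `n_participants`) and `cells` (the participant-level cell means).
#' @export
aggregate_trials <- function(trials, conf_level = 0.95) {
  .summarise_cells(.participant_cells(trials), conf_level)
}

#' @export
print.srt_summary <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Within-subject confidence-interval half-widths
#'
#' Cousineau-centred intervals with the Morey small-sample correction:
#' each participant's cell values are shifted by the grand mean minus the
#' participant's own mean (removing between-participant level
#' differences), the per-cell standard deviation of the centred values is
#' inflated by `sqrt(C / (C - 1))` for `C` cells, and the half-width is
#' the normal quantile times the standard error.
#'
#' @param x Numeric matrix, participants in rows, within-subject cells in
#'   columns.  `NA` cells are tolerated (participant means use the
#'   available cells).
#' @param conf_level Confidence level (default 0.95).
#' @return Named numeric vector of half-widths, one per column.
#' @examples
#' m <- rbind(c(.5, .7), c(.6, .9), c(.4, .5))
#' within_subject_ci(m)
#' @export
within_subject_ci <- function(x, conf_level = 0.95) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    stop("within-subject confidence intervals require at least 2 participants")
  }
  C <- ncol(x)
  grand <- mean(x, na.rm = TRUE)
  centred <- x - rowMeans(x, na.rm = TRUE) + grand
  morey <- if (C > 1L) sqrt(C / (C - 1)) else 1
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  apply(centred, 2L, function(col) {
    col <- col[!is.na(col)]
    z * stats::sd(col) * morey / sqrt(length(col))
  })
}

#' Trial-type learning contrasts
#'
#' For each block (and pooled over blocks, `block = "all"`), the paired
#' contrasts of each trial type against the fully regular baseline --
#' `RT(type) - RT(both_regular)` and the same for error rates -- with
#' confidence intervals over participants.  Positive RT/error contrasts
#' mean the baseline is faster/more accurate.  The attached `"ordering"`
#' attribute flags, per block and measure, whether the expected ordering
#' both_regular < single-regular types < neither holds in the grand
#' means.
#'
#' @param agg An [aggregate_trials()] object.
#' @param conf_level Confidence level (default 0.95).
#' @return A `data.table` with columns `block`, `measure` (`"rt"` or
#'   `"error"`), `contrast`, `estimate`, `ci_lower`, `ci_upper`, `n`.
#' @export
learning_contrasts <- function(agg, conf_level = 0.95) {
  stopifnot(inherits(agg, "srt_summary"))
  cells <- data.table::copy(agg$cells)
  cells[, subject := paste(dataset, participant, sep = ".")]
  pooled <- cells[, list(mean_rt_s = mean(mean_rt_s, na.rm = TRUE),
                         error_rate = mean(error_rate)),
                  by = list(subject, trial_type)]
  pooled[, block := "all"]
  per_block <- cells[, list(subject, trial_type, block = as.character(block),
                            mean_rt_s, error_rate)]
  long <- data.table::rbindlist(list(per_block, pooled), use.names = TRUE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  others <- setdiff(trial_types(), "both_regular")
  res <- list()
  for (blk in unique(long$block)) {
    sub <- long[block == blk]
    base <- sub[trial_type == "both_regular"]
    for (ty in others) {
      cmp <- merge(base, sub[trial_type == ty], by = "subject",
                   suffixes = c("_base", "_cmp"))
      for (meas in c("rt", "error")) {
        d <- if (meas == "rt") {
          cmp$mean_rt_s_cmp - cmp$mean_rt_s_base
        } else {
          cmp$error_rate_cmp - cmp$error_rate_base
        }
        d <- d[!is.na(d)]
        se <- stats::sd(d) / sqrt(length(d))
        res[[length(res) + 1L]] <- data.table::data.table(
          block = blk, measure = meas,
          contrast = paste0(ty, "_minus_both"),
          estimate = mean(d), ci_lower = mean(d) - z * se,
          ci_upper = mean(d) + z * se, n = length(d))
      }
    }
  }
  out <- data.table::rbindlist(res)
  ordering <- .contrast_ordering(agg$summary)
  data.table::setattr(out, "ordering", ordering)
  out
}

# Grand-mean ordering check: both < each single-regular type < neither.
.contrast_ordering <- function(summary) {
  s <- data.table::as.data.table(summary)
  res <- list()
  for (blk in unique(s$block)) {
    for (meas in c("rt", "error")) {
      v <- if (meas == "rt") s[block == blk, mean_rt_s] else
        s[block == blk, error_rate]
      names(v) <- as.character(s[block == blk, trial_type])
      holds <- v["both_regular"] < min(v["stimulus_only"], v["response_only"]) &&
        max(v["stimulus_only"], v["response_only"]) < v["neither"]
      res[[length(res) + 1L]] <- data.table::data.table(
        block = blk, measure = meas, ordering_holds = unname(holds))
    }
  }
  data.table::rbindlist(res)
}

#' Plot and export the block x trial-type summary
#'
#' Renders the two-panel learning-curve figure (mean correct-trial RT in
#' seconds and error proportion, by block, one line per trial type, with
#' within-subject error bars) and optionally writes the summary CSV and
#' the figure alongside.
#'
#' @param agg An [aggregate_trials()] object.
#' @param out_dir Optional directory; when given, `summary.csv` and
#'   `summary.png` are written there.
#' @param plot Render (and, with `out_dir`, save) the figure.
#' @return A list with `plot` (a ggplot, or `NULL`) and `summary` (the
#'   summary table), invisibly.
#' @export
render_summary <- function(agg, out_dir = NULL, plot = TRUE) {
  stopifnot(inherits(agg, "srt_summary"))
  s <- data.table::copy(agg$summary)
  long <- data.table::rbindlist(list(
    s[, list(block, trial_type, value = mean_rt_s, ci = ci_halfwidth_rt,
             measure = "Response time [s]")],
    s[, list(block, trial_type, value = error_rate,
             ci = ci_halfwidth_error, measure = "Error rate")]
  ))
  p <- NULL
  if (plot) {
    p <- ggplot2::ggplot(long, ggplot2::aes(
      x = block, y = value, colour = trial_type, group = trial_type)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = value - ci,
                                          ymax = value + ci),
                             width = 0.15) +
      ggplot2::facet_wrap(~measure, scales = "free_y") +
      ggplot2::scale_x_continuous(breaks = unique(long$block)) +
      ggplot2::labs(x = "Block", y = NULL, colour = "Trial type") +
      ggplot2::theme_bw()
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    data.table::fwrite(s, file.path(out_dir, "summary.csv"))
    if (plot) {
      ggplot2::ggsave(file.path(out_dir, "summary.png"), p,
                      width = 8, height = 4, dpi = 150)
    }
  }
  invisible(list(plot = p, summary = s))
}
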