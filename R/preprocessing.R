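#' Session-level exclusion
#'
#' Drops training sessions (complexity `b` below 0.5) and testing sessions
#' whose overall accuracy (total correct / total trials) falls below 70%.
#'
#' @param trials Trial table (see [generate_mouse_dataset()] for the
#'   columns; `session_id`, `session_b` and `correct` are required).
#' @param min_complexity Minimum session `b` for inclusion.
#' @param min_accuracy Minimum fraction of correct trials for inclusion.
#' @return A list with `trials` (rows from kept sessions only) and
#'   `sessions`, a per-session summary data frame (`mouse_id`, `session_id`,
#'   `b`, `n_trials`, `accuracy`, `mean_rt_raw`, `kept`).
#' @export
filter_sessions <- function(trials, min_complexity = 0.5,
                            min_accuracy = 0.70) {
  stopifnot(all(c("session_id", "session_b", "correct") %in% names(trials)))
  sid <- trials$session_id
  summaries <- do.call(rbind, lapply(split(trials, sid), function(d) {
    data.frame(mouse_id = d$mouse_id[1], session_id = d$session_id[1],
               b = d$session_b[1], n_trials = nrow(d),
               accuracy = mean(d$correct),
               mean_rt_raw = mean(d$rt_raw),
               stringsAsFactors = FALSE)
  }))
  summaries$kept <- summaries$b >= min_complexity &
    summaries$accuracy >= min_accuracy
  rownames(summaries) <- NULL
  kept_ids <- summaries$session_id[summaries$kept]
  kept <- trials[sid %in% kept_ids, , drop = FALSE]
  rownames(kept) <- NULL
  list(trials = kept, sessions = summaries)
}

#' Reaction-time normalization
#'
#' Removes between-session reaction-time variation (e.g. from variable
#' lick-spout positioning): each session's reaction times are divided by the
#' session mean and multiplied by the mouse's grand mean reaction time so
#' the values keep meaningful units. After normalization every session's
#' mean reaction time equals the grand mean. Applied per mouse.
#'
#' @param trials Kept trial table with `rt_raw`.
#' @param grand `"session"` (default): the grand mean is the unweighted mean
#'   of session means; `"trial"`: the trial-weighted overall mean.
#' @return `trials` with `rt_normalized` filled.
#' @export
normalize_reaction_times <- function(trials, grand = c("session", "trial")) {
  grand <- match.arg(grand)
  stopifnot(all(c("mouse_id", "session_id", "rt_raw") %in% names(trials)))
  if (nrow(trials) == 0) stop("no trials to normalize", call. = FALSE)
  out <- trials
  for (m in unique(trials$mouse_id)) {
    rows <- which(trials$mouse_id == m)
    d <- trials[rows, ]
    sess_means <- tapply(d$rt_raw, d$session_id, mean)
    if (any(!is.finite(sess_means))) {
      stop("every session needs at least one responded trial", call. = FALSE)
    }
    grand_mean <- if (grand == "session") mean(sess_means) else mean(d$rt_raw)
    out$rt_normalized[rows] <-
      d$rt_raw / sess_means[d$session_id] * grand_mean
  }
  out
}

#' Psychometric and chronometric summary curves
#'
#' Per mouse and per (trial type, background count) cell: the fraction of
#' "report present" choices and the mean normalized reaction time. These are
#' the behavioural curves against which the interference mechanisms'
#' predictions are compared.
#'
#' @param trials Preprocessed trial table (normalized reaction times
#'   filled; falls back to `rt_raw` if not).
#' @return Data frame with columns `mouse_id`, `trial_type`, `n_background`,
#'   `p_report_present`, `mean_rt`, `n`. Cells with no trials are reported
#'   with `n = 0` and `NA` summaries.
#' @export
behavioral_curves <- function(trials) {
  rt <- if (all(is.na(trials$rt_normalized))) trials$rt_raw else
    trials$rt_normalized
  cells <- rbind(
    expand.grid(trial_type = "target_on", n_background = 0:5,
                stringsAsFactors = FALSE),
    expand.grid(trial_type = "target_off", n_background = 1:6,
                stringsAsFactors = FALSE)
  )
  out <- list()
  for (m in unique(trials$mouse_id)) {
    for (i in seq_len(nrow(cells))) {
      sel <- trials$mouse_id == m &
        trials$trial_type == cells$trial_type[i] &
        trials$n_background == cells$n_background[i]
      n <- sum(sel)
      out[[length(out) + 1L]] <- data.frame(
        mouse_id = m, trial_type = cells$trial_type[i],
        n_background = cells$n_background[i],
        p_report_present = if (n) mean(trials$choice[sel] == "report_present")
          else NA_real_,
        mean_rt = if (n) mean(rt[sel]) else NA_real_,
        n = n, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Across-mouse average of behavioural curves
#'
#' @param curves Output of [behavioral_curves()].
#' @return Per (trial type, background count): across-mouse mean and
#'   standard error of the report-present fraction and mean reaction time,
#'   and the number of contributing mice.
#' @export
average_curves <- function(curves) {
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  cells <- unique(curves[, c("trial_type", "n_background")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    d <- curves[curves$trial_type == cells$trial_type[i] &
                  curves$n_background == cells$n_background[i] &
                  curves$n > 0, ]
    data.frame(trial_type = cells$trial_type[i],
               n_background = cells$n_background[i],
               p_report_present = mean(d$p_report_present),
               se_p = se(d$p_report_present),
               mean_rt = mean(d$mean_rt), se_rt = se(d$mean_rt),
               n_mice = nrow(d), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
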