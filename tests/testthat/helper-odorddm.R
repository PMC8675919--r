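# shared fixtures: all synthetic, generated in code

# reference parameter sets spanning drift signs and biases
reference_params <- function() {
  list(
    ddm_params(drift = 2, diffusion_var = 3, threshold = 1),
    ddm_params(drift = -2.5, diffusion_var = 3, threshold = 1),
    ddm_params(drift = 1, diffusion_var = 1.5, threshold = 0.5,
               start_bias = 0.3),
    ddm_params(drift = -1, diffusion_var = 4, threshold = 0.5,
               start_bias = -0.4),
    ddm_params(drift = 0.5, diffusion_var = 1, threshold = 1,
               start_bias = 0.1)
  )
}

# trial table for one condition from raw simulator output
sim_condition_trials <- function(gt_row, n, outlier_rate = 0,
                                 step = 1e-4, mouse_id = "m1",
                                 session_id = "m1_s001", session_b = 1) {
  pars <- ddm_params(gt_row$drift, gt_row$diffusion_var, gt_row$threshold,
                     gt_row$start_bias, gt_row$non_decision_time)
  s <- simulate_trials(pars, n, outlier_rate = outlier_rate, step = step)
  data.frame(
    mouse_id = mouse_id, session_id = session_id, session_b = session_b,
    condition = gt_row$condition, target_identity = gt_row$target,
    trial_type = gt_row$trial_type, n_background = gt_row$n_background,
    choice = ifelse(s$boundary == "upper", "report_present",
                    "report_absent"),
    correct = (s$boundary == "upper") == (gt_row$trial_type == "target_on"),
    rt_raw = s$reaction_time, rt_normalized = s$reaction_time,
    stringsAsFactors = FALSE
  )
}

# condition-balanced dataset across the full 18-condition grid
balanced_dataset <- function(ground_truth, n_per_condition,
                             outlier_rate = 0, step = 1e-4,
                             mouse_id = "m1") {
  out <- lapply(seq_len(nrow(ground_truth)), function(i) {
    sim_condition_trials(ground_truth[i, ], n_per_condition,
                         outlier_rate = outlier_rate, step = step,
                         mouse_id = mouse_id)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# a hand-built trial table with fully controlled fields
manual_trials <- function(session_id, session_b, correct, rt,
                          mouse_id = "m1", condition = "A:0",
                          trial_type = "target_on", n_background = 0,
                          choice = NULL) {
  if (is.null(choice)) {
    choice <- ifelse((trial_type == "target_on") == correct,
                     "report_present", "report_absent")
  }
  data.frame(mouse_id = mouse_id, session_id = session_id,
             session_b = session_b, condition = condition,
             target_identity = if (trial_type == "target_on") "A" else "none",
             trial_type = trial_type, n_background = n_background,
             choice = choice, correct = correct, rt_raw = rt,
             rt_normalized = NA_real_, stringsAsFactors = FALSE)
}
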