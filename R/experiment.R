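derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Run one trial
#'
#' Executes the full trial sequence: (i) the dynamic control network selects
#' an expert (skipped in the monolithic variant); (ii) the network relaxes on
#' the encoded stimulus with the non-selected experts' motor units clamped
#' under suppression; (iii) softmax over the released motor units picks the
#' action; (iv) reward and prediction error; (v) accessory propagation from
#' the winning motor unit; (vi) reward-gated weight update; (vii) bias-weight
#' update of the control network.  Draws (softmax, control-network noise) use
#' R's current random stream.
#'
#' @param conn A [connection_set()].
#' @param layout A [network_layout()].
#' @param dcn A `dcn_state`, or `NULL` for the monolithic variant.
#' @param velocity Momentum buffer (see [make_velocity()]).
#' @param stim_id Stimulus id (1..32).
#' @param cont The phase's [make_contingency()].
#' @param up,lp,dp Unit, learning and control-network parameters.
#' @param relax List with `dt`, `tol`, `max_steps` for [relax_network()].
#' @return A list with the per-trial `record` (stimulus, expert, action,
#'   predicted value `q_a`, reward `rho`, prediction error `delta`, `correct`
#'   and `converged` flags) and the updated `conn`, `velocity`, `dcn`.
#' @export
run_trial <- function(conn, layout, dcn, velocity, stim_id, cont,
                      up = unit_params(), lp = learning_params(),
                      dp = dcn_params(),
                      relax = list(dt = 0.1, tol = 1e-6, max_steps = 5000)) {
  stim <- stimulus_set()[stim_id, ]
  i_inp <- encode_stimulus(stim)

  if (!is.null(dcn)) {
    dcn <- dcn_select(dcn, dp)
    expert <- dcn$selected
    supp <- suppression_input(dcn, layout, dp)
  } else {
    expert <- 1L
    supp <- 0
  }
  motors <- layout$motor[[expert]]

  st <- relax_network(conn, i_inp, up, dt = relax$dt, tol = relax$tol,
                      max_steps = relax$max_steps, i_inh_ext = supp)
  action <- select_action(st$p[motors], lp$tau)
  unit_a <- motors[action]
  q_a <- st$p[unit_a]
  rho <- reward_for(action, stim$category, cont, lp)
  delta <- prediction_error(rho, q_a)

  skipped <- FALSE
  tryCatch({
    acc <- propagate_accessory(conn, st, up, unit_a)
    # accessory units are shunting-bounded: the scaled boost saturates at
    # the same activity bounds as the regular units
    acc$delta_p <- pmin(pmax(lp$accessory_gain * acc$delta_p, -up$zeta),
                        up$beta)
    upd <- update_weights(conn, st, acc, delta, lp, velocity, i_inp, up)
    conn <- upd$conn
    velocity <- upd$velocity
  }, revlearn_singular_equilibrium = function(e) skipped <<- TRUE)

  if (!is.null(dcn)) dcn <- dcn_update_bias(dcn, delta, dp)

  list(record = list(stimulus_id = stim$id, category = stim$category,
                     expert = expert, action = action, q_a = q_a, rho = rho,
                     delta = delta,
                     correct = rho == lp$reward_correct,
                     converged = isTRUE(st$converged),
                     update_skipped = skipped),
       conn = conn, velocity = velocity, dcn = dcn)
}

#' Run one simulated subject through the serial-reversal protocol
#'
#' Builds a fresh network, then executes `n_phases * trials_per_phase` trials
#' under the reversal schedule and computes the behavioural metrics.  The
#' master seed is split into independent sub-streams for (weight and bias
#' initialization), (stimulus sampling) and (per-trial policy/control noise),
#' so the two model variants see identical stimulus sequences when run with
#' the same seed.
#'
#' @param config A configuration list (see [default_config()]).
#' @param seed Integer seed; the run is bit-for-bit reproducible from it.
#' @param keep_network Keep the trained network (and control state) in the
#'   result, e.g. for [basis_similarity()]?
#' @return An object of class `run_result`: list with the trial log `trials`
#'   (a data frame), `metrics` (see [analyze_trial_log()]), the number of
#'   `nonconverged` relaxations, the `seed`, the `config`, and (optionally)
#'   `conn`, `layout`, `dcn`.
#' @export
run_experiment <- function(config = default_config(), seed = 1L,
                           keep_network = FALSE) {
  obj <- config_objects(config)
  seeds <- derive_seeds(seed, 3)

  set.seed(seeds[1])
  net <- build_network(obj$spec)
  dcn <- if (obj$dcn_enabled) dcn_init(obj$spec$n_experts, obj$dp, obj$up)
         else NULL

  sched <- reversal_schedule(config$task$trials_per_phase,
                             config$task$n_phases,
                             config$task$target_category)
  n_trials <- length(sched$phase)
  set.seed(seeds[2])
  stim_ids <- sample_stimuli(n_trials)

  set.seed(seeds[3])
  velocity <- make_velocity(net$conn)
  conn <- net$conn
  rec <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    cont <- sched$contingencies[[sched$phase[t] + 1L]]
    out <- run_trial(conn, net$layout, dcn, velocity, stim_ids[t], cont,
                     obj$up, obj$lp, obj$dp, config$relax)
    conn <- out$conn; velocity <- out$velocity; dcn <- out$dcn
    rec[[t]] <- out$record
  }

  trials <- data.frame(trial = seq_len(n_trials), phase = sched$phase,
                       do.call(rbind.data.frame, rec))
  nonconv <- sum(!trials$converged)
  if (nonconv > 0)
    warning(nonconv, " of ", n_trials, " relaxations did not converge ",
            "within the step budget; their reached states were used")
  structure(c(list(trials = trials,
                   metrics = analyze_trial_log(trials),
                   nonconverged = nonconv, seed = seed, config = config),
              if (keep_network) list(conn = conn, layout = net$layout,
                                     dcn = dcn)),
            class = "run_result")
}

#' Run a group of simulated subjects
#'
#' Executes `n_runs` independent runs (seeds spawned deterministically from
#' the master seed) and aggregates the group statistics: learner count,
#' per-phase time-to-criterion over learners, and the two paired-phase
#' comparisons (Initial vs. first reversal, first vs. second reversal).
#'
#' @param config A configuration list (see [default_config()]).
#' @param n_runs Number of independent runs.
#' @param seed Master seed.  Groups run from the same master seed share their
#'   per-run stimulus sequences across model variants, for paired
#'   comparability.
#' @param progress Emit a message per run?
#' @return An object of class `group_result`: list with `n_runs`,
#'   `learner_count`, logical `learner`, the `ttc` and `phase_rates` matrices
#'   (runs x phases), the per-run seeds, and `tests` (over learners;
#'   `initial_vs_rev1`, `rev1_vs_rev2`; `NULL` where fewer than 2 complete
#'   pairs exist).
#' @export
run_group <- function(config = default_config(), n_runs = 30L, seed = 1L,
                      progress = FALSE) {
  run_seeds <- derive_seeds(seed, n_runs)
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    runs[[i]] <- suppressWarnings(run_experiment(config, run_seeds[i]))
    if (progress)
      message(sprintf("run %d/%d: learner=%s rates=%s", i, n_runs,
                      runs[[i]]$metrics$learner,
                      paste(round(runs[[i]]$metrics$phase_rates, 2),
                            collapse = "/")))
  }
  summarize_group(runs, run_seeds)
}

summarize_group <- function(runs, run_seeds = NA) {
  n_runs <- length(runs)
  learner <- vapply(runs, function(r) r$metrics$learner, logical(1))
  ttc <- t(vapply(runs, function(r) r$metrics$ttc,
                  numeric(length(runs[[1]]$metrics$ttc))))
  phase_rates <- t(vapply(runs, function(r) r$metrics$phase_rates,
                          numeric(ncol(ttc))))
  safe_cmp <- function(a, b)
    tryCatch(compare_phases(a, b), error = function(e) NULL)
  tests <- if (ncol(ttc) >= 3 && sum(learner) >= 2)
    list(initial_vs_rev1 = safe_cmp(ttc[learner, 1], ttc[learner, 2]),
         rev1_vs_rev2 = safe_cmp(ttc[learner, 2], ttc[learner, 3]))
  else list(initial_vs_rev1 = NULL, rev1_vs_rev2 = NULL)
  structure(list(n_runs = n_runs, learner_count = sum(learner),
                 learner = learner, ttc = ttc, phase_rates = phase_rates,
                 seeds = run_seeds, tests = tests),
            class = "group_result")
}

#' Write a trial log as CSV
#'
#' @param result A `run_result`.
#' @param path Output file.
#' @param run_id Identifier written into the `run_id` column.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(result, path, run_id = result$seed) {
  df <- cbind(run_id = run_id, result$trials)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
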