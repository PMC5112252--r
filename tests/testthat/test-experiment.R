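# Experiment-level tests run a reduced protocol (fewer trials) where the
# full 3 x 160 schedule is not required for the property under test.

short_config <- function(dcn = FALSE, trials = 12) {
  cfg <- default_config(dcn = dcn)
  cfg$task$trials_per_phase <- trials
  cfg
}

test_that("a single trial populates the record and updates state", {
  set.seed(21)
  obj <- revlearn:::config_objects(default_config(dcn = TRUE))
  net <- build_network(obj$spec)
  dcn <- dcn_init(3, obj$dp, obj$up)
  vel <- make_velocity(net$conn)
  cont <- make_contingency(1, 0)
  out <- run_trial(net$conn, net$layout, dcn, vel, stim_id = 5, cont,
                   obj$up, obj$lp, obj$dp)
  rec <- out$record
  expect_true(rec$action %in% 1:2)
  expect_true(rec$expert %in% 1:3)
  expect_true(rec$q_a >= -obj$up$zeta && rec$q_a <= obj$up$beta)
  expect_equal(rec$delta, rec$rho - rec$q_a)
  expect_equal(rec$correct, rec$rho == obj$lp$reward_correct)
  expect_false(identical(out$conn$w_ex, net$conn$w_ex))  # learning happened
  expect_silent(validate_connection_set(out$conn))
})

test_that("runs are reproducible bit-for-bit from the seed", {
  a <- suppressWarnings(run_experiment(short_config(dcn = TRUE), seed = 42))
  b <- suppressWarnings(run_experiment(short_config(dcn = TRUE), seed = 42))
  expect_identical(a$trials, b$trials)
  c <- suppressWarnings(run_experiment(short_config(dcn = TRUE), seed = 43))
  expect_false(identical(a$trials, c$trials))
})

test_that("the trial log covers the full reversal schedule", {
  res <- suppressWarnings(run_experiment(short_config(trials = 10)))
  expect_equal(nrow(res$trials), 30)
  expect_equal(res$trials$phase, rep(0:2, each = 10))
  expect_equal(res$trials$delta, res$trials$rho - res$trials$q_a)
  # monolithic variant: the expert column is constant
  expect_equal(unique(res$trials$expert), 1L)
})

test_that("both variants share the stimulus sequence for the same seed", {
  a <- suppressWarnings(run_experiment(short_config(dcn = FALSE), seed = 7))
  b <- suppressWarnings(run_experiment(short_config(dcn = TRUE), seed = 7))
  expect_identical(a$trials$stimulus_id, b$trials$stimulus_id)
})

test_that("group summaries aggregate learners and phase comparisons", {
  g <- run_group(short_config(trials = 8), n_runs = 3, seed = 5)
  expect_equal(g$n_runs, 3)
  expect_equal(dim(g$ttc), c(3, 3))
  expect_equal(g$learner_count, sum(g$learner))
  expect_true(all(g$phase_rates >= 0 & g$phase_rates <= 1))
  # reproducible from the master seed
  g2 <- run_group(short_config(trials = 8), n_runs = 3, seed = 5)
  expect_identical(g$ttc, g2$ttc)
})

test_that("trial logs round-trip through CSV for external analysis", {
  res <- suppressWarnings(run_experiment(short_config(trials = 8), seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(res, path, run_id = "r1")
  back <- read.csv(path)
  expect_equal(nrow(back), 24)
  expect_true(all(c("run_id", "trial", "phase", "stimulus_id", "expert",
                    "action", "q_a", "rho", "delta", "correct") %in%
                    names(back)))
  m <- analyze_trial_log(back, block_size = 8)
  expect_length(m$phase_rates, 3)
})

test_that("training beats chance within the first learning phase", {
  # average final-block rate over several seeds after one phase of learning
  cfg <- default_config(dcn = TRUE)
  cfg$task$trials_per_phase <- 160
  cfg$task$n_phases <- 1
  final_block <- vapply(1:5, function(s) {
    res <- suppressWarnings(run_experiment(cfg, seed = 200 + s))
    tail(res$metrics$block_rates$phase0, 1)
  }, numeric(1))
  expect_gt(mean(final_block), 0.5)
})

test_that("basis similarity is a valid correlation structure", {
  set.seed(77)
  net <- build_network(architecture_spec(n_experts = 1))
  sim <- basis_similarity(net$conn, net$layout)
  expect_equal(dim(sim$cor), c(32, 32))
  expect_equal(diag(sim$cor), rep(1, 32), tolerance = 1e-12)
  expect_true(isSymmetric(sim$cor))
  expect_true(all(abs(sim$cor) <= 1 + 1e-12))
  rel <- stimulus_pair_relations(1)
  expect_equal(nrow(rel), choose(32, 2))
  expect_equal(sum(rel$relation == "irrelevant"), 4 * choose(8, 2))
  expect_equal(sum(rel$relation == "different_action"), 8 * 24)
})

test_that("category structure before training reflects input geometry only", {
  # same-category stimuli share two attributes, so even an untrained network
  # shows a small positive within-minus-across correlation difference; it
  # must stay far below the separation a trained network develops.
  diffs <- vapply(1:4, function(s) {
    set.seed(300 + s)
    net <- build_network(architecture_spec(n_experts = 1))
    sim <- basis_similarity(net$conn, net$layout)
    rel <- stimulus_pair_relations(1)
    cv <- sim$cor[cbind(rel$i, rel$j)]
    mean(cv[rel$relation == "irrelevant"]) -
      mean(cv[rel$relation == "different_action"])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.2)
})

test_that("configuration files merge over the defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("learning:", "  eta: 0.5", "task:", "  trials_per_phase: 20"),
             path)
  cfg <- read_config(path)
  expect_equal(cfg$learning$eta, 0.5)
  expect_equal(cfg$task$trials_per_phase, 20)
  expect_equal(cfg$learning$momentum, 0.9)  # untouched default
  pj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"dcn": {"enabled": false}}', pj)
  cfg2 <- read_config(pj)
  expect_false(cfg2$dcn$enabled)
  expect_equal(cfg2$architecture$n_experts, 1)
})
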