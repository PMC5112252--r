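test_that("softmax probabilities match direct evaluation", {
  expect_equal(action_probabilities(c(0.4, 0.25), tau = 0.15),
               c(1 / (1 + exp(-1)), 1 - 1 / (1 + exp(-1))))
  expect_equal(action_probabilities(c(1, 1), tau = 0.5), c(0.5, 0.5))
  # low-temperature limit approaches argmax
  pr <- action_probabilities(c(0.4, 0.25), tau = 1e-4)
  expect_gt(pr[1], 1 - 1e-10)
  # numerically stable for large values
  expect_equal(sum(action_probabilities(c(500, 499), tau = 0.15)), 1)
  expect_error(action_probabilities(numeric(0)), "empty")
  expect_error(action_probabilities(1, tau = 0), "tau")
})

test_that("sampled actions follow the softmax distribution", {
  set.seed(42)
  draws <- replicate(10000, select_action(c(0.3, 0.3), tau = 0.15))
  # symmetric values: binomial check at 4 sigma
  expect_lt(abs(mean(draws == 1) - 0.5), 4 * sqrt(0.25 / 10000))
  draws2 <- replicate(5000, select_action(c(0.4, 0.25), tau = 0.15))
  p1 <- 1 / (1 + exp(-1))
  expect_lt(abs(mean(draws2 == 1) - p1), 4 * sqrt(p1 * (1 - p1) / 5000))
})

test_that("prediction error is the exact difference", {
  expect_identical(prediction_error(0.4, 0.4), 0)
  expect_equal(prediction_error(0.4, 0.1), 0.3)
  expect_identical(prediction_error(0, 0.4), -0.4)
})

test_that("plasticity factors evaluate the per-type expressions", {
  up <- unit_params()   # beta = zeta = 1, gamma = 4
  st <- structure(list(p = c(0.5, 0.2), i_ex = c(0, 1), i_inh = c(0, 0),
                       i_mod = c(0, 0.25)), class = "network_state")
  f <- plasticity_factors(st, up)
  expect_equal(f$ex, c(0.5, 0.8 * 2))      # (b - p)(1 + g Imod)
  expect_equal(f$mod, c(0, 4 * 0.8 * 1))   # g (b - p) Iex
  expect_equal(f$inh, c(-1.5, -1.2))       # -(z + p)
})

test_that("weight updates follow the three-factor rule with momentum", {
  up <- unit_params(); lp <- learning_params(eta = 0.2, momentum = 0.9)
  w <- zero_mat(2); w[1, 2] <- 0.8
  conn <- small_conn(w_ex = w, n = 2, w_inp = matrix(c(1, 0), 1, 2))
  st <- relax_network(conn, 1, up, tol = 1e-10)
  acc <- propagate_accessory(conn, st, up, 2)
  vel <- make_velocity(conn)
  delta <- 0.3
  out <- update_weights(conn, st, acc, delta, lp, vel, i_inp = 1, up)
  f <- plasticity_factors(st, up)
  raw <- delta * st$r[1] * acc$delta_p[2] * f$ex[2]
  expect_equal(out$conn$w_ex[1, 2], 0.8 + lp$eta * raw)
  expect_equal(out$velocity$w_ex[1, 2], raw)
  # second call accumulates momentum
  out2 <- update_weights(out$conn, st, acc, delta, lp, out$velocity, 1, up)
  expect_equal(out2$velocity$w_ex[1, 2], lp$momentum * raw + raw)

  # zero error with zero velocity leaves weights unchanged
  out0 <- update_weights(conn, st, acc, 0, lp, make_velocity(conn), 1, up)
  expect_equal(out0$conn$w_ex, conn$w_ex)
  expect_equal(out0$conn$w_inp, conn$w_inp)
})

test_that("updates conserve masks and weight bounds", {
  up <- unit_params(); lp <- learning_params(eta = 0.5, momentum = 0.9)
  set.seed(31)
  for (rep in 1:5) {
    conn <- random_conn(8, scale = 0.5)
    vel <- make_velocity(conn)
    for (t in 1:30) {
      i_inp <- runif(3)
      st <- relax_network(conn, i_inp, up)
      acc <- propagate_accessory(conn, st, up, sample(8, 1))
      acc$delta_p <- 20 * acc$delta_p   # exaggerate to stress the bounds
      out <- update_weights(conn, st, acc, runif(1, -0.4, 0.4), lp, vel,
                            i_inp, up)
      conn <- out$conn; vel <- out$velocity
    }
    expect_silent(validate_connection_set(conn))
  }
})

test_that("a repeated rewarded trial reduces the prediction error", {
  up <- unit_params()
  lp <- learning_params(eta = 0.01, momentum = 0, accessory_gain = 1)
  set.seed(9)
  conn <- random_conn(10)
  vel <- make_velocity(conn)
  i_inp <- c(1, 0.5, 0)
  a <- 10
  st1 <- relax_network(conn, i_inp, up)
  d1 <- prediction_error(0.4, st1$p[a])
  acc <- propagate_accessory(conn, st1, up, a)
  out <- update_weights(conn, st1, acc, d1, lp, vel, i_inp, up)
  st2 <- relax_network(out$conn, i_inp, up)
  d2 <- prediction_error(0.4, st2$p[a])
  expect_lt(abs(d2), abs(d1))
})

test_that("positive error never weakens the direct path to the winner", {
  up <- unit_params(); lp <- learning_params(momentum = 0)
  set.seed(13)
  conn <- random_conn(6)
  conn$w_ex[2, 5] <- 0.3; conn$mask_ex[2, 5] <- 1
  i_inp <- c(1, 1, 0.5)
  st <- relax_network(conn, i_inp, up)
  acc <- propagate_accessory(conn, st, up, 5)
  out <- update_weights(conn, st, acc, 0.3, lp, make_velocity(conn),
                        i_inp, up)
  expect_gte(out$conn$w_ex[2, 5], conn$w_ex[2, 5])
})
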