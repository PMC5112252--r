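test_that("layout partitions units disjointly and completely", {
  spec <- architecture_spec()
  lay <- network_layout(spec)
  all_units <- c(lay$basis1, lay$basis2, unlist(lay$assoc), unlist(lay$motor))
  expect_equal(sort(all_units), seq_len(lay$n_units))
  expect_equal(lay$n_units, 200 + 3 * 50)
  expect_length(lay$basis1, 100)
  expect_length(lay$basis2, 100)
  for (e in 1:3) {
    expect_length(lay$assoc[[e]], 48)
    expect_length(lay$motor[[e]], 2)
    expect_length(lay$experts[[e]], 50)
  }
})

test_that("no mask permits any connection between different experts", {
  set.seed(7)
  net <- build_network(architecture_spec())
  lay <- net$layout
  for (e1 in 1:3) for (e2 in 1:3) {
    if (e1 == e2) next
    u1 <- lay$experts[[e1]]; u2 <- lay$experts[[e2]]
    for (m in list(net$conn$mask_ex, net$conn$mask_inh, net$conn$mask_mod))
      expect_true(all(m[u1, u2] == 0))
  }
})

test_that("pathway structure matches the hierarchy", {
  set.seed(8)
  net <- build_network(architecture_spec())
  lay <- net$layout; conn <- net$conn
  # input reaches only basis layer 1
  expect_true(all(conn$mask_inp[, -lay$basis1] == 0))
  expect_true(all(colSums(conn$mask_inp[, lay$basis1]) > 0))
  # basis layer 1 receives no recurrent excitation or inhibition
  expect_true(all(conn$mask_ex[, lay$basis1] == 0))
  expect_true(all(conn$mask_inh[, lay$basis1] == 0))
  # modulatory feedback only along driven pathways: L2 -> L1, assoc -> L2
  expect_true(all(conn$mask_mod[lay$basis1, ] == 0))
  expect_true(all(conn$mask_mod[unlist(lay$motor), ] == 0))
  expect_true(all(conn$mask_mod[lay$basis2, setdiff(seq_len(lay$n_units),
                                                    lay$basis1)] == 0))
  # motor units receive only from their own association layer
  for (e in 1:3) {
    others <- setdiff(seq_len(lay$n_units), lay$assoc[[e]])
    expect_true(all(conn$mask_ex[others, lay$motor[[e]]] == 0))
    expect_true(all(conn$mask_inh[others, lay$motor[[e]]] == 0))
  }
  # motor units send nothing
  for (m in list(conn$mask_ex, conn$mask_inh, conn$mask_mod))
    expect_true(all(m[unlist(lay$motor), ] == 0))
  # no self-inhibition in the layer-2 competition
  expect_true(all(diag(conn$mask_inh)[lay$basis2] == 0))
})

test_that("initial weights respect the per-class uniform ranges", {
  set.seed(9)
  net <- build_network(architecture_spec())
  conn <- net$conn; lay <- net$layout
  motor_cols <- unlist(lay$motor)
  nonmotor <- setdiff(seq_len(lay$n_units), motor_cols)
  expect_lte(max(conn$w_mod), 0.1)
  expect_lte(max(conn$w_ex[, motor_cols], conn$w_inh[, motor_cols]), 0.3)
  expect_lte(max(conn$w_ex[, nonmotor], conn$w_inh[, nonmotor],
                 conn$w_inp), 0.2)
  expect_gte(min(conn$w_ex, conn$w_inh, conn$w_mod, conn$w_inp), 0)
  # motor afferents actually use the wider range (with high probability)
  expect_gt(max(conn$w_ex[, motor_cols]), 0.2)
  expect_silent(validate_connection_set(conn))
})

test_that("fan-in limits hold per target unit", {
  set.seed(10)
  spec <- architecture_spec(fan_in = 5, fan_input = 2)
  net <- build_network(spec)
  lay <- net$layout
  expect_true(all(colSums(net$conn$mask_inp[, lay$basis1]) == 2))
  expect_true(all(colSums(net$conn$mask_ex[, lay$basis2]) == 5))
  # layer-2 inhibition: feedforward block plus lateral block
  expect_true(all(colSums(net$conn$mask_inh[, lay$basis2]) == 10))
})

test_that("network construction is deterministic given the seed", {
  set.seed(123); a <- build_network(architecture_spec())
  set.seed(123); b <- build_network(architecture_spec())
  expect_identical(a$conn, b$conn)
})

test_that("single-expert build is the degenerate case of the extended one", {
  set.seed(11)
  mono <- build_network(architecture_spec(n_experts = 1))
  expect_equal(mono$layout$n_units, 250)
  expect_length(mono$layout$motor, 1)
  ext_lay <- network_layout(architecture_spec(n_experts = 3))
  # identical unit count and block topology for basis + first expert
  expect_identical(mono$layout$basis1, ext_lay$basis1)
  expect_identical(mono$layout$basis2, ext_lay$basis2)
  expect_identical(mono$layout$assoc[[1]], ext_lay$assoc[[1]])
  expect_identical(mono$layout$motor[[1]], ext_lay$motor[[1]])
})

test_that("invalid specifications are rejected", {
  expect_error(architecture_spec(n_experts = 0), "expert")
  expect_error(architecture_spec(n_basis = c(10, 0)), "layer sizes")
  expect_error(architecture_spec(fan_in = 0), "fan-in")
})
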