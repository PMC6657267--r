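test_that("step_cell executes the reaction templates", {
  ord <- two_comp_order()
  prm <- open_params()
  s0 <- cell_state(c(0, 0))
  # asymmetric division with a forced driver on locus 1
  ds <- step_cell(s0, prm, ord, action = "asym", mutation = "driver", locus = 1)
  expect_equal(ds[[1]], cell_state(c(1, 0), m_n = 0, m_m = 1, k = 1))
  expect_equal(ds[[2]], cell_state(c(0, 0), m_n = 0, m_m = 1, k = 1))
  # symmetric non-driver: two identical mutated daughters
  ds <- step_cell(s0, prm, ord, action = "sym", mutation = "nondriver")
  expect_equal(ds[[1]], ds[[2]])
  expect_equal(ds[[1]]$m_n, 1L)
  expect_equal(ds[[1]]$m_m, 1L)
  # apoptosis annihilates
  expect_length(step_cell(s0, prm, ord, action = "apop"), 0)
  # migration preserves mutations, increments the compartment
  s1 <- cell_state(c(1, 0), m_n = 1, m_m = 2, k = 1)
  ds <- step_cell(s1, prm, ord, action = "pass")
  expect_equal(ds[[1]], cell_state(c(1, 0), m_n = 1, m_m = 2, k = 2))
  expect_error(step_cell(s0, prm, ord, action = "pass"), "cannot migrate")
})

test_that("event log conserves the population count", {
  cfg <- simulation_config(t_end = 1.2, initial_cells = 6, record_dt = 0.3)
  run <- run_replicate(cfg, open_params(), two_comp_order(),
                       keep_log = TRUE, seed = 21)
  lg <- run$log
  net <- c(asym = 1, sym = 1, apop = -1, pass = 0, rejected = 0, drug_kill = -1)
  expect_equal(6 + sum(net[lg$action]), run$population)
  # running sum never goes negative
  expect_true(all(cumsum(c(6, net[lg$action])) >= 0))
})

test_that("mutation clocks are monotone along parent-daughter chains", {
  cfg <- simulation_config(t_end = 1.5, initial_cells = 6, record_dt = 0.5)
  run <- run_replicate(cfg, open_params(), two_comp_order(),
                       keep_log = TRUE, seed = 22)
  lg <- run$log
  div <- lg[lg$action %in% c("asym", "sym"), ]
  expect_gt(nrow(div), 0)
  expect_true(all(div$d1_mm == div$p_mm + 1))
  expect_true(all(div$d2_mm == div$p_mm + 1))
  expect_true(all(div$d1_mn >= div$p_mn))
  # driver masks only gain bits
  expect_true(all(bitwAnd(div$d1_mask, div$p_mask) == div$p_mask))
  mig <- lg[lg$action == "pass", ]
  if (nrow(mig)) expect_true(all(mig$d1_k == mig$p_k + 1))
  expect_true(all(diff(lg$time) >= 0))
})

test_that("capacity and energy bounds are never exceeded", {
  ord <- two_comp_order()
  en <- energy_model(capacity = 5)
  cfg <- simulation_config(t_end = 2.5, initial_cells = 5, record_dt = 0.25)
  run <- run_replicate(cfg, open_params(), ord, en, seed = 31)
  expect_true(all(run$counts <= 5))
  # energy budget: unit needs cap the total compartment population
  en2 <- energy_model(e = rep(1, 3), E_max = 8)
  run2 <- run_replicate(cfg, open_params(), ord, en2, seed = 31)
  expect_true(all(apply(run2$counts, c(1, 2), sum) <= 8))
})

test_that("ensembles are reproducible and degenerate correctly at R = 1", {
  ord <- two_comp_order()
  cfg <- simulation_config(t_end = 1, initial_cells = 8, record_dt = 0.25,
                           replicates = 3, seed = 5)
  e1 <- run_ensemble(cfg, open_params(), ord)
  e2 <- run_ensemble(cfg, open_params(), ord)
  expect_identical(e1$counts, e2$counts)
  cfg1 <- simulation_config(t_end = 1, initial_cells = 8, record_dt = 0.25,
                            replicates = 1, seed = 5)
  es <- run_ensemble(cfg1, open_params(), ord)
  expect_equal(es$mean, es$counts[1, , , ])
  expect_true(all(es$sd == 0))
})

test_that("an all-zero drug signature empties the population at t_drug", {
  ord <- two_comp_order()
  sig0 <- drug_signature(d = c(0, 0), time = 0.6)
  cfg <- simulation_config(t_end = 1.2, initial_cells = 10, record_dt = 0.2,
                           drug = sig0)
  run <- run_replicate(cfg, open_params(), ord, seed = 8)
  after <- run$times >= 0.6
  expect_true(all(apply(run$counts[after, , , drop = FALSE], 1, sum) == 0))
  expect_true(any(apply(run$counts[!after, , , drop = FALSE], 1, sum) > 0))
  expect_equal(run$post_drug_match, 0L)
  expect_true(run$extinct)
})

test_that("the drug leaves the pre-administration trajectory untouched", {
  ord <- two_comp_order()
  sig <- drug_signature(d = c(1, 0), k = 1, time = 0.8)
  cfg_d <- simulation_config(t_end = 1.6, initial_cells = 10, record_dt = 0.2,
                             drug = sig)
  cfg_n <- simulation_config(t_end = 1.6, initial_cells = 10, record_dt = 0.2)
  rd <- run_replicate(cfg_d, open_params(), ord, seed = 77)
  rn <- run_replicate(cfg_n, open_params(), ord, seed = 77)
  before <- rd$times < 0.8
  expect_identical(rd$counts[before, , ], rn$counts[before, , ])
})

test_that("extinction under certain apoptosis matches the exponential law", {
  ord <- two_comp_order()
  prm <- pure_death_params(m_d = 2)
  cfg <- simulation_config(t_end = 2, initial_cells = 30, record_dt = 0.5,
                           replicates = 100, seed = 13)
  ens <- run_ensemble(cfg, prm, ord)
  tot <- apply(ens$counts, c(1, 2), sum)       # replicate x time totals
  m <- colMeans(tot)
  se <- apply(tot, 2, stats::sd) / sqrt(nrow(tot))
  expected <- 30 * exp(-ens$times)
  expect_true(all(abs(m - expected) <= 3 * pmax(se, 1e-9) + 1e-9))
  # absorbing: once extinct, stays extinct
  for (r in seq_len(nrow(tot)))
    expect_true(all(diff(tot[r, ] > 0) <= 0))
})
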