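test_that("stemness follows s_bar * m_d / sqrt(1 + m_n), clipped to [0, s_bar]", {
  expect_equal(stemness(0, 5), 0)
  expect_equal(stemness(3, 8, s_bar = 1), 1)           # 3/sqrt(9)
  expect_equal(stemness(2, 0, s_bar = 1, clip = FALSE), 2)
  expect_equal(stemness(2, 0, s_bar = 1), 1)           # clipped
  expect_equal(stemness(1, 3, s_bar = 2), 1)           # 2 * 1/2
  # strict monotonicity on the unclipped surface
  grid_d <- 0:6; grid_n <- 0:10
  s <- outer(grid_d, grid_n, function(d, n) stemness(d, n, s_bar = 1, clip = FALSE))
  expect_true(all(diff(s) > 0))                        # increasing in m_d
  expect_true(all(t(diff(t(s[-1, ]))) < 0))            # decreasing in m_n
})

test_that("support windows are closed symmetric intervals", {
  expect_equal(chi_support(0.5, 0.5, 0.4), 1L)
  expect_equal(chi_support(0.7, 0.5, 0.4), 1L)   # boundary included
  expect_equal(chi_support(0.9, 0.5, 0.4), 0L)
  expect_equal(chi_support(0.3, 0.5, 0.4), 1L)
  expect_equal(chi_support(0.29, 0.5, 0.4), 0L)
  expect_error(chi_support(0, 0, -1), "width")
})

test_that("action probabilities normalize and respect the filters", {
  ord <- two_comp_order()
  # stemness 0 inside only the apoptosis support -> certain apoptosis
  p_apop <- kinetics_params(1, 1, c(asym = 1, sym = 1, apop = 1, pass = 1),
                            c(asym = -0.8, sym = -0.5, apop = 0), 0.2, 1,
                            bounds = list(m_d = 2, m_n = 2, m_m = 4))
  pr <- action_probabilities(cell_state(c(0, 0)), p_apop, ord)
  expect_equal(unname(pr), c(0, 0, 1, 0))
  # equal numerators split evenly between division and migration
  p_eq <- kinetics_params(1, 1, c(asym = 1, sym = 0, apop = 0, pass = 1),
                          c(asym = 0.9, sym = 0.95, apop = 0.99), 0.5, 1,
                          bounds = list(m_d = 2, m_n = 2, m_m = 4))
  st <- cell_state(c(1, 0), k = 1)     # s = 1, can migrate
  pr <- action_probabilities(st, p_eq, ord)
  expect_equal(unname(pr[c("asym", "pass")]), c(0.5, 0.5))
  # a state with no available action is reported as stuck
  expect_error(action_probabilities(cell_state(c(0, 0)), p_eq, ord), "stuck")
})

test_that("action probabilities sum to one over random states and parameters", {
  set.seed(123)
  for (i in 1:60) {
    ctr <- sort(runif(3, -0.5, 0.9))
    if (any(diff(ctr) == 0)) next
    prm <- kinetics_params(
      alpha = runif(1, 0.1, 3), r = runif(1, 0.5, 5),
      amplitudes = c(asym = runif(1), sym = runif(1), apop = runif(1),
                     pass = runif(1)),
      centers = c(asym = ctr[1], sym = ctr[2], apop = ctr[3]),
      width = runif(1, 0.5, 3), s_bar = 1, beta = runif(1, 0.2, 5),
      bounds = list(m_d = 3, m_n = 6, m_m = 8))
    ord <- driver_order_spec(list(1L, 2:3)); ord$ordered <- runif(1) < 0.5
    for (j in 1:10) {
      st <- cell_state(sample(0:1, 3, TRUE), m_n = sample(0:6, 1),
                       m_m = sample(0:8, 1), k = sample(1:2, 1))
      pr <- tryCatch(action_probabilities(st, prm, ord), error = function(e) NULL)
      if (is.null(pr)) next   # stuck states are legitimately rejected
      expect_equal(sum(pr), 1, tolerance = 1e-12)
      expect_true(all(pr >= 0))
      if (!can_migrate(st, ord)) expect_equal(unname(pr["pass"]), 0)
    }
  }
})

test_that("waiting times are exponential with rate alpha * (r + m_m)", {
  prm <- open_params()
  set.seed(99)
  x <- sample_waiting_time(3, prm, n = 2e4)
  expect_equal(mean(x), 0.25, tolerance = 3 * 0.25 / sqrt(2e4) / 0.25)
  # metabolic acceleration: mean strictly decreases with m_m
  means <- vapply(0:4, function(mm) mean(sample_waiting_time(mm, prm, n = 2e4)), 0)
  expect_true(all(diff(means) < 0))
})

test_that("mutation split weighs the remaining loci", {
  prm <- kinetics_params(1, 1, c(asym = 1, sym = 1, apop = 1, pass = 1),
                         c(asym = 0.2, sym = 0.5, apop = 0.8), 2, 1, beta = 1,
                         bounds = list(m_d = 4, m_n = 10, m_m = 10))
  expect_equal(unname(mutation_split(cell_state(c(1, 0, 0, 0), m_n = 4), prm)),
               c(3 / 9, 6 / 9))
  expect_equal(unname(mutation_split(4, prm, m_n = 3)), c(0, 1))
  expect_equal(unname(mutation_split(2, prm, m_n = 10)), c(1, 0))
  expect_equal(sum(mutation_split(1, prm, m_n = 7)), 1)
  expect_error(mutation_split(4, prm, m_n = 10), "exhausted")
})

test_that("parameter validation rejects broken configurations", {
  amp <- c(asym = 1, sym = 1, apop = 1, pass = 1)
  b <- list(m_d = 2, m_n = 2, m_m = 2)
  expect_error(kinetics_params(1, 1, amp, c(asym = 0.5, sym = 0.2, apop = 0.8),
                               1, 1, bounds = b), "c_asym < c_sym < c_apop")
  expect_error(kinetics_params(1, 1, amp, c(asym = 0.2, sym = 0.5, apop = 1.2),
                               1, 1, bounds = b), "c_asym < c_sym < c_apop")
  expect_error(kinetics_params(-1, 1, amp, c(asym = 0.2, sym = 0.5, apop = 0.8),
                               1, 1, bounds = b), "alpha")
  expect_error(kinetics_params(1, 1, amp[-1], c(asym = 0.2, sym = 0.5, apop = 0.8),
                               1, 1, bounds = b), "amplitudes")
})

test_that("compartment energy is the e(j)-weighted cell count", {
  expect_equal(compartment_energy(numeric(0), energy_model()), 0)
  m1 <- energy_model(e = rep(1, 5))
  expect_equal(compartment_energy(c(3, 2, 1, 0, 4), m1), 10)
  m2 <- energy_model(e = c(1, 2))
  expect_equal(compartment_energy(c(10, 5), m2), 20)
  expect_error(energy_model(e = c(-1, 2)), ">= 0")
  expect_error(energy_model(capacity = 0), "positive")
})
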