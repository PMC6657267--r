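test_that("effective drivers follow the block-prefix rule", {
  ord <- bcb_order()
  # EPCAM alone unlocks breast exit
  expect_equal(effective_drivers(c(1, 0, 0, 0), ord), 1L)
  # everything but EPCAM: all drivers silent
  expect_equal(effective_drivers(c(0, 1, 1, 1), ord), 0L)
  # MET acquired out of order stays silent; unordered counts it
  expect_equal(effective_drivers(c(1, 0, 0, 1), ord), 1L)
  expect_equal(effective_drivers(c(1, 0, 0, 1), bcb_order(ordered = FALSE)), 2L)
  # within-block order is irrelevant
  expect_equal(effective_drivers(c(1, 1, 0, 0), ord),
               effective_drivers(c(1, 0, 1, 0), ord))
  expect_error(effective_drivers(c(1, 0), ord), "length")
})

test_that("effective drivers agree with the activation oracle and are monotone", {
  set.seed(42)
  for (rep in 1:5) {
    m <- sample(3:6, 1)
    cuts <- sort(sample(seq_len(m - 1), sample(1:(m - 1), 1)))
    blocks <- unname(split(seq_len(m), findInterval(seq_len(m), cuts + 1)))
    ord <- driver_order_spec(blocks)
    vecs <- all_driver_vectors(m)
    for (i in seq_len(nrow(vecs))) {
      d <- as.integer(vecs[i, ])
      m_e <- effective_drivers(d, ord)
      expect_identical(m_e, as.integer(oracle_effective(d, ord)))
      expect_lte(m_e, sum(d))
      # acquiring any extra driver never decreases m_e
      for (j in which(d == 0L)) {
        d2 <- d; d2[j] <- 1L
        expect_gte(effective_drivers(d2, ord), m_e)
      }
      # unordered mode: m_e equals m_d
      uno <- ord; uno$ordered <- FALSE
      expect_equal(effective_drivers(d, uno), sum(d))
    }
  }
})

test_that("migration requires the compartment exit threshold", {
  ord <- bcb_order()
  expect_true(can_migrate(cell_state(c(1, 1, 1, 0), k = 2), ord))
  expect_false(can_migrate(cell_state(c(1, 1, 0, 0), k = 2), ord))
  # terminal bone compartment never emits migrants
  expect_false(can_migrate(cell_state(c(1, 1, 1, 1), k = 3), ord))
  # unordered: raw driver count against the same thresholds
  expect_true(can_migrate(cell_state(c(0, 1, 1, 1), k = 2), bcb_order(FALSE)))
})

test_that("drug matching disregards zero components and checks the rest", {
  sig3 <- drug_signature(d = c(0, 1, 0, 0), k = 2)
  expect_true(matches_drug(cell_state(c(1, 1, 0, 0), k = 2), sig3))
  expect_false(matches_drug(cell_state(c(1, 0, 1, 0), k = 2), sig3))
  expect_false(matches_drug(cell_state(c(1, 1, 0, 0), k = 1), sig3))
  # all-zero signature matches everything
  sig0 <- drug_signature(d = c(0, 0, 0, 0))
  expect_true(matches_drug(cell_state(c(0, 0, 0, 0)), sig0))
  expect_true(matches_drug(cell_state(c(1, 0, 1, 1), m_n = 5, m_m = 9, k = 3), sig0))
  # case 1: driver-count component
  sig1 <- drug_signature(d = c(0, 0, 0, 0), k = 2, m_d = 1)
  expect_false(matches_drug(cell_state(c(1, 1, 0, 0), k = 2), sig1))
  expect_true(matches_drug(cell_state(c(0, 0, 1, 0), k = 2), sig1))
})

test_that("adding signature components weakly shrinks the matched set", {
  set.seed(7)
  ord <- bcb_order()
  states <- lapply(1:60, function(i)
    cell_state(sample(0:1, 4, replace = TRUE), m_n = sample(0:4, 1),
               m_m = sample(0:6, 1), k = sample(1:3, 1)))
  base <- drug_signature(d = c(0, 0, 0, 0))
  n0 <- sum(vapply(states, matches_drug, TRUE, sig = base))
  expect_equal(n0, 60L)
  for (i in 1:20) {
    d <- integer(4); d[sample(4, sample(0:2, 1))] <- 1L
    sig <- drug_signature(d = d, k = sample(0:3, 1), m_d = sample(0:3, 1))
    n <- sum(vapply(states, matches_drug, TRUE, sig = sig))
    expect_lte(n, n0)
  }
})

test_that("targeted fractions match brute-force enumeration", {
  set.seed(11)
  for (rep in 1:4) {
    m <- sample(3:5, 1)
    cuts <- sort(sample(seq_len(m - 1), sample(1:(m - 1), 1)))
    blocks <- unname(split(seq_len(m), findInterval(seq_len(m), cuts + 1)))
    for (ordered in c(TRUE, FALSE)) {
      ord <- driver_order_spec(blocks); ord$ordered <- ordered
      d_sig <- integer(m); d_sig[sample(m, sample(0:2, 1))] <- 1L
      comp <- sample(seq_len(ord$n_compartments), 1)
      sig <- drug_signature(d = d_sig, k = comp)
      for (md in 1:m) {
        fr <- fraction_targeted(sig, ord, md, comp)
        # oracle: filter all binary vectors directly
        vecs <- all_driver_vectors(m)
        vecs <- vecs[rowSums(vecs) == md, , drop = FALSE]
        req <- if (comp >= 2) ord$exit_threshold[comp - 1] else 0L
        viable <- apply(vecs, 1, function(d) oracle_effective(as.integer(d), ord) >= req)
        match <- viable & apply(vecs, 1, function(d) all(d[d_sig == 1L] == 1L))
        expect_equal(fr$denominator, sum(viable))
        expect_equal(fr$numerator, sum(match))
      }
    }
  }
})

test_that("no viable combination gives the explicit empty-domain result", {
  ord <- bcb_order()
  # one driver cannot have entered the bone compartment
  fr <- fraction_targeted(drug_signature(d = rep(0L, 4)), ord, m_d = 1, compartment = 3)
  expect_equal(fr$denominator, 0L)
  expect_true(is.na(fr$value))
})

test_that("state and spec constructors validate their invariants", {
  expect_error(cell_state(c(0, 2)), "binary")
  expect_error(cell_state(c(0, 1), m_n = -1), "non-negative")
  expect_error(driver_order_spec(list(1:2, 2:3)), "partition")
  expect_error(driver_order_spec(list(c("A", "B")), genes = "A"), "not all found")
  expect_error(drug_signature(c(0, 1), m_d = -1), "non-negative")
})
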