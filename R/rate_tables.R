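# Precomputed lookup tables over the (driver-mask, m_n, k) sub-space.
# The action probabilities do not depend on m_m (the metabolic count only
# sets the clock rate), so the whole kinetics of a scenario collapses to a
# table of n_mask * (m_n_bar+1) * k_bar rows shared by the event-driven
# simulator and the master-equation generator.

.rate_tables <- function(params, order) {
  mdb <- params$bounds$m_d
  mnb <- params$bounds$m_n
  mmb <- params$bounds$m_m
  kb <- order$n_compartments
  if (order$m_d_bar != mdb)
    stop(sprintf("bounds declare %d driver loci but the order spec has %d",
                 mdb, order$m_d_bar))
  n_mask <- bitwShiftL(1L, mdb)
  masks <- seq_len(n_mask) - 1L

  bitvals <- if (mdb) bitwShiftL(1L, seq_len(mdb) - 1L) else integer(0)
  bitmat <- matrix(0L, n_mask, max(mdb, 1L))
  for (j in seq_len(mdb))
    bitmat[, j] <- as.integer(bitwAnd(masks, bitvals[j]) != 0L)
  m_d_of <- as.integer(rowSums(bitmat[, seq_len(mdb), drop = FALSE]))
  m_e_of <- vapply(seq_len(n_mask), function(i)
    as.integer(effective_drivers(bitmat[i, seq_len(mdb)], order)), integer(1))
  zero_bits <- lapply(seq_len(n_mask), function(i)
    bitvals[bitmat[i, seq_len(mdb)] == 0L])

  # migration filter k_pass per (mask, k)
  mig <- matrix(0, n_mask, kb)
  if (kb >= 2L)
    for (k in seq_len(kb - 1L))
      mig[, k] <- as.numeric(m_e_of >= order$exit_threshold[k])

  # stemness per (mask, m_n)
  s_mat <- outer(m_d_of, 0:mnb, function(md, mn) stemness(md, mn, params$s_bar))

  A <- params$amplitudes; ctr <- params$centers; w <- params$width
  n_rows <- n_mask * (mnb + 1L) * kb
  probs <- matrix(0, n_rows, 4L)
  colnames(probs) <- c("asym", "sym", "apop", "pass")
  row_of <- function(mask, mn, k) 1L + mask + n_mask * (mn + (mnb + 1L) * (k - 1L))
  for (k in seq_len(kb)) {
    for (mn in 0:mnb) {
      s <- s_mat[, mn + 1L]
      rows <- row_of(masks, mn, k)
      probs[rows, 1L] <- A[["asym"]] * chi_support(s, ctr[["asym"]], w)
      probs[rows, 2L] <- A[["sym"]]  * chi_support(s, ctr[["sym"]],  w)
      probs[rows, 3L] <- A[["apop"]] * chi_support(s, ctr[["apop"]], w)
      probs[rows, 4L] <- A[["pass"]] * mig[, k]
    }
  }
  tot <- rowSums(probs)
  stuck <- tot == 0
  probs[!stuck, ] <- probs[!stuck, , drop = FALSE] / tot[!stuck]
  cum <- t(apply(probs, 1L, cumsum))

  # driver-vs-nondriver split per (m_d, m_n); NA marks full exhaustion
  pdtab <- matrix(NA_real_, mdb + 1L, mnb + 1L)
  for (md in 0:mdb) for (mn in 0:mnb) {
    nd <- mdb - md; nn <- mnb - mn
    if (nd + nn > 0) pdtab[md + 1L, mn + 1L] <- nd / (nd + params$beta * nn)
  }

  list(n_mask = n_mask, mdb = mdb, mnb = mnb, mmb = mmb, kb = kb,
       m_d_of = m_d_of, m_e_of = m_e_of, zero_bits = zero_bits,
       probs = probs, cum = cum, stuck = stuck, row_of = row_of,
       pdtab = pdtab, lam = params$alpha * (params$r + 0:mmb))
}
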