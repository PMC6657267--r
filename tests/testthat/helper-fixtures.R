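# Shared builders for small test models.

bcb_order <- function(ordered = TRUE) {
  o <- driver_order_spec(list("EPCAM", c("CD47", "CD44"), "MET"))
  o$ordered <- ordered
  o
}

# wide overlapping supports: every action active at every stemness value
open_params <- function(m_d = 2, m_n = 2, m_m = 6,
                        A = c(asym = 1, sym = 0.6, apop = 0.3, pass = 0.8),
                        alpha = 1, r = 1, beta = 0.7) {
  kinetics_params(
    alpha = alpha, r = r, amplitudes = A,
    centers = c(asym = 0.25, sym = 0.5, apop = 0.75),
    width = 2, s_bar = 1, beta = beta,
    bounds = list(m_d = m_d, m_n = m_n, m_m = m_m))
}

# narrow supports so that the unmutated state (stemness 0) can only die
pure_death_params <- function(m_d = 1) {
  kinetics_params(
    alpha = 1, r = 1,
    amplitudes = c(asym = 1, sym = 1, apop = 1, pass = 1),
    centers = c(asym = -0.8, sym = -0.5, apop = 0),
    width = 0.2, s_bar = 1,
    bounds = list(m_d = m_d, m_n = 1, m_m = 2))
}

two_comp_order <- function(ordered = TRUE) {
  o <- driver_order_spec(list("g1", "g2"))
  o$ordered <- ordered
  o
}

# independent oracle for effective drivers: block i contributes its
# acquired loci iff all earlier blocks are fully acquired
oracle_effective <- function(d, order) {
  if (!order$ordered) return(sum(d))
  m_e <- 0L
  for (i in seq_along(order$blocks)) {
    earlier_complete <- all(unlist(lapply(seq_len(i - 1L), function(j)
      d[order$blocks[[j]] ] == 1L)))
    if (earlier_complete) m_e <- m_e + sum(d[order$blocks[[i]]])
  }
  m_e
}

all_driver_vectors <- function(m) {
  if (m == 0) return(matrix(integer(0), 1, 0))
  as.matrix(expand.grid(rep(list(0:1), m)))
}

fixture_path <- function(name) {
  p <- system.file("extdata", paste0(name, ".yaml"), package = "compclone")
  if (p == "") p <- file.path("..", "..", "inst", "extdata", paste0(name, ".yaml"))
  p
}
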