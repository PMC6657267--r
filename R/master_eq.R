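#' Dense index over the truncated cell state space
#'
#' Deterministic bijection between admissible states
#' `sigma = {d, m_n, m_m, k}` (within the declared bounds) and the integers
#' `1..n_states`, used to lay out the master-equation generator.  Driver
#' vectors are encoded as bit masks (locus j is bit j-1).
#'
#' @param m_d_bar,m_n_bar,m_m_bar,k_bar state-space bounds.
#' @return An object of class `state_index` with fields `n_states`,
#'   `encode(mask, m_n, m_m, k)`, `decode(i)` (data frame of components),
#'   and the bounds.
#' @export
state_index <- function(m_d_bar, m_n_bar, m_m_bar, k_bar) {
  n_mask <- bitwShiftL(1L, m_d_bar)
  dn <- m_n_bar + 1L; dm <- m_m_bar + 1L
  n_states <- n_mask * dn * dm * k_bar
  encode <- function(mask, m_n, m_m, k)
    1L + mask + n_mask * (m_n + dn * (m_m + dm * (k - 1L)))
  decode <- function(i) {
    i0 <- i - 1L
    mask <- i0 %% n_mask; i0 <- i0 %/% n_mask
    m_n <- i0 %% dn; i0 <- i0 %/% dn
    m_m <- i0 %% dm
    k <- i0 %/% dm + 1L
    data.frame(mask = mask, m_n = m_n, m_m = m_m, k = k)
  }
  structure(list(n_states = n_states, encode = encode, decode = decode,
                 m_d_bar = m_d_bar, m_n_bar = m_n_bar, m_m_bar = m_m_bar,
                 k_bar = k_bar, n_mask = n_mask),
            class = "state_index")
}

#' Build the master-equation generator
#'
#' Sparse linear operator `L` with `dp/dt = L p` for the expected
#' per-state counts on the truncated state space.
#'
#' `reaction_consistent` (the default, and the oracle used to validate the
#' simulator) derives the generator directly from the reaction set: each
#' division removes the parent and adds both daughters at `m_m + 1` (the
#' driver branch splits uniformly over the unacquired loci with the
#' driver/non-driver weights of [mutation_split]); apoptosis removes the
#' cell; migration moves it to `k + 1` at the filtered rate.  Outgoing
#' mutation flux at the `m_m`/`m_n`/`m_d` bounds is suppressed, mirroring
#' the simulator's event rejection.
#'
#' `as_printed` transcribes the published physical-time equation term for
#' term: gains carry the prefactor `alpha*(r + m_m - 1)` with the
#' `1/m_d_bar` locus weighting, losses carry `alpha*(r + m_m)` for
#' symmetric division, apoptosis and migration, and asymmetric division
#' contributes no loss term; the symmetric driver sum (written over the
#' metabolic index in the source) is taken over the driver loci.  It is
#' kept for fidelity to the printed equation rather than for consistency
#' with the reactions.
#'
#' Rates are the normalized action probabilities multiplying the metabolic
#' clock rate `alpha*(r + m_m)`.
#'
#' @param params a [kinetics_params] (its `bounds` set the truncation).
#' @param order a [driver_order_spec].
#' @param mode `"reaction_consistent"` or `"as_printed"`.
#' @param max_states refuse to build generators larger than this.
#' @return An object of class `generator_matrix` with the sparse matrix
#'   `L` (`dgCMatrix`), the `state_index` `sindex`, and `mode`.
#' @export
build_generator <- function(params, order,
                            mode = c("reaction_consistent", "as_printed"),
                            max_states = 50000L) {
  mode <- match.arg(mode)
  tab <- .rate_tables(params, order)
  sx <- state_index(tab$mdb, tab$mnb, tab$mmb, tab$kb)
  if (sx$n_states > max_states)
    stop(sprintf("state space has %d states, above the configured limit %d",
                 sx$n_states, max_states))
  mdb <- tab$mdb; mnb <- tab$mnb; mmb <- tab$mmb; kb <- tab$kb
  n_mask <- tab$n_mask
  enc <- sx$encode
  cap0 <- 64L
  ti <- integer(cap0); tj <- integer(cap0); tx <- numeric(cap0); nt <- 0L
  push <- function(i, j, x) {
    if (x == 0) return(invisible())
    if (nt >= length(ti)) {
      ti <<- c(ti, integer(length(ti))); tj <<- c(tj, integer(length(tj)))
      tx <<- c(tx, numeric(length(tx)))
    }
    nt <<- nt + 1L
    ti[nt] <<- i; tj[nt] <<- j; tx[nt] <<- x
  }

  for (k in seq_len(kb)) for (q in 0:mmb) for (n in 0:mnb) for (m in 0:(n_mask - 1L)) {
    src <- enc(m, n, q, k)
    ridx <- tab$row_of(m, n, k)
    if (tab$stuck[ridx]) next
    P <- tab$probs[ridx, ]
    lam <- tab$lam[q + 1L]
    md <- tab$m_d_of[m + 1L]

    if (mode == "reaction_consistent") {
      # apoptosis: pure loss
      push(src, src, -lam * P[3L])
      # migration
      if (P[4L] > 0) {
        push(enc(m, n, q, k + 1L), src, lam * P[4L])
        push(src, src, -lam * P[4L])
      }
      # divisions: suppressed entirely at the metabolic bound or exhaustion
      if (q < mmb) {
        pd <- tab$pdtab[md + 1L, n + 1L]
        if (!is.na(pd)) {
          zb <- tab$zero_bits[[m + 1L]]
          if (pd > 0 && length(zb)) {
            for (act in 1:2) {
              rate <- lam * P[act] * pd
              if (rate == 0) next
              per <- rate / length(zb)
              for (bit in zb) {
                tgt <- enc(bitwOr(m, bit), n, q + 1L, k)
                if (act == 1L) {               # asym: mutated + sibling
                  push(tgt, src, per)
                  push(enc(m, n, q + 1L, k), src, per)
                } else {                       # sym: two mutated copies
                  push(tgt, src, 2 * per)
                }
              }
              push(src, src, -rate)
            }
          }
          pn <- 1 - pd
          if (pn > 0 && n < mnb) {
            for (act in 1:2) {
              rate <- lam * P[act] * pn
              if (rate == 0) next
              if (act == 1L) {                 # asym: mutated + sibling
                push(enc(m, n + 1L, q + 1L, k), src, rate)
                push(enc(m, n, q + 1L, k), src, rate)
              } else {                         # sym: two mutated copies
                push(enc(m, n + 1L, q + 1L, k), src, 2 * rate)
              }
              push(src, src, -rate)
            }
          }
        }
      }
    } else {  # as_printed
      # losses at alpha*(r + m_m): symmetric division, apoptosis, migration
      push(src, src, -lam * (P[2L] + P[3L]))
      if (P[4L] > 0) {
        push(enc(m, n, q, k + 1L), src, lam * P[4L])
        push(src, src, -lam * P[4L])
      }
      # gains into m_m + 1 with prefactor alpha*(r + (m_m+1) - 1) = lam
      if (q < mmb) {
        pd <- tab$pdtab[md + 1L, n + 1L]
        if (!is.na(pd)) {
          pn <- 1 - pd
          zb <- tab$zero_bits[[m + 1L]]
          for (bit in zb) {
            tgt <- enc(bitwOr(m, bit), n, q + 1L, k)
            push(tgt, src, lam * P[1L] * pd / mdb)      # asym driver, 1/m_d_bar
            push(tgt, src, 2 * lam * P[2L] * pd / mdb)  # sym driver
          }
          # non-driver gain terms as printed: density argument keeps m_n
          push(enc(m, n, q + 1L, k), src, lam * P[1L] * pn)
          push(enc(m, n, q + 1L, k), src, 2 * lam * P[2L] * pn)
        }
      }
    }
  }
  L <- Matrix::sparseMatrix(i = ti[seq_len(nt)], j = tj[seq_len(nt)],
                            x = tx[seq_len(nt)],
                            dims = c(sx$n_states, sx$n_states))
  structure(list(L = L, sindex = sx, mode = mode), class = "generator_matrix")
}

#' Integrate the master equation
#'
#' Solves `dp/dt = L p` from the initial expected counts `p0` on the given
#' time grid with a stiff-capable adaptive integrator.  The equation is
#' linear, so an initial mass `N_0` placed on `sigma_0` scales the whole
#' solution.
#'
#' @param gen a `generator_matrix` from [build_generator].
#' @param p0 numeric vector of initial expected counts per state (length
#'   `n_states`), non-negative.
#' @param times numeric time grid starting at the initial time.
#' @param rtol,atol relative / absolute integration tolerances.
#' @return An object of class `master_trajectory` with `times`, `states`
#'   (matrix time x state) and the `state_index`.
#' @export
integrate_master <- function(gen, p0, times, rtol = 1e-8, atol = 1e-10) {
  if (length(p0) != gen$sindex$n_states)
    stop("'p0' length does not match the generator's state space")
  if (any(p0 < 0)) stop("'p0' must be non-negative")
  L <- gen$L
  out <- deSolve::ode(y = p0, times = times,
                      func = function(t, y, parms) list(as.vector(L %*% y)),
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop(sprintf("master-equation integration failed after t = %.6g",
                 out[nrow(out), 1L]))
  structure(list(times = out[, 1L], states = unname(out[, -1L, drop = FALSE]),
                 sindex = gen$sindex),
            class = "master_trajectory")
}

#' Project a master-equation trajectory onto (compartment, driver count)
#'
#' Sums expected counts over the remaining state dimensions, producing the
#' same grouping as the simulator's recorded counts (CSV schema with
#' `replicate = "ode"`).
#'
#' @param traj a `master_trajectory`.
#' @return data frame with columns `replicate`, `time`, `compartment`,
#'   `m_d`, `count`.
#' @export
project_counts <- function(traj) {
  sx <- traj$sindex
  comp <- sx$decode(seq_len(sx$n_states))
  m_d <- vapply(comp$mask, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(max(sx$m_d_bar, 1) - 1L))) > 0L), 0L)
  if (sx$m_d_bar == 0L) m_d <- rep(0L, sx$n_states)
  key <- interaction(comp$k, m_d, drop = FALSE)
  out <- do.call(rbind, lapply(seq_along(traj$times), function(ti) {
    agg <- rowsum(traj$states[ti, ], group = paste(comp$k, m_d))
    data.frame(replicate = "ode", time = traj$times[ti],
               compartment = as.integer(sub(" .*", "", rownames(agg))),
               m_d = as.integer(sub(".* ", "", rownames(agg))),
               count = agg[, 1L])
  }))
  rownames(out) <- NULL
  out[order(out$time, out$compartment, out$m_d), ]
}

#' Expected counts of a (compartment, driver count) group over time
#'
#' Convenience accessor returning the matrix time x group of projected
#' expected counts, with groups labelled `"k<compartment>_md<count>"`.
#'
#' @param traj a `master_trajectory`.
#' @return numeric matrix with one column per (compartment, m_d) group.
#' @export
group_count_matrix <- function(traj) {
  pc <- project_counts(traj)
  labs <- sort(unique(paste0("k", pc$compartment, "_md", pc$m_d)))
  mat <- matrix(0, length(traj$times), length(labs),
                dimnames = list(NULL, labs))
  for (g in labs) {
    sel <- paste0("k", pc$compartment, "_md", pc$m_d) == g
    mat[, g] <- pc$count[sel][order(pc$time[sel])]
  }
  mat
}
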