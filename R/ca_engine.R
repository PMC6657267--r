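#' Simulation configuration
#'
#' Run-level settings of the event-driven simulator.  Every replicate
#' starts with `initial_cells` identical unmutated cells in compartment 1
#' (state `sigma_0 = {0, 0, 0, 1}`) whose first timers are drawn
#' independently.
#'
#' @param t_end simulation horizon (simulation time units; `1/(alpha*r)`
#'   is the unmutated cell-cycle mean time).
#' @param initial_cells number of founder cells `N_0`.
#' @param record_dt output grid step; counts per (compartment, driver
#'   count) are sampled at `seq(0, t_end, by = record_dt)`.
#' @param replicates ensemble size.
#' @param seed master random seed; per-replicate sub-seeds are derived
#'   from it so runs are reproducible.
#' @param t_drug optional drug administration time (`< t_end`); defaults
#'   to the signature's own `time` field when a drug is given.
#' @param drug optional [drug_signature]; at `t_drug` all matching cells
#'   are removed instantaneously.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(t_end, initial_cells = 10L, record_dt = t_end / 50,
                              replicates = 1L, seed = 1L,
                              t_drug = NA_real_, drug = NULL) {
  if (t_end <= 0) stop("'t_end' must be positive")
  if (record_dt <= 0) stop("'record_dt' must be positive")
  if (initial_cells < 1L) stop("'initial_cells' must be >= 1")
  if (replicates < 1L) stop("'replicates' must be >= 1")
  if (!is.null(drug) && !inherits(drug, "drug_signature"))
    stop("'drug' must be a drug_signature")
  if (!is.null(drug) && is.na(t_drug)) t_drug <- drug$time
  if (!is.null(drug) && (is.na(t_drug) || t_drug >= t_end))
    stop("'t_drug' must be given and satisfy t_drug < t_end when a drug is set")
  structure(list(t_end = as.numeric(t_end),
                 initial_cells = as.integer(initial_cells),
                 record_dt = as.numeric(record_dt),
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 t_drug = as.numeric(t_drug), drug = drug),
            class = "simulation_config")
}

#' Execute one reaction for a single cell
#'
#' Reference single-step semantics of the reaction set: the parent is
#' always consumed; asymmetric division yields one mutated and one
#' unmutated daughter, symmetric division two identical mutated daughters
#' (every division adds one metabolic mutation to each daughter),
#' apoptosis yields nothing, and migration moves the cell to compartment
#' `k + 1` unchanged.  The action, the driver/non-driver branch and the
#' driver locus are drawn from the model's distributions unless forced
#' through the optional arguments (useful for tests and illustration).
#' Bound checking is the scheduler's job, not this function's.
#'
#' @param state a [cell_state].
#' @param params a [kinetics_params].
#' @param order a [driver_order_spec].
#' @param action optional forced action, one of `"asym"`, `"sym"`,
#'   `"apop"`, `"pass"`.
#' @param mutation optional forced branch, `"driver"` or `"nondriver"`.
#' @param locus optional forced driver locus.
#' @return list of daughter [cell_state]s (possibly empty).
#' @export
step_cell <- function(state, params, order, action = NULL,
                      mutation = NULL, locus = NULL) {
  if (is.null(action)) {
    p <- action_probabilities(state, params, order)
    action <- sample(names(p), 1L, prob = p)
  }
  action <- match.arg(action, c("asym", "sym", "apop", "pass"))
  if (action == "apop") return(list())
  if (action == "pass") {
    if (!can_migrate(state, order))
      stop("migration drawn for a cell that cannot migrate (k_pass = 0)")
    return(list(cell_state(state$d, state$m_n, state$m_m, state$k + 1L)))
  }
  split <- mutation_split(state, params)
  if (is.null(mutation))
    mutation <- sample(c("driver", "nondriver"), 1L, prob = split)
  mutation <- match.arg(mutation, c("driver", "nondriver"))
  if (mutation == "driver") {
    open <- which(state$d == 0L)
    if (!length(open)) stop("no driver locus left to mutate")
    if (is.null(locus))
      locus <- if (length(open) == 1L) open else sample(open, 1L)
    if (!locus %in% open) stop("'locus' is already mutated")
    d2 <- state$d; d2[locus] <- 1L
    mutated <- cell_state(d2, state$m_n, state$m_m + 1L, state$k)
  } else {
    mutated <- cell_state(state$d, state$m_n + 1L, state$m_m + 1L, state$k)
  }
  sib <- cell_state(state$d, state$m_n, state$m_m + 1L, state$k)
  if (action == "asym") list(mutated, sib) else list(mutated, mutated)
}

.capacity_matrix <- function(energy, kb, mdb) {
  cap <- energy$capacity
  if (is.matrix(cap)) {
    if (nrow(cap) != kb || ncol(cap) != mdb + 1L)
      stop("capacity matrix must be n_compartments x (m_d_bar + 1)")
    cap
  } else if (length(cap) == kb) {
    matrix(rep(as.numeric(cap), mdb + 1L), kb, mdb + 1L)
  } else if (length(cap) == 1L) {
    matrix(as.numeric(cap), kb, mdb + 1L)
  } else stop("capacity must be a scalar, a per-compartment vector, or a matrix")
}

.sig_mask <- function(sig) {
  w <- which(sig$d == 1L)
  if (length(w)) sum(bitwShiftL(1L, w - 1L)) else 0L
}

#' Run one stochastic replicate
#'
#' Asynchronous, self-clocked event loop: every cell carries an
#' independent exponential timer at rate `alpha*(r + m_m)` and an action
#' pre-drawn at birth from its state's action probabilities (reactions do
#' not compete, so the action can be tossed when the period starts).  When
#' a timer expires the action executes unless it would exceed a
#' state-space bound, a capacity, or an energy budget — in which case the
#' event is *put back*: the parent survives unchanged and redraws both
#' timer and action.  Cells for which every remaining action is
#' permanently impossible are frozen in place.  At `t_drug` every cell
#' matching the drug signature is removed before any cell event at that
#' time.  Counts per (compartment, driver count) are sampled on the
#' recording grid; extinction is a valid result.
#'
#' @param config a [simulation_config].
#' @param params a [kinetics_params].
#' @param order a [driver_order_spec].
#' @param energy an [energy_model] (default: unbounded).
#' @param keep_log record every event (including rejections and drug
#'   kills) — intended for small runs.
#' @param seed optional integer seed set before the run.
#' @return An object of class `ca_run`: `times`, `counts` (array time x
#'   compartment x driver count), `final_counts`, `population`, `extinct`,
#'   `post_drug_match` (number of signature-matching cells immediately
#'   after the drug event; 0 when complete, `NA` without a drug), `cells`
#'   (data frame of surviving cells), and `log` when requested.
#' @export
run_replicate <- function(config, params, order, energy = NULL,
                          keep_log = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(energy)) energy <- energy_model()
  tab <- .rate_tables(params, order)
  n_mask <- tab$n_mask; mdb <- tab$mdb; mnb <- tab$mnb; mmb <- tab$mmb; kb <- tab$kb
  cap <- .capacity_matrix(energy, kb, mdb)
  evec <- energy$e
  if (!is.null(evec)) {
    evec <- c(evec, rep(0, max(0L, mdb + 1L - length(evec))))[seq_len(mdb + 1L)]
    if (all(evec == 0)) evec <- NULL
  }
  Emax <- rep(energy$E_max, length.out = kb)
  lam <- tab$lam; cum <- tab$cum; probs <- tab$probs; stuckv <- tab$stuck
  pdtab <- tab$pdtab; m_d_of <- tab$m_d_of; zero_bits <- tab$zero_bits

  grid <- seq(0, config$t_end, by = config$record_dt)
  if (grid[length(grid)] < config$t_end - 1e-12) grid <- c(grid, config$t_end)
  ng <- length(grid)
  rec <- array(0, dim = c(ng, kb, mdb + 1L))

  n_alloc <- max(64L, 2L * config$initial_cells)
  mask <- integer(n_alloc); mn <- integer(n_alloc); mm <- integer(n_alloc)
  kk <- rep(1L, n_alloc); tnext <- rep(Inf, n_alloc)
  act <- integer(n_alloc); alive <- logical(n_alloc)
  n_used <- 0L
  counts <- matrix(0, kb, mdb + 1L)
  Ecur <- numeric(kb)

  log_rows <- if (keep_log) vector("list", 0L) else NULL
  add_log <- function(time, action, cell, pm, pn, pq, pk, daughters = NULL) {
    d1 <- if (length(daughters) >= 1L) daughters[[1L]] else rep(NA_integer_, 4L)
    d2 <- if (length(daughters) >= 2L) daughters[[2L]] else rep(NA_integer_, 4L)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      time = time, action = action, cell = cell,
      p_mask = pm, p_mn = pn, p_mm = pq, p_k = pk,
      d1_mask = d1[1], d1_mn = d1[2], d1_mm = d1[3], d1_k = d1[4],
      d2_mask = d2[1], d2_mn = d2[2], d2_mm = d2[3], d2_k = d2[4])
  }

  new_slot <- function() {
    if (n_used >= length(tnext)) {
      grow <- length(tnext)
      mask <<- c(mask, integer(grow)); mn <<- c(mn, integer(grow))
      mm <<- c(mm, integer(grow)); kk <<- c(kk, rep(1L, grow))
      tnext <<- c(tnext, rep(Inf, grow)); act <<- c(act, integer(grow))
      alive <<- c(alive, logical(grow))
    }
    n_used <<- n_used + 1L
    n_used
  }

  # redraw timer + action for cell i at time tnow; freeze permanently
  # inert cells (state bounds make every possible outcome rejected forever)
  schedule <- function(i, tnow) {
    ridx <- 1L + mask[i] + n_mask * (mn[i] + (mnb + 1L) * (kk[i] - 1L))
    if (stuckv[ridx])
      stop(sprintf(
        "stuck state: no action has a nonzero rate (mask=%d, m_n=%d, m_m=%d, k=%d); mis-specified scenario",
        mask[i], mn[i], mm[i], kk[i]))
    prolif_blocked <- (mm[i] >= mmb) ||
      is.na(pdtab[m_d_of[mask[i] + 1L] + 1L, mn[i] + 1L])
    if (prolif_blocked && probs[ridx, 3L] == 0 && probs[ridx, 4L] == 0) {
      tnext[i] <<- Inf
      return(invisible())
    }
    tnext[i] <<- tnow + stats::rexp(1L, lam[mm[i] + 1L])
    u <- stats::runif(1L)
    act[i] <<- 1L + sum(u > cum[ridx, 1:3])
  }

  for (ci in seq_len(config$initial_cells)) {
    j <- new_slot()
    alive[j] <- TRUE
    counts[1L, 1L] <- counts[1L, 1L] + 1
    schedule(j, 0)
  }
  if (!is.null(evec)) Ecur[1L] <- evec[1L] * config$initial_cells

  drug_pending <- !is.null(config$drug)
  t_drug <- if (drug_pending) config$t_drug else Inf
  sig <- config$drug
  if (drug_pending && length(sig$d) != mdb)
    stop("drug signature driver vector length does not match the model's loci")
  sig_mask <- if (drug_pending) .sig_mask(sig) else 0L
  post_drug_match <- NA_integer_

  match_sel <- function() {
    sel <- alive
    if (sig_mask > 0L) sel <- sel & bitwAnd(mask, sig_mask) == sig_mask
    if (sig$m_n != 0L) sel <- sel & mn == sig$m_n
    if (sig$m_m != 0L) sel <- sel & mm == sig$m_m
    if (sig$k != 0L) sel <- sel & kk == sig$k
    if (sig$m_d != 0L) sel <- sel & m_d_of[mask + 1L] == sig$m_d
    sel
  }

  gp <- 1L
  repeat {
    i <- which.min(tnext)
    te <- if (length(tnext)) tnext[i] else Inf

    if (drug_pending && t_drug <= min(te, config$t_end)) {
      while (gp <= ng && grid[gp] < t_drug) { rec[gp, , ] <- counts; gp <- gp + 1L }
      kill <- which(match_sel())
      for (j in kill) {
        mdj <- m_d_of[mask[j] + 1L]
        counts[kk[j], mdj + 1L] <- counts[kk[j], mdj + 1L] - 1
        if (!is.null(evec)) Ecur[kk[j]] <- Ecur[kk[j]] - evec[mdj + 1L]
        if (keep_log) add_log(t_drug, "drug_kill", j, mask[j], mn[j], mm[j], kk[j])
      }
      alive[kill] <- FALSE; tnext[kill] <- Inf
      post_drug_match <- sum(match_sel())
      drug_pending <- FALSE
      next
    }
    if (!is.finite(te) || te > config$t_end) break
    while (gp <= ng && grid[gp] < te) { rec[gp, , ] <- counts; gp <- gp + 1L }

    m <- mask[i]; n_i <- mn[i]; q <- mm[i]; k <- kk[i]
    md <- m_d_of[m + 1L]
    a <- act[i]
    rejected <- FALSE

    if (a == 3L) {                                   # apoptosis: C -> 0
      counts[k, md + 1L] <- counts[k, md + 1L] - 1
      if (!is.null(evec)) Ecur[k] <- Ecur[k] - evec[md + 1L]
      alive[i] <- FALSE; tnext[i] <- Inf
      if (keep_log) add_log(te, "apop", i, m, n_i, q, k)
    } else if (a == 4L) {                            # migration: k -> k+1
      if (counts[k + 1L, md + 1L] + 1 > cap[k + 1L, md + 1L] ||
          (!is.null(evec) && Ecur[k + 1L] + evec[md + 1L] > Emax[k + 1L])) {
        rejected <- TRUE
      } else {
        counts[k, md + 1L] <- counts[k, md + 1L] - 1
        counts[k + 1L, md + 1L] <- counts[k + 1L, md + 1L] + 1
        if (!is.null(evec)) {
          Ecur[k] <- Ecur[k] - evec[md + 1L]
          Ecur[k + 1L] <- Ecur[k + 1L] + evec[md + 1L]
        }
        kk[i] <- k + 1L
        schedule(i, te)
        if (keep_log) add_log(te, "pass", i, m, n_i, q, k,
                              list(c(m, n_i, q, k + 1L)))
      }
    } else {                                         # division (asym or sym)
      if (q >= mmb) {
        rejected <- TRUE
      } else {
        pd <- pdtab[md + 1L, n_i + 1L]
        if (is.na(pd)) {
          rejected <- TRUE
        } else if (stats::runif(1L) < pd) {          # driver branch
          zb <- zero_bits[[m + 1L]]
          bit <- if (length(zb) == 1L) zb else zb[sample.int(length(zb), 1L)]
          newmask <- bitwOr(m, bit)
          need <- if (a == 1L) 1 else 2
          dE <- if (is.null(evec)) 0 else
            need * evec[md + 2L] + (if (a == 1L) 0 else -evec[md + 1L])
          if (counts[k, md + 2L] + need > cap[k, md + 2L] ||
              (!is.null(evec) && Ecur[k] + dE > Emax[k])) {
            rejected <- TRUE
          } else {
            if (a == 1L) {                           # asym: mutated + sibling
              mask[i] <- newmask; mm[i] <- q + 1L
              j <- new_slot()
              alive[j] <- TRUE; mask[j] <- m; mn[j] <- n_i; mm[j] <- q + 1L; kk[j] <- k
              counts[k, md + 2L] <- counts[k, md + 2L] + 1
              if (keep_log) add_log(te, "asym", i, m, n_i, q, k,
                                    list(c(newmask, n_i, q + 1L, k), c(m, n_i, q + 1L, k)))
            } else {                                 # sym: two mutated copies
              mask[i] <- newmask; mm[i] <- q + 1L
              j <- new_slot()
              alive[j] <- TRUE; mask[j] <- newmask; mn[j] <- n_i; mm[j] <- q + 1L; kk[j] <- k
              counts[k, md + 1L] <- counts[k, md + 1L] - 1
              counts[k, md + 2L] <- counts[k, md + 2L] + 2
              if (keep_log) add_log(te, "sym", i, m, n_i, q, k,
                                    list(c(newmask, n_i, q + 1L, k), c(newmask, n_i, q + 1L, k)))
            }
            if (!is.null(evec)) Ecur[k] <- Ecur[k] + dE
            schedule(i, te); schedule(j, te)
          }
        } else {                                     # non-driver branch
          if (n_i >= mnb ||
              counts[k, md + 1L] + 1 > cap[k, md + 1L] ||
              (!is.null(evec) && Ecur[k] + evec[md + 1L] > Emax[k])) {
            rejected <- TRUE
          } else {
            mn[i] <- n_i + 1L; mm[i] <- q + 1L
            j <- new_slot()
            alive[j] <- TRUE; mask[j] <- m; kk[j] <- k
            if (a == 1L) { mn[j] <- n_i; mm[j] <- q + 1L }       # asym sibling
            else         { mn[j] <- n_i + 1L; mm[j] <- q + 1L }  # sym copy
            counts[k, md + 1L] <- counts[k, md + 1L] + 1
            if (!is.null(evec)) Ecur[k] <- Ecur[k] + evec[md + 1L]
            if (keep_log) add_log(te, if (a == 1L) "asym" else "sym", i, m, n_i, q, k,
                                  list(c(m, n_i + 1L, q + 1L, k),
                                       c(m, if (a == 1L) n_i else n_i + 1L, q + 1L, k)))
            schedule(i, te); schedule(j, te)
          }
        }
      }
    }
    if (rejected) {                                  # put back: parent unchanged
      if (keep_log) add_log(te, "rejected", i, m, n_i, q, k)
      schedule(i, te)
    }
  }
  while (gp <= ng) { rec[gp, , ] <- counts; gp <- gp + 1L }

  idx_alive <- which(alive)
  cells <- data.frame(
    mask = mask[idx_alive], m_d = m_d_of[mask[idx_alive] + 1L],
    m_n = mn[idx_alive], m_m = mm[idx_alive], k = kk[idx_alive])
  structure(list(
    times = grid, counts = rec, final_counts = counts,
    population = sum(counts), extinct = sum(counts) == 0,
    post_drug_match = post_drug_match, cells = cells,
    log = if (keep_log) do.call(rbind, log_rows) else NULL,
    dims = list(k_bar = kb, m_d_bar = mdb)),
    class = "ca_run")
}

#' Run an ensemble of replicates
#'
#' Runs `config$replicates` independent replicates with sub-seeds derived
#' from the master seed and returns the per-replicate counts together with
#' their pointwise ensemble mean and standard deviation, grouped by
#' (compartment, driver count).
#'
#' @inheritParams run_replicate
#' @return An object of class `ca_ensemble`: `times`, `counts` (array
#'   replicate x time x compartment x driver count), `mean`, `sd` (arrays
#'   time x compartment x driver count), `seeds`, `post_drug_match`
#'   (per-replicate), `config`.
#' @export
run_ensemble <- function(config, params, order, energy = NULL) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$replicates)
  first <- run_replicate(config, params, order, energy, seed = seeds[1L])
  ng <- length(first$times); kb <- first$dims$k_bar; mdb <- first$dims$m_d_bar
  R <- config$replicates
  arr <- array(0, dim = c(R, ng, kb, mdb + 1L))
  arr[1L, , , ] <- first$counts
  pdm <- rep(NA_integer_, R); pdm[1L] <- first$post_drug_match
  extinct <- logical(R); extinct[1L] <- first$extinct
  if (R > 1L) for (r in 2:R) {
    run <- run_replicate(config, params, order, energy, seed = seeds[r])
    arr[r, , , ] <- run$counts
    pdm[r] <- run$post_drug_match
    extinct[r] <- run$extinct
  }
  mean_c <- apply(arr, c(2, 3, 4), mean)
  sd_c <- if (R > 1L) apply(arr, c(2, 3, 4), stats::sd) else array(0, dim(arr)[2:4])
  structure(list(times = first$times, counts = arr, mean = mean_c, sd = sd_c,
                 seeds = seeds, post_drug_match = pdm, extinct = extinct,
                 config = config, dims = first$dims),
            class = "ca_ensemble")
}

#' Tidy trajectory table of an ensemble
#'
#' Long-format table with one row per (statistic or replicate, time,
#' compartment, driver count), the schema used by the CSV reports.
#'
#' @param x a `ca_ensemble`.
#' @param replicates include each replicate's counts in addition to the
#'   ensemble mean and standard deviation.
#' @return data frame with columns `replicate` (`"mean"`, `"sd"`, or the
#'   replicate number), `time`, `compartment`, `m_d`, `count`.
#' @export
trajectory_frame <- function(x, replicates = FALSE) {
  stopifnot(inherits(x, "ca_ensemble"))
  ng <- length(x$times); kb <- x$dims$k_bar; mdv <- 0:x$dims$m_d_bar
  base <- expand.grid(time = x$times, compartment = seq_len(kb), m_d = mdv,
                      KEEP.OUT.ATTRS = FALSE)
  out <- rbind(
    cbind(replicate = "mean", base, count = as.vector(x$mean)),
    cbind(replicate = "sd", base, count = as.vector(x$sd)))
  if (replicates) {
    for (r in seq_len(dim(x$counts)[1L]))
      out <- rbind(out, cbind(replicate = as.character(r), base,
                              count = as.vector(x$counts[r, , , ])))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.ca_ensemble <- function(x, ...) {
  tot <- apply(x$mean, 1, sum)
  cat(sprintf(
    "<ca_ensemble> %d replicate(s), %d grid points, %d compartments, m_d 0..%d\n",
    dim(x$counts)[1L], length(x$times), x$dims$k_bar, x$dims$m_d_bar))
  cat(sprintf("  mean population: %.2f at t=0  ->  %.2f at t=%.3g\n",
              tot[1L], tot[length(tot)], x$times[length(x$times)]))
  invisible(x)
}
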