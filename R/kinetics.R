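#' Kinetic parameters of the clonal-evolution model
#'
#' Collects the waiting-time parameters, the action-rate amplitudes and
#' stemness supports, the driver/non-driver split weight, and the
#' state-space bounds.
#'
#' The internal clock of a cell with `m_m` metabolic mutations fires at
#' rate `alpha * (r + m_m)`; `1/(alpha*r)` is the mean cycle time of an
#' unmutated cell and each metabolic mutation adds `alpha` to the rate.
#' When the clock fires, the cell performs one of four actions —
#' asymmetric division, symmetric division, apoptosis, migration — with
#' probabilities proportional to `A_act * chi_act(s) * k_act(m_e, k)`,
#' where `chi_act` is a window of width `w` centred on `c_act` in stemness
#' `s`, and the migration filter `k_pass` requires enough effective
#' drivers.  The centres must satisfy `c_asym < c_sym < c_apop < s_bar`;
#' the windows may overlap.
#'
#' @param alpha cycle-rate scale (1/time), `> 0`.
#' @param r baseline rate multiplier (dimensionless), `> 0`.
#' @param amplitudes named non-negative numeric vector with entries
#'   `asym`, `sym`, `apop`, `pass`.
#' @param centers named numeric vector with entries `asym`, `sym`, `apop`
#'   (stemness units), strictly increasing and below `s_bar`.
#' @param width support width `w` (stemness units), `> 0`.
#' @param s_bar maximum stemness, `> 0`.
#' @param beta weight of the remaining non-driver loci in the
#'   driver/non-driver mutation split (see [mutation_split]), `> 0`.
#' @param bounds named list with positive integer state-space bounds
#'   `m_d` (driver loci), `m_n` (non-driver count), `m_m` (metabolic count).
#' @return An object of class `kinetics_params`.
#' @examples
#' kinetics_params(
#'   alpha = 1, r = 1,
#'   amplitudes = c(asym = 1, sym = 0.5, apop = 0.4, pass = 0.6),
#'   centers = c(asym = 0.25, sym = 0.5, apop = 0.75),
#'   width = 1.2, s_bar = 1,
#'   bounds = list(m_d = 4, m_n = 8, m_m = 10))
#' @export
kinetics_params <- function(alpha, r, amplitudes, centers, width, s_bar,
                            beta = 1, bounds) {
  problems <- character(0)
  need <- c("asym", "sym", "apop", "pass")
  if (!all(need %in% names(amplitudes)))
    problems <- c(problems, "amplitudes: must name asym, sym, apop, pass")
  if (!all(c("asym", "sym", "apop") %in% names(centers)))
    problems <- c(problems, "centers: must name asym, sym, apop")
  if (!is.numeric(alpha) || alpha <= 0) problems <- c(problems, "alpha: must be > 0")
  if (!is.numeric(r) || r <= 0) problems <- c(problems, "r: must be > 0")
  if (!is.numeric(width) || width <= 0) problems <- c(problems, "width: must be > 0")
  if (!is.numeric(s_bar) || s_bar <= 0) problems <- c(problems, "s_bar: must be > 0")
  if (!is.numeric(beta) || beta <= 0) problems <- c(problems, "beta: must be > 0")
  if (any(amplitudes < 0)) problems <- c(problems, "amplitudes: must be >= 0")
  if (all(c("asym", "sym", "apop") %in% names(centers))) {
    if (!(centers[["asym"]] < centers[["sym"]] &&
          centers[["sym"]] < centers[["apop"]] &&
          centers[["apop"]] < s_bar))
      problems <- c(problems,
        "centers: must satisfy c_asym < c_sym < c_apop < s_bar")
  }
  if (!is.list(bounds) || !all(c("m_d", "m_n", "m_m") %in% names(bounds)))
    problems <- c(problems, "bounds: must be a list naming m_d, m_n, m_m")
  else if (any(unlist(bounds[c("m_d", "m_n", "m_m")]) < 0))
    problems <- c(problems, "bounds: must be non-negative integers")
  if (length(problems))
    stop("invalid kinetics parameters:\n  ", paste(problems, collapse = "\n  "))
  structure(list(
    alpha = as.numeric(alpha), r = as.numeric(r),
    amplitudes = as.numeric(amplitudes[need]) |> stats::setNames(need),
    centers = as.numeric(centers[c("asym", "sym", "apop")]) |>
      stats::setNames(c("asym", "sym", "apop")),
    width = as.numeric(width), s_bar = as.numeric(s_bar),
    beta = as.numeric(beta),
    bounds = list(m_d = as.integer(bounds$m_d), m_n = as.integer(bounds$m_n),
                  m_m = as.integer(bounds$m_m))
  ), class = "kinetics_params")
}

#' Cancer stemness
#'
#' `s(m_d, m_n) = s_bar * m_d / sqrt(1 + m_n)`, clipped into the declared
#' codomain `[0, s_bar]` (the raw formula is unbounded for many drivers and
#' few passengers; `clip = FALSE` returns the raw value).  Stemness is
#' strictly increasing in the driver count, strictly decreasing in the
#' non-driver count, and independent of the metabolic mutations.
#'
#' @param m_d driver count(s).
#' @param m_n non-driver count(s).
#' @param s_bar maximum stemness.
#' @param clip clip to `[0, s_bar]` (default).
#' @return numeric, vectorized over `m_d`/`m_n`.
#' @examples
#' stemness(3, 8, s_bar = 1)  # 3/sqrt(9) = 1
#' @export
stemness <- function(m_d, m_n, s_bar = 1, clip = TRUE) {
  s <- s_bar * m_d / sqrt(1 + m_n)
  if (clip) s <- pmin(pmax(s, 0), s_bar)
  s
}

#' Stemness support window
#'
#' The product of step functions `Theta(s - c + w/2) * Theta(c + w/2 - s)`:
#' 1 on the closed interval `[center - width/2, center + width/2]`, 0
#' outside.  Boundaries are included.
#'
#' @param s stemness value(s).
#' @param center window centre `c_act`.
#' @param width window width `w > 0`.
#' @return 0/1 integer, vectorized over `s`.
#' @export
chi_support <- function(s, center, width) {
  if (width <= 0) stop("'width' must be > 0")
  as.integer(abs(s - center) <= width / 2)
}

#' Normalized action probabilities of a cell
#'
#' Each action's unnormalized rate is `A_act * chi_act(s) * k_act(m_e, k)`
#' with `chi_pass = 1`, `k_asym = k_sym = k_apop = 1` and `k_pass` the
#' migration filter of [can_migrate]; dividing by the normalization `N`
#' (the sum over actions) yields probabilities summing to one.  A state in
#' which every numerator vanishes cannot act at all and signals a
#' mis-specified scenario.
#'
#' @param state a [cell_state].
#' @param params a [kinetics_params].
#' @param order a [driver_order_spec].
#' @return named numeric vector `c(asym, sym, apop, pass)` summing to 1.
#' @export
action_probabilities <- function(state, params, order) {
  s <- stemness(sum(state$d), state$m_n, params$s_bar)
  A <- params$amplitudes; ctr <- params$centers; w <- params$width
  num <- c(
    asym = A[["asym"]] * chi_support(s, ctr[["asym"]], w),
    sym  = A[["sym"]]  * chi_support(s, ctr[["sym"]],  w),
    apop = A[["apop"]] * chi_support(s, ctr[["apop"]], w),
    pass = A[["pass"]] * as.numeric(can_migrate(state, order))
  )
  N <- sum(num)
  if (N == 0)
    stop(sprintf(
      "stuck state: no action has a nonzero rate for d=(%s), m_n=%d, m_m=%d, k=%d (stemness %.4g)",
      paste(state$d, collapse = ","), state$m_n, state$m_m, state$k, s))
  num / N
}

#' Draw waiting times of the metabolic clock
#'
#' Waiting times between events of a cell with `m_m` metabolic mutations
#' follow the exponential law `psi(m_m, t) = alpha*(r + m_m) *
#' exp(-alpha*(r + m_m)*t)`; more metabolic mutations mean a faster clock.
#'
#' @param m_m metabolic mutation count.
#' @param params a [kinetics_params].
#' @param n number of deviates.
#' @return numeric vector of `n` positive waiting times.
#' @export
sample_waiting_time <- function(m_m, params, n = 1L) {
  if (m_m < 0) stop("'m_m' must be non-negative")
  stats::rexp(n, rate = params$alpha * (params$r + m_m))
}

#' Driver versus non-driver split of a new mutation
#'
#' The probability that the mutation carried by a proliferation event hits
#' a driver locus is the beta-weighted share of the remaining loci:
#' `p_driver = (m_d_bar - m_d) / ((m_d_bar - m_d) + beta*(m_n_bar - m_n))`.
#' When every locus of both classes is exhausted no proliferation is
#' possible and an exhaustion error is raised (the simulator blocks such
#' events through its rejection path instead).
#'
#' @param state a [cell_state], or a driver count (with `m_n` supplied).
#' @param params a [kinetics_params].
#' @param m_n non-driver count when `state` is given as a count.
#' @return named numeric vector `c(driver, nondriver)` summing to 1.
#' @examples
#' p <- kinetics_params(1, 1, c(asym = 1, sym = 1, apop = 1, pass = 1),
#'                      c(asym = .2, sym = .5, apop = .8), 2, 1,
#'                      bounds = list(m_d = 4, m_n = 10, m_m = 10))
#' mutation_split(cell_state(c(1, 0, 0, 0), m_n = 4), p)  # (3/9, 6/9)
#' @export
mutation_split <- function(state, params, m_n = NULL) {
  if (inherits(state, "cell_state")) {
    m_d <- sum(state$d); m_n <- state$m_n
  } else {
    m_d <- state
    if (is.null(m_n)) stop("'m_n' required when 'state' is a driver count")
  }
  nd <- params$bounds$m_d - m_d
  nn <- params$bounds$m_n - m_n
  if (nd < 0 || nn < 0) stop("state exceeds the declared mutation bounds")
  if (nd == 0 && nn == 0)
    stop("mutation space exhausted: no driver or non-driver locus left to mutate")
  p_d <- nd / (nd + params$beta * nn)
  c(driver = p_d, nondriver = 1 - p_d)
}

#' Energy and capacity constraints of a compartment
#'
#' Cells in a compartment are limited by a volume-exclusion capacity on
#' each driver-count class and, optionally, by a compartment energy budget
#' `E = sum_j e(j) * N(j) <= E_max`, where `e(j)` is the energetic need of
#' a cell with `j` drivers.  Either constraint can be disabled by leaving
#' it unbounded.
#'
#' @param capacity maximum cell count per (compartment, driver count):
#'   a scalar, a per-compartment vector, or a full matrix
#'   `[n_compartments x (m_d_bar+1)]`; `Inf` disables.
#' @param e optional numeric vector of energetic needs `e(j)`,
#'   `j = 0..m_d_bar`.
#' @param E_max per-compartment energy budget (scalar or vector); `Inf`
#'   disables.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(capacity = Inf, e = NULL, E_max = Inf) {
  if (!is.null(e) && any(e < 0)) stop("energetic needs 'e(j)' must be >= 0")
  if (any(capacity <= 0)) stop("capacities must be positive (or Inf)")
  structure(list(capacity = capacity, e = e, E_max = E_max),
            class = "energy_model")
}

#' Compartment energy
#'
#' The weighted sum `E = sum_j e(j) * N(j)` over driver-count classes; 0
#' when the model carries no energetic needs.
#'
#' @param counts numeric vector of cell counts `N(j)` for `j = 0, 1, ...`
#'   (position 1 is `j = 0`).
#' @param model an [energy_model].
#' @return numeric scalar.
#' @export
compartment_energy <- function(counts, model) {
  if (any(counts < 0)) stop("'counts' must be non-negative")
  if (is.null(model$e)) return(0)
  e <- model$e
  if (length(e) < length(counts)) e <- c(e, rep(0, length(counts) - length(e)))
  sum(e[seq_along(counts)] * counts)
}
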