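#' Cell state in mutation x compartment space
#'
#' A cell is described by `sigma = {d, m_n, m_m, k}`: a binary vector `d`
#' over the driver loci (1 = mutation acquired, loci never revert), the
#' count `m_n` of non-driver (passenger) mutations, the count `m_m` of
#' metabolic mutations (one is added at every proliferation event and
#' accelerates the cell's internal clock), and the 1-based compartment
#' index `k` (the tissue the cell currently occupies).
#'
#' @param d integer vector of 0/1 over the driver loci.
#' @param m_n non-negative integer, number of non-driver mutations.
#' @param m_m non-negative integer, number of metabolic mutations.
#' @param k compartment index, 1-based.
#' @return An object of class `cell_state`.
#' @examples
#' cell_state(c(1, 0, 0, 0), m_n = 2, m_m = 3, k = 1)
#' @export
cell_state <- function(d, m_n = 0L, m_m = 0L, k = 1L) {
  d <- as.integer(d)
  if (anyNA(d) || !all(d %in% c(0L, 1L)))
    stop("'d' must be a binary (0/1) vector over the driver loci")
  m_n <- as.integer(m_n); m_m <- as.integer(m_m); k <- as.integer(k)
  if (m_n < 0L || m_m < 0L) stop("mutation counts must be non-negative")
  if (k < 1L) stop("compartment index 'k' is 1-based")
  structure(list(d = d, m_n = m_n, m_m = m_m, k = k), class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state> d = (%s)  m_n = %d  m_m = %d  k = %d\n",
              paste(x$d, collapse = ","), x$m_n, x$m_m, x$k))
  invisible(x)
}

#' Ordered driver blocks and per-compartment migration thresholds
#'
#' Encodes the compartment-defined order of driver mutations as ordered
#' blocks `S''_1, ..., S''_l` (the drivers a cell must add while in
#' compartment k in order to move to compartment k+1).  Within a block the
#' order of acquisition is irrelevant; a block only starts to count once
#' every earlier block is complete.  The exit threshold of compartment k is
#' the size of the cumulative union `S'_k`, i.e. the number of effective
#' drivers needed to migrate out of (or, for the last compartment, seed in)
#' compartment k.
#'
#' @param blocks list of disjoint driver-locus index vectors (or gene-name
#'   vectors when `genes` is given or can be inferred), in compartment
#'   order; they must partition `1..m_d_bar`.
#' @param genes optional character vector of driver gene labels, one per
#'   locus, in locus order.
#' @param ordered logical; `FALSE` switches to unordered dynamics where the
#'   driver count `m_d` replaces the effective count `m_e` everywhere.
#' @return An object of class `driver_order_spec` with fields `genes`,
#'   `blocks`, `exit_threshold`, `ordered`, `n_compartments`, `m_d_bar`.
#' @examples
#' # breast -> circulation -> bone ordering of EPCAM, {CD47, CD44}, MET
#' driver_order_spec(
#'   blocks = list("EPCAM", c("CD47", "CD44"), "MET"))
#' @export
driver_order_spec <- function(blocks, genes = NULL, ordered = TRUE) {
  if (!is.list(blocks)) stop("'blocks' must be a list of index or name vectors")
  if (all(vapply(blocks, function(b) is.character(b) || length(b) == 0L, TRUE))) {
    nm <- unlist(blocks, use.names = FALSE)
    if (is.null(genes)) genes <- nm
    blocks <- lapply(blocks, function(b) match(b, genes))
    if (anyNA(unlist(blocks))) stop("block gene names not all found in 'genes'")
  } else {
    blocks <- lapply(blocks, as.integer)
  }
  idx <- unlist(blocks, use.names = FALSE)
  m_d_bar <- length(idx)
  if (m_d_bar > 0L && !identical(sort(idx), seq_len(m_d_bar)))
    stop("'blocks' must partition the driver loci 1..m_d_bar (disjoint, complete)")
  if (is.null(genes)) genes <- if (m_d_bar) paste0("driver", seq_len(m_d_bar)) else character(0)
  if (length(genes) != m_d_bar)
    stop("'genes' must have one label per driver locus")
  structure(list(
    genes = genes,
    blocks = blocks,
    exit_threshold = cumsum(lengths(blocks)),
    ordered = isTRUE(ordered),
    n_compartments = length(blocks),
    m_d_bar = m_d_bar
  ), class = "driver_order_spec")
}

#' @export
print.driver_order_spec <- function(x, ...) {
  cat(sprintf("<driver_order_spec> %s dynamics, %d loci, %d compartments\n",
              if (x$ordered) "ordered" else "unordered", x$m_d_bar, x$n_compartments))
  for (k in seq_along(x$blocks))
    cat(sprintf("  S''_%d = {%s}  exit threshold %d\n", k,
                paste(x$genes[x$blocks[[k]]], collapse = ", "),
                x$exit_threshold[k]))
  invisible(x)
}

#' Count effective driver mutations
#'
#' An acquired driver is *effective* only once every driver in all earlier
#' blocks has been acquired; drivers acquired out of order stay silent
#' until the missing prerequisites arrive.  Blocks are scanned in order:
#' complete blocks contribute their full size, the first incomplete block
#' contributes its acquired loci, and later blocks contribute nothing.  In
#' unordered mode the plain driver count `m_d = sum(d)` is returned.
#'
#' @param state a [cell_state] or a raw 0/1 driver vector.
#' @param order a [driver_order_spec].
#' @return Non-negative integer `m_e <= m_d`.
#' @examples
#' ord <- driver_order_spec(list("EPCAM", c("CD47", "CD44"), "MET"))
#' effective_drivers(c(1, 0, 0, 1), ord)  # MET silent without CD47+CD44 -> 1
#' @export
effective_drivers <- function(state, order) {
  d <- if (inherits(state, "cell_state")) state$d else as.integer(state)
  if (length(d) != order$m_d_bar)
    stop(sprintf("driver vector has length %d but the order spec has %d loci",
                 length(d), order$m_d_bar))
  if (!order$ordered) return(sum(d))
  m_e <- 0L
  for (b in order$blocks) {
    got <- sum(d[b])
    m_e <- m_e + got
    if (got < length(b)) break
  }
  m_e
}

#' Can a cell migrate out of its compartment?
#'
#' Migration `k -> k+1` requires at least the exit threshold of effective
#' drivers for compartment k (the filter k_pass of the transition rates);
#' cells in the terminal (secondary-site) compartment never migrate.
#'
#' @param state a [cell_state].
#' @param order a [driver_order_spec].
#' @return logical.
#' @export
can_migrate <- function(state, order) {
  k <- state$k
  if (k >= order$n_compartments) return(FALSE)
  effective_drivers(state, order) >= order$exit_threshold[k]
}

#' Drug target signature
#'
#' A partial state pattern: at administration time every cell whose state
#' matches all *nonzero* components of the signature is removed.  Zero
#' components are disregarded ("factors which do not affect the system when
#' they are equal to zero"), so the all-zero signature matches every cell.
#'
#' @param d 0/1 vector over driver loci; loci set to 1 must be mutated in a
#'   matching cell.
#' @param m_n,m_m exact non-driver / metabolic counts required (0 = any).
#' @param k compartment targeted (0 = any).
#' @param m_d exact total driver count required (0 = any).
#' @param time administration time `t_drug` in simulation time units
#'   (`NA` when the signature is used outside a simulation).
#' @return An object of class `drug_signature`.
#' @examples
#' # the CD47-specific circulating-cell drug of the bone-metastasis case study
#' drug_signature(d = c(0, 1, 0, 0), k = 2)
#' @export
drug_signature <- function(d, m_n = 0L, m_m = 0L, k = 0L, m_d = 0L, time = NA_real_) {
  d <- as.integer(d)
  if (anyNA(d) || !all(d %in% c(0L, 1L)))
    stop("'d' must be a binary (0/1) vector")
  if (m_n < 0L || m_m < 0L || k < 0L || m_d < 0L)
    stop("signature components must be non-negative")
  structure(list(d = d, m_n = as.integer(m_n), m_m = as.integer(m_m),
                 k = as.integer(k), m_d = as.integer(m_d), time = as.numeric(time)),
            class = "drug_signature")
}

#' Does a cell match a drug signature?
#'
#' Implements the Hadamard-product match `sigma_drug o sigma = sigma_drug o
#' sigma_drug` together with the driver-count condition
#' `m_d_drug * ||d||_1 = m_d_drug^2`: every nonzero signature component
#' must be reproduced exactly by the cell, and when `m_d > 0` the cell's
#' total driver count must equal it.
#'
#' @param state a [cell_state].
#' @param sig a [drug_signature].
#' @return logical.
#' @export
matches_drug <- function(state, sig) {
  if (length(sig$d) != length(state$d))
    stop("signature and cell driver vectors have different lengths")
  if (any(sig$d == 1L & state$d == 0L)) return(FALSE)
  if (sig$m_n != 0L && state$m_n != sig$m_n) return(FALSE)
  if (sig$m_m != 0L && state$m_m != sig$m_m) return(FALSE)
  if (sig$k != 0L && state$k != sig$k) return(FALSE)
  if (sig$m_d != 0L && sum(state$d) != sig$m_d) return(FALSE)
  TRUE
}

#' Exact fraction of driver combinations targeted by a drug
#'
#' Enumerates every driver vector with `sum(d) = m_d` that is viable in the
#' given compartment and returns the exact rational fraction of those that
#' match the signature's driver constraints.  Viability in ordered mode
#' means the vector contains every block needed to have entered the
#' compartment (effective drivers at least the exit threshold of the
#' previous compartment); in unordered mode `m_e = m_d`, so every
#' combination is viable whenever the compartment is reachable at all.
#'
#' @param sig a [drug_signature]; its `d` and `m_d` components constrain
#'   the match (a nonzero `k` different from `compartment` targets nothing).
#' @param order a [driver_order_spec]; its `ordered` flag selects the mode.
#' @param m_d total driver count of the sub-population, `1 <= m_d <= m_d_bar`.
#' @param compartment compartment index of the sub-population.
#' @return An object of class `targeting_fraction` with integer fields
#'   `numerator` and `denominator` and numeric `value` (`NA` with
#'   `denominator = 0` when no combination is viable — the explicit
#'   empty-domain result).
#' @examples
#' ord <- driver_order_spec(list("EPCAM", c("CD47", "CD44"), "MET"))
#' sig <- drug_signature(d = c(0, 1, 0, 0), k = 2)
#' fraction_targeted(sig, ord, m_d = 2, compartment = 2)  # 1/3
#' @export
fraction_targeted <- function(sig, order, m_d, compartment) {
  mbar <- order$m_d_bar
  if (m_d < 1L || m_d > mbar) stop("'m_d' must satisfy 1 <= m_d <= m_d_bar")
  if (mbar > 16L) stop("exact enumeration is guarded to m_d_bar <= 16 loci")
  if (compartment < 1L || compartment > order$n_compartments)
    stop("'compartment' out of range")
  req <- if (compartment >= 2L) order$exit_threshold[compartment - 1L] else 0L
  combs <- utils::combn(mbar, m_d)
  n_viable <- 0L; n_match <- 0L
  for (j in seq_len(ncol(combs))) {
    d <- integer(mbar); d[combs[, j]] <- 1L
    if (effective_drivers(d, order) < req) next
    n_viable <- n_viable + 1L
    if (sig$k != 0L && sig$k != compartment) next
    if (length(sig$d) != mbar) stop("signature driver vector length mismatch")
    if (any(sig$d == 1L & d == 0L)) next
    if (sig$m_d != 0L && m_d != sig$m_d) next
    n_match <- n_match + 1L
  }
  structure(list(numerator = n_match, denominator = n_viable,
                 value = if (n_viable > 0L) n_match / n_viable else NA_real_,
                 mode = if (order$ordered) "ordered" else "unordered",
                 m_d = as.integer(m_d), compartment = as.integer(compartment)),
            class = "targeting_fraction")
}

#' @export
print.targeting_fraction <- function(x, ...) {
  cat(sprintf("<targeting_fraction> %s, m_d = %d, compartment %d: %d/%d%s\n",
              x$mode, x$m_d, x$compartment, x$numerator, x$denominator,
              if (is.na(x$value)) "  (no viable combination)"
              else sprintf(" = %.6g", x$value)))
  invisible(x)
}
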