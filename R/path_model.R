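#' Compartment graph with migration transition matrix
#'
#' The compartments `c_1..c_m` form a graph with row-stochastic transition
#' matrix `T`; `c_1` is the primary tumour site and the last `n_secondary`
#' compartments are absorbing secondary (metastasis) sites, whose diagonal
#' entries are 1.  Each compartment may carry the set `S_k` of driver genes
#' a cell needs there to improve its fitness or migrate onward.
#'
#' @param transition numeric `m x m` row-stochastic matrix `T[i, j] =`
#'   probability of moving from compartment i to j.
#' @param labels optional compartment names.
#' @param n_secondary number of absorbing secondary sites (the last
#'   `n_secondary` indices).
#' @param required_sets optional list of per-compartment driver gene sets
#'   `S_k` (character vectors), used by [ordered_sets].
#' @return An object of class `compartment_graph`.
#' @examples
#' compartment_graph(
#'   transition = rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 1)),
#'   labels = c("breast", "circulation", "bone"), n_secondary = 1,
#'   required_sets = list("EPCAM", c("CD47", "CD44"), "MET"))
#' @export
compartment_graph <- function(transition, labels = NULL, n_secondary = 1L,
                              required_sets = NULL) {
  transition <- as.matrix(transition)
  m <- nrow(transition)
  problems <- character(0)
  if (ncol(transition) != m) problems <- c(problems, "transition: must be square")
  if (n_secondary < 1L || n_secondary >= m)
    problems <- c(problems, "n_secondary: need 1 <= n_secondary < m")
  if (any(transition < 0)) problems <- c(problems, "transition: entries must be >= 0")
  rs <- rowSums(transition)
  if (any(abs(rs - 1) > 1e-9))
    problems <- c(problems, sprintf("transition: rows must sum to 1 (row %s)",
                                    paste(which(abs(rs - 1) > 1e-9), collapse = ",")))
  secondary <- seq(m - n_secondary + 1L, m)
  if (length(problems) == 0) {
    if (any(abs(diag(transition)[secondary] - 1) > 1e-9))
      problems <- c(problems, "transition: secondary-site diagonal entries must be 1")
    if (m - n_secondary >= 1 && any(abs(diag(transition)[seq_len(m - n_secondary)]) > 1e-9))
      problems <- c(problems, "transition: non-secondary diagonal entries must be 0")
  }
  if (!is.null(required_sets) && length(required_sets) != m)
    problems <- c(problems, "required_sets: need one driver set per compartment")
  if (length(problems))
    stop("invalid compartment graph:\n  ", paste(problems, collapse = "\n  "))
  if (is.null(labels)) labels <- paste0("c", seq_len(m))
  structure(list(transition = transition, labels = labels, m = m,
                 n_secondary = as.integer(n_secondary), secondary = secondary,
                 required_sets = required_sets),
            class = "compartment_graph")
}

#' Probability density of a compartment path
#'
#' The density of a path `sigma(1), ..., sigma(n)` started in the primary
#' site is the product of its transition entries,
#' `rho = prod T[sigma(i), sigma(i+1)]` (the initial density is 1 since all
#' cells start in `c_1`).  A path may touch an absorbing secondary site
#' only as its final element.
#'
#' @param graph a [compartment_graph].
#' @param path integer vector of compartment indices starting at 1.
#' @return numeric probability in `[0, 1]`.
#' @export
path_density <- function(graph, path) {
  path <- as.integer(path)
  if (length(path) < 1L || path[1] != 1L)
    stop("a path must start at the primary site (compartment 1)")
  if (any(path < 1L | path > graph$m)) stop("path contains invalid compartment indices")
  if (length(path) > 1L && any(path[-length(path)] %in% graph$secondary))
    stop("invalid path: an absorbing secondary site can only terminate a path")
  if (length(path) == 1L) return(1)
  prod(graph$transition[cbind(path[-length(path)], path[-1])])
}

#' Most probable first-passage paths to a secondary site
#'
#' Enumerates every simple path that starts at the primary site and stops
#' at the *first* absorbing secondary site it reaches, and returns the
#' path(s) of maximal density (all ties are returned).  Enumeration is
#' guarded to graphs of at most 10 compartments.
#'
#' @param graph a [compartment_graph].
#' @return A list of class `compartment_paths` with `paths` (list of
#'   integer vectors), `densities`, `best` (indices of the maximal paths),
#'   and `max_density` (0 and empty `best` when no path has positive
#'   density).
#' @export
most_probable_paths <- function(graph) {
  if (graph$m > 10L)
    stop(sprintf("path enumeration is guarded to <= 10 compartments (got %d)", graph$m))
  paths <- list(); densities <- numeric(0)
  Tm <- graph$transition; secondary <- graph$secondary
  visit <- function(path, dens) {
    last <- path[length(path)]
    if (last %in% secondary) {
      paths[[length(paths) + 1L]] <<- path
      densities[[length(densities) + 1L]] <<- dens
      return(invisible())
    }
    for (j in setdiff(seq_len(graph$m), path)) {
      if (Tm[last, j] > 0) visit(c(path, j), dens * Tm[last, j])
    }
  }
  visit(1L, 1)
  best <- if (length(densities) && max(densities) > 0)
    which(densities >= max(densities) - 1e-12) else integer(0)
  structure(list(paths = paths, densities = densities, best = best,
                 max_density = if (length(densities)) max(densities) else 0,
                 labels = graph$labels),
            class = "compartment_paths")
}

#' @export
print.compartment_paths <- function(x, ...) {
  if (!length(x$best)) {
    cat("<compartment_paths> no path with positive density reaches a secondary site\n")
    return(invisible(x))
  }
  cat(sprintf("<compartment_paths> %d first-passage path(s), max density %.6g\n",
              length(x$paths), x$max_density))
  for (i in x$best)
    cat(sprintf("  * %s  (density %.6g)\n",
                paste(x$labels[x$paths[[i]]], collapse = " -> "), x$densities[i]))
  invisible(x)
}

#' Ordered driver sets along a compartment path
#'
#' From the per-compartment required sets `S_k` along a path, builds the
#' cumulative unions `S'_k = S_1 U ... U S_k` (the drivers a cell following
#' the right order holds on entering compartment k+1) and the increments
#' `S''_k = S'_k \ S'_(k-1)` (the drivers it must add while in compartment
#' k); when the `S_k` are disjoint, `S''_k = S_k`.  The result is exported
#' as a [driver_order_spec] whose exit thresholds are the sizes `|S'_k|`.
#'
#' @param graph a [compartment_graph] with `required_sets`.
#' @param path integer vector of compartment indices (e.g. the most
#'   probable path).
#' @return list with `S_prime`, `S_dprime` (lists of character vectors) and
#'   `order` (a [driver_order_spec]).
#' @examples
#' g <- compartment_graph(rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 1)),
#'                        c("breast", "circulation", "bone"), 1,
#'                        list("EPCAM", c("CD47", "CD44"), "MET"))
#' ordered_sets(g, c(1, 2, 3))$order
#' @export
ordered_sets <- function(graph, path) {
  if (is.null(graph$required_sets))
    stop("the compartment graph carries no per-compartment required driver sets")
  path <- as.integer(path)
  sets <- lapply(graph$required_sets[path], as.character)
  l <- length(sets)
  S_prime <- vector("list", l); S_dprime <- vector("list", l)
  acc <- character(0)
  for (k in seq_len(l)) {
    S_dprime[[k]] <- setdiff(sets[[k]], acc)
    acc <- c(acc, S_dprime[[k]])
    S_prime[[k]] <- acc
  }
  genes <- if (l) S_prime[[l]] else character(0)
  ord <- driver_order_spec(blocks = S_dprime, genes = genes, ordered = TRUE)
  list(S_prime = S_prime, S_dprime = S_dprime, order = ord)
}
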