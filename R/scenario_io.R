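#' @keywords internal
.scenario_schema <- list(
  top = c("name", "description", "provenance", "genes", "compartments",
          "ordered", "kinetics", "energy", "simulation", "drug"),
  compartments = c("labels", "n_secondary", "transition", "required_sets"),
  kinetics = c("alpha", "r", "amplitudes", "centers", "width", "s_bar",
               "beta", "bounds"),
  amplitudes = c("asym", "sym", "apop", "pass"),
  centers = c("asym", "sym", "apop"),
  bounds = c("m_d", "m_n", "m_m"),
  energy = c("capacity", "e", "E_max"),
  simulation = c("initial_cells", "t_end", "record_dt", "replicates", "seed"),
  drug = c("d", "m_n", "m_m", "k", "m_d", "time")
)

.check_keys <- function(x, allowed, where, problems) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    problems <- c(problems, sprintf("%s: unknown key(s) %s", where,
                                    paste(sQuote(unknown), collapse = ", ")))
  problems
}

#' Load a scenario configuration file
#'
#' Reads a YAML scenario (compartment graph with required driver sets,
#' kinetic parameters, energy/capacity constraints, simulation settings
#' and an optional drug signature), validates it, and assembles the
#' package objects: the migration path is the most probable compartment
#' path, from which the ordered driver sets and migration thresholds are
#' derived.  Unknown keys and every invalid field are reported by name.
#'
#' @param path path to the scenario file.
#' @return An object of class `scenario` with fields `name`,
#'   `description`, `provenance`, `graph`, `path`, `order`, `params`,
#'   `energy`, `config`, `drug`, `ordered`.
#' @seealso [scenario_fixture] for the packaged breast-to-bone cases.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop(sprintf("scenario file not found: %s", path))
  raw <- yaml::read_yaml(path)
  problems <- character(0)
  problems <- .check_keys(raw, .scenario_schema$top, "scenario", problems)
  for (sec in c("compartments", "kinetics", "simulation")) {
    if (is.null(raw[[sec]])) problems <- c(problems, sprintf("%s: section missing", sec))
  }
  if (!is.null(raw$compartments))
    problems <- .check_keys(raw$compartments, .scenario_schema$compartments,
                            "compartments", problems)
  if (!is.null(raw$kinetics)) {
    problems <- .check_keys(raw$kinetics, .scenario_schema$kinetics, "kinetics", problems)
    for (sub in c("amplitudes", "centers", "bounds"))
      if (!is.null(raw$kinetics[[sub]]))
        problems <- .check_keys(raw$kinetics[[sub]], .scenario_schema[[sub]],
                                paste0("kinetics$", sub), problems)
  }
  if (!is.null(raw$energy))
    problems <- .check_keys(raw$energy, .scenario_schema$energy, "energy", problems)
  if (!is.null(raw$simulation))
    problems <- .check_keys(raw$simulation, .scenario_schema$simulation,
                            "simulation", problems)
  if (!is.null(raw$drug))
    problems <- .check_keys(raw$drug, .scenario_schema$drug, "drug", problems)
  if (length(problems))
    stop("invalid scenario file:\n  ", paste(problems, collapse = "\n  "))

  collect <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      problems <<- c(problems, sprintf("%s: %s", what, conditionMessage(e)))
      NULL
    })
  }
  graph <- collect(compartment_graph(
    transition = do.call(rbind, raw$compartments$transition),
    labels = raw$compartments$labels,
    n_secondary = raw$compartments$n_secondary %||% 1L,
    required_sets = raw$compartments$required_sets), "compartments")
  kin <- raw$kinetics
  params <- collect(kinetics_params(
    alpha = kin$alpha, r = kin$r,
    amplitudes = unlist(kin$amplitudes), centers = unlist(kin$centers),
    width = kin$width, s_bar = kin$s_bar, beta = kin$beta %||% 1,
    bounds = kin$bounds), "kinetics")
  energy <- collect(energy_model(
    capacity = raw$energy$capacity %||% Inf,
    e = raw$energy$e,
    E_max = raw$energy$E_max %||% Inf), "energy")
  drug <- NULL
  if (!is.null(raw$drug))
    drug <- collect(drug_signature(
      d = unlist(raw$drug$d), m_n = raw$drug$m_n %||% 0L,
      m_m = raw$drug$m_m %||% 0L, k = raw$drug$k %||% 0L,
      m_d = raw$drug$m_d %||% 0L, time = raw$drug$time %||% NA_real_), "drug")
  sim <- raw$simulation
  config <- collect(simulation_config(
    t_end = sim$t_end, initial_cells = sim$initial_cells %||% 10L,
    record_dt = sim$record_dt %||% (sim$t_end / 50),
    replicates = sim$replicates %||% 1L, seed = sim$seed %||% 1L,
    drug = drug), "simulation")
  if (length(problems))
    stop("invalid scenario file:\n  ", paste(problems, collapse = "\n  "))

  mp <- most_probable_paths(graph)
  if (!length(mp$best))
    stop("scenario: no compartment path with positive density reaches a secondary site")
  path <- mp$paths[[mp$best[1L]]]
  os <- ordered_sets(graph, path)
  order <- os$order
  order$ordered <- !identical(raw$ordered, FALSE)
  genes <- raw$genes %||% order$genes
  if (!setequal(genes, order$genes))
    stop("scenario: 'genes' disagrees with the union of the compartments' required sets")
  if (params$bounds$m_d != order$m_d_bar)
    stop(sprintf("scenario: kinetics$bounds$m_d = %d but the path requires %d driver loci",
                 params$bounds$m_d, order$m_d_bar))
  if (!is.null(drug) && length(drug$d) != order$m_d_bar)
    stop("scenario: drug$d length does not match the driver loci")

  structure(list(
    name = raw$name %||% basename(path),
    description = raw$description %||% "",
    provenance = raw$provenance %||% "",
    graph = graph, path = path, order = order, params = params,
    energy = energy, config = config, drug = drug,
    ordered = order$ordered),
    class = "scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario back to a YAML file
#'
#' Inverse of [load_scenario]; loading the written file reproduces the
#' scenario's fields.
#'
#' @param scenario a `scenario`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  g <- scenario$graph; p <- scenario$params; cfg <- scenario$config
  out <- list(
    name = scenario$name,
    description = scenario$description,
    provenance = scenario$provenance,
    genes = scenario$order$genes,
    compartments = list(
      labels = g$labels,
      n_secondary = g$n_secondary,
      transition = lapply(seq_len(g$m), function(i) as.numeric(g$transition[i, ])),
      required_sets = lapply(g$required_sets, as.character)),
    ordered = scenario$ordered,
    kinetics = list(
      alpha = p$alpha, r = p$r,
      amplitudes = as.list(p$amplitudes),
      centers = as.list(p$centers),
      width = p$width, s_bar = p$s_bar, beta = p$beta,
      bounds = p$bounds),
    energy = list(capacity = scenario$energy$capacity,
                  e = scenario$energy$e, E_max = scenario$energy$E_max),
    simulation = list(initial_cells = cfg$initial_cells, t_end = cfg$t_end,
                      record_dt = cfg$record_dt, replicates = cfg$replicates,
                      seed = cfg$seed))
  if (!is.null(scenario$drug)) {
    d <- scenario$drug
    out$drug <- list(d = d$d, m_n = d$m_n, m_m = d$m_m, k = d$k,
                     m_d = d$m_d, time = d$time)
  }
  out$energy <- Filter(Negate(is.null), out$energy)
  if (identical(out$energy$E_max, Inf)) out$energy$E_max <- NULL
  if (identical(out$energy$capacity, Inf)) out$energy$capacity <- NULL
  if (!length(out$energy)) out$energy <- NULL
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Packaged breast-to-bone case scenarios
#'
#' Loads one of the shipped drug-treatment scenarios of the breast duct ->
#' circulation -> bone case study: `"case1"` kills every circulating cell
#' with exactly one driver mutation, `"case2"` those with exactly two, and
#' `"case3"` the circulating cells carrying the CD47 driver specifically.
#' Kinetic amplitudes, supports and capacities are calibrated defaults
#' (the published study does not print them) and are flagged as such in
#' each file's `provenance` field.
#'
#' @param name `"case1"`, `"case2"` or `"case3"`.
#' @return a `scenario`.
#' @export
scenario_fixture <- function(name = c("case1", "case2", "case3")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "compclone")
  if (path == "") stop("packaged scenario not found; is the package installed?")
  load_scenario(path)
}

#' Exact drug-targeting combinatorics of a scenario
#'
#' For the scenario's drug signature and compartment, tabulates the exact
#' fraction of driver combinations targeted for each driver count in both
#' ordered and unordered dynamics (the signature's compartment is used;
#' driver counts 1..3 by default, capped at the number of loci).
#'
#' @param scenario a `scenario` with a drug.
#' @param m_d driver counts to tabulate.
#' @return data frame with columns `mode`, `m_d`, `numerator`,
#'   `denominator`, `fraction`.
#' @export
combinatorics_report <- function(scenario, m_d = 1:3) {
  if (is.null(scenario$drug)) stop("the scenario has no drug signature")
  sig <- scenario$drug
  compartment <- if (sig$k != 0L) sig$k else 1L
  m_d <- m_d[m_d <= scenario$order$m_d_bar]
  rows <- list()
  for (mode in c("unordered", "ordered")) {
    ord <- scenario$order
    ord$ordered <- mode == "ordered"
    for (md in m_d) {
      fr <- fraction_targeted(sig, ord, md, compartment)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, m_d = md, numerator = fr$numerator,
        denominator = fr$denominator, fraction = fr$value)
    }
  }
  do.call(rbind, rows)
}

#' Run the ordered/unordered x drug/no-drug variants of a scenario
#'
#' Runs the four ensemble variants the case studies compare, optionally
#' writing per-variant trajectory CSVs, a JSON summary and a combined
#' figure.  All variants share the scenario's master seed, so the no-drug
#' variants are the exact drug-free counterfactuals of the drug runs.
#'
#' @param scenario a `scenario`.
#' @param variants subset of `c("ordered", "unordered")` to run.
#' @param drug subset of `c(TRUE, FALSE)`: with and/or without the drug.
#' @param replicates optional override of the scenario's ensemble size.
#' @param out_dir optional output directory for CSV/JSON (and PNG when
#'   `plot = TRUE`).
#' @param plot write a trajectory figure (requires an available graphics
#'   device).
#' @return list with `ensembles` (named `ordered_drug`, `ordered_nodrug`,
#'   ...) and `summary` (data frame: variant, final counts per
#'   compartment, extinction flag, first bone-seeding time).
#' @export
run_case <- function(scenario, variants = c("ordered", "unordered"),
                     drug = c(TRUE, FALSE), replicates = NULL,
                     out_dir = NULL, plot = FALSE) {
  variants <- match.arg(variants, several.ok = TRUE)
  ensembles <- list()
  summaries <- list()
  for (v in variants) for (dg in drug) {
    tag <- paste0(v, if (dg) "_drug" else "_nodrug")
    ord <- scenario$order; ord$ordered <- v == "ordered"
    cfg <- scenario$config
    if (!dg) { cfg$drug <- NULL; cfg$t_drug <- NA_real_ }
    if (dg && is.null(cfg$drug)) next
    if (!is.null(replicates)) cfg$replicates <- as.integer(replicates)
    ens <- run_ensemble(cfg, scenario$params, ord, scenario$energy)
    ensembles[[tag]] <- ens
    kb <- ens$dims$k_bar
    last <- length(ens$times)
    final_by_k <- apply(ens$mean[last, , , drop = FALSE], 2, sum)
    bone <- apply(ens$mean[, kb, , drop = FALSE], 1, sum)
    first_seed <- if (any(bone > 0)) ens$times[which(bone > 0)[1L]] else NA_real_
    summaries[[tag]] <- data.frame(
      variant = tag,
      t(stats::setNames(final_by_k, paste0("final_", scenario$graph$labels))),
      extinct = all(ens$extinct),
      first_seeding_time = first_seed)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(trajectory_frame(ens, replicates = FALSE),
                       file.path(out_dir, paste0(scenario$name, "_", tag, ".csv")),
                       row.names = FALSE)
    }
  }
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    manifest <- list(
      scenario = scenario$name, provenance = scenario$provenance,
      seed = scenario$config$seed,
      replicates = if (is.null(replicates)) scenario$config$replicates else replicates,
      variants = names(ensembles),
      package_version = as.character(utils::packageVersion("compclone")),
      r_version = R.version.string)
    jsonlite::write_json(manifest,
                         file.path(out_dir, paste0(scenario$name, "_manifest.json")),
                         auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(summary,
                         file.path(out_dir, paste0(scenario$name, "_summary.json")),
                         dataframe = "rows", pretty = TRUE)
    if (plot) {
      gg <- plot_case(ensembles, scenario)
      ggplot2::ggsave(file.path(out_dir, paste0(scenario$name, ".png")),
                      gg, width = 10, height = 2.5 * length(ensembles), dpi = 150)
    }
  }
  list(ensembles = ensembles, summary = summary)
}

#' Trajectory figure for a set of case variants
#'
#' One panel per (variant, compartment), sub-population curves coloured by
#' driver count, with a vertical marker at the drug administration time.
#'
#' @param ensembles named list of `ca_ensemble` objects (as produced by
#'   [run_case]).
#' @param scenario the `scenario` the ensembles came from.
#' @return a ggplot object.
#' @export
plot_case <- function(ensembles, scenario) {
  frames <- lapply(names(ensembles), function(tag) {
    fr <- trajectory_frame(ensembles[[tag]])
    fr <- fr[fr$replicate == "mean", ]
    fr$variant <- tag
    fr
  })
  df <- do.call(rbind, frames)
  df$compartment <- factor(df$compartment, levels = seq_len(scenario$graph$m),
                           labels = scenario$graph$labels)
  df$m_d <- factor(df$m_d)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = time, y = count, colour = m_d)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(variant ~ compartment) +
    ggplot2::labs(x = "time (simulation units)", y = "mean cell count",
                  colour = "drivers") +
    ggplot2::theme_bw()
  if (!is.null(scenario$drug) && is.finite(scenario$config$t_drug))
    gg <- gg + ggplot2::geom_vline(xintercept = scenario$config$t_drug,
                                   linetype = "dashed")
  gg
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s (%s dynamics)\n", x$name,
              if (x$ordered) "ordered" else "unordered"))
  cat(sprintf("  path: %s\n", paste(x$graph$labels[x$path], collapse = " -> ")))
  cat(sprintf("  drivers: %s\n", paste(x$order$genes, collapse = ", ")))
  if (!is.null(x$drug))
    cat(sprintf("  drug at t=%.3g: d=(%s) m_n=%d m_m=%d k=%d m_d=%d\n",
                x$config$t_drug, paste(x$drug$d, collapse = ","),
                x$drug$m_n, x$drug$m_m, x$drug$k, x$drug$m_d))
  if (nzchar(x$provenance)) cat(sprintf("  provenance: %s\n", x$provenance))
  invisible(x)
}
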