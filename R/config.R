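#' Read and validate a run configuration
#'
#' Configurations are YAML mappings. Recognized top-level keys:
#' `networks` (list of file paths, or the string `"synthetic_suite"`, or a
#' list of generator mappings with keys `n_plants`, `m_pollinators`,
#' `connectance_target`, `attachment_bias`, `seed`), `models`, `scenarios`,
#' `fractions`, `strategies`, `ensembles`, `master_seed`, `target_side`,
#' `params` (overrides for [nd_params()] / [oned_params()] fields),
#' `control` (see [simulate_restoration()]), and `output_dir`. Unknown
#' keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  validate_run_config(yaml::read_yaml(path))
}

#' @describeIn read_run_config Validate an in-memory configuration list.
#' @param cfg Configuration list.
#' @export
validate_run_config <- function(cfg) {
  known <- c("networks", "models", "scenarios", "fractions", "strategies",
             "ensembles", "master_seed", "target_side", "params", "control",
             "output_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  }
  cfg$models <- cfg$models %||% c("1D", "2D")
  cfg$scenarios <- cfg$scenarios %||%
    c("random", "generalist_preferred", "specialist_preferred")
  cfg$fractions <- cfg$fractions %||% c(0.3, 0.6, 0.9)
  cfg$strategies <- cfg$strategies %||%
    c("degree", "closeness", "betweenness", "beta_eff_greedy", "random")
  cfg$ensembles <- cfg$ensembles %||% 10L
  cfg$master_seed <- cfg$master_seed %||% 1L
  cfg$target_side <- cfg$target_side %||% "both"
  cfg$params <- cfg$params %||% list()
  cfg$control <- cfg$control %||% list()
  stopifnot(all(cfg$models %in% c("1D", "2D", "nD")),
            all(cfg$scenarios %in% c("random", "generalist_preferred",
                                     "specialist_preferred")),
            all(cfg$strategies %in% c("degree", "closeness", "betweenness",
                                      "beta_eff_greedy", "random")),
            cfg$target_side %in% c("both", "plants", "pollinators"),
            cfg$ensembles >= 1)
  if (any(cfg$fractions <= 0 | cfg$fractions >= 1)) {
    stop("fractions must lie strictly between 0 and 1")
  }
  bad_par <- setdiff(names(cfg$params),
                     c(names(formals(nd_params)), names(formals(oned_params))))
  if (length(bad_par)) {
    stop("unknown model parameters: ", paste(bad_par, collapse = ", "))
  }
  class(cfg) <- "run_config"
  cfg
}

# Materialize the configured networks as a named list.
config_networks <- function(cfg) {
  nets <- cfg$networks
  if (is.null(nets) || identical(nets, "synthetic_suite")) {
    suite <- synthetic_suite()
    return(stats::setNames(lapply(suite, generate_network), names(suite)))
  }
  if (is.character(nets)) {
    out <- lapply(nets, read_incidence)
    names(out) <- tools::file_path_sans_ext(basename(nets))
    return(out)
  }
  out <- list()
  for (i in seq_along(nets)) {
    g <- nets[[i]]
    cfgi <- generator_config(g$n_plants, g$m_pollinators,
                             g$connectance_target,
                             g$attachment_bias %||% 0, g$seed %||% i)
    nm <- names(nets)[i] %||% sprintf("GEN_%02d", i)
    if (is.null(nm) || nm == "") nm <- sprintf("GEN_%02d", i)
    out[[nm]] <- generate_network(cfgi)
  }
  out
}

config_model_params <- function(cfg) {
  nd_over <- cfg$params[intersect(names(cfg$params), names(formals(nd_params)))]
  od_over <- cfg$params[intersect(names(cfg$params), names(formals(oned_params)))]
  list(nd = do.call(nd_params, nd_over),
       oned = do.call(oned_params, od_over))
}

#' Generate and write the configured network suite
#'
#' Writes one incidence CSV per configured network plus a
#' `manifest.json` (file names, generator settings, package version),
#' deterministically for a given configuration.
#'
#' @param cfg A [read_run_config()] configuration (or path to one).
#' @param out_dir Output directory (created if missing); defaults to the
#'   config's `output_dir`.
#' @return Invisibly, the paths written.
#' @export
cmd_generate <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  out_dir <- out_dir %||% cfg$output_dir %||% stop("no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nets <- config_networks(cfg)
  paths <- character()
  for (nm in names(nets)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_incidence(nets[[nm]], p, "weblife_csv")
    paths <- c(paths, p)
  }
  manifest <- list(networks = basename(paths),
                   master_seed = cfg$master_seed,
                   package_version = as.character(utils::packageVersion("netrestore")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, file.path(out_dir, "manifest.json")))
}

#' Run the configured experiment and write result tables
#'
#' Executes [run_experiment()] for the configuration and writes
#' `results.csv` (step-level records), `winners.csv` (per-cell winning
#' strategies for each criterion), `correlations.csv`
#' (attribute-criterion statistics per model), and `manifest.json`
#' (config echo + master seed) into the output directory. With
#' `resume = TRUE`, cells already present in an existing `results.csv`
#' are kept and skipped.
#'
#' @inheritParams cmd_generate
#' @param resume Reuse completed cells from an existing `results.csv`.
#' @return Invisibly, the step-level results data.frame.
#' @export
cmd_run <- function(cfg, out_dir = NULL, resume = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  out_dir <- out_dir %||% cfg$output_dir %||% stop("no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nets <- config_networks(cfg)
  pars <- config_model_params(cfg)
  res_path <- file.path(out_dir, "results.csv")
  prev <- NULL
  if (resume && file.exists(res_path)) {
    prev <- utils::read.csv(res_path, stringsAsFactors = FALSE)
    done <- unique(prev$network_id)
    nets <- nets[setdiff(names(nets), done)]
  }
  res <- if (length(nets)) {
    run_experiment(nets, models = cfg$models, scenarios = cfg$scenarios,
                   fractions = cfg$fractions, strategies = cfg$strategies,
                   ensembles = cfg$ensembles, master_seed = cfg$master_seed,
                   target_side = cfg$target_side, nd = pars$nd,
                   oned = pars$oned, control = cfg$control)
  } else NULL
  if (!is.null(prev)) res <- rbind(prev, as.data.frame(res))
  utils::write.csv(res, res_path, row.names = FALSE)
  summ <- summarize_experiment(res)
  utils::write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
  winners <- do.call(rbind, lapply(c("X", "ST", "P"), function(cr) {
    w <- identify_winner(summ, cr)
    w$criterion <- cr
    w
  }))
  utils::write.csv(winners, file.path(out_dir, "winners.csv"),
                   row.names = FALSE)
  corrs <- do.call(rbind, lapply(intersect(cfg$models, unique(res$model)),
                                 function(md) {
    ac <- tryCatch(attribute_correlations(res, md, "X"),
                   error = function(e) NULL)
    if (is.null(ac)) return(NULL)
    cbind(data.frame(model = md, r_squared = ac$r_squared), ac$per_attribute)
  }))
  utils::write.csv(corrs, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  manifest <- list(master_seed = cfg$master_seed, models = cfg$models,
                   scenarios = cfg$scenarios, fractions = cfg$fractions,
                   strategies = cfg$strategies, ensembles = cfg$ensembles,
                   n_failed_cells = sum(!res$ok),
                   package_version = as.character(utils::packageVersion("netrestore")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Exhaustively enumerate restoration pathways for one network
#'
#' Perturbs the network once, enumerates every reintroduction ordering of
#' the removed species (see [enumerate_pathways()]), simulates each with
#' the chosen model, and overlays the named strategies' pathways. The
#' resulting table supports the "strategy curves inside the exhaustive
#' envelope" analysis.
#'
#' @param net A [bipartite_network()].
#' @param fraction Removal fraction.
#' @param model `"1D"`, `"2D"` or `"nD"`.
#' @param scenario_kind Perturbation scenario kind.
#' @param target_side Removal pool.
#' @param seed Seed for the perturbation draw.
#' @param strategies Strategy kinds to overlay.
#' @param cap Enumeration cap on the number of removed species.
#' @param out Optional CSV path for the combined table.
#' @param control Passed to [simulate_restoration()].
#' @return Data.frame: pathway (id or strategy name), step, species, X,
#'   ST, P; exhaustive pathways carry `kind = "enumerated"`, overlays
#'   `kind = "strategy"`.
#' @export
cmd_enumerate <- function(net, fraction, model = "1D",
                          scenario_kind = "random", target_side = "plants",
                          seed = 1L,
                          strategies = c("degree", "closeness",
                                         "betweenness", "random"),
                          cap = 8L, out = NULL, control = list()) {
  scen <- perturbation_scenario(scenario_kind, fraction, target_side,
                                seed = seed)
  outcome <- perturb(net, scen)
  removed <- c(outcome$primary_removed, outcome$secondary_removed)
  paths <- enumerate_pathways(removed, cap = cap)
  params <- if (model == "1D") oned_params() else nd_params()
  sim <- function(sq) simulate_restoration(net, outcome, sq, model = model,
                                           params = params, control = control)
  rows <- lapply(seq_along(paths), function(i) {
    ps <- sim(paths[[i]])$per_step
    cbind(data.frame(kind = "enumerated", pathway = sprintf("path_%04d", i)),
          ps[c("step", "species", "X", "ST", "P")])
  })
  for (st in strategies) {
    stg <- restoration_strategy(st, seed = seed)
    sq <- if (st == "beta_eff_greedy") {
      beta_eff_greedy_sequence(net, outcome$degraded_net, removed)
    } else {
      rank_sequence(net, removed, stg, degraded_net = outcome$degraded_net)
    }
    ps <- sim(sq)$per_step
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(kind = "strategy", pathway = st),
            ps[c("step", "species", "X", "ST", "P")])
  }
  res <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  invisible(res)
}
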