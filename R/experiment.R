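#' Run the full restoration experiment sweep
#'
#' Full factorial sweep over networks x models x perturbation scenarios x
#' removal fractions x strategies x ensembles. Every cell derives its own
#' seed from the master seed and a stable hash of the cell key, so the
#' whole sweep is reproducible and any cell can be recomputed in
#' isolation. A failing cell is recorded (flag `ok = FALSE`) and the sweep
#' continues.
#'
#' @param networks Named list of [bipartite_network()] objects.
#' @param models Character subset of `c("1D", "2D", "nD")`.
#' @param scenarios Character subset of the [perturbation_scenario()]
#'   kinds.
#' @param fractions Removal fractions (the standard design is
#'   `c(0.3, 0.6, 0.9)`).
#' @param strategies Character subset of the [restoration_strategy()]
#'   kinds.
#' @param ensembles Ensembles per combination (default 10).
#' @param master_seed Master seed for the whole sweep.
#' @param target_side Removal pool, see [perturbation_scenario()].
#' @param nd,oned Base parameter objects ([nd_params()], [oned_params()]).
#' @param control Passed to [simulate_restoration()].
#' @return A data.frame of class `experiment_result`: one row per
#'   restoration step with columns network_id, model, scenario, fraction,
#'   strategy, ensemble, seed, ok, step, species, X, ST, P, settled, and
#'   the current network attributes S, A, C, NODF.
#' @export
run_experiment <- function(networks, models = c("1D", "2D"),
                           scenarios = c("random", "generalist_preferred",
                                         "specialist_preferred"),
                           fractions = c(0.3, 0.6, 0.9),
                           strategies = c("degree", "closeness",
                                          "betweenness", "beta_eff_greedy",
                                          "random"),
                           ensembles = 10L, master_seed = 1L,
                           target_side = "both",
                           nd = nd_params(), oned = oned_params(),
                           control = list()) {
  stopifnot(length(networks) > 0, !is.null(names(networks)))
  rows <- list()
  for (net_id in names(networks)) {
    net <- networks[[net_id]]
    for (model in models) for (sc in scenarios) for (fr in fractions) {
      for (ens in seq_len(ensembles)) {
        pseed <- derive_seed(master_seed,
                             paste(net_id, sc, fr, ens, sep = "|"))
        scen <- perturbation_scenario(sc, fr, target_side, seed = pseed)
        outcome <- tryCatch(perturb(net, scen), error = function(e) e)
        for (strat in strategies) {
          key <- paste(net_id, model, sc, fr, strat, ens, sep = "|")
          sseed <- derive_seed(master_seed, key)
          cell <- tryCatch({
            if (inherits(outcome, "error")) stop(conditionMessage(outcome))
            removed <- c(outcome$primary_removed, outcome$secondary_removed)
            stg <- restoration_strategy(strat, seed = sseed)
            sq <- if (strat == "beta_eff_greedy") {
              beta_eff_greedy_sequence(net, outcome$degraded_net, removed,
                                       side = control$side %||% "plants")
            } else {
              rank_sequence(net, removed, stg,
                            degraded_net = outcome$degraded_net)
            }
            run <- simulate_restoration(
              net, outcome, sq, model = model,
              params = if (model == "1D") oned else nd,
              control = control, strategy = stg)
            if (nrow(run$per_step) == 0) stop("empty restoration run")
            cbind(data.frame(network_id = net_id, model = model,
                             scenario = sc, fraction = fr, strategy = strat,
                             ensemble = ens, seed = sseed,
                             ok = !run$failed, stringsAsFactors = FALSE),
                  run$per_step)
          }, error = function(e) {
            data.frame(network_id = net_id, model = model, scenario = sc,
                       fraction = fr, strategy = strat, ensemble = ens,
                       seed = sseed, ok = FALSE, step = NA_integer_,
                       species = NA_character_, X = NA_real_, ST = NA_real_,
                       P = NA_real_, settled = NA, S = NA_real_,
                       A = NA_real_, C = NA_real_, NODF = NA_real_,
                       stringsAsFactors = FALSE)
          })
          rows[[length(rows) + 1L]] <- cell
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("experiment_result", "data.frame")
  res
}

#' Average criteria per strategy cell
#'
#' For every (network, model, scenario, fraction, strategy) cell: mean of
#' each criterion over the restoration steps within a run, then over the
#' ensembles. Averaging over steps first makes networks with different
#' numbers of removed species comparable. Runs that never settled carry
#' the sentinel settling time (the integration horizon); their count is
#' reported as `n_censored`.
#'
#' @param result An [run_experiment()] result (or any data.frame with the
#'   same columns).
#' @return Data.frame with one row per cell: mean_X, mean_ST, mean_P,
#'   n_ensembles, n_censored.
#' @export
summarize_experiment <- function(result) {
  res <- result[!is.na(result$step) & result$ok, , drop = FALSE]
  if (!nrow(res)) stop("no successful runs to summarize")
  key_run <- c("network_id", "model", "scenario", "fraction", "strategy",
               "ensemble")
  per_run <- stats::aggregate(res[c("X", "ST", "P")], by = res[key_run],
                              FUN = mean)
  per_run$censored <- stats::aggregate(
    !res$settled, by = res[key_run], FUN = any)$x
  key_cell <- utils::head(key_run, -1L)
  out <- stats::aggregate(per_run[c("X", "ST", "P")], by = per_run[key_cell],
                          FUN = mean)
  names(out)[names(out) %in% c("X", "ST", "P")] <-
    c("mean_X", "mean_ST", "mean_P")
  out$n_ensembles <- stats::aggregate(
    per_run$ensemble, by = per_run[key_cell], FUN = length)$x
  out$n_censored <- stats::aggregate(
    per_run$censored, by = per_run[key_cell], FUN = sum)$x
  out[do.call(order, out[key_cell]), , drop = FALSE]
}

#' Identify the winning strategy per cell
#'
#' For each (network, model, scenario, fraction) cell the winner under a
#' criterion is the strategy with the highest mean abundance or
#' persistence, or the lowest mean settling time. Exact ties are resolved
#' by abundance, then settling time, then ascending strategy label. The
#' margin to the runner-up is reported as a percentage of the winning
#' value, supporting "best vs rest within x%" comparisons.
#'
#' @param summary A [summarize_experiment()] table.
#' @param criterion `"X"`, `"P"` or `"ST"`.
#' @return Data.frame with one row per cell: winner, runner_up,
#'   margin_pct.
#' @export
identify_winner <- function(summary, criterion = c("X", "P", "ST")) {
  criterion <- match.arg(criterion)
  col <- paste0("mean_", criterion)
  key <- c("network_id", "model", "scenario", "fraction")
  cells <- unique(summary[key])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, , drop = FALSE]
    sub <- merge(summary, cell)
    if (nrow(sub) < 2L) stop("need at least two strategies per cell")
    sgn <- if (criterion == "ST") 1 else -1
    ord <- order(sgn * sub[[col]], -sub$mean_X, sub$mean_ST, sub$strategy)
    sub <- sub[ord, , drop = FALSE]
    best <- sub[[col]][1L]
    second <- sub[[col]][2L]
    margin <- if (best == 0) 0 else abs(best - second) / abs(best) * 100
    cbind(cell,
          data.frame(winner = sub$strategy[1L], runner_up = sub$strategy[2L],
                     margin_pct = margin, stringsAsFactors = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` computed by a sweep over the pooled sample
#' points, with the asymptotic Kolmogorov p-value using the Stephens
#' small-sample correction
#' `lambda = (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * D`.
#'
#' @param a,b Numeric samples (each of size `>= 2`).
#' @return List with `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("both samples need at least 2 observations")
  }
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(pts, function(x) mean(b <= x), numeric(1))
  D <- max(abs(Fa - Fb))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(statistic = D, p.value = min(1, max(0, p)))
}

#' Attribute-criterion correlations and regression
#'
#' Pools the step-level records for one model, min-max normalizes the
#' criterion and the four network attributes (S, A, C, NODF) to 0-1, and
#' reports for each attribute the Spearman rank correlation and the simple
#' linear-regression slope, plus the R-squared of one multivariate
#' ordinary-least-squares fit of the criterion on all attributes jointly.
#' Zero-variance attributes are excluded with a warning.
#'
#' @param result An [run_experiment()] result.
#' @param model Which model's rows to analyze.
#' @param criterion `"X"`, `"ST"` or `"P"`.
#' @return List with `per_attribute` (data.frame: attribute, spearman_rho,
#'   coef) and `r_squared`.
#' @export
attribute_correlations <- function(result, model, criterion = "X") {
  stopifnot(criterion %in% c("X", "ST", "P"))
  sub <- result[result$model == model & result$ok & !is.na(result$step), ,
                drop = FALSE]
  cols <- c("S", "A", "C", "NODF")
  sub <- sub[stats::complete.cases(sub[c(criterion, cols)]), , drop = FALSE]
  if (nrow(sub) < 3L) stop("need at least 3 complete rows")
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) return(NULL)
    (x - r[1L]) / diff(r)
  }
  y <- norm01(sub[[criterion]])
  if (is.null(y)) stop("criterion has zero variance")
  attrs <- list()
  for (a in cols) {
    v <- norm01(sub[[a]])
    if (is.null(v)) {
      warning("attribute ", a, " has zero variance; excluded")
    } else {
      attrs[[a]] <- v
    }
  }
  per <- do.call(rbind, lapply(names(attrs), function(a) {
    data.frame(attribute = a,
               spearman_rho = stats::cor(y, attrs[[a]], method = "spearman"),
               coef = unname(stats::coef(
                 stats::lm(y ~ attrs[[a]]))[2L]),
               stringsAsFactors = FALSE)
  }))
  df <- data.frame(y = y, attrs)
  fit <- stats::lm(y ~ ., data = df)
  list(per_attribute = per, r_squared = summary(fit)$r.squared)
}
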