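# Probabilistic sensitivity analysis, one-way deterministic sensitivity
# analysis and scenario analyses.

# Write one sampled/altered value back into its slot in the parameter set.
assign_parameter <- function(pset, block, key, value) {
  switch(block,
    effectiveness = {
      pset$effectiveness$quit_prob_12m[pset$effectiveness$arm == key] <- value
    },
    smi = pset$smi[[key]][["mean"]] <- value,
    utilities = pset$utilities[[key]][["mean"]] <- value,
    comorbidity_cost = {
      pset$comorbidities$annual_cost_mean[
        pset$comorbidities$condition == key] <- value
    },
    comorbidity_utility = {
      pset$comorbidities$utility_mean[
        pset$comorbidities$condition == key] <- value
    },
    transitions = pset$transitions[[key]][["mean"]] <- value,
    stop("unknown parameter block: ", block)
  )
  pset
}

#' Set a named model parameter to a given value
#'
#' @param pset An \code{smi_parameters} object.
#' @param name Parameter name as in \code{\link{psa_parameter_table}}.
#' @param value New value (magnitude scale for decrements).
#' @return The modified parameter set.
#' @export
set_parameter <- function(pset, name, value) {
  tab <- psa_parameter_table(pset)
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1) stop("unknown parameter: ", name, call. = FALSE)
  assign_parameter(pset, row$block, row$key, value)
}

#' Draw one probabilistic parameter set
#'
#' Replaces every stochastic parameter by a single draw from its
#' moment-matched distribution (see \code{\link{psa_parameter_table}});
#' parameters with SD 0 stay at their point estimate. Draws use the current
#' RNG stream in the fixed row order of the parameter table, so a given
#' seed reproduces the same sequence of sets. Shared parameters are drawn
#' once per call and therefore act as common random numbers across arms;
#' each arm's effectiveness is drawn independently. Decrements are drawn on
#' magnitude; the negative sign is applied where they enter the model.
#'
#' @param pset An \code{smi_parameters} object (point estimates and SDs).
#' @param table Optional pre-computed parameter table.
#' @return A new \code{smi_parameters} object with sampled point values.
#' @export
sample_iteration <- function(pset, table = psa_parameter_table(pset)) {
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    spec <- moment_match(r$family, r$mean, r$sd, sign = r$sign, name = r$name)
    pset <- assign_parameter(pset, r$block, r$key, dist_draw(spec, 1))
  }
  pset
}

#' Cost-effectiveness acceptability curve
#'
#' @param delta_cost,delta_qalys Per-iteration incremental costs and QALYs.
#' @param thresholds Willingness-to-pay grid (GBP/QALY).
#' @return Data frame with columns \code{threshold} and
#'   \code{probability} (fraction of iterations with positive net monetary
#'   benefit).
#' @export
ceac <- function(delta_cost, delta_qalys, thresholds = seq(0, 50000, 500)) {
  probability <- vapply(thresholds, function(l) {
    mean(l * delta_qalys - delta_cost > 0)
  }, numeric(1))
  data.frame(threshold = thresholds, probability = probability)
}

#' Probabilistic sensitivity analysis
#'
#' Evaluates the full model once per iteration with a fresh probabilistic
#' parameter set, using common random numbers for parameters shared across
#' arms. Reports iteration-level costs and QALYs per arm, the probabilistic
#' ICER (ratio of mean incremental cost to mean incremental QALYs), the
#' probability the intervention is cost-effective at the decision
#' threshold, and the acceptability curve over a threshold grid.
#'
#' @param pset An \code{smi_parameters} object.
#' @param surfaces An \code{smi_surfaces} object.
#' @param comparison \code{"bsci_vs_uc"} or \code{"ic_vs_scc"}.
#' @param n_iterations Number of iterations (default 3000).
#' @param seed Integer seed.
#' @param thresholds CEAC willingness-to-pay grid.
#' @param config Deterministic overrides passed to each evaluation (e.g.
#'   scenario rates or a restricted horizon).
#' @return Object of class \code{"psa_result"}: list with \code{draws}
#'   (iteration, arm, cost, qaly), \code{delta_cost}, \code{delta_qalys},
#'   summary means/SDs, \code{probabilistic_icer}, \code{prob_cost_effective},
#'   \code{ceac}, \code{running_icer}, \code{seed}, \code{n_iterations},
#'   \code{threshold}.
#' @export
run_psa <- function(pset, surfaces,
                    comparison = c("bsci_vs_uc", "ic_vs_scc"),
                    n_iterations = 3000, seed = 1,
                    thresholds = seq(0, 50000, 500), config = list()) {
  if (n_iterations < 1) stop("`n_iterations` must be >= 1", call. = FALSE)
  arms <- comparison_arms(comparison)
  tab <- psa_parameter_table(pset)
  threshold <- config$threshold %||% pset$threshold_gbp_per_qaly
  horizon <- config$horizon %||% Inf
  cost <- matrix(NA_real_, n_iterations, 2, dimnames = list(NULL, arms))
  qaly <- cost
  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      ps_i <- sample_iteration(pset, tab)
      ec <- build_eval_context(ps_i, surfaces, config)
      for (a in arms) {
        cfg <- config
        cfg$eval_context <- ec
        if (is.list(config$quit_prob)) cfg$quit_prob <- config$quit_prob[[a]]
        if (is.list(config$intervention_cost))
          cfg$intervention_cost <- config$intervention_cost[[a]]
        out <- arm_outcome(a, ps_i, surfaces, cfg)
        cost[it, a] <- out$cost_total
        qaly[it, a] <- out$qalys
      }
    }
  })
  dC <- cost[, arms[1]] - cost[, arms[2]]
  dQ <- qaly[, arms[1]] - qaly[, arms[2]]
  draws <- data.frame(
    iteration = rep(seq_len(n_iterations), 2),
    arm = rep(arms, each = n_iterations),
    cost = c(cost[, arms[1]], cost[, arms[2]]),
    qaly = c(qaly[, arms[1]], qaly[, arms[2]]),
    stringsAsFactors = FALSE)
  run_icer <- cumsum(dC) / seq_len(n_iterations) /
    (cumsum(dQ) / seq_len(n_iterations))
  structure(list(
    comparison = comparison, draws = draws,
    delta_cost = dC, delta_qalys = dQ,
    mean_delta_cost = mean(dC), sd_delta_cost = stats::sd(dC),
    mean_delta_qalys = mean(dQ), sd_delta_qalys = stats::sd(dQ),
    probabilistic_icer = mean(dC) / mean(dQ),
    prob_cost_effective = mean(threshold * dQ - dC > 0),
    ceac = ceac(dC, dQ, thresholds),
    running_icer = run_icer,
    seed = seed, n_iterations = n_iterations, threshold = threshold
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %s, %d iterations (seed %d)\n", x$comparison,
              x$n_iterations, x$seed))
  cat(sprintf("  mean dCost £%.0f (SD %.0f), mean dQALY %.3f (SD %.3f)\n",
              x$mean_delta_cost, x$sd_delta_cost, x$mean_delta_qalys,
              x$sd_delta_qalys))
  cat(sprintf("  probabilistic ICER £%.0f; P(cost-effective at £%s) = %.1f%%\n",
              x$probabilistic_icer, format(x$threshold, big.mark = ","),
              100 * x$prob_cost_effective))
  invisible(x)
}

# 95% CI bounds for one-way DSA: mean +/- 1.96 SD on the natural scale,
# except log-normal parameters, whose bounds are exp(mu +/- 1.96 sigma);
# clamped to the family's support.
dsa_bounds <- function(family, mean, sd) {
  if (sd == 0) return(c(low = mean, high = mean))
  if (family == "lognormal") {
    spec <- moment_match("lognormal", mean, sd)
    b <- exp(spec$params$meanlog + c(-1, 1) * 1.96 * spec$params$sdlog)
  } else {
    b <- mean + c(-1, 1) * 1.96 * sd
  }
  if (family == "beta") b <- clamp(b, 0, 1)
  if (family == "gamma") b <- pmax(b, 0)
  c(low = b[1], high = b[2])
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the deterministic comparison with each parameter set to its
#' lower and upper 95% confidence bound (mean ± 1.96 SD on the natural
#' scale; log scale for log-normal parameters), holding everything else at
#' the mean. Shared parameters move in both arms simultaneously;
#' effectiveness is varied one arm at a time. Entries are sorted by the
#' width of the resulting ICER range (dominance at a bound gives an
#' undefined width and sorts last).
#'
#' @param pset An \code{smi_parameters} object.
#' @param surfaces An \code{smi_surfaces} object.
#' @param comparison \code{"bsci_vs_uc"} or \code{"ic_vs_scc"}.
#' @param parameters Parameter names to vary; default all with SD > 0.
#' @param config Deterministic overrides passed to every run.
#' @return Data frame with one row per parameter: bounds, ICER or
#'   classification label at each bound, and the base-case ICER.
#' @export
run_dsa <- function(pset, surfaces,
                    comparison = c("bsci_vs_uc", "ic_vs_scc"),
                    parameters = NULL, config = list()) {
  comparison <- match.arg(comparison)
  tab <- psa_parameter_table(pset)
  if (is.null(parameters)) parameters <- tab$name[tab$sd > 0]
  base <- run_comparison(pset, surfaces, comparison, config)
  rows <- lapply(parameters, function(nm) {
    r <- tab[tab$name == nm, ]
    if (nrow(r) != 1) stop("unknown parameter: ", nm, call. = FALSE)
    b <- dsa_bounds(r$family, r$mean, r$sd)
    res <- lapply(b, function(v) {
      run_comparison(set_parameter(pset, nm, v), surfaces, comparison, config)
    })
    lab <- vapply(res, function(x) {
      if (x$classification == "icer") sprintf("%.0f", x$icer)
      else x$classification
    }, character(1))
    icers <- vapply(res, function(x) x$icer, numeric(1))
    data.frame(parameter = nm, mean = r$mean, low = b[["low"]],
               high = b[["high"]],
               icer_low = icers[["low"]], icer_high = icers[["high"]],
               label_low = lab[["low"]], label_high = lab[["high"]],
               icer_range = abs(icers[["high"]] - icers[["low"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$base_icer <- if (base$classification == "icer") base$icer else NA_real_
  out[order(-out$icer_range, na.last = TRUE), , drop = FALSE]
}

#' Apply a scenario's input substitutions to the parameter set
#'
#' Scenario \code{"1"} swaps in the self-reported (plus validated)
#' effectiveness estimates; scenario \code{"2"} adds the per-arm
#' service-utilisation costs to the cycle-0 intervention costs; scenario
#' \code{"3"} replaces the post-12-month net rates with bidirectional
#' cessation/relapse rates (defaults 4.1% and 10%).
#'
#' @param pset An \code{smi_parameters} object.
#' @param scenario \code{"base"}, \code{"1"}, \code{"2"} or \code{"3"}.
#' @param config Optional list: \code{s3_cessation} (default 0.041),
#'   \code{s3_relapse} (default 0.10), \code{service_utilisation} (named
#'   per-arm add-on costs overriding the shipped defaults),
#'   \code{selfreport_effectiveness} (data frame overriding the shipped
#'   placeholder values).
#' @return The modified parameter set.
#' @export
scenario_inputs <- function(pset, scenario = c("base", "1", "2", "3"),
                            config = list()) {
  scenario <- match.arg(scenario)
  if (scenario == "1") {
    sr <- config$selfreport_effectiveness %||% pset$selfreport_effectiveness
    if (is.null(sr)) {
      stop("scenario 1 requires self-report effectiveness inputs",
           call. = FALSE)
    }
    pset$effectiveness <- sr
  } else if (scenario == "2") {
    addons <- config$service_utilisation %||% pset$service_utilisation
    if (is.null(addons)) {
      stop("scenario 2 requires service-utilisation add-on costs",
           call. = FALSE)
    }
    tot <- pset$intervention_costs$totals
    pset$intervention_costs$totals <- tot + addons[names(tot)]
  } else if (scenario == "3") {
    pset$transitions$net_cessation[["mean"]] <- config$s3_cessation %||% 0.041
    pset$transitions$relapse[["mean"]] <- config$s3_relapse %||% 0.10
  }
  pset
}

#' Run one of the predefined scenario analyses
#'
#' @inheritParams scenario_inputs
#' @param surfaces An \code{smi_surfaces} object.
#' @param comparison \code{"bsci_vs_uc"} or \code{"ic_vs_scc"}.
#' @param config Scenario options (see \code{\link{scenario_inputs}}) plus
#'   any deterministic overrides such as \code{horizon}.
#' @return A \code{ce_result}.
#' @export
run_scenario <- function(pset, surfaces,
                         comparison = c("bsci_vs_uc", "ic_vs_scc"),
                         scenario = c("base", "1", "2", "3"),
                         config = list()) {
  ps <- scenario_inputs(pset, scenario, config)
  res <- run_comparison(ps, surfaces, comparison, config)
  res$scenario <- match.arg(scenario)
  res
}
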