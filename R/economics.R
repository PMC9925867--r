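# Population aggregation and incremental cost-effectiveness.

#' Aggregate per-cohort lifetime outcomes with population weights
#'
#' Weighted mean of lifetime discounted costs and QALYs across starting
#' age/sex cohorts. Weights are normalised internally, so rescaling them
#' leaves the result unchanged.
#'
#' @param cells Data frame with columns \code{age}, \code{sex} and one or
#'   more numeric outcome columns.
#' @param weights Weight matrix \code{[age, sex]} as from
#'   \code{\link{generate_population_weights}}.
#' @return Named vector of weighted means, one per outcome column.
#' @export
aggregate_population <- function(cells, weights) {
  ages <- as.integer(rownames(weights))
  sexes <- colnames(weights)
  w <- weights / sum(weights)
  key <- paste(cells$age, cells$sex)
  need <- expand.grid(age = ages, sex = sexes, stringsAsFactors = FALSE)
  need <- need[w[cbind(match(need$age, ages), match(need$sex, sexes))] > 0, ]
  missing <- setdiff(paste(need$age, need$sex), key)
  if (length(missing) > 0) {
    stop("no trace for weighted cell(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  wv <- w[cbind(match(cells$age, ages), match(cells$sex, sexes))]
  num_cols <- setdiff(names(cells), c("age", "sex"))
  vapply(num_cols, function(cl) sum(cells[[cl]] * wv), numeric(1))
}

#' Additional quitters per 1000 people at 12 months
#'
#' @param quit_prob_intervention,quit_prob_comparator 12-month quit
#'   probabilities.
#' @return The unrounded difference times 1000; round to the nearest
#'   integer for reporting.
#' @export
quitters_per_1000 <- function(quit_prob_intervention, quit_prob_comparator) {
  stopifnot(quit_prob_intervention >= 0, quit_prob_intervention <= 1,
            quit_prob_comparator >= 0, quit_prob_comparator <= 1)
  (quit_prob_intervention - quit_prob_comparator) * 1000
}

#' Lifetime outcome summary for one arm
#'
#' Runs the cohort engine for every starting age and sex, aggregates with
#' the population weights, and attaches the arm's (cycle-0) intervention
#' cost. Comorbidity costs and QALYs are lifetime discounted values per
#' person.
#'
#' @param arm Arm name.
#' @param pset An \code{smi_parameters} object.
#' @param surfaces An \code{smi_surfaces} object.
#' @param config Optional list: \code{horizon}, \code{rates},
#'   \code{discount_rate}, \code{quit_prob}, \code{intervention_cost}
#'   overrides; internally an already-built evaluation context can be
#'   supplied as \code{eval_context} to avoid rebuilding per arm.
#' @return Object of class \code{"arm_outcome"}: list with \code{arm},
#'   \code{quit_prob}, \code{cost_intervention}, \code{cost_comorbidity},
#'   \code{cost_total}, \code{qalys}.
#' @export
arm_outcome <- function(arm, pset, surfaces, config = list()) {
  ec <- config$eval_context %||% build_eval_context(pset, surfaces, config)
  quit_prob <- config$quit_prob %||%
    pset$effectiveness$quit_prob_12m[pset$effectiveness$arm == arm]
  if (length(quit_prob) != 1) stop("unknown arm: ", arm, call. = FALSE)
  ic <- config$intervention_cost %||% pset$intervention_costs$totals[[arm]]
  cells <- population_outcomes(ec, quit_prob, config$horizon %||% Inf)
  agg <- aggregate_population(cells, ec$weights)
  structure(list(
    arm = arm, quit_prob = quit_prob,
    cost_intervention = ic,
    cost_comorbidity = agg[["disc_cost_comorbidity"]],
    cost_total = ic + agg[["disc_cost_comorbidity"]],
    qalys = agg[["disc_qaly"]]
  ), class = "arm_outcome")
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("<arm_outcome> %s: intervention £%.0f + comorbidity £%.0f = £%.0f; %.2f QALYs\n",
              x$arm, x$cost_intervention, x$cost_comorbidity, x$cost_total,
              x$qalys))
  invisible(x)
}

#' Incremental cost-effectiveness analysis for two arms
#'
#' Computes incremental costs and QALYs, classifies the comparison
#' (\code{"icer"}, \code{"dominant"}, \code{"dominated"},
#' \code{"equivalent"}), and evaluates net monetary benefit
#' \code{NMB = threshold * dQ - dC}. The intervention is flagged
#' cost-effective when NMB > 0 — equivalent to being dominant, or having an
#' ICER below the threshold in the north-east quadrant (above it in the
#' south-west quadrant, where a larger ratio means more savings per QALY
#' forgone). No ICER is reported when incremental QALYs are zero.
#'
#' @param intervention,comparator \code{arm_outcome} objects.
#' @param threshold Willingness to pay in GBP per QALY.
#' @return Object of class \code{"ce_result"}: list with the two outcomes,
#'   \code{delta_cost}, \code{delta_cost_intervention},
#'   \code{delta_cost_comorbidity}, \code{delta_qalys}, \code{icer},
#'   \code{classification}, \code{quadrant}, \code{nmb},
#'   \code{cost_effective}, \code{threshold}.
#' @export
incremental_analysis <- function(intervention, comparator, threshold = 20000) {
  dC <- intervention$cost_total - comparator$cost_total
  dQ <- intervention$qalys - comparator$qalys
  quadrant <- if (dQ >= 0 && dC >= 0) "north-east"
    else if (dQ >= 0 && dC < 0) "south-east"
    else if (dQ < 0 && dC < 0) "south-west"
    else "north-west"
  classification <- if (dC < 0 && dQ >= 0 && !(dC == 0 && dQ == 0)) "dominant"
    else if (dC >= 0 && dQ <= 0 && !(dC == 0 && dQ == 0)) "dominated"
    else if (dC == 0 && dQ == 0) "equivalent"
    else "icer"
  icer <- if (dQ != 0 && classification == "icer") dC / dQ else NA_real_
  nmb <- threshold * dQ - dC
  structure(list(
    intervention = intervention, comparator = comparator,
    delta_cost = dC,
    delta_cost_intervention =
      intervention$cost_intervention - comparator$cost_intervention,
    delta_cost_comorbidity =
      intervention$cost_comorbidity - comparator$cost_comorbidity,
    delta_qalys = dQ,
    icer = icer, classification = classification, quadrant = quadrant,
    nmb = nmb, cost_effective = nmb > 0, threshold = threshold
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("<ce_result> %s vs %s\n", x$intervention$arm, x$comparator$arm))
  cat(sprintf("  dCost £%.0f (intervention £%.0f, comorbidity £%.0f); dQALY %.3f\n",
              x$delta_cost, x$delta_cost_intervention,
              x$delta_cost_comorbidity, x$delta_qalys))
  lab <- switch(x$classification,
                icer = sprintf("ICER £%.0f/QALY", x$icer),
                x$classification)
  cat(sprintf("  %s; NMB £%.0f at £%s/QALY; cost-effective: %s\n", lab,
              x$nmb, format(x$threshold, big.mark = ","),
              x$cost_effective))
  invisible(x)
}

# Arms of each pairwise comparison, intervention first.
comparison_arms <- function(comparison = c("bsci_vs_uc", "ic_vs_scc")) {
  comparison <- match.arg(comparison)
  switch(comparison,
         bsci_vs_uc = c("bsci", "usual_care"),
         ic_vs_scc = c("integrated_care", "scc_referral"))
}

#' Deterministic cost-effectiveness comparison of two arms
#'
#' Runs both arms of the named comparison on the same evaluation context
#' and returns the incremental analysis.
#'
#' @param pset An \code{smi_parameters} object.
#' @param surfaces An \code{smi_surfaces} object.
#' @param comparison \code{"bsci_vs_uc"} or \code{"ic_vs_scc"}.
#' @param config Optional overrides as in \code{\link{arm_outcome}}; per-arm
#'   overrides can be given as named lists \code{quit_prob} and
#'   \code{intervention_cost} keyed by arm.
#' @return A \code{ce_result}.
#' @export
run_comparison <- function(pset, surfaces,
                           comparison = c("bsci_vs_uc", "ic_vs_scc"),
                           config = list()) {
  arms <- comparison_arms(comparison)
  ec <- config$eval_context %||% build_eval_context(pset, surfaces, config)
  arm_cfg <- function(a) {
    cfg <- config
    cfg$eval_context <- ec
    if (is.list(config$quit_prob)) cfg$quit_prob <- config$quit_prob[[a]]
    if (is.list(config$intervention_cost))
      cfg$intervention_cost <- config$intervention_cost[[a]]
    cfg
  }
  res <- incremental_analysis(
    arm_outcome(arms[1], pset, surfaces, arm_cfg(arms[1])),
    arm_outcome(arms[2], pset, surfaces, arm_cfg(arms[2])),
    threshold = config$threshold %||% pset$threshold_gbp_per_qaly)
  res$comparison <- comparison
  res$quitters_per_1000 <- quitters_per_1000(
    res$intervention$quit_prob, res$comparator$quit_prob)
  res
}

#' Export a cost-effectiveness result as a summary table
#'
#' One row per arm plus the incremental row, mirroring the conventional
#' published layout (intervention / comorbidity / total costs, QALYs, ICER
#' or dominance label).
#'
#' @param result A \code{ce_result}.
#' @return Data frame ready for \code{write.csv}.
#' @export
ce_summary_table <- function(result) {
  rows <- list(result$intervention, result$comparator)
  df <- data.frame(
    row = c(rows[[1]]$arm, rows[[2]]$arm, "incremental"),
    cost_intervention = c(rows[[1]]$cost_intervention,
                          rows[[2]]$cost_intervention,
                          result$delta_cost_intervention),
    cost_comorbidity = c(rows[[1]]$cost_comorbidity,
                         rows[[2]]$cost_comorbidity,
                         result$delta_cost_comorbidity),
    cost_total = c(rows[[1]]$cost_total, rows[[2]]$cost_total,
                   result$delta_cost),
    qalys = c(rows[[1]]$qalys, rows[[2]]$qalys, result$delta_qalys),
    icer = c(NA, NA, if (result$classification == "icer")
      result$icer else NA),
    label = c("", "", if (result$classification == "icer")
      sprintf("%.0f", result$icer) else result$classification),
    stringsAsFactors = FALSE)
  df
}
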