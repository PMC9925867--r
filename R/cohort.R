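# Three-state annual-cycle Markov cohort: current smoker, former smoker,
# dead. The cohort enters entirely as current smokers; the intervention
# effect materialises at the 12-month boundary (transition into cycle 1),
# later transitions use the net cessation and relapse rates. Death competes
# first each cycle, so behavioural transitions apply conditional on
# survival and rows stay stochastic without renormalisation.

STATE_NAMES <- c("current", "former", "dead")

#' Discount factor for an annual cycle
#'
#' @param cycle_index Cycle number t (0-based; cycle 0 is undiscounted).
#' @param rate Annual discount rate (e.g. 0.035).
#' @return \code{(1 + rate)^(-t)}.
#' @export
discount_factor <- function(cycle_index, rate) {
  if (any(rate < 0)) stop("`rate` must be non-negative", call. = FALSE)
  (1 + rate)^(-cycle_index)
}

# Annual death probability for a live state at an attained age, with the
# SMI relative mortality risk applied.
death_prob <- function(life_table, age, sex, status, rr_mortality) {
  adjust_mortality(life_table[as.character(age), sex, status], rr_mortality)
}

#' Transition matrix for one cycle of the cohort model
#'
#' Builds the row-stochastic 3x3 matrix governing the transition *into*
#' cycle \code{cycle_index}, evaluated at the attained age of the source
#' cycle. The transition into cycle 1 (the 12-month boundary) uses the
#' arm's quit probability; all later transitions use the net cessation and
#' relapse rates. Death competes first: with death probability \code{d},
#' current -> former is \code{(1 - d) * q}.
#'
#' @param cycle_index Target cycle (>= 1).
#' @param age Attained age during the source cycle.
#' @param sex \code{"female"} or \code{"male"}.
#' @param arm_quit_prob 12-month quit probability for the arm.
#' @param rates List with \code{net_cessation} and \code{relapse} (annual
#'   probabilities).
#' @param life_table Life-table array \code{[age, sex, status]}.
#' @param rr_mortality Relative mortality risk multiplier.
#' @return 3x3 matrix with rows/columns \code{current, former, dead}.
#' @export
build_transition_matrix <- function(cycle_index, age, sex, arm_quit_prob,
                                    rates, life_table, rr_mortality) {
  stopifnot(cycle_index >= 1)
  q <- if (cycle_index == 1) arm_quit_prob else rates$net_cessation
  rel <- if (cycle_index == 1) 0 else rates$relapse
  probs <- c(q, rel, rates$net_cessation, rates$relapse, arm_quit_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  d_cur <- death_prob(life_table, age, sex, "current", rr_mortality)
  d_for <- death_prob(life_table, age, sex, "former", rr_mortality)
  m <- rbind(
    c((1 - d_cur) * (1 - q), (1 - d_cur) * q, d_cur),
    c((1 - d_for) * rel, (1 - d_for) * (1 - rel), d_for),
    c(0, 0, 1)
  )
  dimnames(m) <- list(STATE_NAMES, STATE_NAMES)
  m
}

#' Annual utility of a live health state
#'
#' Combines the base non-smoker utility with additive decrements for
#' smoking status and severe mental illness, plus prevalence-weighted
#' decrements \code{base - u_c} for each comorbidity, clamped to [0, 1].
#' The dead state is handled by the caller as utility 0.
#'
#' @param state \code{"current"} or \code{"former"}.
#' @param age Attained age.
#' @param sex \code{"female"} or \code{"male"}.
#' @param utilities List with scalars \code{base}, \code{decrement_current},
#'   \code{decrement_former}, \code{smi_decrement}.
#' @param prevalence (Adjusted) prevalence array
#'   \code{[condition, age, sex, status]}.
#' @param comorbidity_utilities Named vector of condition utilities, in the
#'   prevalence array's condition order.
#' @return Utility in [0, 1].
#' @export
state_utility <- function(state, age, sex, utilities, prevalence,
                          comorbidity_utilities) {
  if (!state %in% c("current", "former")) {
    stop("`state` must be a live state", call. = FALSE)
  }
  dec_status <- if (state == "current") utilities$decrement_current
                else utilities$decrement_former
  prev <- prevalence[, as.character(age), sex, state]
  como_dec <- sum(prev * (utilities$base - comorbidity_utilities))
  clamp(utilities$base - dec_status - utilities$smi_decrement - como_dec, 0, 1)
}

#' Annual comorbidity treatment cost of a live health state
#'
#' Prevalence-weighted sum of per-cycle condition costs. The dead state is
#' handled by the caller as cost 0.
#'
#' @inheritParams state_utility
#' @param comorbidity_costs Named vector of annual condition costs, in the
#'   prevalence array's condition order.
#' @return Cost in GBP per cycle.
#' @export
state_cost <- function(state, age, sex, prevalence, comorbidity_costs) {
  if (!state %in% c("current", "former")) {
    stop("`state` must be a live state", call. = FALSE)
  }
  sum(prevalence[, as.character(age), sex, state] * comorbidity_costs)
}

# Assemble everything a model evaluation needs from a parameter set and
# surfaces, applying any overrides: per-age/sex/status death probabilities,
# annual costs and utilities for the live states, transition rates,
# discount rate and population weights. `overrides` may carry `rates`,
# `discount_rate`, or `prevalence` replacements.
build_eval_context <- function(pset, surfaces, overrides = list()) {
  or_val <- pset$smi$or_comorbidity[["mean"]]
  exempt <- pset$comorbidities$condition[!pset$comorbidities$smi_adjustable]
  prev <- overrides$prevalence %||%
    apply_smi_comorbidity_adjustment(surfaces$prevalence, or_val, exempt)

  conds <- dimnames(prev)$condition
  idx <- match(conds, pset$comorbidities$condition)
  if (anyNA(idx)) stop("prevalence conditions unknown to the parameter set")
  costs <- pset$comorbidities$annual_cost_mean[idx]
  utils_c <- pset$comorbidities$utility_mean[idx]

  u <- pset$utilities
  base <- u$base_nonsmoker[["mean"]]
  dec <- c(current = u$decrement_current[["mean"]],
           former = u$decrement_former[["mean"]])
  smi_dis <- pset$smi$smi_disutility[["mean"]]
  rr <- pset$smi$rr_mortality[["mean"]]

  n_age <- length(surfaces$ages)
  cost_arr <- array(0, dim = c(n_age, 2, 2),
                    dimnames = list(age = surfaces$ages, sex = SEXES,
                                    status = c("current", "former")))
  util_arr <- cost_arr
  for (sx in SEXES) {
    for (st in c("current", "former")) {
      pm <- prev[, , sx, st, drop = TRUE]  # condition x age
      cost_arr[, sx, st] <- colSums(pm * costs)
      util_arr[, sx, st] <- clamp(
        base - dec[[st]] - smi_dis - colSums(pm * (base - utils_c)), 0, 1)
    }
  }
  d_arr <- array(0, dim = c(n_age, 2, 2),
                 dimnames = dimnames(cost_arr))
  for (sx in SEXES) {
    for (st in c("current", "former")) {
      d_arr[, sx, st] <- adjust_mortality(surfaces$life_table[, sx, st], rr)
    }
  }
  rates <- overrides$rates %||% list(
    net_cessation = pset$transitions$net_cessation[["mean"]],
    relapse = pset$transitions$relapse[["mean"]])
  list(
    ages = surfaces$ages,
    prevalence = prev,
    cost = cost_arr, util = util_arr, death = d_arr,
    rates = rates,
    discount_rate = overrides$discount_rate %||% pset$discount_rate,
    weights = surfaces$weights,
    comorbidity_costs = stats::setNames(costs, conds),
    comorbidity_utilities = stats::setNames(utils_c, conds),
    utilities = list(base = base, decrement_current = dec[["current"]],
                     decrement_former = dec[["former"]],
                     smi_decrement = smi_dis),
    rr_mortality = rr,
    life_table = surfaces$life_table
  )
}

#' Run the Markov cohort for one starting age, sex and arm
#'
#' The cohort enters 100% current smokers. Cycle 0 accrues the arm's
#' intervention cost plus one year of current-smoker cost and utility
#' (undiscounted); the quit split materialises at the 12-month boundary.
#' Each later cycle accrues costs/QALYs at that cycle's occupancy,
#' discounted at \code{(1+r)^-t}, with no half-cycle correction. The run
#' terminates at age 100 (or the configured horizon): the attained-age-100
#' cycle is the last to accrue.
#'
#' @param starting_age Integer in 12-100.
#' @param sex \code{"female"} or \code{"male"}.
#' @param arm Arm name as in the effectiveness table.
#' @param pset An \code{smi_parameters} object.
#' @param surfaces An \code{smi_surfaces} object.
#' @param config Optional list: \code{horizon} (years, default lifetime),
#'   \code{rates}, \code{discount_rate}, \code{quit_prob} (override the
#'   arm's effectiveness), \code{intervention_cost} (override the arm's
#'   cycle-0 cost).
#' @return A data frame of class \code{"cohort_trace"} with one row per
#'   cycle: \code{cycle}, \code{age}, occupancies \code{current},
#'   \code{former}, \code{dead}, undiscounted and discounted \code{cost} and
#'   \code{qaly}, and cumulative discounted totals. Attributes
#'   \code{intervention_cost}, \code{totals} (lifetime discounted
#'   cost/QALY split).
#' @export
run_cohort <- function(starting_age, sex, arm, pset, surfaces,
                       config = list()) {
  if (starting_age < 12 || starting_age > 100) {
    stop("`starting_age` must lie in 12-100", call. = FALSE)
  }
  horizon <- config$horizon %||% Inf
  if (horizon < 1) stop("`horizon` must be at least 1 cycle", call. = FALSE)
  ec <- build_eval_context(pset, surfaces, config)
  quit_prob <- config$quit_prob %||%
    pset$effectiveness$quit_prob_12m[pset$effectiveness$arm == arm]
  if (length(quit_prob) != 1) stop("unknown arm: ", arm, call. = FALSE)
  ic <- config$intervention_cost %||% pset$intervention_costs$totals[[arm]]

  n_cycles <- min(horizon, 101 - starting_age)  # accruing cycles
  occ <- c(current = 1, former = 0, dead = 0)
  rows <- vector("list", n_cycles)
  for (t in seq_len(n_cycles) - 1L) {
    age <- starting_age + t
    ai <- as.character(age)
    cost_t <- occ[["current"]] * ec$cost[ai, sex, "current"] +
      occ[["former"]] * ec$cost[ai, sex, "former"]
    qaly_t <- occ[["current"]] * ec$util[ai, sex, "current"] +
      occ[["former"]] * ec$util[ai, sex, "former"]
    if (t == 0) cost_t <- cost_t + ic
    df <- discount_factor(t, ec$discount_rate)
    rows[[t + 1L]] <- data.frame(
      cycle = t, age = age,
      current = occ[["current"]], former = occ[["former"]],
      dead = occ[["dead"]],
      cost = cost_t, qaly = qaly_t,
      disc_cost = cost_t * df, disc_qaly = qaly_t * df)
    m <- build_transition_matrix(t + 1L, age, sex, quit_prob, ec$rates,
                                 surfaces$life_table, ec$rr_mortality)
    occ <- drop(occ %*% m)
  }
  trace <- do.call(rbind, rows)
  trace$cum_disc_cost <- cumsum(trace$disc_cost)
  trace$cum_disc_qaly <- cumsum(trace$disc_qaly)
  attr(trace, "intervention_cost") <- ic
  attr(trace, "totals") <- c(
    disc_cost = sum(trace$disc_cost),
    disc_cost_comorbidity = sum(trace$disc_cost) - ic,
    disc_qaly = sum(trace$disc_qaly))
  class(trace) <- c("cohort_trace", class(trace))
  trace
}

# Vectorised lifetime outcomes for every starting age and both sexes at
# once. Mathematically identical to running run_cohort per cohort (a test
# asserts this); used on the PSA hot path. Returns a data frame with one
# row per (age, sex): discounted comorbidity cost and discounted QALYs.
population_outcomes <- function(ec, quit_prob, horizon = Inf) {
  n <- length(ec$ages)
  out <- vector("list", 2)
  max_t <- min(horizon, n) - 1L
  for (si in seq_along(SEXES)) {
    sx <- SEXES[si]
    cur <- rep(1, n); fmr <- rep(0, n)
    dcost <- rep(0, n); dqaly <- rep(0, n)
    cost_c <- ec$cost[, sx, "current"]; cost_f <- ec$cost[, sx, "former"]
    util_c <- ec$util[, sx, "current"]; util_f <- ec$util[, sx, "former"]
    dth_c <- ec$death[, sx, "current"]; dth_f <- ec$death[, sx, "former"]
    ces <- ec$rates$net_cessation; rel <- ec$rates$relapse
    r <- ec$discount_rate
    # per-starting-age cap: cohort starting at ages[i] accrues while
    # attained age <= 100, i.e. for cycles t < n - i + 1
    alive_cycles <- n - seq_len(n) + 1L
    for (t in 0:max_t) {
      idx <- pmin(seq_len(n) + t, n)
      active <- (t < alive_cycles) & (t < horizon)
      df <- (1 + r)^(-t)
      acc <- active * df
      dcost <- dcost + acc * (cur * cost_c[idx] + fmr * cost_f[idx])
      dqaly <- dqaly + acc * (cur * util_c[idx] + fmr * util_f[idx])
      q <- if (t == 0) quit_prob else ces
      rl <- if (t == 0) 0 else rel
      sc <- 1 - dth_c[idx]; sf <- 1 - dth_f[idx]
      new_cur <- cur * sc * (1 - q) + fmr * sf * rl
      fmr <- cur * sc * q + fmr * sf * (1 - rl)
      cur <- new_cur
    }
    out[[si]] <- data.frame(age = ec$ages, sex = sx,
                            disc_cost_comorbidity = dcost, disc_qaly = dqaly,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
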