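# Shared fixtures and independent oracles, built in code at test time.

base_pset <- build_parameter_set()
base_surfaces <- make_reference_surfaces(seed = 42)

# Surfaces with mortality switched off everywhere (for closed-form
# occupancy checks; the engine accepts any user-supplied life table).
zero_mortality_surfaces <- function(template = base_surfaces) {
  lt <- template$life_table
  lt[] <- 0
  make_reference_surfaces(seed = 0L, life_table = lt,
                          prevalence = template$prevalence,
                          weights = template$weights)
}

# A prevalence array that is zero except where set; dims match the model grid.
blank_prevalence <- function() {
  pv <- base_surfaces$prevalence
  pv[] <- 0
  pv
}

# Independent brute-force cohort oracle: explicit per-cycle 3x3 matrices
# (death competes first, behaviour conditional on survival) multiplied out
# step by step, with rewards accrued from the raw arrays. Shares no code
# with the engine beyond the input objects.
oracle_cohort <- function(starting_age, sex, quit_prob, net_cessation,
                          relapse, life_table, rr_mortality, cost_arr,
                          util_arr, intervention_cost, discount_rate,
                          horizon) {
  n_cycles <- min(horizon, 101 - starting_age)
  occ <- matrix(c(1, 0, 0), nrow = 1)
  occ_hist <- matrix(NA_real_, n_cycles, 3)
  disc_cost <- 0
  disc_qaly <- 0
  for (t in seq_len(n_cycles) - 1L) {
    age <- as.character(starting_age + t)
    occ_hist[t + 1L, ] <- occ
    cost_t <- occ[1] * cost_arr[age, sex, "current"] +
      occ[2] * cost_arr[age, sex, "former"]
    qaly_t <- occ[1] * util_arr[age, sex, "current"] +
      occ[2] * util_arr[age, sex, "former"]
    if (t == 0) cost_t <- cost_t + intervention_cost
    disc_cost <- disc_cost + cost_t / (1 + discount_rate)^t
    disc_qaly <- disc_qaly + qaly_t / (1 + discount_rate)^t
    d_cur <- min(1, life_table[age, sex, "current"] * rr_mortality)
    d_for <- min(1, life_table[age, sex, "former"] * rr_mortality)
    q <- if (t == 0) quit_prob else net_cessation
    rl <- if (t == 0) 0 else relapse
    m <- matrix(c(
      (1 - d_cur) * (1 - q), (1 - d_cur) * q, d_cur,
      (1 - d_for) * rl, (1 - d_for) * (1 - rl), d_for,
      0, 0, 1), nrow = 3, byrow = TRUE)
    occ <- occ %*% m
  }
  list(occupancy = occ_hist, disc_cost = disc_cost, disc_qaly = disc_qaly)
}

# Random but valid life table for property tests (not necessarily
# age-monotone; the chain math must not depend on that).
random_life_table <- function() {
  lt <- base_surfaces$life_table
  lt[] <- runif(length(lt), 0, 0.2)
  lt[length(MODEL_AGES_T()), , ] <- 1
  lt
}

MODEL_AGES_T <- function() 12:100

# A parameter set whose SDs are all zero: every sampled iteration must
# reproduce it exactly.
degenerate_pset <- function(pset = base_pset) {
  pset$effectiveness$sd <- 0
  pset$comorbidities$annual_cost_sd <- 0
  pset$comorbidities$utility_sd <- 0
  for (k in names(pset$smi)) pset$smi[[k]][["sd"]] <- 0
  for (k in names(pset$utilities)) pset$utilities[[k]][["sd"]] <- 0
  for (k in names(pset$transitions)) pset$transitions[[k]][["sd"]] <- 0
  pset
}
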