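#' Convert an odds ratio to a relative risk at a given baseline risk
#'
#' Uses the standard conversion \code{RR = OR / (1 - p + p * OR)}, where
#' \code{p} is the absolute probability of the outcome in the unexposed
#' (general) population. The result always lies between \code{min(1, OR)}
#' and \code{max(1, OR)} and decreases towards 1 as the outcome becomes
#' common.
#'
#' @param odds_ratio Odds ratio, a positive number (vectorised).
#' @param baseline_prob Baseline outcome probability in \code{[0, 1)}
#'   (vectorised).
#' @return Relative risk on the same scale as \code{odds_ratio}.
#' @examples
#' or_to_rr(3.1, 0.1) # 2.562
#' @export
or_to_rr <- function(odds_ratio, baseline_prob) {
  if (any(odds_ratio <= 0)) {
    stop("`odds_ratio` must be positive", call. = FALSE)
  }
  if (any(baseline_prob < 0) || any(baseline_prob >= 1)) {
    stop("`baseline_prob` must lie in [0, 1)", call. = FALSE)
  }
  odds_ratio / (1 - baseline_prob + baseline_prob * odds_ratio)
}

#' Population-weighted disutility across mental-health conditions
#'
#' Collapses condition-specific utility decrements into a single decrement
#' using the conditions' population weights. Weights are normalised
#' internally, so any non-negative weighting (counts, proportions,
#' percentages) can be supplied.
#'
#' @param components Data frame with columns \code{disutility} (decrement
#'   magnitudes in \code{[0, 1]}) and \code{weight} (non-negative).
#' @return A single decrement magnitude.
#' @export
weighted_disutility <- function(components) {
  if (!is.data.frame(components) || nrow(components) == 0) {
    stop("`components` must be a non-empty data frame", call. = FALSE)
  }
  stopifnot(all(c("disutility", "weight") %in% names(components)))
  w <- components$weight
  if (any(w < 0) || sum(w) <= 0) {
    stop("weights must be non-negative and not all zero", call. = FALSE)
  }
  sum(components$disutility * w / sum(w))
}

#' Apply a relative mortality risk to an annual death probability
#'
#' @param base_annual_prob Annual death probability (vectorised).
#' @param rr Relative risk multiplier.
#' @return \code{min(1, base_annual_prob * rr)}.
#' @export
adjust_mortality <- function(base_annual_prob, rr) {
  if (any(base_annual_prob < 0) || any(rr < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  pmin(1, base_annual_prob * rr)
}

#' Moment-matched sampling distribution for a model parameter
#'
#' Maps a reported (mean, SD) pair onto the shape parameters of the named
#' family by method of moments:
#' \itemize{
#'   \item gamma: \code{shape = mean^2/sd^2}, \code{scale = sd^2/mean};
#'   \item lognormal: \code{sigma^2 = log(1 + sd^2/mean^2)},
#'     \code{mu = log(mean) - sigma^2/2};
#'   \item beta: \code{nu = mean(1-mean)/sd^2 - 1}, \code{alpha = mean*nu},
#'     \code{beta = (1-mean)*nu} (requires \code{sd^2 < mean*(1-mean)});
#'   \item \code{sd = 0} collapses any family to a degenerate point mass.
#' }
#'
#' @param family One of \code{"lognormal"}, \code{"beta"}, \code{"gamma"},
#'   \code{"degenerate"}.
#' @param mean Target mean on the natural scale.
#' @param sd Target standard deviation; 0 gives a point mass.
#' @param sign +1, or -1 for decrements that are sampled on magnitude and
#'   applied negatively.
#' @param name Optional parameter label used in error messages.
#' @return An object of class \code{"dist_spec"}.
#' @export
moment_match <- function(family = c("lognormal", "beta", "gamma", "degenerate"),
                         mean, sd, sign = 1, name = NULL) {
  family <- match.arg(family)
  label <- if (is.null(name)) family else name
  if (sd < 0) stop("`sd` must be non-negative for ", label, call. = FALSE)
  if (sd == 0) family <- "degenerate"
  params <- switch(family,
    degenerate = list(value = mean),
    gamma = {
      if (mean <= 0) stop("gamma requires mean > 0 for ", label, call. = FALSE)
      list(shape = mean^2 / sd^2, scale = sd^2 / mean)
    },
    lognormal = {
      if (mean <= 0) stop("lognormal requires mean > 0 for ", label, call. = FALSE)
      s2 <- log(1 + sd^2 / mean^2)
      list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
    },
    beta = {
      if (mean <= 0 || mean >= 1) {
        stop("beta requires 0 < mean < 1 for ", label, call. = FALSE)
      }
      if (sd^2 >= mean * (1 - mean)) {
        stop("beta infeasible for ", label, ": sd^2 must be < mean*(1-mean)",
             call. = FALSE)
      }
      nu <- mean * (1 - mean) / sd^2 - 1
      list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
    }
  )
  structure(
    list(family = family, mean = mean, sd = sd, sign = sign,
         params = params, name = label),
    class = "dist_spec"
  )
}

#' Closed-form mean of a dist_spec
#' @param spec A \code{dist_spec}.
#' @return The distribution mean (on magnitude scale, before sign).
#' @export
dist_mean <- function(spec) {
  p <- spec$params
  switch(spec$family,
    degenerate = p$value,
    gamma = p$shape * p$scale,
    lognormal = exp(p$meanlog + p$sdlog^2 / 2),
    beta = p$shape1 / (p$shape1 + p$shape2)
  )
}

#' Closed-form variance of a dist_spec
#' @param spec A \code{dist_spec}.
#' @return The distribution variance.
#' @export
dist_var <- function(spec) {
  p <- spec$params
  switch(spec$family,
    degenerate = 0,
    gamma = p$shape * p$scale^2,
    lognormal = (exp(p$sdlog^2) - 1) * exp(2 * p$meanlog + p$sdlog^2),
    beta = {
      s <- p$shape1 + p$shape2
      p$shape1 * p$shape2 / (s^2 * (s + 1))
    }
  )
}

#' Draw from a moment-matched distribution
#'
#' Sampling uses the current RNG stream; decrement specs (\code{sign = -1})
#' are drawn on magnitude and returned as magnitudes — the sign is applied
#' where the parameter enters the model.
#'
#' @param spec A \code{dist_spec}.
#' @param n Number of draws.
#' @return Numeric vector of draws (magnitude scale).
#' @export
dist_draw <- function(spec, n = 1) {
  p <- spec$params
  switch(spec$family,
    degenerate = rep(p$value, n),
    gamma = stats::rgamma(n, shape = p$shape, scale = p$scale),
    lognormal = stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog),
    beta = stats::rbeta(n, shape1 = p$shape1, shape2 = p$shape2)
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s: %s(mean = %g, sd = %g)\n",
              x$name, x$family, x$mean, x$sd))
  invisible(x)
}

# Read one fixture table, stopping with the file name on failure.
read_fixture <- function(dir, file) {
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("missing parameter table: ", file, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build the complete model parameter set from the shipped input tables
#'
#' Reads the transcribed effectiveness, cost, comorbidity, utility and
#' transition tables (GBP 2018/19), validates them, and derives the
#' quantities the model needs: the population-weighted SMI disutility and
#' the per-arm intervention cost totals (printed totals are canonical where
#' they disagree with component sums by up to the declared rounding
#' tolerance of \pounds 7).
#'
#' @param dir Directory holding the CSV tables; defaults to the copies
#'   shipped with the package.
#' @param rounding_tol Largest allowed absolute difference between a printed
#'   intervention-cost total and its component sum.
#' @return An object of class \code{"smi_parameters"}: a validated list with
#'   elements \code{effectiveness}, \code{intervention_costs},
#'   \code{comorbidities}, \code{utilities}, \code{smi}, \code{transitions},
#'   \code{disutility_components}, \code{service_utilisation},
#'   \code{selfreport_effectiveness}, \code{discount_rate},
#'   \code{threshold_gbp_per_qaly} and \code{age_range}.
#' @export
build_parameter_set <- function(dir = system.file("extdata", package = "smicea"),
                                rounding_tol = 7) {
  eff <- read_fixture(dir, "effectiveness.csv")
  cost_components <- read_fixture(dir, "intervention_costs.csv")
  cost_totals <- read_fixture(dir, "intervention_cost_totals.csv")
  smi_tab <- read_fixture(dir, "smi_adjustments.csv")
  comps <- read_fixture(dir, "disutility_components.csv")
  como <- read_fixture(dir, "comorbidities.csv")
  util <- read_fixture(dir, "utilities.csv")
  trans <- read_fixture(dir, "transitions.csv")
  service <- read_fixture(dir, "service_utilisation.csv")
  selfrep <- read_fixture(dir, "selfreport_effectiveness_synthetic.csv")

  problems <- character()
  need <- function(ok, msg) if (!ok) problems <<- c(problems, msg)

  arms <- c("bsci", "usual_care", "integrated_care", "scc_referral")
  conditions <- c("asthma", "copd", "chd", "lung_cancer", "mi", "stroke")

  need(setequal(eff$arm, arms), "effectiveness: must contain exactly the four arms")
  need(!anyDuplicated(eff$arm), "effectiveness: duplicate arm rows")
  bad <- eff$arm[eff$quit_prob_12m < 0 | eff$quit_prob_12m > 1 | eff$sd < 0]
  need(length(bad) == 0, paste0("effectiveness out of range for: ",
                                paste(bad, collapse = ", ")))

  need(setequal(cost_totals$arm, arms), "intervention costs: arms incomplete")
  bad <- cost_components$arm[cost_components$gbp < 0]
  need(length(bad) == 0, paste0("negative intervention cost for: ",
                                paste(unique(bad), collapse = ", ")))
  sums <- tapply(cost_components$gbp, cost_components$arm, sum)
  for (a in intersect(cost_totals$arm, names(sums))) {
    tot <- cost_totals$total_gbp[cost_totals$arm == a]
    need(abs(tot - sums[[a]]) <= rounding_tol,
         paste0("intervention cost total for ", a,
                " differs from component sum by more than the rounding tolerance"))
  }

  need(setequal(como$condition, conditions),
       paste0("comorbidities: expected exactly ",
              paste(conditions, collapse = ", ")))
  for (i in seq_len(nrow(como))) {
    r <- como[i, ]
    if (is.na(r$annual_cost_mean) || r$annual_cost_mean < 0 ||
        is.na(r$annual_cost_sd) || r$annual_cost_sd < 0)
      need(FALSE, paste0("comorbidity cost invalid for ", r$condition))
    if (is.na(r$utility_mean) || r$utility_mean < 0 || r$utility_mean > 1 ||
        is.na(r$utility_sd) || r$utility_sd < 0)
      need(FALSE, paste0("comorbidity utility invalid for ", r$condition))
  }
  need(!any(como$smi_adjustable[como$condition == "asthma"]),
       "asthma must not be SMI-adjustable")

  need(setequal(util$parameter,
                c("base_nonsmoker", "decrement_current", "decrement_former")),
       "utilities: parameter rows incomplete")
  need(setequal(smi_tab$parameter,
                c("rr_mortality", "or_comorbidity", "smi_disutility")),
       "smi adjustments: parameter rows incomplete")
  need(setequal(trans$parameter, c("net_cessation", "relapse")),
       "transitions: parameter rows incomplete")
  need(all(comps$disutility >= 0 & comps$disutility <= 1) &&
         all(comps$weight >= 0),
       "disutility components out of range")

  if (length(problems) > 0) {
    stop("invalid parameter tables:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  for (cl in c("annual_cost_mean", "annual_cost_sd", "utility_mean",
               "utility_sd")) {
    como[[cl]] <- as.numeric(como[[cl]])
  }
  grab <- function(tab, key, col = "parameter") {
    r <- tab[tab[[col]] == key, ]
    c(mean = r$mean, sd = r$sd)
  }
  totals <- stats::setNames(cost_totals$total_gbp, cost_totals$arm)

  ps <- structure(list(
    effectiveness = eff,
    intervention_costs = list(components = cost_components, totals = totals),
    comorbidities = como,
    utilities = list(
      base_nonsmoker = grab(util, "base_nonsmoker"),
      decrement_current = grab(util, "decrement_current"),
      decrement_former = grab(util, "decrement_former")
    ),
    smi = list(
      rr_mortality = grab(smi_tab, "rr_mortality"),
      or_comorbidity = grab(smi_tab, "or_comorbidity"),
      smi_disutility = grab(smi_tab, "smi_disutility")
    ),
    disutility_components = comps,
    derived_smi_disutility = weighted_disutility(comps),
    transitions = list(
      net_cessation = grab(trans, "net_cessation"),
      relapse = grab(trans, "relapse")
    ),
    service_utilisation = stats::setNames(service$addon_gbp, service$arm),
    selfreport_effectiveness = selfrep,
    discount_rate = 0.035,
    threshold_gbp_per_qaly = 20000,
    age_range = c(12L, 100L)
  ), class = "smi_parameters")
  ps
}

#' @export
print.smi_parameters <- function(x, ...) {
  cat("<smi_parameters>\n")
  cat(sprintf("  arms: %s\n", paste(x$effectiveness$arm, collapse = ", ")))
  cat(sprintf("  comorbidities: %s\n",
              paste(x$comorbidities$condition, collapse = ", ")))
  cat(sprintf("  SMI adjustments: RR mortality %.2f, OR comorbidity %.2f, disutility %.3f\n",
              x$smi$rr_mortality[["mean"]], x$smi$or_comorbidity[["mean"]],
              x$smi$smi_disutility[["mean"]]))
  cat(sprintf("  discount %.1f%%, threshold £%s/QALY, ages %d-%d\n",
              100 * x$discount_rate,
              format(x$threshold_gbp_per_qaly, big.mark = ","),
              x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' Table of all stochastic parameters with their PSA distributions
#'
#' One row per sampled quantity: effectiveness (beta, arm-specific), relative
#' mortality risk and comorbidity odds ratio (log-normal, shared), SMI and
#' smoker-status utility decrements (beta on magnitude, applied negatively),
#' base utility and comorbidity utilities (beta), comorbidity costs (gamma),
#' and the net cessation/relapse probabilities (beta). Parameters with SD 0
#' collapse to degenerate point masses.
#'
#' @param pset An \code{smi_parameters} object.
#' @return Data frame with columns \code{name}, \code{block}, \code{key},
#'   \code{family}, \code{mean}, \code{sd}, \code{sign}, \code{scope}.
#' @export
psa_parameter_table <- function(pset) {
  rows <- list()
  add <- function(name, block, key, family, mean, sd, sign = 1,
                  scope = "shared") {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, block = block, key = key, family = family,
      mean = mean, sd = sd, sign = sign, scope = scope,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pset$effectiveness))) {
    r <- pset$effectiveness[i, ]
    add(paste0("effectiveness_", r$arm), "effectiveness", r$arm, "beta",
        r$quit_prob_12m, r$sd, scope = "arm")
  }
  s <- pset$smi
  add("rr_mortality", "smi", "rr_mortality", "lognormal",
      s$rr_mortality[["mean"]], s$rr_mortality[["sd"]])
  add("or_comorbidity", "smi", "or_comorbidity", "lognormal",
      s$or_comorbidity[["mean"]], s$or_comorbidity[["sd"]])
  add("smi_disutility", "smi", "smi_disutility", "beta",
      s$smi_disutility[["mean"]], s$smi_disutility[["sd"]], sign = -1)
  u <- pset$utilities
  add("utility_base_nonsmoker", "utilities", "base_nonsmoker", "beta",
      u$base_nonsmoker[["mean"]], u$base_nonsmoker[["sd"]])
  add("utility_decrement_current", "utilities", "decrement_current", "beta",
      u$decrement_current[["mean"]], u$decrement_current[["sd"]], sign = -1)
  add("utility_decrement_former", "utilities", "decrement_former", "beta",
      u$decrement_former[["mean"]], u$decrement_former[["sd"]], sign = -1)
  for (i in seq_len(nrow(pset$comorbidities))) {
    r <- pset$comorbidities[i, ]
    add(paste0("cost_", r$condition), "comorbidity_cost", r$condition, "gamma",
        r$annual_cost_mean, r$annual_cost_sd)
    add(paste0("utility_", r$condition), "comorbidity_utility", r$condition,
        "beta", r$utility_mean, r$utility_sd)
  }
  tr <- pset$transitions
  add("net_cessation", "transitions", "net_cessation", "beta",
      tr$net_cessation[["mean"]], tr$net_cessation[["sd"]])
  add("relapse", "transitions", "relapse", "beta",
      tr$relapse[["mean"]], tr$relapse[["sd"]])
  do.call(rbind, rows)
}
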