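# Synthetic stand-ins for the external reference surfaces the model needs:
# age/sex/smoking-status mortality, comorbidity prevalence for current and
# former smokers, and population age weights. Real surfaces in the same
# long-CSV layout can be dropped in via read_surfaces() without code changes.

MODEL_AGES <- 12:100
SEXES <- c("female", "male")
STATUSES <- c("never", "current", "former")
CONDITIONS <- c("asthma", "copd", "chd", "lung_cancer", "mi", "stroke")

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Generate a synthetic life table by age, sex and smoking status
#'
#' Annual death probabilities follow a Gompertz hazard
#' \code{q(age) = min(1, a * exp(b * age))} scaled by a status multiplier
#' with \code{m_current >= m_former >= m_never = 1}, so mortality increases
#' with age and is highest for current smokers at every age. Age 100 is
#' treated as absorbing-by-death: its annual death probability is 1. The
#' seed perturbs the level \code{a} (within \code{±jitter} on the log scale)
#' and slope \code{b} (within \code{±jitter/3}) separately by sex, so
#' different seeds give different but structurally identical tables.
#'
#' @param seed Integer seed; the same seed reproduces the table bit-for-bit.
#' @param gompertz List with \code{a} (named by sex) and \code{b} (shared
#'   baseline slope).
#' @param multipliers Named vector with entries \code{never}, \code{former},
#'   \code{current}; must be ordered \code{current >= former >= never}.
#' @param jitter Relative half-width of the seed perturbation.
#' @return Array \code{[age 12-100, sex, status]} of annual death
#'   probabilities.
#' @export
generate_life_table <- function(seed = 1,
                                gompertz = list(
                                  a = c(female = 1.4e-05, male = 2.0e-05),
                                  b = 0.0925),
                                multipliers = c(never = 1, former = 1.35,
                                                current = 1.9),
                                jitter = 0.03) {
  m <- multipliers[STATUSES]
  if (any(is.na(m))) stop("multipliers must name never, former, current")
  if (!(m[["current"]] >= m[["former"]] && m[["former"]] >= m[["never"]])) {
    stop("status multipliers must satisfy current >= former >= never",
         call. = FALSE)
  }
  lt <- array(NA_real_, dim = c(length(MODEL_AGES), 2, 3),
              dimnames = list(age = MODEL_AGES, sex = SEXES,
                              status = STATUSES))
  with_seed(seed, {
    for (sx in SEXES) {
      a <- gompertz$a[[sx]] * exp(stats::runif(1, -jitter, jitter))
      b <- gompertz$b * (1 + stats::runif(1, -jitter / 3, jitter / 3))
      base_q <- pmin(1, a * exp(b * MODEL_AGES))
      for (st in STATUSES) {
        lt[, sx, st] <- pmin(1, base_q * m[[st]])
      }
    }
  })
  lt[length(MODEL_AGES), , ] <- 1  # age 100 absorbing
  lt
}

#' Generate synthetic comorbidity prevalence surfaces
#'
#' Prevalence among current smokers follows a logistic curve in age,
#' \code{asymptote / (1 + exp(-slope * (age - midpoint)))}, per condition;
#' former smokers get the same curve scaled by an attenuation factor in
#' (0, 1], so current-smoker prevalence is never below former-smoker
#' prevalence. Males carry a small uplift. The seed perturbs each
#' condition's asymptote within \code{±jitter}.
#'
#' @param seed Integer seed.
#' @param params Data frame with columns \code{condition},
#'   \code{asymptote}, \code{midpoint}, \code{slope}; defaults cover the six
#'   modelled conditions.
#' @param former_attenuation Scalar in (0, 1]: former-smoker prevalence as a
#'   fraction of current-smoker prevalence.
#' @param male_uplift Multiplier (>= 1) applied to male prevalence, capped at
#'   the asymptote scale by clamping to [0, 1].
#' @param jitter Relative half-width of the seed perturbation.
#' @return Array \code{[condition, age 12-100, sex, status current/former]}
#'   of prevalences.
#' @export
generate_prevalence <- function(seed = 1,
                                params = default_prevalence_params(),
                                former_attenuation = 0.6,
                                male_uplift = 1.1,
                                jitter = 0.05) {
  if (former_attenuation <= 0 || former_attenuation > 1) {
    stop("`former_attenuation` must lie in (0, 1]", call. = FALSE)
  }
  if (any(params$asymptote > 1)) {
    stop("asymptotes must not exceed 1", call. = FALSE)
  }
  pv <- array(NA_real_,
              dim = c(nrow(params), length(MODEL_AGES), 2, 2),
              dimnames = list(condition = params$condition, age = MODEL_AGES,
                              sex = SEXES, status = c("current", "former")))
  with_seed(seed, {
    for (i in seq_len(nrow(params))) {
      asym <- min(1, params$asymptote[i] * exp(stats::runif(1, -jitter, jitter)))
      cur <- asym / (1 + exp(-params$slope[i] * (MODEL_AGES - params$midpoint[i])))
      for (sx in SEXES) {
        uplift <- if (sx == "male") male_uplift else 1
        pv[i, , sx, "current"] <- clamp(cur * uplift, 0, 1)
        pv[i, , sx, "former"] <- clamp(cur * uplift * former_attenuation, 0, 1)
      }
    }
  })
  pv
}

#' Default logistic parameters for the synthetic prevalence surfaces
#'
#' Asymptotes, midpoints and slopes chosen to mimic the broad epidemiology
#' of each condition among smokers: common, late-rising conditions (COPD,
#' CHD, stroke) have sizeable asymptotes and midpoints in the 70s; lung
#' cancer stays rare; asthma is common but nearly flat in age.
#'
#' @return Data frame with columns \code{condition}, \code{asymptote},
#'   \code{midpoint}, \code{slope}.
#' @export
default_prevalence_params <- function() {
  data.frame(
    condition = CONDITIONS,
    asymptote = c(0.10, 0.34, 0.27, 0.045, 0.16, 0.20),
    midpoint = c(40, 72, 74, 78, 74, 78),
    slope = c(0.02, 0.085, 0.08, 0.09, 0.08, 0.09),
    stringsAsFactors = FALSE
  )
}

#' Apply the SMI comorbidity risk adjustment to a prevalence surface
#'
#' Converts the SMI odds ratio to a relative risk cell-by-cell using each
#' cell's general-population prevalence as the baseline, then multiplies:
#' \code{new = min(1, p * or_to_rr(OR, p))}. Conditions in \code{exempt}
#' (asthma by default, whose exacerbations match general-population rates)
#' are left unchanged.
#'
#' @param prevalence Prevalence array as from \code{generate_prevalence}.
#' @param or_comorbidity Odds ratio for smoking-related comorbidity in SMI
#'   vs general populations.
#' @param exempt Character vector of condition names left unadjusted.
#' @return Adjusted prevalence array of the same shape.
#' @export
apply_smi_comorbidity_adjustment <- function(prevalence, or_comorbidity,
                                             exempt = "asthma") {
  out <- prevalence
  conds <- dimnames(prevalence)$condition
  for (i in seq_along(conds)) {
    if (conds[i] %in% exempt) next
    p <- prevalence[i, , , , drop = FALSE]
    # saturated cells (p = 1) stay at 1; or_to_rr requires p < 1
    rr <- array(1, dim = dim(p))
    rr[p < 1] <- or_to_rr(or_comorbidity, p[p < 1])
    out[i, , , ] <- pmin(1, p * rr)
  }
  out
}

#' Generate synthetic population age/sex weights
#'
#' A smooth unimodal age profile (Gaussian in age) split evenly between the
#' sexes and normalised to sum to one, standing in for national population
#' weightings over ages 12-100. The seed perturbs the peak age slightly.
#'
#' @param seed Integer seed.
#' @param peak_age Mode of the age profile.
#' @param width Standard deviation of the age profile.
#' @param uniform If TRUE, return equal weight on every (age, sex) cell.
#' @return Matrix \code{[age 12-100, sex]} of weights summing to 1.
#' @export
generate_population_weights <- function(seed = 1, peak_age = 41, width = 21,
                                        uniform = FALSE) {
  w <- matrix(NA_real_, nrow = length(MODEL_AGES), ncol = 2,
              dimnames = list(age = MODEL_AGES, sex = SEXES))
  if (uniform) {
    w[] <- 1 / length(w)
    return(w)
  }
  with_seed(seed, {
    peak <- peak_age + stats::runif(1, -2, 2)
    prof <- exp(-((MODEL_AGES - peak)^2) / (2 * width^2))
    w[, "female"] <- prof / 2
    w[, "male"] <- prof / 2
  })
  w / sum(w)
}

#' Bundle all synthetic reference surfaces for a model run
#'
#' @param seed Integer seed driving every surface.
#' @param life_table,prevalence,weights Optional pre-built components; by
#'   default generated from \code{seed}.
#' @return An object of class \code{"smi_surfaces"}: list with elements
#'   \code{life_table}, \code{prevalence} (general-population, unadjusted),
#'   \code{weights}, \code{ages}, \code{seed}.
#' @export
make_reference_surfaces <- function(seed = 1,
                                    life_table = generate_life_table(seed),
                                    prevalence = generate_prevalence(seed),
                                    weights = generate_population_weights(seed)) {
  structure(list(life_table = life_table, prevalence = prevalence,
                 weights = weights, ages = MODEL_AGES, seed = seed),
            class = "smi_surfaces")
}

#' @export
print.smi_surfaces <- function(x, ...) {
  cat("<smi_surfaces>\n")
  cat(sprintf("  ages %d-%d, seed %s\n", min(x$ages), max(x$ages),
              format(x$seed)))
  cat(sprintf("  conditions: %s\n",
              paste(dimnames(x$prevalence)$condition, collapse = ", ")))
  invisible(x)
}

#' Export reference surfaces as long-format CSV
#'
#' Writes \code{life_table.csv} (age, sex, status, value),
#' \code{prevalence.csv} (condition, age, sex, status, value) and
#' \code{weights.csv} (age, sex, value) so real reference data can replace
#' the synthetic surfaces.
#'
#' @param surfaces An \code{smi_surfaces} object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_surfaces <- function(surfaces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lt <- as.data.frame.table(surfaces$life_table, responseName = "value",
                            stringsAsFactors = FALSE)
  pv <- as.data.frame.table(surfaces$prevalence, responseName = "value",
                            stringsAsFactors = FALSE)
  w <- as.data.frame.table(surfaces$weights, responseName = "value",
                           stringsAsFactors = FALSE)
  names(w)[1:2] <- c("age", "sex")
  utils::write.csv(lt, file.path(dir, "life_table.csv"), row.names = FALSE)
  utils::write.csv(pv, file.path(dir, "prevalence.csv"), row.names = FALSE)
  utils::write.csv(w, file.path(dir, "weights.csv"), row.names = FALSE)
  invisible(dir)
}

#' Import reference surfaces from long-format CSV
#'
#' @param dir Directory holding \code{life_table.csv}, \code{prevalence.csv}
#'   and \code{weights.csv} as written by \code{\link{write_surfaces}}.
#' @return An \code{smi_surfaces} object.
#' @export
read_surfaces <- function(dir) {
  lt_df <- utils::read.csv(file.path(dir, "life_table.csv"),
                           stringsAsFactors = FALSE)
  pv_df <- utils::read.csv(file.path(dir, "prevalence.csv"),
                           stringsAsFactors = FALSE)
  w_df <- utils::read.csv(file.path(dir, "weights.csv"),
                          stringsAsFactors = FALSE)
  lt <- array(NA_real_, dim = c(length(MODEL_AGES), 2, 3),
              dimnames = list(age = MODEL_AGES, sex = SEXES,
                              status = STATUSES))
  lt[cbind(match(lt_df$age, MODEL_AGES), match(lt_df$sex, SEXES),
           match(lt_df$status, STATUSES))] <- lt_df$value
  conds <- unique(pv_df$condition)
  pv <- array(NA_real_, dim = c(length(conds), length(MODEL_AGES), 2, 2),
              dimnames = list(condition = conds, age = MODEL_AGES,
                              sex = SEXES, status = c("current", "former")))
  pv[cbind(match(pv_df$condition, conds), match(pv_df$age, MODEL_AGES),
           match(pv_df$sex, SEXES),
           match(pv_df$status, c("current", "former")))] <- pv_df$value
  w <- matrix(NA_real_, nrow = length(MODEL_AGES), ncol = 2,
              dimnames = list(age = MODEL_AGES, sex = SEXES))
  w[cbind(match(w_df$age, MODEL_AGES), match(w_df$sex, SEXES))] <- w_df$value
  if (anyNA(lt) || anyNA(pv) || anyNA(w)) {
    stop("surface CSVs do not cover the full age 12-100 grid", call. = FALSE)
  }
  make_reference_surfaces(seed = NA_integer_, life_table = lt,
                          prevalence = pv, weights = w / sum(w))
}
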