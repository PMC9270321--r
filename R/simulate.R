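#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of a national ageing-cohort baseline:
#' 9412 subjects in 10 strata of 7 primary sampling units (70 PSUs in all,
#' standing in for 70 municipalities), 19 binary chronic conditions with
#' sparse pairwise dependence, hospitalisation prevalence calibrated to 10%,
#' and a missing-at-random mechanism flagging 6.4% of rows.
#'
#' @param n_subjects cohort size.
#' @param n_strata,psus_per_stratum survey design dimensions.
#' @param p_diseases number of chronic-condition indicators (2 to 19).
#' @param edge_density fraction of disease pairs coupled in the true Ising
#'   graph.
#' @param coupling_range interval for |theta| on coupled pairs.
#' @param target_hospitalisation_prevalence calibration target for the
#'   hospitalisation intercept.
#' @param missing_fraction expected share of rows flagged missing.
#' @param seed integer; fully determines the generated cohort.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 9412L,
                              n_strata = 10L,
                              psus_per_stratum = 7L,
                              p_diseases = 19L,
                              edge_density = 0.15,
                              coupling_range = c(0.3, 1.0),
                              target_hospitalisation_prevalence = 0.10,
                              missing_fraction = 0.064,
                              seed = 1L) {
  stopifnot(n_subjects >= 1, n_strata >= 1, psus_per_stratum >= 1,
            p_diseases >= 2, p_diseases <= 19,
            edge_density >= 0, edge_density <= 1,
            length(coupling_range) == 2, coupling_range[1] <= coupling_range[2],
            target_hospitalisation_prevalence > 0,
            target_hospitalisation_prevalence < 1,
            missing_fraction >= 0, missing_fraction < 1)
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_strata = as.integer(n_strata),
    psus_per_stratum = as.integer(psus_per_stratum),
    p_diseases = as.integer(p_diseases),
    edge_density = edge_density,
    coupling_range = coupling_range,
    target_hospitalisation_prevalence = target_hospitalisation_prevalence,
    missing_fraction = missing_fraction,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Chronic-condition labels for the default 19-disease cohort.
disease_labels <- function(p) {
  all19 <- c("hypertension", "spine_problem", "high_cholesterol", "cataract",
             "arthritis_rheumatism", "diabetes", "heart_disease", "stroke",
             "depression", "cancer", "kidney_failure", "asthma", "copd",
             "glaucoma", "diabetic_retinopathy", "macular_degeneration",
             "alzheimer", "parkinson", "osteoporosis")
  all19[seq_len(p)]
}

# Target marginal prevalences for the generated diseases: hypertension and
# back problems common, neurodegenerative conditions rare, matching the
# usual profile of chronic conditions in over-50 cohorts.
disease_target_prevalence <- function(p) {
  all19 <- c(0.52, 0.40, 0.30, 0.24, 0.21, 0.15, 0.10, 0.05, 0.18, 0.05,
             0.03, 0.06, 0.05, 0.05, 0.03, 0.03, 0.02, 0.015, 0.14)
  all19[seq_len(p)]
}

#' Schema used by the synthetic cohort
#'
#' @param p_diseases number of disease indicators.
#' @param n_assets number of household asset variables.
#' @return A [cohort_schema()] describing the generated table.
#' @export
simulation_schema <- function(p_diseases = 19L, n_assets = 12L) {
  dis <- disease_labels(p_diseases)
  assets <- sprintf("asset_%02d", seq_len(n_assets))
  vars <- data.frame(
    name = c("subject_id", "stratum", "psu", "weight",
             "sex", "age_group", "urban", "partner", "alcohol",
             assets, dis,
             "hospitalisation", "readmission", "length_of_stay"),
    type = c("count", "count", "count", "continuous",
             "categorical", "categorical", "categorical", "categorical",
             "categorical",
             rep("count", n_assets), rep("binary", p_diseases),
             "binary", "count", "continuous"),
    role = c("id", "design", "design", "design",
             rep("covariate", 5 + n_assets), rep("disease", p_diseases),
             rep("outcome", 3)),
    design = c(NA, "stratum", "psu", "weight",
               rep(NA, 5 + n_assets + p_diseases + 3)),
    stringsAsFactors = FALSE
  )
  vars$levels <- vector("list", nrow(vars))
  lev <- list(sex = c("female", "male"),
              age_group = c("50-59", "60-74", "75+"),
              urban = c("urban", "rural"),
              partner = c("yes", "no"),
              alcohol = c("once_plus", "less_than_once", "never"))
  for (nm in names(lev)) vars$levels[[match(nm, vars$name)]] <- lev[[nm]]
  cohort_schema(vars)
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483629 + 1)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a complete subject-level table: sociodemographic covariates from
#' fixed marginals, disease indicators from an Ising model whose thresholds
#' shift upward with age (reproducing the age gradient in multimorbidity),
#' hospitalisation from a log-link Bernoulli model calibrated to the target
#' prevalence, readmission (1 + Poisson) and right-skewed lognormal length
#' of stay among the hospitalised only, and a stratified PSU design with
#' inverse-inclusion-probability weights varying 1-5x. The true parameters
#' are returned alongside so downstream estimators can be tested for
#' parameter recovery. If `missing_fraction > 0` the missing-data mechanism
#' of [inject_missingness()] is applied.
#'
#' @param config a [simulation_config()].
#' @return A list with `table` (a [cohort_table()]) and `truth` (couplings
#'   `theta`, thresholds `tau`, age threshold shifts, outcome coefficient
#'   vectors, missingness coefficients, per-stratum notional population
#'   sizes, and a config echo).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_subjects
  p <- config$p_diseases
  dis <- disease_labels(p)
  schema <- simulation_schema(p)

  ## --- true disease dependence graph -----------------------------------
  set.seed(derive_seed(config$seed, 1))
  theta <- matrix(0, p, p, dimnames = list(dis, dis))
  ut <- upper.tri(theta)
  on_edge <- runif(sum(ut)) < config$edge_density
  mag <- runif(sum(ut), config$coupling_range[1], config$coupling_range[2])
  sgn <- ifelse(runif(sum(ut)) < 0.8, 1, -1)   # diseases mostly co-occur
  theta[ut] <- ifelse(on_edge, sgn * mag, 0)
  theta <- theta + t(theta)
  # thresholds aimed at realistic marginal prevalences, with a first-order
  # mean-field correction for the drive the couplings add
  prev_target <- disease_target_prevalence(p)
  tau <- setNames(qlogis(prev_target) - drop(theta %*% prev_target), dis)
  # older age shifts every threshold up; centred so the population marginal
  # stays near its target
  age_tau_shift <- c("50-59" = 0, "60-74" = 0.25, "75+" = 0.5)
  age_probs <- c(0.483, 0.383, 0.135)
  age_tau_shift <- age_tau_shift - sum(age_tau_shift * age_probs) /
    sum(age_probs)

  ## --- survey design ----------------------------------------------------
  set.seed(derive_seed(config$seed, 2))
  S <- config$n_strata; K <- config$psus_per_stratum
  stratum <- sample.int(S, n, replace = TRUE,
                        prob = runif(S, 0.5, 1.5))
  psu_in_stratum <- integer(n)
  for (s in seq_len(S)) {
    idx <- which(stratum == s)
    psu_in_stratum[idx] <- sample.int(K, length(idx), replace = TRUE,
                                      prob = runif(K, 0.5, 1.5))
  }
  psu <- (stratum - 1L) * K + psu_in_stratum   # globally unique PSU ids
  psu_weight <- runif(S * K, 1, 5)             # inverse inclusion probability
  weight <- psu_weight[psu]
  psu_urban <- rbinom(S * K, 1, 0.85)          # urbanicity is PSU-level

  ## --- covariates -------------------------------------------------------
  set.seed(derive_seed(config$seed, 3))
  sex <- ifelse(runif(n) < 0.463, "male", "female")
  age_group <- sample(c("50-59", "60-74", "75+"), n, replace = TRUE,
                      prob = c(0.483, 0.383, 0.135))
  urban <- ifelse(psu_urban[psu] == 1, "urban", "rural")
  partner <- ifelse(runif(n) < 0.637, "yes", "no")
  p_never <- c("50-59" = 0.64, "60-74" = 0.74, "75+" = 0.85)[age_group]
  u <- runif(n)
  alcohol <- ifelse(u < p_never, "never",
                    ifelse(u < p_never + 0.06, "less_than_once", "once_plus"))
  wealth <- rnorm(n)
  asset_size <- rep_len(c(1, 2, 3, 4), 12)
  asset_int <- seq(-1, 1, length.out = 12)
  assets <- sapply(seq_len(12), function(j)
    rbinom(n, asset_size[j], plogis(asset_int[j] + 0.8 * wealth)))
  colnames(assets) <- sprintf("asset_%02d", 1:12)

  ## --- diseases: Ising draws per age group (thresholds shift with age) --
  X <- matrix(0L, n, p, dimnames = list(NULL, dis))
  for (g in names(age_tau_shift)) {
    idx <- which(age_group == g)
    if (!length(idx)) next
    tau_g <- tau + age_tau_shift[[g]]
    sg <- derive_seed(config$seed, 10 + match(g, names(age_tau_shift)))
    X[idx, ] <- if (p <= 12)
      sample_ising_exact(theta, tau_g, length(idx), seed = sg)
    else
      sample_ising_gibbs(theta, tau_g, length(idx), burn_in = 500L,
                         thin = 10L, seed = sg)
  }
  mm_count <- rowSums(X)
  mm2 <- as.numeric(mm_count == 2)
  mm3 <- as.numeric(mm_count >= 3)

  ## --- hospitalisation: log-link Bernoulli, intercept calibrated --------
  set.seed(derive_seed(config$seed, 4))
  hosp_coefs <- c("(Intercept)" = NA_real_,
                  sex_male = log(1.41), partner_no = log(1.21),
                  alcohol_never = log(1.66), alcohol_less = log(1.36),
                  age_60_74 = log(1.01), age_75p = log(1.12),
                  mm_2 = log(1.58), mm_3plus = log(2.39))
  u_psu <- rnorm(S * K, 0, 0.15)               # PSU-level log-risk effect
  s_lin <- hosp_coefs["sex_male"] * (sex == "male") +
    hosp_coefs["partner_no"] * (partner == "no") +
    hosp_coefs["alcohol_never"] * (alcohol == "never") +
    hosp_coefs["alcohol_less"] * (alcohol == "less_than_once") +
    hosp_coefs["age_60_74"] * (age_group == "60-74") +
    hosp_coefs["age_75p"] * (age_group == "75+") +
    hosp_coefs["mm_2"] * mm2 + hosp_coefs["mm_3plus"] * mm3 +
    u_psu[psu]
  # log link: the calibrated intercept has a closed form
  b0 <- log(config$target_hospitalisation_prevalence) - log(mean(exp(s_lin)))
  pr_hosp <- exp(b0 + s_lin)
  if (any(pr_hosp >= 1))
    stop("infeasible prevalence calibration: fitted hospitalisation ",
         "probabilities reach ", signif(max(pr_hosp), 3),
         " at target ", config$target_hospitalisation_prevalence)
  hosp_coefs["(Intercept)"] <- b0
  hosp <- rbinom(n, 1, pr_hosp)

  ## --- readmission and length of stay (hospitalised subjects only) ------
  set.seed(derive_seed(config$seed, 5))
  readm_coefs <- c("(Intercept)" = log(0.45), mm_3plus = 0.2)
  los_coefs <- c("(Intercept)" = 5.2, sex_male = 3.5, urban_rural = -2.7)
  los_sdlog <- 1.15
  readmission <- rep(NA_integer_, n)
  length_of_stay <- rep(NA_real_, n)
  ih <- which(hosp == 1)
  if (length(ih)) {
    rate <- exp(readm_coefs["(Intercept)"] + readm_coefs["mm_3plus"] * mm3[ih])
    readmission[ih] <- 1L + rpois(length(ih), rate)
    lp_los <- los_coefs["(Intercept)"] +
      los_coefs["sex_male"] * (sex[ih] == "male") +
      los_coefs["urban_rural"] * (urban[ih] == "rural")
    # multiplicative lognormal noise with unit mean keeps E[LOS | x] linear
    length_of_stay[ih] <- lp_los *
      rlnorm(length(ih), meanlog = -los_sdlog^2 / 2, sdlog = los_sdlog)
  }

  df <- data.frame(
    subject_id = seq_len(n), stratum = stratum, psu = psu, weight = weight,
    sex = sex, age_group = age_group, urban = urban, partner = partner,
    alcohol = alcohol, assets, X,
    hospitalisation = hosp, readmission = readmission,
    length_of_stay = length_of_stay,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  table <- cohort_table(df, schema)

  stratum_popsize <- tapply(weight, stratum, sum)
  missing_coefs <- c("age_group=60-74" = 0.2, "age_group=75+" = 0.45,
                     "sex=male" = -0.1)
  truth <- list(theta = theta, tau = tau, age_tau_shift = age_tau_shift,
                outcome_coefs = list(hospitalisation = hosp_coefs,
                                     readmission = readm_coefs,
                                     length_of_stay = los_coefs,
                                     los_sdlog = los_sdlog),
                missing_coefs = missing_coefs,
                psu_log_risk = u_psu,
                stratum_popsize = stratum_popsize,
                config = config)

  if (config$missing_fraction > 0)
    table <- inject_missingness(table, missing_coefs,
                                fraction = config$missing_fraction,
                                seed = derive_seed(config$seed, 6))
  list(table = table, truth = truth)
}

#' Inject missing-at-random cells into a cohort
#'
#' Flags rows for missingness with probability logit-linear in fully
#' observed covariates (intercept calibrated so the expected flagged share
#' equals `fraction`) and blanks one randomly chosen blankable variable per
#' flagged row, making "missing on at least one analysis variable" literal.
#'
#' @param table a [cohort_table()].
#' @param missing_coefs named numeric vector; names are either plain numeric
#'   variable names or `"var=level"` indicators for categorical variables.
#'   `NULL` or all-zero gives missingness completely at random.
#' @param fraction expected flagged share, in \[0, 1).
#' @param seed integer seed.
#' @param blankable candidate variables for blanking (default: the disease
#'   columns plus `hospitalisation`).
#' @return The cohort with blanked cells; flagged row indices are attached
#'   as attribute `flagged`.
#' @export
inject_missingness <- function(table, missing_coefs = NULL, fraction,
                               seed, blankable = NULL) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(table)
  sc <- attr(table, "schema")
  df <- as.data.frame(table)
  if (is.null(blankable))
    blankable <- c(schema_vars(sc, role = "disease"),
                   intersect("hospitalisation", sc$variables$name))
  lp <- missingness_lp(df, missing_coefs)
  # calibrate the intercept so that mean(plogis(m0 + lp)) == fraction
  f <- function(m0) mean(plogis(m0 + lp)) - fraction
  m0 <- uniroot(f, lower = -30, upper = 30, tol = 1e-12)$root
  set.seed(as.integer(seed))
  flagged <- which(runif(nrow(df)) < plogis(m0 + lp))
  blank_var <- sample(blankable, length(flagged), replace = TRUE)
  for (k in seq_along(flagged)) df[flagged[k], blank_var[k]] <- NA
  out <- cohort_table(df, sc, validate = FALSE)
  attr(out, "flagged") <- flagged
  out
}

missingness_lp <- function(df, coefs) {
  lp <- rep(0, nrow(df))
  if (is.null(coefs) || !length(coefs)) return(lp)
  for (nm in names(coefs)) {
    if (grepl("=", nm, fixed = TRUE)) {
      parts <- strsplit(nm, "=", fixed = TRUE)[[1]]
      if (!parts[1] %in% names(df))
        stop("missingness coefficient references unknown variable: ", parts[1])
      lp <- lp + coefs[[nm]] * (df[[parts[1]]] == parts[2])
    } else {
      if (!nm %in% names(df))
        stop("missingness coefficient references unknown variable: ", nm)
      lp <- lp + coefs[[nm]] * as.numeric(df[[nm]])
    }
  }
  lp
}
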