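#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> prepare -> regress -> network -> analyse as one
#' reproducible run: every stage writes its artefacts under `out_dir` and a
#' manifest records versions, seeds, a config hash and per-stage row counts.
#' Any stage failure aborts with the stage name and cause, and the manifest
#' (written on exit) flags the partial run.
#'
#' The configuration is a nested list (or the path of a YAML file with the
#' same structure):
#' \describe{
#'   \item{simulate}{arguments for [simulation_config()]; alternatively
#'     `input = list(cohort = <csv>, schema = <yml>)` to read real data.}
#'   \item{ipw_predictors}{fully observed predictors for [compute_ipw()]
#'     (default sex, age_group, urban, partner).}
#'   \item{weight_mode}{`"combined"` (survey weight x IPW multiplier, the
#'     default) or `"design"` (survey weights alone).}
#'   \item{ebic}{arguments for [ebic_config()].}
#'   \item{bootstrap}{`B` (replicates; 0 disables), `seed`.}
#'   \item{stability}{`B` per drop fraction (0 disables), `seed`.}
#'   \item{out_dir}{output directory.}
#' }
#'
#' Sampling weights are deliberately not used in network estimation: the
#' graphical models are fitted unweighted on the complete-case sample, and
#' the run log says so.
#'
#' @param config nested list or YAML file path.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # fail-fast validation before any computation
  if (is.null(config$simulate) && is.null(config$input))
    stop("config must provide either 'simulate' or 'input'")
  if (!is.null(config$input)) {
    for (f in c(config$input$cohort, config$input$schema))
      if (!file.exists(f)) stop("input file not found: ", f)
  }
  ebic_cfg <- do.call(ebic_config, as_plain_list(config$ebic))
  weight_mode <- if (is.null(config$weight_mode)) "combined" else
    config$weight_mode
  stopifnot(weight_mode %in% c("combined", "design"))

  cfg_path <- file.path(out_dir, "config.json")
  write_json_report(config, cfg_path)
  manifest <- list(package = "morbinet",
                   version = as.character(utils::packageVersion("morbinet")),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   stages = list(), complete = FALSE)
  on.exit(write_json_report(manifest, file.path(out_dir, "manifest.json")))

  log_stage <- function(name, ...) message("[", name, "] ", ...)
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- res$info
    res$value
  }

  ## stage 1: simulate or read -------------------------------------------
  cohort <- run_stage("simulate", function() {
    if (!is.null(config$simulate)) {
      sim_cfg <- do.call(simulation_config, as_plain_list(config$simulate))
      log_stage("simulate", "generating cohort, n = ", sim_cfg$n_subjects,
                ", seed = ", sim_cfg$seed)
      gen <- generate_cohort(sim_cfg)
      write_cohort(gen$table, file.path(out_dir, "cohort.csv"))
      write_schema(attr(gen$table, "schema"),
                   file.path(out_dir, "schema.yml"))
      write_json_report(truth_bundle(gen$truth),
                        file.path(out_dir, "truth.json"))
      list(value = gen$table,
           info = list(n = nrow(gen$table), seed = sim_cfg$seed,
                       source = "simulated"))
    } else {
      log_stage("simulate", "reading cohort from ", config$input$cohort)
      tab <- read_cohort(config$input$cohort, config$input$schema)
      list(value = tab, info = list(n = nrow(tab), source = "file"))
    }
  })
  sc <- attr(cohort, "schema")

  ## stage 2: prepare ------------------------------------------------------
  prep <- run_stage("prepare", function() {
    diseases <- schema_vars(sc, role = "disease")
    base_covs <- intersect(c("sex", "age_group", "urban", "partner",
                             "alcohol"), sc$variables$name)
    analysis_vars <- c(diseases, base_covs, "hospitalisation")
    ipw_pred <- config$ipw_predictors
    if (is.null(ipw_pred))
      ipw_pred <- intersect(c("sex", "age_group", "urban", "partner"),
                            sc$variables$name)
    ipw <- compute_ipw(cohort, predictors = ipw_pred,
                       analysis_vars = setdiff(analysis_vars, ipw_pred))
    exc <- exclusion_report(cohort, analysis_vars)
    write_json_report(exc$report, file.path(out_dir, "exclusions.json"))
    log_stage("prepare", "excluded ", exc$report$n_missing, " of ",
              exc$report$n_baseline, " rows (", exc$report$pct_missing,
              "%)")
    kept_rows <- complete.cases(
      as.data.frame(cohort)[, analysis_vars, drop = FALSE])
    tab <- exc$table
    des_w <- survey_design(tab)$weight
    analysis_weight <- if (weight_mode == "combined")
      des_w * ipw[kept_rows] else des_w
    mm <- multimorbidity_category(tab)
    df <- as.data.frame(tab)
    df$multimorbidity <- as.character(mm)
    sc2 <- add_schema_variable(sc, "multimorbidity", "categorical",
                               "covariate", levels = c("<=1", "2", ">=3"))
    tab2 <- cohort_table(df, sc2, validate = FALSE)
    write_cohort(tab2, file.path(out_dir, "prepared.csv"))
    write_schema(sc2, file.path(out_dir, "schema_prepared.yml"))
    prev <- weighted_prevalence(tab2, "hospitalisation",
                                weights = analysis_weight)
    asset_vars <- grep("^asset_", sc$variables$name, value = TRUE)
    assets <- if (length(asset_vars) >= 12)
      asset_index(tab2, asset_vars) else NULL
    write_json_report(list(
      hospitalisation_prevalence = unclass(prev),
      asset_boundaries = if (!is.null(assets)) assets$boundaries),
      file.path(out_dir, "prevalence.json"))
    list(value = list(table = tab2, weight = analysis_weight,
                      exclusions = exc$report, prevalence = prev),
         info = list(n_final = exc$report$n_final,
                     pct_missing = exc$report$pct_missing,
                     weight_mode = weight_mode))
  })
  tab <- prep$table

  ## stage 3: regress ------------------------------------------------------
  reg <- run_stage("regress", function() {
    covs <- intersect(c("sex", "age_group", "urban", "partner", "alcohol",
                        "multimorbidity"), attr(tab, "schema")$variables$name)
    log_stage("regress", "Poisson PR model for hospitalisation; linear ",
              "models for readmission and length of stay (hospitalised ",
              "subset)")
    pr <- fit_poisson_pr(tab, "hospitalisation", covs, weights = prep$weight)
    lin_re <- fit_linear(tab, "readmission", covs, weights = prep$weight)
    lin_los <- fit_linear(tab, "length_of_stay", covs,
                          weights = prep$weight)
    res <- list(hospitalisation = regression_bundle(pr),
                readmission = regression_bundle(lin_re),
                length_of_stay = regression_bundle(lin_los))
    write_json_report(res, file.path(out_dir, "regression.json"))
    write.csv(rbind(
      cbind(outcome = "hospitalisation", pr$terms),
      cbind(outcome = "readmission", lin_re$terms),
      cbind(outcome = "length_of_stay", lin_los$terms)),
      file.path(out_dir, "regression.csv"), row.names = FALSE, na = "")
    list(value = list(hospitalisation = pr, readmission = lin_re,
                      length_of_stay = lin_los),
         info = list(n_poisson = pr$n_used, n_readmission = lin_re$n_used,
                     n_los = lin_los$n_used))
  })

  ## stage 4: network ------------------------------------------------------
  nets <- run_stage("network", function() {
    log_stage("network", "NOTE: graphical models are fitted unweighted on ",
              "the complete-case sample (sampling weights not used)")
    df <- as.data.frame(tab)
    diseases <- schema_vars(attr(tab, "schema"), role = "disease")
    block_h <- df[, c(diseases, "hospitalisation")]
    block_h <- block_h[complete.cases(block_h), ]
    net_h <- fit_ising(block_h, ebic_cfg)
    hosp_rows <- !is.na(df$readmission)
    block_r <- df[hosp_rows, c(diseases, "readmission")]
    block_r <- block_r[complete.cases(block_r), ]
    net_r <- fit_mgm(block_r, c(rep("binary", length(diseases)), "count"),
                     ebic_cfg)
    block_l <- df[hosp_rows, c(diseases, "length_of_stay")]
    block_l <- block_l[complete.cases(block_l), ]
    net_l <- fit_mgm(block_l,
                     c(rep("binary", length(diseases)), "continuous"),
                     ebic_cfg)
    for (x in list(list(net_h, "hospitalisation"), list(net_r, "readmission"),
                   list(net_l, "length_of_stay"))) {
      write.csv(edge_list(x[[1]]),
                file.path(out_dir, paste0("edges_", x[[2]], ".csv")),
                row.names = FALSE)
      write_json_report(network_bundle(x[[1]]),
                        file.path(out_dir, paste0("network_", x[[2]],
                                                  ".json")))
    }
    list(value = list(hospitalisation = list(net = net_h, block = block_h),
                      readmission = list(net = net_r, block = block_r),
                      length_of_stay = list(net = net_l, block = block_l)),
         info = list(
           edges_hospitalisation = nrow(edge_list(net_h)),
           edges_readmission = nrow(edge_list(net_r)),
           edges_length_of_stay = nrow(edge_list(net_l))))
  })

  ## stage 5: analyse ------------------------------------------------------
  run_stage("analyse", function() {
    info <- list()
    for (nm in names(nets)) {
      net <- nets[[nm]]$net
      block <- nets[[nm]]$block
      comm <- walktrap(abs(net$weights))
      pred <- node_predictability(block, net)
      fl <- flow_layers(net, nm)
      prevalence <- colMeans(as.matrix(block))
      bs <- NULL
      if (nm == "hospitalisation" && !is.null(config$bootstrap) &&
          (config$bootstrap$B %||% 0) >= 50) {
        log_stage("analyse", "bootstrapping ", config$bootstrap$B,
                  " replicates of the hospitalisation network")
        bs <- bootstrap_edges(block,
                              function(m) fit_ising(m, ebic_cfg),
                              B = config$bootstrap$B,
                              seed = config$bootstrap$seed %||% 1L)
        write_json_report(list(B = bs$B, n_failed = bs$n_failed,
                               edges = bs$edges),
                          file.path(out_dir, "bootstrap_hospitalisation.json"))
      }
      cs <- NULL
      if (nm == "hospitalisation" && !is.null(config$stability) &&
          (config$stability$B %||% 0) > 0) {
        cs <- case_drop_stability(block,
                                  function(m) fit_ising(m, ebic_cfg),
                                  B = config$stability$B,
                                  seed = config$stability$seed %||% 1L)
        write_json_report(list(curve = cs$curve,
                               cs_coefficient = cs$cs_coefficient),
                          file.path(out_dir, "stability_hospitalisation.json"))
      }
      write_graphml(net, file.path(out_dir, paste0("net_", nm, ".graphml")),
                    prevalence = prevalence, predictability = pred,
                    communities = comm, flow = fl, bootstrap = bs)
      write_json_report(list(
        communities = as.list(comm$assignment),
        modularity = comm$modularity,
        predictability = pred,
        flow_layers = as.list(fl$layer),
        cs_coefficient = if (!is.null(cs)) cs$cs_coefficient),
        file.path(out_dir, paste0("analysis_", nm, ".json")))
      info[[paste0("communities_", nm)]] <-
        length(unique(comm$assignment))
    }
    list(value = NULL, info = info)
  })

  manifest$complete <- TRUE
  manifest$seeds <- list(
    simulation = config$simulate$seed,
    bootstrap = config$bootstrap$seed,
    stability = config$stability$seed)
  log_stage("done", "all five stages complete; artefacts in ", out_dir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_plain_list <- function(x) {
  if (is.null(x)) return(list())
  x <- as.list(x)
  if (!is.null(x$coupling_range)) x$coupling_range <-
      as.numeric(unlist(x$coupling_range))
  x
}

add_schema_variable <- function(schema, name, type, role, levels = NULL) {
  v <- schema$variables
  if (name %in% v$name) return(schema)
  add <- data.frame(name = name, type = type, role = role,
                    design = NA_character_, stringsAsFactors = FALSE)
  add$levels <- list(levels)
  cohort_schema(rbind(v, add))
}

regression_bundle <- function(res) {
  list(family = res$model_family, n_used = res$n_used, terms = res$terms)
}

truth_bundle <- function(truth) {
  list(theta = truth$theta, tau = as.list(truth$tau),
       age_tau_shift = as.list(truth$age_tau_shift),
       outcome_coefs = lapply(truth$outcome_coefs, as.list),
       missing_coefs = as.list(truth$missing_coefs),
       stratum_popsize = as.list(truth$stratum_popsize),
       config = unclass(truth$config))
}
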