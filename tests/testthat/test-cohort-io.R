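test_that("schema validation catches malformed declarations", {
  v <- data.frame(name = c("psu", "stratum", "weight", "d1", "d2"),
                  type = c("count", "count", "continuous", "binary",
                           "binary"),
                  role = c("design", "design", "design", "disease",
                           "disease"),
                  design = c("psu", "stratum", "weight", NA, NA))
  expect_s3_class(cohort_schema(v), "cohort_schema")
  # missing weight subtype
  v2 <- v; v2$design[3] <- NA
  expect_error(cohort_schema(v2), "weight")
  # only one disease
  v3 <- v[-5, ]
  expect_error(cohort_schema(v3), "disease")
  # non-binary disease
  v4 <- v; v4$type[4] <- "count"
  expect_error(cohort_schema(v4), "binary")
})

test_that("cohort CSV round-trips and rejects out-of-domain cells", {
  tab <- tiny_cohort(50, seed = 2)
  tmp <- tempfile(fileext = ".csv")
  write_cohort(tab, tmp)
  back <- read_cohort(tmp, attr(tab, "schema"))
  expect_equal(as.data.frame(back), as.data.frame(tab))

  # disease coded "2" -> error naming row and column
  df <- as.data.frame(tab)
  df$d1[7] <- 2
  write.csv(df, tmp, row.names = FALSE, na = "")
  expect_error(read_cohort(tmp, attr(tab, "schema")), "d1.*row 7")

  # header missing the weight column is a fatal schema error
  df2 <- as.data.frame(tab)
  df2$weight <- NULL
  write.csv(df2, tmp, row.names = FALSE, na = "")
  expect_error(read_cohort(tmp, attr(tab, "schema")),
               "schema error.*weight")
})

test_that("schema YAML round-trips", {
  sc <- simulation_schema(p_diseases = 5)
  tmp <- tempfile(fileext = ".yml")
  write_schema(sc, tmp)
  back <- read_schema(tmp)
  expect_equal(back$variables$name, sc$variables$name)
  expect_equal(back$variables$type, sc$variables$type)
  expect_equal(back$variables$levels, sc$variables$levels)
})

test_that("exclusion accounting conserves rows and flags edge cases", {
  tab <- tiny_cohort(100, seed = 3)
  df <- as.data.frame(tab)
  df$d1[c(4, 9, 20)] <- NA
  tab2 <- cohort_table(df, attr(tab, "schema"), validate = FALSE)
  res <- exclusion_report(tab2, c("d1", "d2", "y"))
  expect_equal(res$report$n_missing, 3)
  expect_equal(res$report$n_final + res$report$n_missing,
               res$report$n_baseline)
  expect_equal(nrow(res$table), 97)

  # no missing cells: table unchanged
  res0 <- exclusion_report(tab, c("d1", "d2", "y"))
  expect_equal(res0$report$n_missing, 0)
  expect_equal(as.data.frame(res0$table), as.data.frame(tab))

  # all rows missing: n_final 0 with a warning
  df$d1 <- NA
  tab3 <- cohort_table(df, attr(tab, "schema"), validate = FALSE)
  expect_warning(res3 <- exclusion_report(tab3, "d1"), "all rows")
  expect_equal(res3$report$n_final, 0)

  expect_error(exclusion_report(tab, character(0)), "at least one")
})

test_that("multimorbidity category counts diseases and never imputes", {
  sc <- simulation_schema(p_diseases = 5)
  nm <- schema_vars(sc, role = "disease")
  base <- data.frame(subject_id = 1:4, stratum = 1, psu = 1:4, weight = 1,
                     sex = "female", age_group = "50-59", urban = "urban",
                     partner = "yes", alcohol = "never")
  for (a in sprintf("asset_%02d", 1:12)) base[[a]] <- 0
  dis <- matrix(0, 4, 5, dimnames = list(NULL, nm))
  dis[2, 1:2] <- 1          # exactly two conditions
  dis[3, 1:5] <- 1          # five conditions
  dis[4, 1] <- NA           # unknown response
  tab <- cohort_table(cbind(base, dis, hospitalisation = 0L,
                            readmission = NA, length_of_stay = NA),
                      sc, validate = FALSE)
  mm <- multimorbidity_category(tab)
  expect_equal(as.character(mm), c("<=1", "2", ">=3", NA))
})

test_that("asset index is sign-canonical and cuts weighted quintiles", {
  set.seed(5)
  n <- 500
  wealth <- rnorm(n)
  assets <- sapply(1:12, function(j)
    rbinom(n, 3, plogis(-0.5 + 0.9 * wealth)))
  colnames(assets) <- sprintf("a%02d", 1:12)
  extra <- data.frame(name = colnames(assets), type = "count",
                      role = "covariate", design = NA,
                      levels = I(rep(list(NULL), 12)))
  sc <- tiny_schema(extra = extra)
  df <- cbind(as.data.frame(tiny_cohort(n, seed = 6)), assets)
  tab <- cohort_table(df, sc, validate = FALSE)

  res <- asset_index(tab, colnames(assets))
  # equal weights: each quintile holds ~20%
  occ <- table(res$quintile)
  expect_true(all(abs(occ - n / 5) <= n * 0.02 + 1))

  # flipping the sign of every input leaves the categories unchanged
  df2 <- df
  df2[colnames(assets)] <- -df2[colnames(assets)]
  tab2 <- cohort_table(df2, sc, validate = FALSE)
  res2 <- asset_index(tab2, colnames(assets))
  expect_equal(res2$quintile, res$quintile)

  # a variable carrying the shared wealth signal noiselessly dominates the
  # first component
  assets_dom <- sapply(1:12, function(j)
    0.9 * wealth + sqrt(1 - 0.81) * rnorm(n))
  assets_dom[, 1] <- wealth
  colnames(assets_dom) <- colnames(assets)
  df3 <- df; df3[colnames(assets)] <- assets_dom
  tab3 <- cohort_table(df3, sc, validate = FALSE)
  res3 <- asset_index(tab3, colnames(assets))
  expect_gt(abs(cor(res3$score, assets_dom[, 1])), 0.99)

  expect_error(asset_index(tab, colnames(assets)[1:5]), "12")
  df4 <- df; df4$a01 <- 1
  tab4 <- cohort_table(df4, sc, validate = FALSE)
  expect_warning(asset_index(tab4, colnames(assets)), "zero-variance")
})
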