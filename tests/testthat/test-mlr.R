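# OLS refit of group values with holdout evaluation.

make_tiny_dataset <- function(n = 40, sd = 0, seed = 5,
                              universe = c("C-(H)3(C)", "C-(H)2(C)2",
                                           "C_B-(H)(C_B)2", "O-(H)(CO)")) {
  generate_thermo_dataset(n_molecules = n, group_universe = universe,
                          noise_sd = c(S = sd, dfG = sd),
                          seed = seed)$dataset
}

test_that("holdout split has floor sizes, is disjoint and seed-deterministic", {
  ds <- make_tiny_dataset(n = 10)
  sp <- split_holdout(ds, 0.7, seed = 3)
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$test), 3)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), ds$molecule_id)
  sp2 <- split_holdout(ds, 0.7, seed = 3)
  expect_identical(sp$train_ids, sp2$train_ids)
  expect_false(identical(sp$train_ids,
                         split_holdout(ds, 0.7, seed = 4)$train_ids))
  # the study-sized case: floor(0.7 * 77)
  ds77 <- make_tiny_dataset(n = 77)
  sp77 <- split_holdout(ds77, 0.7, seed = 1)
  expect_equal(nrow(sp77$train), 53)
  expect_equal(nrow(sp77$test), 24)
  # floor(0.4 * 2) = 0 training rows
  expect_error(split_holdout(suppressWarnings(make_tiny_dataset(n = 2)),
                             0.4, 1), "too small")
})

test_that("noiseless full-rank fits recover the generating coefficients", {
  universe <- c("C-(H)3(C)", "C-(H)2(C)2", "C_B-(H)(C_B)2", "O-(H)(CO)")
  sim <- generate_thermo_dataset(n_molecules = 60, group_universe = universe,
                                 noise_sd = c(S = 0, dfG = 0), seed = 9)
  fit <- fit_mlr(sim$dataset, "S")
  truth <- sim$truth
  idx <- match(universe, truth$values$label)
  expect_equal(unname(fit$coefficients[universe]),
               truth$values$S[idx], tolerance = 1e-6)
  expect_equal(fit$intercept, unname(truth$intercept["S"]),
               tolerance = 1e-6)
})

test_that("an all-zero design fits the intercept as the mean", {
  df <- data.frame(molecule_id = paste0("m", 1:6),
                   S_J_molK = c(10, 12, 14, 16, 18, 20),
                   `group:C-(H)3(C)` = 0, check.names = FALSE)
  ds <- thermo_dataset(df)
  fit <- suppressWarnings(fit_mlr(ds, "S"))
  expect_equal(fit$intercept + mean(fit$coefficients) * 0, 15)
})

test_that("duplicated columns warn and leave predictions unchanged", {
  ds <- make_tiny_dataset(n = 30)
  df <- as.data.frame(ds)
  df[["group:C-(H)3(N)"]] <- df[["group:C-(H)3(C)"]]  # exact alias
  ds_dup <- thermo_dataset(df)
  expect_warning(fit_dup <- fit_mlr(ds_dup, "S"), "minimum-norm")
  expect_warning(fit_mlr(ds_dup, "S"), "Aliased column")
  fit <- fit_mlr(ds, "S")
  expect_equal(fit_dup$fitted, fit$fitted, tolerance = 1e-8)
  # the two aliased coefficients share the effect
  expect_equal(unname(fit_dup$coefficients["C-(H)3(C)"] +
                        fit_dup$coefficients["C-(H)3(N)"]),
               unname(fit$coefficients["C-(H)3(C)"]), tolerance = 1e-6)
})

test_that("metrics match their definitions and bounds", {
  obs <- c(1, 2, 3, 4)
  expect_equal(unname(regression_metrics(obs, obs)), c(1, 0, 0))
  m0 <- regression_metrics(rep(mean(obs), 4), obs)
  expect_equal(unname(m0["R2"]), 0)
  m <- regression_metrics(c(4, 6), c(1, 2))  # errors -3, -4
  expect_equal(unname(m["MAE"]), 3.5)
  expect_equal(unname(m["RMSE"]), sqrt(12.5))
  expect_gte(unname(m["RMSE"]), unname(m["MAE"]))
  expect_error(regression_metrics(c(1, 2), c(5, 5)), "zero variance")
  # RMSE >= MAE >= 0 on random cases
  set.seed(2)
  for (i in 1:20) {
    mm <- regression_metrics(stats::rnorm(10), stats::rnorm(10))
    expect_gte(unname(mm["RMSE"]), unname(mm["MAE"]))
    expect_gte(unname(mm["MAE"]), 0)
  }
})

test_that("pipeline on noiseless data is exact and self-consistent", {
  ds <- make_tiny_dataset(n = 50, sd = 0)
  pipe <- run_pipeline(ds, seed = 42)
  for (p in c("S", "dfS", "dfG")) {
    r2_test <- pipe$metrics$R2[pipe$metrics$property == p &
                                 pipe$metrics$split == "test"]
    expect_equal(r2_test, 1, tolerance = 1e-9)
  }
  # the assembled table reproduces the fit's own training predictions
  pred_tab <- predict_dataset(pipe$split$train, pipe$table, "S")
  expect_equal(pred_tab, pipe$fits$S$fitted, tolerance = 1e-9)
})

test_that("S and dfS fits share residuals, MAE and RMSE but not R2", {
  # elemental composition is an exact linear map of group counts, so the
  # element-entropy offset lies in the design's column space
  sim <- generate_thermo_dataset(n_molecules = 70,
                                 group_universe = c("C-(H)3(C)",
                                                    "C-(H)2(C)2",
                                                    "C_B-(H)(C_B)2",
                                                    "CO-(O)(C_B)",
                                                    "O-(H)(CO)"),
                                 noise_sd = c(S = 4, dfG = 3), seed = 21)
  pipe <- run_pipeline(sim$dataset, c("S", "dfS"), seed = 8)
  expect_equal(pipe$fits$S$residuals, pipe$fits$dfS$residuals,
               tolerance = 1e-8)
  m <- pipe$metrics
  for (split in c("train", "test")) {
    expect_equal(m$MAE[m$property == "S" & m$split == split],
                 m$MAE[m$property == "dfS" & m$split == split],
                 tolerance = 1e-8)
    expect_equal(m$RMSE[m$property == "S" & m$split == split],
                 m$RMSE[m$property == "dfS" & m$split == split],
                 tolerance = 1e-8)
  }
  expect_false(isTRUE(all.equal(m$R2[m$property == "S"],
                                m$R2[m$property == "dfS"])))
})

test_that("train R2 is at least test R2 in expectation over seeds", {
  diffs <- vapply(1:8, function(s) {
    sim <- generate_thermo_dataset(n_molecules = 60,
                                   group_universe = c("C-(H)3(C)",
                                                      "C-(H)2(C)2",
                                                      "C_B-(H)(C_B)2"),
                                   noise_sd = c(S = 5, dfG = 5), seed = s)
    pipe <- run_pipeline(sim$dataset, "S", seed = s + 100)
    m <- pipe$metrics
    m$R2[m$split == "train"] - m$R2[m$split == "test"]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("coefficients recover to better than 1 J/mol/K RMSE under noise", {
  sim <- generate_thermo_dataset(n_molecules = 500,
                                 noise_sd = c(S = 5, dfG = 5), seed = 17)
  fit <- fit_mlr(sim$dataset, "S")
  idx <- match(names(fit$coefficients), sim$truth$values$label)
  err <- unname(fit$coefficients) - sim$truth$values$S[idx]
  expect_lt(sqrt(mean(err^2)), 1)
})

test_that("datasets round-trip through the wide CSV layout", {
  ds <- make_tiny_dataset(n = 12, sd = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_thermo_dataset(ds, path)
  back <- read_thermo_dataset(path)
  expect_equal(attr(back, "group_universe"), attr(ds, "group_universe"))
  expect_equal(back$S_J_molK, ds$S_J_molK)
  expect_equal(dataset_counts(back), dataset_counts(ds))
})
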