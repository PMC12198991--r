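# Refitting group values by ordinary least squares with a single holdout
# split, and the evaluation metrics used to judge the fit.

.property_cols <- c(S = "S_J_molK", dfS = "dfS_J_molK", dfG = "dfG_kJ_mol")

#' Regression dataset of (group counts, property) rows
#'
#' A data frame with `molecule_id`, optional `formula`, observed property
#' columns (`S_J_molK`, `dfS_J_molK`, `dfG_kJ_mol`; any subset) and one
#' `group:<label>` column per group in the universe.
#'
#' @param df data frame in the wide CSV layout.
#' @return The validated data frame, classed `thermo_dataset`, with the
#'   ordered group universe in `attr(, "group_universe")`.
#' @export
thermo_dataset <- function(df) {
  df <- as.data.frame(df)
  if (!"molecule_id" %in% names(df))
    stop("dataset needs a 'molecule_id' column")
  if (anyDuplicated(df$molecule_id)) stop("duplicate molecule ids")
  gcols <- grep("^group:", names(df), value = TRUE)
  if (!length(gcols)) stop("dataset has no 'group:<label>' columns")
  for (g in gcols) {
    df[[g]][is.na(df[[g]])] <- 0
    if (any(df[[g]] < 0)) stop("negative group count in column ", g)
  }
  if (!any(.property_cols %in% names(df)))
    stop("dataset has no observed property columns")
  universe <- canonical_label(sub("^group:", "", gcols))
  if (anyDuplicated(universe)) stop("duplicate group columns after ",
                                    "label canonicalization")
  names(df)[match(gcols, names(df))] <- paste0("group:", universe)
  attr(df, "group_universe") <- universe
  class(df) <- c("thermo_dataset", "data.frame")
  df
}

#' Group-count design matrix of a dataset
#' @param ds a [thermo_dataset()].
#' @return Numeric matrix, one column per group label (no intercept column).
#' @export
dataset_counts <- function(ds) {
  universe <- attr(ds, "group_universe")
  m <- as.matrix(as.data.frame(ds)[, paste0("group:", universe),
                                   drop = FALSE])
  colnames(m) <- universe
  rownames(m) <- ds$molecule_id
  m
}

#' Read / write a regression dataset
#'
#' CSV uses the wide layout described in [thermo_dataset()]; JSON holds
#' `{"rows": [{"molecule_id": ..., "groups": {label: count}, "S_J_molK":
#' ...}, ...]}`.
#'
#' @param path file path (`.csv` or `.json`).
#' @return A [thermo_dataset()].
#' @export
read_thermo_dataset <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = FALSE)
    labs <- unique(unlist(lapply(j$rows, function(r) names(r$groups))))
    labs <- canonical_label(labs)
    rows <- lapply(j$rows, function(r) {
      out <- as.list(stats::setNames(rep(0, length(labs)),
                                     paste0("group:", labs)))
      for (g in names(r$groups))
        out[[paste0("group:", canonical_label(g))]] <- r$groups[[g]]
      for (cc in c("molecule_id", "formula", unname(.property_cols)))
        if (!is.null(r[[cc]])) out[[cc]] <- r[[cc]]
      as.data.frame(out, check.names = FALSE)
    })
    df <- do.call(rbind, lapply(rows, function(r) {
      miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
      for (m in miss) r[[m]] <- NA
      r[, unique(unlist(lapply(rows, names)))]
    }))
    thermo_dataset(df)
  } else {
    thermo_dataset(utils::read.csv(path, check.names = FALSE,
                                   stringsAsFactors = FALSE))
  }
}

#' @rdname read_thermo_dataset
#' @param ds a [thermo_dataset()].
#' @export
write_thermo_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "thermo_dataset"))
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Single holdout train/test split
#'
#' Uniform sampling without replacement; the training set has
#' `floor(train_frac * n)` rows.  Deterministic for a given seed and
#' independent of (and not disturbing) the session RNG state.
#'
#' @param ds a [thermo_dataset()].
#' @param train_frac training fraction in (0, 1); default 0.7.
#' @param seed integer seed.
#' @return List with elements `train`, `test` (datasets) and `train_ids`,
#'   `test_ids`.
#' @export
split_holdout <- function(ds, train_frac = 0.7, seed = 42L) {
  stopifnot(inherits(ds, "thermo_dataset"),
            train_frac > 0, train_frac < 1)
  n <- nrow(ds)
  n_train <- floor(train_frac * n)
  if (n_train < 1 || n_train >= n)
    stop("dataset too small for a nonempty train and test set")
  idx <- .with_seed(seed, sample.int(n, n_train))
  sub <- function(i) {
    out <- as.data.frame(ds)[i, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "group_universe") <- attr(ds, "group_universe")
    class(out) <- class(ds)
    out
  }
  list(train = sub(idx), test = sub(setdiff(seq_len(n), idx)),
       train_ids = ds$molecule_id[idx],
       test_ids = ds$molecule_id[setdiff(seq_len(n), idx)])
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Ordinary least-squares fit of group values
#'
#' Fits `observed ~ intercept + group counts` by OLS.  Rank-deficient
#' designs (aliased group columns, e.g. exactly collinear groups) are solved
#' by the minimum-norm least-squares solution via the pseudoinverse, with a
#' warning naming the aliased columns; predictions are unaffected by the
#' aliasing.
#'
#' @param train a [thermo_dataset()].
#' @param property `"S"`, `"dfS"` or `"dfG"`.
#' @return An object of class `gav_fit` with elements `coefficients` (named
#'   by group label), `intercept`, `property`, `fitted`, `residuals`,
#'   `aliased`.
#' @export
fit_mlr <- function(train, property = c("S", "dfS", "dfG")) {
  property <- match.arg(property)
  stopifnot(inherits(train, "thermo_dataset"))
  ycol <- .property_cols[property]
  if (!ycol %in% names(train))
    stop("dataset has no observed column for property ", sQuote(property))
  y <- train[[ycol]]
  if (!nrow(train) || all(is.na(y))) stop("empty training set")
  if (anyNA(y)) stop("missing observations for property ", sQuote(property))
  X <- cbind(`(intercept)` = 1, dataset_counts(train))
  qx <- qr(X)
  aliased <- character(0)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning("rank-deficient design; minimum-norm solution used. ",
            "Aliased column(s): ", paste(aliased, collapse = ", "))
    beta <- as.numeric(MASS::ginv(X) %*% y)
  } else {
    beta <- qr.coef(qx, y)
  }
  names(beta) <- colnames(X)
  fitted <- as.numeric(X %*% beta)
  structure(list(coefficients = beta[-1], intercept = unname(beta[1]),
                 property = property, fitted = fitted,
                 residuals = y - fitted, aliased = aliased),
            class = "gav_fit")
}

#' Predict a property for a dataset from a fit or parameter table
#'
#' @param ds a [thermo_dataset()].
#' @param fit a `gav_fit` from [fit_mlr()], or a [gav_table()].
#' @param property required when `fit` is a table.
#' @return Numeric vector of predictions.
#' @export
predict_dataset <- function(ds, fit, property = NULL) {
  m <- dataset_counts(ds)
  if (inherits(fit, "gav_fit")) {
    coef <- fit$coefficients[colnames(m)]
    if (anyNA(coef)) stop("fit lacks coefficients for some dataset groups")
    as.numeric(m %*% coef + fit$intercept)
  } else if (inherits(fit, "gav_table")) {
    if (is.null(property)) stop("'property' needed with a gav_table")
    idx <- match(colnames(m), fit$values$label)
    if (anyNA(idx))
      stop("table lacks group(s): ",
           paste(colnames(m)[is.na(idx)], collapse = ", "))
    as.numeric(m %*% fit$values[[property]][idx] +
                 fit$intercept[property])
  } else stop("'fit' must be a gav_fit or gav_table")
}

#' Regression evaluation metrics
#'
#' `R2 = 1 - SS_res/SS_tot`, mean absolute error, and root mean squared
#' error.  Errors (rather than returning `NaN`) when the observations have
#' zero variance, where R2 is undefined.
#'
#' @param predicted,observed equal-length numeric vectors.
#' @return Named numeric vector `c(R2=, MAE=, RMSE=)`.
#' @examples
#' regression_metrics(c(1, 2), c(4, 6))
#' @export
regression_metrics <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) > 0)
  if (anyNA(predicted) || anyNA(observed)) stop("NA in metric inputs")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("R2 undefined: observations have zero variance")
  e <- observed - predicted
  c(R2 = 1 - sum(e^2) / ss_tot, MAE = mean(abs(e)),
    RMSE = sqrt(mean(e^2)))
}

#' Refit group values and evaluate on a holdout split
#'
#' One shared 70/30 split; one independent OLS fit per requested property;
#' train and test metrics for each; and the fitted coefficients assembled
#' into a new [gav_table()] usable by [gav_estimate()].
#'
#' @param ds a [thermo_dataset()].
#' @param properties subset of `c("S", "dfS", "dfG")`.
#' @param train_frac training fraction.
#' @param seed integer seed for the split (logged in the result and the
#'   table provenance).
#' @return List of class `gav_pipeline` with `table`, `fits`, `metrics`
#'   (data frame), `split`, `seed`.
#' @export
run_pipeline <- function(ds, properties = c("S", "dfS", "dfG"),
                         train_frac = 0.7, seed = 42L) {
  properties <- match.arg(properties, several.ok = TRUE)
  sp <- split_holdout(ds, train_frac, seed)
  fits <- list(); metrics <- list()
  for (p in properties) {
    f <- fit_mlr(sp$train, p)
    pred_test <- predict_dataset(sp$test, f)
    obs_test <- sp$test[[.property_cols[p]]]
    metrics[[p]] <- rbind(
      data.frame(property = p, split = "train",
                 t(regression_metrics(f$fitted,
                                      sp$train[[.property_cols[p]]]))),
      data.frame(property = p, split = "test",
                 t(regression_metrics(pred_test, obs_test))))
    fits[[p]] <- f
  }
  universe <- attr(ds, "group_universe")
  values <- data.frame(label = universe)
  intercept <- c(S = NA_real_, dfS = NA_real_, dfG = NA_real_)
  for (p in c("S", "dfS", "dfG")) {
    values[[p]] <- if (p %in% properties)
      unname(fits[[p]]$coefficients[universe]) else NA_real_
    if (p %in% properties) intercept[p] <- fits[[p]]$intercept
  }
  tab <- gav_table(values, intercept,
                   provenance = sprintf(
                     "OLS refit on %d molecules (train %d / test %d), seed %d",
                     nrow(ds), nrow(sp$train), nrow(sp$test), seed),
                   version = "refit")
  structure(list(table = tab, fits = fits,
                 metrics = do.call(rbind, metrics), split = sp,
                 seed = seed),
            class = "gav_pipeline")
}

#' @export
print.gav_pipeline <- function(x, ...) {
  cat("<gav_pipeline> seed ", x$seed, "\n", sep = "")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
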