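DEFAULT_COVARIATES <- c("WSST", "WSIC", "WSBT", "SSBT", "SNPP", "depth")

#' Year-stratified train/test split of a survey table
#'
#' Partitions survey rows into a training set of exactly
#' `floor(fraction * n)` rows and a test set of the remainder,
#' stratified by year so that every survey year contributes to training
#' (per-year quotas are proportional, settled by largest remainder).
#'
#' @param table survey data.frame with a `year` column.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed; the same seed always yields the same split.
#' @return list with `train` and `test` data.frames.
#' @export
split_train_test <- function(table, fraction = 0.8, seed = 1L) {
  n <- nrow(table)
  if (n < 2) stop("need at least 2 rows to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0,1)")
  n_train <- floor(fraction * n)
  years <- unique(table$year)
  n_y <- vapply(years, function(y) sum(table$year == y), integer(1))
  quota <- fraction * n_y
  alloc <- floor(quota)
  rem <- n_train - sum(alloc)
  if (rem > 0) {
    ord <- order(quota - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    ord <- order(quota - alloc)
    take <- ord[alloc[ord] > 0][seq_len(-rem)]
    alloc[take] <- alloc[take] - 1L
  }
  ## every year with data must appear in training
  while (any(fix <- alloc == 0 & n_y > 0) && any(alloc > 1)) {
    donor <- which.max(alloc)
    alloc[donor] <- alloc[donor] - 1L
    alloc[which(fix)[1]] <- 1L
  }
  alloc <- pmin(alloc, n_y)
  train_idx <- with_seed(seed, {
    unlist(lapply(seq_along(years), function(i) {
      rows <- which(table$year == years[i])
      if (alloc[i] == 0) integer(0) else sample(rows, alloc[i])
    }))
  })
  list(train = table[sort(train_idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), train_idx), , drop = FALSE])
}

default_grid <- function(algorithm, n_covariates) {
  if (algorithm == "rf") {
    expand.grid(mtry = unique(pmin(c(2L, 3L, 5L), n_covariates)),
                min_node_size = c(5L, 10L),
                num_trees = c(200L, 500L))
  } else {
    expand.grid(learning_rate = c(0.05, 0.1),
                interaction_depth = c(2L, 3L),
                num_trees = c(100L, 300L))
  }
}

fit_member <- function(algorithm, data, spec, covariates, seed = 1L) {
  if (algorithm == "rf") {
    ranger::ranger(
      dependent.variable.name = "cpue",
      data = data[, c("cpue", covariates)],
      num.trees = spec$num_trees,
      mtry = min(spec$mtry, length(covariates)),
      min.node.size = spec$min_node_size,
      seed = seed, num.threads = 1, verbose = FALSE)
  } else {
    dtrain <- xgboost::xgb.DMatrix(as.matrix(data[, covariates, drop = FALSE]),
                                   label = data$cpue)
    xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    eta = spec$learning_rate,
                    max_depth = spec$interaction_depth,
                    nthread = 1, seed = seed),
      data = dtrain, nrounds = spec$num_trees, verbose = 0)
  }
}

predict_member <- function(algorithm, model, newdata, covariates) {
  if (algorithm == "rf") {
    stats::predict(model, data = newdata[, covariates, drop = FALSE],
                   num.threads = 1)$predictions
  } else {
    stats::predict(model,
                   xgboost::xgb.DMatrix(as.matrix(newdata[, covariates, drop = FALSE])))
  }
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

#' Exhaustive cross-validated hyperparameter tuning
#'
#' Evaluates every row of a hyperparameter grid by k-fold
#' cross-validated RMSE on the training split only (keeping the holdout
#' untouched) and returns the minimiser. Ties are settled in favour of
#' the simpler model: fewer trees first, then smaller
#' complexity (`mtry` for random forests, interaction depth for boosted
#' trees), then grid order. A degenerate response (all CPUE identical)
#' short-circuits to the simplest grid point with a warning.
#'
#' @param train training data.frame with `cpue` and covariate columns.
#' @param algorithm `"rf"` or `"brt"`.
#' @param grid data.frame of hyperparameter rows; `NULL` uses a compact
#'   default grid.
#' @param cv_folds number of cross-validation folds (default 5).
#' @param seed integer seed controlling fold assignment and fits.
#' @param covariates covariate column names.
#' @return list (class `tuned_model_spec`): algorithm, the chosen
#'   hyperparameters (`spec`), its cross-validated RMSE `cv_rmse`, and
#'   the full grid results.
#' @export
tune_hyperparameters <- function(train, algorithm = c("rf", "brt"),
                                 grid = NULL, cv_folds = 5, seed = 1L,
                                 covariates = DEFAULT_COVARIATES) {
  algorithm <- match.arg(algorithm)
  if (is.null(grid)) grid <- default_grid(algorithm, length(covariates))
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  if (nrow(train) < cv_folds) stop("fewer training rows than folds")
  complexity <- if (algorithm == "rf") grid$mtry else grid$interaction_depth
  simplicity_order <- order(grid$num_trees, complexity, seq_len(nrow(grid)))
  if (stats::sd(train$cpue) == 0) {
    warning("degenerate response (all CPUE identical); returning simplest grid point")
    pick <- simplicity_order[1]
    return(structure(list(algorithm = algorithm, spec = as.list(grid[pick, ]),
                          cv_rmse = 0, grid_rmse = rep(0, nrow(grid))),
                     class = "tuned_model_spec"))
  }
  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), nrow(train))))
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    spec <- as.list(grid[i, ])
    fold_rmse <- vapply(seq_len(cv_folds), function(f) {
      tr <- train[folds != f, , drop = FALSE]
      te <- train[folds == f, , drop = FALSE]
      m <- fit_member(algorithm, tr, spec, covariates, seed = seed)
      rmse(te$cpue, predict_member(algorithm, m, te, covariates))
    }, numeric(1))
    mean(fold_rmse)
  }, numeric(1))
  best <- simplicity_order[which.min(scores[simplicity_order])]
  structure(list(algorithm = algorithm, spec = as.list(grid[best, ]),
                 cv_rmse = scores[best], grid_rmse = scores),
            class = "tuned_model_spec")
}

#' Fit the two-member tree ensemble for one species
#'
#' Fits a random forest and a boosted-trees model on the training split,
#' scores both on the holdout, and combines them with inverse-RMSE
#' weights `w_m = (1/RMSE_m) / sum(1/RMSE_k)`, so the member with the
#' lower holdout error always receives the strictly larger weight and
#' the weights sum to one. If both holdout RMSEs are zero (degenerate)
#' the members are weighted equally.
#'
#' @param train,test data.frames from [split_train_test].
#' @param rf_spec,brt_spec hyperparameter lists (the `spec` element of
#'   [tune_hyperparameters], or `NULL` for the simplest defaults).
#' @param seed integer seed for both fits.
#' @param covariates covariate column names.
#' @param species species label stored with the model.
#' @return an `ensemble_model`: fitted members, weights, holdout RMSEs,
#'   holdout variance explained, and the holdout itself (used for
#'   permutation importance).
#' @export
fit_ensemble <- function(train, test, rf_spec = NULL, brt_spec = NULL,
                         seed = 1L, covariates = DEFAULT_COVARIATES,
                         species = "species") {
  if (is.null(rf_spec))
    rf_spec <- list(mtry = min(3L, length(covariates)), min_node_size = 5L,
                    num_trees = 500L)
  if (is.null(brt_spec))
    brt_spec <- list(learning_rate = 0.1, interaction_depth = 3L,
                     num_trees = 300L)
  rf <- fit_member("rf", train, rf_spec, covariates, seed = seed)
  brt <- fit_member("brt", train, brt_spec, covariates, seed = seed)
  pred <- list(rf = predict_member("rf", rf, test, covariates),
               brt = predict_member("brt", brt, test, covariates))
  errs <- c(rf = rmse(test$cpue, pred$rf), brt = rmse(test$cpue, pred$brt))
  w <- inverse_rmse_weights(errs)
  ens <- w["rf"] * pred$rf + w["brt"] * pred$brt
  sst <- sum((test$cpue - mean(test$cpue))^2)
  ve <- if (sst > 0) 1 - sum((test$cpue - ens)^2) / sst else NA_real_
  structure(list(species = species, rf = rf, brt = brt,
                 rf_spec = rf_spec, brt_spec = brt_spec,
                 weights = w, rmse = errs, var_explained = ve,
                 covariates = covariates, holdout = test, seed = seed),
            class = "ensemble_model")
}

#' Inverse-RMSE ensemble weights
#'
#' @param errs named numeric vector of member RMSEs.
#' @return weights summing to one; a zero-RMSE member takes all weight,
#'   all-zero RMSEs give equal weights.
#' @export
inverse_rmse_weights <- function(errs) {
  if (all(errs == 0)) return(stats::setNames(rep(1 / length(errs), length(errs)),
                                             names(errs)))
  if (any(errs == 0)) {
    w <- as.numeric(errs == 0)
    return(stats::setNames(w / sum(w), names(errs)))
  }
  inv <- 1 / errs
  inv / sum(inv)
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %s  w_RF=%.3f w_BRT=%.3f  RMSE RF=%.3g BRT=%.3g  R2=%.3f\n",
              x$species, x$weights["rf"], x$weights["brt"],
              x$rmse["rf"], x$rmse["brt"], x$var_explained))
  invisible(x)
}

#' Predict an abundance surface from an ensemble model
#'
#' Evaluates the weighted-average ensemble at every marine cell of an
#' environmental stack. Negative weighted predictions are floored at
#' zero (tree ensembles on a nonnegative response can still interpolate
#' below zero after weighting); masked cells propagate as missing.
#'
#' @param model an `ensemble_model`.
#' @param env_stack named list of [env_grid] covering all model
#'   covariates on one mesh.
#' @return an [env_grid] of predicted density (kg/km2), variable
#'   `"abundance"`, tagged with the stack's period and scenario.
#' @export
predict_surface <- function(model, env_stack) {
  missing_cov <- setdiff(model$covariates, names(env_stack))
  if (length(missing_cov) > 0)
    stop("covariates missing from stack: ", paste(missing_cov, collapse = ", "))
  ref <- env_stack[[model$covariates[1]]]
  mask <- Reduce(`&`, lapply(env_stack[model$covariates], `[[`, "mask"))
  idx <- which(mask)
  newdata <- as.data.frame(lapply(env_stack[model$covariates],
                                  function(g) g$values[idx]))
  names(newdata) <- model$covariates
  pr <- model$weights["rf"] * predict_member("rf", model$rf, newdata, model$covariates) +
    model$weights["brt"] * predict_member("brt", model$brt, newdata, model$covariates)
  vals <- matrix(NA_real_, length(ref$lat), length(ref$lon))
  vals[idx] <- pmax(pr, 0)
  meta <- env_stack[[if ("SSBT" %in% names(env_stack)) "SSBT" else 1]]
  env_grid(vals, ref$lon, ref$lat, variable = "abundance",
           period = meta$period, scenario = meta$scenario, mask = mask)
}

#' Permutation importance of the ensemble's covariates
#'
#' For each covariate, holdout rows are permuted and the increase in
#' holdout RMSE is recorded per member, averaged over permutations,
#' combined across members with the ensemble weights, truncated at
#' zero, and normalised to sum to one.
#'
#' @param model an `ensemble_model`.
#' @param holdout evaluation data.frame (default: the stored holdout).
#' @param n_perm permutations per covariate (default 5).
#' @param seed integer seed for the permutations.
#' @return data.frame of covariates and importances, sorted decreasing.
#' @export
variable_importance <- function(model, holdout = model$holdout,
                                n_perm = 5, seed = 1L) {
  covs <- model$covariates
  base <- c(rf = rmse(holdout$cpue,
                      predict_member("rf", model$rf, holdout, covs)),
            brt = rmse(holdout$cpue,
                       predict_member("brt", model$brt, holdout, covs)))
  raw <- with_seed(seed, {
    vapply(covs, function(v) {
      incr <- replicate(n_perm, {
        perm <- holdout
        perm[[v]] <- sample(perm[[v]])
        d_rf <- rmse(perm$cpue, predict_member("rf", model$rf, perm, covs)) - base["rf"]
        d_brt <- rmse(perm$cpue, predict_member("brt", model$brt, perm, covs)) - base["brt"]
        model$weights["rf"] * d_rf + model$weights["brt"] * d_brt
      })
      mean(incr)
    }, numeric(1))
  })
  imp <- pmax(raw, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  out <- data.frame(covariate = covs, importance = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}
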