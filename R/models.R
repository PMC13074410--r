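#' Regression evaluation metrics
#'
#' The four metrics used throughout: coefficient of determination
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, root-mean-square
#' error, mean absolute error, and relative error
#' `RE = mean(|y - yhat| / y)` (reported as a fraction, e.g. 0.225).
#'
#' @param y_true,y_pred Numeric vectors of equal length (>= 2).
#' @param re Compute the relative error (requires all `y_true != 0`).
#' @return Named numeric vector `c(r2, rmse, mae, re)` (`re` is `NA` when
#'   not requested).
#' @examples
#' yield_metrics(c(10, 20), c(12, 16))
#' @export
yield_metrics <- function(y_true, y_pred, re = TRUE) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("need at least two observations")
  err <- y_true - y_pred
  r2 <- 1 - sum(err^2) / sum((y_true - mean(y_true))^2)
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  re_val <- NA_real_
  if (re) {
    zero <- which(y_true == 0)
    if (length(zero) > 0) {
      stop("relative error undefined: y_true is zero at index ", zero[1])
    }
    re_val <- mean(abs(err) / abs(y_true))
  }
  c(r2 = r2, rmse = rmse, mae = mae, re = re_val)
}

#' Lasso feature selection
#'
#' Features are z-scored, an L1-penalized linear regression is fitted at a
#' fixed penalty (`lambda = alpha` in the 1/(2n) squared-loss
#' parameterization), features with non-zero coefficients are ranked by
#' absolute coefficient (ties broken alphabetically) and the list is
#' truncated to `top_k`.
#'
#' @param x Numeric matrix or data frame of features (columns named).
#' @param y Numeric response (yield, kg).
#' @param alpha L1 penalty weight, default 0.01.
#' @param top_k Maximum number of features kept, default 8.
#' @return Data frame with columns `feature` and `coefficient`, strongest
#'   first; zero rows when the penalty removes everything.
#' @export
lasso_select <- function(x, y, alpha = 0.01, top_k = 8L) {
  stopifnot(alpha > 0, top_k >= 1)
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("feature columns must be named")
  if (nrow(x) < 10) stop("need at least 10 observations for selection")
  if (stats::sd(y) == 0) stop("degenerate (constant) response")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xz <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  fit <- glmnet::glmnet(xz, y, alpha = 1, lambda = alpha,
                        standardize = FALSE, intercept = TRUE, thresh = 1e-10)
  beta <- as.numeric(coef(fit))[-1]
  names(beta) <- colnames(x)
  nz <- beta[beta != 0]
  if (length(nz) == 0) {
    return(data.frame(feature = character(0), coefficient = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ord <- order(-abs(nz), names(nz))
  nz <- nz[ord][seq_len(min(top_k, length(nz)))]
  data.frame(feature = names(nz), coefficient = unname(nz),
             stringsAsFactors = FALSE)
}

#' The regression model panel
#'
#' Seven regressors spanning linear, kernel, ensemble and neural families:
#' `smr` (stepwise multiple regression, forward selection by AIC), `rf`
#' (random forest), `xgb` (gradient-boosted trees, depth-wise), `gbdt_hist`
#' (gradient-boosted trees with histogram binning and leaf-wise growth),
#' `svr` (RBF-kernel support vector regression), `bpnn` (single hidden
#' sigmoid layer network) and `mlp` (two hidden ReLU layers).
#'
#' @return Character vector of panel model names.
#' @export
model_panel <- function() {
  c("smr", "rf", "xgb", "gbdt_hist", "svr", "bpnn", "mlp")
}

# Fit one panel member on (x_tr, y_tr) and predict both splits.
fit_predict_model <- function(model, x_tr, y_tr, x_te, seed = 1L) {
  x_tr <- as.matrix(x_tr)
  x_te <- as.matrix(x_te)
  std <- function(x, ctr, scl) sweep(sweep(x, 2, ctr), 2, scl, "/")
  switch(model,
    smr = {
      df_tr <- data.frame(x_tr, check.names = TRUE)
      nm_map <- setNames(names(df_tr), colnames(x_tr))
      df_tr$.y <- y_tr
      df_te <- data.frame(x_te, check.names = TRUE)
      full <- stats::as.formula(paste(".y ~", paste(nm_map, collapse = " + ")))
      base_fit <- stats::lm(.y ~ 1, data = df_tr)
      fit <- suppressWarnings(
        stats::step(base_fit, scope = list(lower = ~1, upper = full),
                    direction = "forward", trace = 0))
      list(train = stats::predict(fit, df_tr),
           test = stats::predict(fit, df_te))
    },
    rf = with_seed(seed, {
      fit <- randomForest::randomForest(x_tr, y_tr, ntree = 500)
      list(train = stats::predict(fit, x_tr),
           test = stats::predict(fit, x_te))
    }),
    xgb = {
      dtr <- xgboost::xgb.DMatrix(x_tr, label = y_tr)
      fit <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = 0.05,
                      max_depth = 4, subsample = 0.9,
                      colsample_bytree = 0.9, nthread = 1, seed = seed),
        data = dtr, nrounds = 300, verbose = 0)
      list(train = stats::predict(fit, xgboost::xgb.DMatrix(x_tr)),
           test = stats::predict(fit, xgboost::xgb.DMatrix(x_te)))
    },
    gbdt_hist = {
      dtr <- xgboost::xgb.DMatrix(x_tr, label = y_tr)
      fit <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = 0.05,
                      tree_method = "hist", grow_policy = "lossguide",
                      max_leaves = 15, max_depth = 0, subsample = 0.9,
                      colsample_bytree = 0.9, nthread = 1, seed = seed),
        data = dtr, nrounds = 300, verbose = 0)
      list(train = stats::predict(fit, xgboost::xgb.DMatrix(x_tr)),
           test = stats::predict(fit, xgboost::xgb.DMatrix(x_te)))
    },
    svr = {
      ctr <- colMeans(x_tr)
      scl <- apply(x_tr, 2, stats::sd)
      scl[scl == 0] <- 1
      fit <- e1071::svm(std(x_tr, ctr, scl), y_tr, kernel = "radial",
                        cost = 10, epsilon = 0.1, scale = FALSE)
      list(train = stats::predict(fit, std(x_tr, ctr, scl)),
           test = stats::predict(fit, std(x_te, ctr, scl)))
    },
    bpnn = with_seed(seed, {
      ctr <- colMeans(x_tr)
      scl <- apply(x_tr, 2, stats::sd)
      scl[scl == 0] <- 1
      yc <- mean(y_tr)
      ys <- stats::sd(y_tr)
      if (is.na(ys) || ys == 0) ys <- 1
      fit <- nnet::nnet(std(x_tr, ctr, scl), (y_tr - yc) / ys, size = 12,
                        linout = TRUE, decay = 1e-3, maxit = 500,
                        trace = FALSE)
      list(train = drop(stats::predict(fit, std(x_tr, ctr, scl))) * ys + yc,
           test = drop(stats::predict(fit, std(x_te, ctr, scl))) * ys + yc)
    }),
    mlp = {
      fit <- mlp_fit(x_tr, y_tr, seed = seed)
      list(train = mlp_predict(fit, x_tr), test = mlp_predict(fit, x_te))
    },
    stop("unknown model: ", model)
  )
}

#' Cross-validated evaluation of the model panel over feature groups
#'
#' Shuffled k-fold cross-validation (default 5 folds) with a fixed seed:
#' every tree lands in exactly one test fold. For every (group, model, fold)
#' combination the model is fitted on the training folds and evaluated on
#' both splits with [yield_metrics()]. When `optimize = TRUE`, Lasso
#' selection ([lasso_select()]) restricts each group to its top-`top_k`
#' features first — either refitted inside every training fold
#' (`standardize = "fold_wise"`, leakage-free default) or once on the full
#' table (`standardize = "global"`, mirroring a selection-then-CV
#' procedure) — and group names gain an `_opt` suffix.
#'
#' @param table Feature table with `tree_id`, the 50 schema features and
#'   `yield_kg`.
#' @param groups Character vector of group names (see [feature_groups()]).
#' @param models Character vector drawn from [model_panel()].
#' @param seed Integer seed governing fold assignment and stochastic fits.
#' @param nfolds Number of CV folds.
#' @param optimize Apply Lasso feature selection per group.
#' @param alpha,top_k Lasso parameters, see [lasso_select()].
#' @param standardize Where Lasso selection is fitted, see above.
#' @return Object of class `bloom_eval`: list with `folds` (per-fold
#'   metrics) and `summary` (fold means per model x group x split), plus
#'   the seed.
#' @export
evaluate_models <- function(table, groups = "mixed_all",
                            models = model_panel(), seed = 1L, nfolds = 5L,
                            optimize = FALSE, alpha = 0.01, top_k = 8L,
                            standardize = c("fold_wise", "global")) {
  standardize <- match.arg(standardize)
  stopifnot(is.data.frame(table))
  if (!"yield_kg" %in% names(table)) stop("table must contain `yield_kg`")
  gnames <- feature_group_names()
  bad <- setdiff(groups, names(gnames))
  if (length(bad) > 0) {
    stop("unknown feature group(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(names(gnames), collapse = ", "))
  }
  bad_m <- setdiff(models, model_panel())
  if (length(bad_m) > 0) stop("unknown model(s): ", paste(bad_m, collapse = ", "))
  n <- nrow(table)
  y <- table$yield_kg
  fold_id <- with_seed(seed, sample(rep_len(seq_len(nfolds), n)))

  rows <- list()
  for (g in groups) {
    cols <- gnames[[g]]
    x_full <- as.matrix(table[, cols, drop = FALSE])
    g_out <- if (optimize) paste0(g, "_opt") else g
    sel_global <- NULL
    if (optimize && standardize == "global") {
      sel_global <- lasso_select(x_full, y, alpha, top_k)$feature
    }
    for (f in seq_len(nfolds)) {
      tr <- fold_id != f
      use_cols <- cols
      if (optimize) {
        use_cols <- if (standardize == "global") sel_global else {
          lasso_select(x_full[tr, , drop = FALSE], y[tr], alpha,
                       top_k)$feature
        }
        if (length(use_cols) == 0) use_cols <- cols  # penalty killed all
      }
      x <- x_full[, use_cols, drop = FALSE]
      for (m in models) {
        pr <- fit_predict_model(m, x[tr, , drop = FALSE], y[tr],
                                x[!tr, , drop = FALSE],
                                seed = seed * 100L + f)
        for (split in c("train", "test")) {
          yt <- if (split == "train") y[tr] else y[!tr]
          mt <- yield_metrics(yt, pr[[split]])
          rows[[length(rows) + 1L]] <- data.frame(
            model = m, group = g_out, split = split, fold = f,
            r2 = mt["r2"], rmse = mt["rmse"], mae = mt["mae"], re = mt["re"],
            row.names = NULL, stringsAsFactors = FALSE)
        }
      }
    }
  }
  folds <- do.call(rbind, rows)
  summary <- stats::aggregate(folds[, c("r2", "rmse", "mae", "re")],
                              folds[, c("model", "group", "split")], mean)
  structure(list(folds = folds, summary = summary, seed = seed,
                 nfolds = nfolds), class = "bloom_eval")
}

#' @export
print.bloom_eval <- function(x, ...) {
  cat(sprintf("<bloom_eval> %d-fold CV (seed %d)\n", x$nfolds, x$seed))
  print(x$summary[x$summary$split == "test", ], row.names = FALSE)
  invisible(x)
}

#' Feature-group ablation study
#'
#' Evaluates the chosen model(s) over all five feature groups, raw and
#' Lasso-optimized (`_opt` suffix), under the same fold assignment, and
#' returns one comparison table mirroring a group-by-group benchmark.
#'
#' @inheritParams evaluate_models
#' @param models Models to evaluate (default `"xgb"`, the panel's
#'   gradient-boosted reference).
#' @return Data frame: `model`, `group`, `split`, mean `r2`, `rmse`,
#'   `mae`, `re`.
#' @export
ablation <- function(table, seed = 1L, models = "xgb", nfolds = 5L,
                     alpha = 0.01, top_k = 8L,
                     standardize = c("fold_wise", "global")) {
  standardize <- match.arg(standardize)
  groups <- c("original", "strategy1", "strategy2", "mixed_strategy",
              "mixed_all")
  raw <- evaluate_models(table, groups, models, seed, nfolds,
                         optimize = FALSE)
  opt <- evaluate_models(table, groups, models, seed, nfolds,
                         optimize = TRUE, alpha = alpha, top_k = top_k,
                         standardize = standardize)
  out <- rbind(raw$summary, opt$summary)
  out[order(out$model, out$group, out$split), ]
}
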