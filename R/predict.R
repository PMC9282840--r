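# Multi-PRS longevity classifier: assemble per-trait score matrices and
# select a model by repeated stratified k-fold cross-validation over a
# hyper-parameter grid, then evaluate the winner on a held-out split.
# Deliberately thin glue: each candidate family wraps a standard library
# behind a uniform fit/predict interface.

#' Assemble a column-standardized PRS matrix across traits
#'
#' Joins per-trait score vectors on their shared individuals (inner join,
#' logged when individuals are dropped), drops constant-score traits with a
#' warning, and standardizes every column to mean 0, SD 1.
#'
#' @param per_trait_scores Named list; each element is a named numeric
#'   vector of per-individual scores for one trait.
#' @return Numeric matrix (individuals x traits) with row and column names.
#' @export
assemble_prs_matrix <- function(per_trait_scores) {
  if (!is.list(per_trait_scores) || is.null(names(per_trait_scores)))
    stop("per_trait_scores must be a named list of score vectors")
  ids <- Reduce(intersect, lapply(per_trait_scores, names))
  n_all <- length(unique(unlist(lapply(per_trait_scores, names))))
  if (length(ids) < n_all)
    message(n_all - length(ids),
            " individual(s) dropped by the inner join across traits")
  if (length(ids) < 2) stop("fewer than 2 individuals after joining traits")
  x <- vapply(per_trait_scores, function(s) unname(s[ids]),
              numeric(length(ids)))
  rownames(x) <- ids
  keep <- apply(x, 2, function(col) stats::sd(col, na.rm = TRUE) > 0)
  if (!all(keep))
    warning("dropping constant-score trait(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  x <- x[, keep, drop = FALSE]
  scale(x)[, , drop = FALSE]
}

# ---- candidate model families --------------------------------------------
# Each family: a hyper-parameter grid plus fit/predict closures returning a
# numeric score usable for both accuracy (threshold 0.5 or sign) and AUC.

default_model_grid <- function() {
  list(
    logistic = list(
      grid = expand.grid(penalty = c("l1", "l2"),
                         lambda = c(1e-4, 1e-3, 1e-2, 1e-1),
                         stringsAsFactors = FALSE),
      fit = function(x, y, par) {
        glmnet::glmnet(x, y, family = "binomial",
                       alpha = if (par$penalty == "l1") 1 else 0,
                       lambda = par$lambda)
      },
      predict = function(model, x)
        as.numeric(stats::predict(model, x, type = "response"))),
    svm_linear = list(
      grid = data.frame(cost = c(0.1, 1)),
      fit = function(x, y, par)
        e1071::svm(x, factor(y), kernel = "linear", cost = par$cost,
                   scale = FALSE),
      predict = function(model, x) {
        dv <- attr(stats::predict(model, x, decision.values = TRUE),
                   "decision.values")
        # orient the decision value toward class "1"
        if (colnames(dv)[1] == "0/1") -dv[, 1] else dv[, 1]
      }),
    knn = list(
      grid = data.frame(k = c(5, 15, 25)),
      fit = function(x, y, par) list(x = x, y = factor(y), k = par$k),
      predict = function(model, x) {
        pred <- class::knn(model$x, x, model$y, k = model$k, prob = TRUE)
        pr <- attr(pred, "prob")
        ifelse(pred == "1", pr, 1 - pr)
      }),
    naive_bayes = list(
      grid = data.frame(laplace = 0),
      fit = function(x, y, par)
        e1071::naiveBayes(as.data.frame(x), factor(y), laplace = par$laplace),
      predict = function(model, x)
        stats::predict(model, as.data.frame(x), type = "raw")[, "1"]),
    decision_tree = list(
      grid = data.frame(cp = c(0.01, 0.001)),
      fit = function(x, y, par) {
        d <- data.frame(y = factor(y), x)
        rpart::rpart(y ~ ., d, method = "class",
                     control = rpart::rpart.control(cp = par$cp))
      },
      predict = function(model, x)
        stats::predict(model, data.frame(x), type = "prob")[, "1"]),
    random_forest = list(
      grid = data.frame(mtry = c(2, 4)),
      fit = function(x, y, par)
        randomForest::randomForest(x, factor(y),
                                   mtry = min(par$mtry, ncol(x)),
                                   ntree = 200),
      predict = function(model, x)
        stats::predict(model, x, type = "prob")[, "1"]))
}

# stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

auc_score <- function(y, score) {
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Model selection by repeated stratified cross-validation
#'
#' Runs every candidate family / hyper-parameter combination through
#' `iterations` rounds of stratified `k`-fold cross-validation with
#' re-randomized splits, selects the combination with the best mean
#' validation accuracy (AUC is reported alongside), refits it on a
#' stratified 80% training split, and evaluates AUC and a calibration
#' pseudo-R2 on the held-out 20%.
#'
#' @param x Standardized PRS matrix from [assemble_prs_matrix()].
#' @param y Binary 0/1 outcome aligned to `rownames(x)`.
#' @param families Candidate model list (default [default_model_grid()]
#'   covering penalized logistic regression, linear SVM, k-nearest
#'   neighbors, naive Bayes, decision tree and random forest); restrict via
#'   `families = default_model_grid()[c("logistic")]` for speed.
#' @param k Folds per iteration (default 10).
#' @param iterations CV repetitions with fresh fold assignments (default
#'   100).
#' @param seed Integer; all randomness (folds and the final split) flows
#'   from it.
#' @param train_frac Fraction for the final training split (default 0.8).
#' @return An object of class `prediction_report`: `cv_table` (per
#'   family/params mean and SD of accuracy and AUC), `best_family`,
#'   `best_params`, `final_auc`, `pseudo_r2`, `coefficients` (per-PRS
#'   coefficients when the winner is the logistic family, otherwise `NA`).
#' @export
model_selection_cv <- function(x, y, families = default_model_grid(),
                               k = 10, iterations = 100, seed = 1,
                               train_frac = 0.8) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("outcome is constant")
  if (k < 2) stop("k must be at least 2")
  if (k > min(table(y))) stop("k exceeds the size of the smallest class")
  set.seed(seed)

  combos <- list()
  for (fam in names(families)) {
    grid <- families[[fam]]$grid
    for (g in seq_len(nrow(grid)))
      combos[[length(combos) + 1]] <- list(family = fam,
                                           params = grid[g, , drop = FALSE])
  }
  acc <- matrix(NA_real_, length(combos), iterations * k)
  auc <- matrix(NA_real_, length(combos), iterations * k)
  col <- 0L
  for (it in seq_len(iterations)) {
    fold <- stratified_folds(y, k)
    for (f in seq_len(k)) {
      col <- col + 1L
      tr <- fold != f
      for (ci in seq_along(combos)) {
        fam <- families[[combos[[ci]]$family]]
        model <- fam$fit(x[tr, , drop = FALSE], y[tr], combos[[ci]]$params)
        sc <- fam$predict(model, x[!tr, , drop = FALSE])
        yhat <- as.integer(sc > if (combos[[ci]]$family == "svm_linear") 0
                           else 0.5)
        acc[ci, col] <- mean(yhat == y[!tr])
        auc[ci, col] <- auc_score(y[!tr], sc)
      }
    }
  }
  cv_table <- do.call(rbind, lapply(seq_along(combos), function(ci)
    data.frame(family = combos[[ci]]$family,
               params = paste(names(combos[[ci]]$params),
                              unlist(combos[[ci]]$params),
                              sep = "=", collapse = ","),
               mean_accuracy = mean(acc[ci, ]), sd_accuracy = stats::sd(acc[ci, ]),
               mean_auc = mean(auc[ci, ]), sd_auc = stats::sd(auc[ci, ]),
               stringsAsFactors = FALSE)))
  best_ci <- which.max(cv_table$mean_accuracy)
  best <- combos[[best_ci]]

  # final stratified 80/20 split, refit, held-out evaluation
  test <- rep(TRUE, length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    test[idx[seq_len(round(train_frac * length(idx)))]] <- FALSE
  }
  fam <- families[[best$family]]
  final_model <- fam$fit(x[!test, , drop = FALSE], y[!test], best$params)
  sc_test <- fam$predict(final_model, x[test, , drop = FALSE])
  final_auc <- auc_score(y[test], sc_test)

  # calibration pseudo-R2: logistic fit of held-out status on the score
  pseudo_r2 <- if (stats::sd(sc_test) > 0) {
    cal <- fit_logistic(y[test], as.numeric(scale(sc_test)))
    nagelkerke_r2(cal$ll_null, cal$ll_full, cal$n)
  } else NA_real_

  coefs <- rep(NA_real_, ncol(x))
  names(coefs) <- colnames(x)
  if (best$family == "logistic")
    coefs[] <- as.numeric(stats::coef(final_model))[-1]
  structure(list(cv_table = cv_table, best_family = best$family,
                 best_params = best$params, final_auc = final_auc,
                 pseudo_r2 = pseudo_r2, coefficients = coefs,
                 n_test = sum(test)),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("Multi-PRS longevity classifier\n")
  cat("best model:", x$best_family, "(",
      paste(names(x$best_params), unlist(x$best_params), sep = "=",
            collapse = ", "), ")\n")
  cat(sprintf("held-out AUC = %.3f, pseudo-R2 = %.3f (n_test = %d)\n",
              x$final_auc, x$pseudo_r2, x$n_test))
  cat("cross-validation summary:\n")
  print(x$cv_table, row.names = FALSE)
  invisible(x)
}
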