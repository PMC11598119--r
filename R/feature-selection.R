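#' Configure the wrapper feature-selection protocol
#'
#' Defaults follow the published protocol: fitness weights alpha = 0.99 and
#' beta = 0.01, KNN with 5 neighbors, 10-fold stratified cross-validation,
#' an 80/20 stratified train/test split (use `test_fraction = 0.1` for the
#' 90/10 variant), binarization threshold 0.5, and an optimizer over
#' `[0, 1]^n_features` with population 20 and 100 iterations.
#'
#' @param alpha,beta Fitness weights on the error term `1 - Acc` and the
#'   selected-feature ratio `n/N`; a warning is issued when they do not sum
#'   to 1.
#' @param n_neighbors KNN neighbor count.
#' @param n_folds Number of cross-validation folds.
#' @param test_fraction Held-out fraction of samples (stratified by class).
#' @param threshold Binarization threshold on solution components.
#' @param split_seed Seed of the train/test split.
#' @param inject_baseline Inject the all-ones (all features) solution as one
#'   member of the initial population, guaranteeing the returned fitness is
#'   never worse than the all-features baseline.
#' @param optimizer An [slo_config()]; its `pop_size`/`max_iter` default to
#'   the published 20/100.
#' @return An object of class `fs_config`.
#' @export
fs_config <- function(alpha = 0.99, beta = 0.01, n_neighbors = 5L,
                      n_folds = 10L, test_fraction = 0.2, threshold = 0.5,
                      split_seed = 1L, inject_baseline = TRUE,
                      optimizer = slo_config(pop_size = 20L, max_iter = 100L,
                                             seed = 1L)) {
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie strictly in (0, 1)")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must lie strictly in (0, 1)")
  if (abs(alpha + beta - 1) > 1e-8)
    warning("alpha + beta != 1; fitness no longer lies in [0, 1]")
  structure(
    list(alpha = alpha, beta = beta, n_neighbors = as.integer(n_neighbors),
         n_folds = as.integer(n_folds), test_fraction = test_fraction,
         threshold = threshold, split_seed = as.integer(split_seed),
         inject_baseline = isTRUE(inject_baseline), optimizer = optimizer),
    class = "fs_config"
  )
}

#' Binarize a continuous solution into a feature mask
#'
#' Component `i` selects feature `i` iff `solution[i] >= threshold`; the
#' boundary value selects.
#'
#' @param solution Numeric vector with components in `[0, 1]`.
#' @param threshold Threshold in (0, 1), default 0.5.
#' @return Logical mask of the same length.
#' @examples
#' binarize(c(0.1, 0.9, 0.5))  # FALSE TRUE TRUE
#' @export
binarize <- function(solution, threshold = 0.5) {
  if (any(!is.finite(solution)) || any(solution < 0) || any(solution > 1))
    stop("solution components must lie in [0, 1]")
  solution >= threshold
}

#' Feature-selection fitness
#'
#' `alpha * (1 - cv_accuracy) + beta * n_selected / n_total`: a weighted sum
#' of the classification error and the selected-feature ratio; lower is
#' better, and with `alpha + beta = 1` the value lies in `[0, 1]`.
#'
#' @param cv_accuracy Cross-validated accuracy in `[0, 1]`.
#' @param n_selected Number of selected features.
#' @param n_total Total number of features (>= 1).
#' @param alpha,beta Weights (defaults 0.99 / 0.01).
#' @return Scalar fitness.
#' @examples
#' fs_fitness(0.9, 100, 2000)  # 0.0995
#' @export
fs_fitness <- function(cv_accuracy, n_selected, n_total,
                       alpha = 0.99, beta = 0.01) {
  if (cv_accuracy < 0 || cv_accuracy > 1)
    stop("`cv_accuracy` must lie in [0, 1]")
  if (n_total < 1L || n_selected < 0L || n_selected > n_total)
    stop("need 0 <= n_selected <= n_total and n_total >= 1")
  alpha * (1 - cv_accuracy) + beta * n_selected / n_total
}

#' Build stratified cross-validation folds
#'
#' Per class, sample indices are shuffled (current RNG) and dealt
#' round-robin to folds `1..n_folds`, so per-class fold sizes differ by at
#' most one and no fold can lose an entire class from its training side
#' (for classes with >= 2 members). Classes smaller than `n_folds` simply
#' appear in only some folds.
#'
#' @param y Integer class labels.
#' @param n_folds Number of folds.
#' @return Integer fold assignment, one entry per sample.
#' @export
make_stratified_folds <- function(y, n_folds) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("`n_folds` must be >= 2")
  fold <- integer(length(y))
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- (seq_along(idx) - 1L) %% n_folds + 1L
  }
  fold
}

# CV accuracy for one mask from a precomputed full distance matrix restricted
# to the masked features is not possible (distances depend on the mask), so
# the n x n distance matrix is recomputed per call on the masked columns;
# fold loops then reuse it.
.cv_accuracy_masked <- function(X, y, mask, folds, n_folds, k) {
  Xm <- X[, mask, drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  acc <- numeric(0)
  for (f in seq_len(n_folds)) {
    te <- which(folds == f)
    if (!length(te)) next
    tr <- which(folds != f)
    ok <- 0L
    for (i in te) {
      pred <- .knn_vote(D[i, tr], y[tr], k, tr)
      ok <- ok + (pred == y[i])
    }
    acc <- c(acc, ok / length(te))
  }
  mean(acc)
}

#' Stratified K-fold KNN accuracy of a feature mask
#'
#' Builds stratified folds (from the current RNG unless `folds` is given),
#' then for each fold trains the deterministic KNN on the remaining folds
#' restricted to the masked features and scores the held-out fold; returns
#' the mean of the per-fold accuracies.
#'
#' @param data A [labeled_dataset()].
#' @param mask Logical feature mask selecting at least one feature.
#' @param cfg An [fs_config()].
#' @param folds Optional precomputed fold assignment from
#'   [make_stratified_folds()]; pass this to keep the objective
#'   deterministic across evaluations.
#' @return Mean fold accuracy in `[0, 1]`.
#' @export
stratified_kfold_accuracy <- function(data, mask, cfg = fs_config(),
                                      folds = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!any(mask)) stop("the mask must select at least one feature")
  if (is.null(folds)) folds <- make_stratified_folds(data$y, cfg$n_folds)
  .cv_accuracy_masked(data$X, data$y, mask, folds, cfg$n_folds,
                      cfg$n_neighbors)
}

#' Turn a labeled dataset into a continuous optimization problem
#'
#' Returns an [slo_problem()] over `[0, 1]^n_features` whose objective
#' binarizes the solution, guards the empty mask with the worst value
#' `alpha + beta`, computes the stratified K-fold KNN accuracy on the given
#' data under a fixed fold assignment, and returns [fs_fitness()]. With
#' fixed folds the objective is deterministic, as required by the greedy
#' optimizer.
#'
#' @param data A [labeled_dataset()] (in the full protocol: the training
#'   partition only).
#' @param cfg An [fs_config()].
#' @param folds Optional fold assignment; built from the current RNG when
#'   `NULL`.
#' @return An `slo_problem` of dimension `ncol(data$X)`.
#' @export
make_fs_problem <- function(data, cfg = fs_config(), folds = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (is.null(folds)) folds <- make_stratified_folds(data$y, cfg$n_folds)
  n_total <- ncol(data$X)
  force(cfg)
  obj <- function(v) {
    mask <- v >= cfg$threshold
    if (!any(mask)) return(cfg$alpha + cfg$beta)
    acc <- .cv_accuracy_masked(data$X, data$y, mask, folds, cfg$n_folds,
                               cfg$n_neighbors)
    fs_fitness(acc, sum(mask), n_total, cfg$alpha, cfg$beta)
  }
  slo_problem(obj, dim = n_total, lower = 0, upper = 1)
}

# stratified split: per class, shuffled, round(n_c * fraction) rows to test
# (capped so every class keeps at least one training row)
.stratified_split <- function(y, test_fraction) {
  test <- integer(0)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    n_te <- min(round(length(idx) * test_fraction), length(idx) - 1L)
    if (n_te > 0L) test <- c(test, idx[seq_len(n_te)])
  }
  sort(test)
}

#' Run the full wrapper feature-selection protocol
#'
#' Splits the samples into stratified train/test partitions (seeded by
#' `split_seed`), fixes the cross-validation folds on the training
#' partition, optimizes the continuous selection problem with snow leopard
#' optimization, binarizes the best solution, and finally scores a KNN
#' trained on the full training partition (masked features) against the
#' held-out test partition. Test rows play no part in fold construction,
#' the objective, or the optimizer; they are touched only in the final
#' scoring step.
#'
#' @param data A [labeled_dataset()]; every class needs >= 2 members.
#' @param cfg An [fs_config()].
#' @return An object of class `fs_result`: `best_solution`,
#'   `selected_mask`, `n_selected`, `cv_accuracy` (training-side CV accuracy
#'   of the selected mask), `fitness`, `holdout_accuracy`, `history`
#'   (per-iteration best fitness), the partition indices and a config echo.
#' @export
run_feature_selection <- function(data, cfg = fs_config()) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(cfg, "fs_config"))
  if (any(table(data$y) < 2L)) stop("every class needs at least 2 members")
  n_total <- ncol(data$X)

  test_idx <- .with_seed(cfg$split_seed,
                         function() .stratified_split(data$y, cfg$test_fraction))
  train_idx <- setdiff(seq_len(nrow(data$X)), test_idx)
  tr <- labeled_dataset(data$X[train_idx, , drop = FALSE],
                        data$labels[data$y[train_idx]],
                        feature_names = data$feature_names)

  # folds fixed once per run; offset keeps the fold shuffle off the
  # optimizer's draw stream
  folds <- .with_seed(cfg$optimizer$seed + 10007L,
                      function() make_stratified_folds(tr$y, cfg$n_folds))
  problem <- make_fs_problem(tr, cfg, folds = folds)

  opt_cfg <- cfg$optimizer
  opt_cfg$max_iter <- as.integer(opt_cfg$max_iter)
  init <- if (cfg$inject_baseline) matrix(1, nrow = 1L, ncol = n_total)
  res <- slo_optimize(problem, opt_cfg, init_territories = init)

  mask <- binarize(res$best_territory, cfg$threshold)
  if (!any(mask)) mask[which.max(res$best_territory)] <- TRUE  # degenerate run
  n_sel <- sum(mask)
  cv_acc <- .cv_accuracy_masked(tr$X, tr$y, mask, folds, cfg$n_folds,
                                cfg$n_neighbors)
  fit <- fs_fitness(cv_acc, n_sel, n_total, cfg$alpha, cfg$beta)

  pred <- knn_predict(tr$X[, mask, drop = FALSE], tr$y,
                      data$X[test_idx, mask, drop = FALSE],
                      k = cfg$n_neighbors)
  holdout <- mean(pred == data$y[test_idx])

  structure(
    list(best_solution = res$best_territory, selected_mask = mask,
         n_selected = n_sel, cv_accuracy = cv_acc, fitness = fit,
         holdout_accuracy = holdout, history = res$history,
         train_idx = train_idx, test_idx = test_idx,
         feature_names = data$feature_names, config = cfg,
         evals = res$evals),
    class = "fs_result"
  )
}

#' @export
print.fs_result <- function(x, ...) {
  cat(sprintf(
    paste0("<fs_result> %d/%d features selected; CV accuracy %.4f; ",
           "fitness %.4f; hold-out accuracy %.4f\n"),
    x$n_selected, length(x$selected_mask), x$cv_accuracy, x$fitness,
    x$holdout_accuracy))
  invisible(x)
}

#' Serialize a feature-selection result
#'
#' Writes the result as JSON (solution, mask, accuracies, fitness, config
#' echo), the selected feature names one per line, and the convergence
#' history as a two-column CSV (`iteration`, `best_fitness`).
#'
#' @param res An [run_feature_selection()] result.
#' @param json_path,features_path,history_path Output paths; `NULL` skips.
#' @return `json_path`, invisibly.
#' @export
write_fs_result <- function(res, json_path, features_path = NULL,
                            history_path = NULL) {
  stopifnot(inherits(res, "fs_result"))
  cfg <- res$config
  payload <- list(
    n_selected = res$n_selected, cv_accuracy = res$cv_accuracy,
    fitness = res$fitness, holdout_accuracy = res$holdout_accuracy,
    selected = which(res$selected_mask),
    best_solution = res$best_solution,
    config = list(alpha = cfg$alpha, beta = cfg$beta,
                  n_neighbors = cfg$n_neighbors, n_folds = cfg$n_folds,
                  test_fraction = cfg$test_fraction,
                  threshold = cfg$threshold, split_seed = cfg$split_seed,
                  optimizer = unclass(cfg$optimizer)))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(features_path))
    writeLines(res$feature_names[res$selected_mask], features_path)
  if (!is.null(history_path)) {
    utils::write.csv(
      data.frame(iteration = seq_along(res$history) - 1L,
                 best_fitness = res$history),
      history_path, row.names = FALSE)
  }
  invisible(json_path)
}
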