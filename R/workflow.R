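#' Random train/test division
#'
#' Randomly assigns `round(N * test_fraction)` samples to the test side and
#' the rest to the training side; the two sides are disjoint and exhaustive.
#'
#' @param beta A [beta_matrix()].
#' @param ages Ages aligned to `beta`.
#' @param test_fraction Fraction of samples held out; default 0.25.
#' @param seed Integer seed.
#' @return List with `train` and `test`, each a list holding `beta`, `ages`,
#'   and `sample_ids`.
#' @export
split_train_test <- function(beta, ages, test_fraction = 0.25, seed = 1L) {
  ages <- align_ages(beta, ages)
  n <- ncol(beta)
  if (n < 4) stop("need at least 4 samples to split")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
  n_test <- round(n * test_fraction)
  if (n_test < 1 || n_test >= n)
    stop("degenerate split: ", n_test, " test samples out of ", n)
  withr::local_seed(seed)
  test_idx <- sort(sample.int(n, n_test))
  take <- function(idx) {
    ids <- colnames(beta)[idx]
    list(beta = beta_matrix(unclass(beta)[, idx, drop = FALSE],
                            feature_level = feature_level(beta)),
         ages = age_vector(as.numeric(ages)[idx], ids, units = age_units(ages)),
         sample_ids = ids)
  }
  list(train = take(setdiff(seq_len(n), test_idx)), test = take(test_idx))
}

#' Evaluate predictions against true ages
#'
#' @param truth True ages (named by sample, or aligned by position).
#' @param predicted Predicted ages, same samples.
#' @param dataset_tag `"train"` or `"test"` (metadata only).
#' @return An object of class `eval_report`: list with `samples` (data.frame:
#'   sample_id, true_age, predicted_age, residual = predicted - true), `r2`
#'   (squared Pearson correlation; 0 with a warning when undefined), and
#'   `mse` (mean squared residual).
#' @export
evaluate <- function(truth, predicted, dataset_tag = c("train", "test")) {
  dataset_tag <- match.arg(dataset_tag)
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (length(truth) < 2) stop("need at least 2 samples to evaluate")
  if (!is.null(names(truth)) && !is.null(names(predicted)))
    predicted <- predicted[names(truth)]
  truth <- as.numeric(truth)
  res <- as.numeric(predicted) - truth
  structure(list(
    samples = data.frame(
      sample_id = names(predicted) %||% paste0("s", seq_along(truth)),
      true_age = truth, predicted_age = as.numeric(predicted),
      residual = res, stringsAsFactors = FALSE),
    r2 = r_squared(truth, as.numeric(predicted)),
    mse = mean(res^2),
    dataset_tag = dataset_tag
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (%s): n = %d, R^2 = %.3f, MSE = %.3g\n",
              x$dataset_tag, nrow(x$samples), x$r2, x$mse))
  invisible(x)
}

#' Train a bagged ensemble clock (balanced or plain bootstrapped)
#'
#' The core training routine. With `balancing = TRUE` (the balanced clock),
#' each of the `n_learners` training subsets is drawn by [resample_bin()] —
#' per-age-bin bootstrapped under-sampling plus SMOTE over-sampling — so each
#' base learner sees a flattened age distribution while, across the bag, all
#' original samples are used. With `balancing = FALSE` the subsets come from
#' [simple_boot()] (a plain bagging clock with no distribution adjustment).
#' Each subset trains an elastic-net selector; the selectors' coefficients
#' are integrated by [score_features()] and [select_top_features()]; the
#' integrated feature set is given back to every subset for an ordinary
#' linear re-fit; and the linear learners are gated and weighted by their
#' R-squared on the full original training set ([compute_weights()]).
#'
#' Per-learner seeds are derived as `seed + learner_index`.
#'
#' @param beta Training [beta_matrix()].
#' @param ages Training ages.
#' @param n_learners Number of base learners; default 10.
#' @param balancing Rebalance the age distribution per subset? Default
#'   `TRUE`.
#' @param n_top Number of top-scoring features to integrate; default 50.
#' @param alphas Elastic-net mixing grid; default 0.5.
#' @param n_folds CV folds per base learner; default 10.
#' @param initial_bin_width Starting bin width for [adapt_bin_width()];
#'   default 1 age unit.
#' @param seed Integer seed.
#' @return List with `model` (an `ensemble_clock`), `report` (the training
#'   [evaluate()] report), and `subsets` (the `resampled_set` list, for
#'   provenance/inspection).
#' @export
single_balance <- function(beta, ages, n_learners = 10L, balancing = TRUE,
                           n_top = 50L, alphas = 0.5, n_folds = 10L,
                           initial_bin_width = 1, seed = 1L) {
  ages <- align_ages(beta, ages)
  plan <- if (balancing) adapt_bin_width(ages, initial_width = initial_bin_width)
          else NULL
  subsets <- lapply(seq_len(n_learners), function(k) {
    if (balancing) resample_bin(beta, ages, plan, seed = seed + k)
    else simple_boot(beta, ages, seed = seed + k)
  })
  selectors <- lapply(seq_len(n_learners), function(k)
    fit_elastic_net_learner(subsets[[k]]$beta, subsets[[k]]$ages,
                            alphas = alphas, n_folds = n_folds,
                            seed = seed + k))
  scores <- score_features(selectors)
  selected <- select_top_features(scores, n_top = n_top)
  if (!length(selected))
    stop("no features selected by any base learner; the penalized fits are empty")
  linears <- lapply(subsets, fit_linear_learner, features = selected,
                    train_beta = beta, train_ages = ages)
  gw <- compute_weights(linears)
  model <- ensemble_clock(
    gw$learners, gw$weights, selected,
    model_kind = if (balancing) "balanced" else "bootstrapped",
    config = list(seed = seed, n_learners = n_learners, n_top = n_top,
                  alphas = alphas, n_folds = n_folds,
                  bin_width = if (balancing) plan$width else NULL,
                  bin_edges = if (balancing) plan$edges else NULL,
                  units = age_units(ages)))
  report <- evaluate(ages, predict(model, beta), dataset_tag = "train")
  list(model = model, report = report, subsets = subsets,
       feature_scores = scores)
}

#' Train a traditional single penalized-regression clock
#'
#' One cross-validated elastic-net fit on the unmodified training set; the
#' classical clock-model construction, with no resampling and no ensemble.
#'
#' @inheritParams single_balance
#' @return List with `model` (an `enet_learner`) and `report` (training
#'   [evaluate()] report).
#' @export
single_selection <- function(beta, ages, alphas = 0.5, n_folds = 10L,
                             seed = 1L) {
  ages <- align_ages(beta, ages)
  model <- fit_elastic_net_learner(beta, ages, alphas = alphas,
                                   n_folds = n_folds, seed = seed)
  model$config$units <- age_units(ages)
  list(model = model, report = evaluate(ages, predict(model, beta),
                                        dataset_tag = "train"))
}

#' Multi-round training/testing comparison of the clock modes
#'
#' Repeats, `rounds` times: a fresh seeded train/test division, training of
#' the requested model modes on the training side only, and evaluation on
#' both sides. Round r uses seed `seed + (r - 1) * 1000`, so `rounds = 1`
#' reproduces a manual [split_train_test()] + training call with `seed`.
#' Residuals are then pooled over rounds and averaged within equal-width age
#' bins (the width adapted from the full age vector) to give per-mode
#' averaged residual curves.
#'
#' @param beta Full [beta_matrix()].
#' @param ages Full ages.
#' @param rounds Number of rounds; default 10.
#' @param modes Subset of `c("balanced", "bootstrapped", "normal")`.
#' @param test_fraction Held-out fraction per round; default 0.25.
#' @param n_learners,n_top,alphas,n_folds,initial_bin_width Passed through to
#'   the trainers.
#' @param seed Integer seed.
#' @return An object of class `cross_training`: list with `rounds` (per
#'   round: `split_ids`, and per mode the fitted model plus train/test
#'   [evaluate()] reports) and `residual_curves` (data.frame: mode,
#'   dataset_tag, bin_mid, mean_residual, n).
#' @export
cross_training <- function(beta, ages, rounds = 10L,
                           modes = c("balanced", "bootstrapped", "normal"),
                           test_fraction = 0.25, n_learners = 10L,
                           n_top = 50L, alphas = 0.5, n_folds = 10L,
                           initial_bin_width = 1, seed = 1L) {
  modes <- match.arg(modes, several.ok = TRUE)
  if (rounds < 1) stop("rounds must be >= 1")
  ages <- align_ages(beta, ages)
  round_results <- lapply(seq_len(rounds), function(r) {
    rseed <- seed + (r - 1L) * 1000L
    sp <- split_train_test(beta, ages, test_fraction = test_fraction,
                           seed = rseed)
    fits <- lapply(stats::setNames(modes, modes), function(mode) {
      fit <- switch(mode,
        balanced = single_balance(sp$train$beta, sp$train$ages,
                                  n_learners = n_learners, balancing = TRUE,
                                  n_top = n_top, alphas = alphas,
                                  n_folds = n_folds,
                                  initial_bin_width = initial_bin_width,
                                  seed = rseed),
        bootstrapped = single_balance(sp$train$beta, sp$train$ages,
                                      n_learners = n_learners,
                                      balancing = FALSE, n_top = n_top,
                                      alphas = alphas, n_folds = n_folds,
                                      seed = rseed),
        normal = single_selection(sp$train$beta, sp$train$ages,
                                  alphas = alphas, n_folds = n_folds,
                                  seed = rseed))
      list(model = fit$model,
           train_report = fit$report,
           test_report = evaluate(sp$test$ages,
                                  predict(fit$model, sp$test$beta),
                                  dataset_tag = "test"),
           subsets = fit$subsets)
    })
    list(round = r, split_ids = list(train = sp$train$sample_ids,
                                     test = sp$test$sample_ids),
         fits = fits)
  })
  structure(list(
    rounds = round_results,
    residual_curves = aggregate_residuals(round_results, ages,
                                          initial_bin_width),
    config = list(rounds = rounds, modes = modes,
                  test_fraction = test_fraction, seed = seed)
  ), class = "cross_training")
}

# Pool residuals per (mode, tag) over rounds and average within equal-width
# age bins; the bin width is adapted from the full age vector.
aggregate_residuals <- function(round_results, ages, initial_bin_width = 1) {
  plan <- adapt_bin_width(ages, initial_width = initial_bin_width)
  width <- plan$width
  lo <- min(as.numeric(ages))
  rows <- list()
  for (rr in round_results) {
    for (mode in names(rr$fits)) {
      for (tag in c("train_report", "test_report")) {
        s <- rr$fits[[mode]][[tag]]$samples
        rows[[length(rows) + 1L]] <- data.frame(
          mode = mode, dataset_tag = sub("_report", "", tag),
          true_age = s$true_age, residual = s$residual,
          stringsAsFactors = FALSE)
      }
    }
  }
  pooled <- do.call(rbind, rows)
  eps <- 1e-9 * max(1, abs(width * plan$n_bins))
  pooled$bin <- floor((pooled$true_age - lo + eps) / width) + 1L
  agg <- stats::aggregate(residual ~ mode + dataset_tag + bin, data = pooled,
                          FUN = mean)
  cnt <- stats::aggregate(residual ~ mode + dataset_tag + bin, data = pooled,
                          FUN = length)
  agg$n <- cnt$residual
  agg$bin_mid <- lo + (agg$bin - 0.5) * width
  names(agg)[names(agg) == "residual"] <- "mean_residual"
  agg[order(agg$mode, agg$dataset_tag, agg$bin),
      c("mode", "dataset_tag", "bin", "bin_mid", "mean_residual", "n")]
}

#' @export
print.cross_training <- function(x, ...) {
  cat(sprintf("cross_training: %d rounds, modes %s\n",
              length(x$rounds), paste(x$config$modes, collapse = "/")))
  for (mode in x$config$modes) {
    r2 <- vapply(x$rounds, function(rr) rr$fits[[mode]]$test_report$r2,
                 numeric(1))
    mse <- vapply(x$rounds, function(rr) rr$fits[[mode]]$test_report$mse,
                  numeric(1))
    cat(sprintf("  %-12s test R^2 %.3f +/- %.3f, test MSE %.3g\n",
                mode, mean(r2), stats::sd(r2), mean(mse)))
  }
  invisible(x)
}
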