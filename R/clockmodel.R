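#' Fit one cross-validated elastic-net base learner
#'
#' Fits the penalized regression
#' `min over (b0, b) of (1/N) sum_i (y_i - b0 - b'x_i)^2 / 2 +
#' lambda * ((1 - alpha)/2 * ||b||_2^2 + alpha * ||b||_1)`
#' over a grid of mixing parameters `alphas`, cross-validating the
#' regularization constant lambda with `n_folds` folds (shared seeded fold
#' assignment across the alpha grid). The returned (alpha, lambda) pair is
#' the one-standard-error choice generalized over the grid: among all
#' combinations whose mean CV error is within one standard error of the
#' global minimum, the largest lambda wins (ties break to the smaller
#' alpha).
#'
#' @param beta A [beta_matrix()] of training features x samples.
#' @param ages Training ages aligned to `beta`.
#' @param alphas Numeric vector of mixing parameters in \[0,1\]; default 0.5
#'   (an even L1/L2 mix).
#' @param n_folds Number of CV folds, default 10.
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `enet_learner`: list with `alpha`, `lambda`,
#'   `intercept`, `coefficients` (named numeric, nonzero entries only),
#'   `feature_universe`, `cv_curve` (per (alpha, lambda): mean CV error and
#'   its SE), and `config`.
#' @export
fit_elastic_net_learner <- function(beta, ages, alphas = 0.5, n_folds = 10L,
                                    seed = 1L) {
  ages <- align_ages(beta, ages)
  if (!length(alphas)) stop("empty alpha grid")
  if (any(alphas < 0 | alphas > 1)) stop("alphas must lie in [0,1]")
  n <- ncol(beta)
  if (n < n_folds)
    stop("need at least n_folds = ", n_folds, " samples, got ", n)
  x <- t(unclass(beta))
  y <- as.numeric(ages)
  withr::local_seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = n))
  cvs <- lapply(alphas, function(a)
    glmnet::cv.glmnet(x, y, alpha = a, foldid = foldid, standardize = TRUE))
  curve <- do.call(rbind, Map(function(a, cv)
    data.frame(alpha = a, lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd),
    alphas, cvs))
  i_min <- which.min(curve$cvm)
  threshold <- curve$cvm[i_min] + curve$cvsd[i_min]
  cand <- curve[curve$cvm <= threshold, , drop = FALSE]
  cand <- cand[order(-cand$lambda, cand$alpha), , drop = FALSE]
  alpha_star <- cand$alpha[1]
  lambda_star <- cand$lambda[1]
  fit <- cvs[[match(alpha_star, alphas)]]$glmnet.fit
  cf <- as.numeric(stats::coef(fit, s = lambda_star))
  names(cf) <- c("(Intercept)", rownames(beta))
  nz <- cf[-1][cf[-1] != 0]
  structure(list(
    alpha = alpha_star,
    lambda = lambda_star,
    intercept = cf[[1]],
    coefficients = nz,
    feature_universe = rownames(beta),
    cv_curve = curve,
    lambda_min = curve$lambda[i_min],
    config = list(alphas = alphas, n_folds = n_folds, seed = seed)
  ), class = "enet_learner")
}

#' @export
print.enet_learner <- function(x, ...) {
  cat(sprintf("enet_learner: alpha %.3g, lambda %.4g, %d nonzero of %d features\n",
              x$alpha, x$lambda, length(x$coefficients),
              length(x$feature_universe)))
  invisible(x)
}

#' Predict ages with a single elastic-net clock
#'
#' @param object An `enet_learner`.
#' @param beta A [beta_matrix()] containing every feature of the learner's
#'   training universe (extra features are ignored).
#' @param ... Unused.
#' @return Named numeric vector of predicted ages.
#' @export
predict.enet_learner <- function(object, beta, ...) {
  feats <- names(object$coefficients)
  missing <- setdiff(feats, rownames(beta))
  if (length(missing))
    stop("input is missing required features: ",
         paste(utils::head(missing, 10), collapse = ", "))
  p <- rep(object$intercept, ncol(beta))
  if (length(feats))
    p <- p + as.numeric(crossprod(unclass(beta)[feats, , drop = FALSE],
                                  object$coefficients))
  stats::setNames(p, colnames(beta))
}

#' Aggregate feature evidence across elastic-net base learners
#'
#' For each feature p across K base learners, `f_plus` and `f_minus` are the
#' fractions of learners whose coefficient for p is positive or negative,
#' `beta_bar` is the mean coefficient over all K learners (absent features
#' count as 0), and the feature score is `(f_plus - f_minus) * beta_bar`.
#' Features selected consistently and with the same sign thus score high in
#' magnitude; features selected with conflicting signs cancel.
#'
#' @param learners List of `enet_learner` objects trained on the same
#'   feature universe.
#' @return Data frame with columns `feature_id`, `f_plus`, `f_minus`,
#'   `beta_bar`, `score`, in feature-universe order.
#' @export
score_features <- function(learners) {
  if (!length(learners)) stop("need at least one learner")
  universe <- learners[[1]]$feature_universe
  for (l in learners[-1])
    if (!setequal(l$feature_universe, universe))
      stop("learners were trained on different feature universes")
  K <- length(learners)
  cmat <- vapply(learners, function(l) {
    v <- stats::setNames(numeric(length(universe)), universe)
    v[names(l$coefficients)] <- l$coefficients
    v
  }, numeric(length(universe)))
  cmat <- matrix(cmat, nrow = length(universe),
                 dimnames = list(universe, NULL))
  f_plus <- rowMeans(cmat > 0)
  f_minus <- rowMeans(cmat < 0)
  beta_bar <- rowMeans(cmat)
  data.frame(feature_id = universe, f_plus = f_plus, f_minus = f_minus,
             beta_bar = beta_bar, score = (f_plus - f_minus) * beta_bar,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the top-scoring features
#'
#' Ranks features by absolute score, keeps the `n_top` largest (deterministic
#' tie-break by feature ID), and drops zero-score features; fewer than
#' `n_top` features are returned when fewer have nonzero score.
#'
#' @param table A feature-score table from [score_features()].
#' @param n_top Number of features to keep; default 50.
#' @return Character vector of selected feature IDs.
#' @export
select_top_features <- function(table, n_top = 50L) {
  if (n_top < 1) stop("n_top must be >= 1")
  tab <- table[table$score != 0, , drop = FALSE]
  if (!nrow(tab)) {
    warning("all feature scores are zero; no features selected")
    return(character(0))
  }
  tab <- tab[order(-abs(tab$score), tab$feature_id), , drop = FALSE]
  utils::head(tab$feature_id, n_top)
}

#' Fit one ordinary linear base learner on a resampled subset
#'
#' Least-squares affine fit of age on the integrated feature set, computed on
#' one resampled subset. Rank-deficient designs (possible when the selected
#' feature count approaches the subset size, or features are duplicated) use
#' the minimum-norm least-squares solution via the Moore-Penrose
#' pseudoinverse. The learner's gating statistic `train_r2` is the squared
#' Pearson correlation between its predictions and the true ages on the FULL
#' original training set — not on the subset it was fitted to.
#'
#' @param subset A `resampled_set` (from [resample_bin()] or
#'   [simple_boot()]).
#' @param features Character vector of selected feature IDs (non-empty).
#' @param train_beta,train_ages The full original training data on which
#'   `train_r2` is evaluated.
#' @return An object of class `linear_learner`: list with `features`,
#'   `intercept`, `coefficients` (named, dense over `features`), `train_r2`.
#' @export
fit_linear_learner <- function(subset, features, train_beta, train_ages) {
  if (!length(features)) stop("empty feature set")
  missing <- setdiff(features, rownames(subset$beta))
  if (length(missing))
    stop("subset is missing features: ", paste(utils::head(missing, 5), collapse = ", "))
  X <- t(unclass(subset$beta)[features, , drop = FALSE])
  y <- as.numeric(subset$ages)
  A <- cbind(`(Intercept)` = 1, X)
  cf <- as.numeric(MASS::ginv(A) %*% y)
  learner <- structure(list(
    features = features,
    intercept = cf[1],
    coefficients = stats::setNames(cf[-1], features),
    train_r2 = NA_real_
  ), class = "linear_learner")
  train_ages <- align_ages(train_beta, train_ages)
  pred <- predict(learner, train_beta)
  learner$train_r2 <- r_squared(as.numeric(train_ages), pred)
  learner
}

#' @export
predict.linear_learner <- function(object, beta, ...) {
  missing <- setdiff(object$features, rownames(beta))
  if (length(missing))
    stop("input is missing required features: ",
         paste(utils::head(missing, 10), collapse = ", "))
  p <- object$intercept +
    as.numeric(crossprod(unclass(beta)[object$features, , drop = FALSE],
                         object$coefficients))
  stats::setNames(p, colnames(beta))
}

# Squared Pearson correlation; 0 (with a warning) when either side is
# constant and the correlation is undefined.
r_squared <- function(truth, pred) {
  if (stats::sd(truth) == 0 || stats::sd(pred) == 0) {
    warning("zero variance: R^2 undefined, reporting 0")
    return(0)
  }
  stats::cor(truth, pred)^2
}

#' Gate and weight linear base learners by training R-squared
#'
#' Only learners with `train_r2` strictly greater than 0.5 are kept. Each
#' survivor gets a raw weight `0.5 * log(R2 / (1 - R2))` — positive for any
#' R2 above 0.5 and increasing in R2 — and the raw weights are scaled to sum
#' to 1. The normalized weights do not depend on the logarithm base.
#'
#' @param learners List of `linear_learner` objects.
#' @param r2_gate Gate threshold, default 0.5 (strict inequality).
#' @return List with `learners` (the retained ones) and `weights` (numeric,
#'   summing to 1).
#' @export
compute_weights <- function(learners, r2_gate = 0.5) {
  if (!length(learners)) stop("need at least one learner")
  r2 <- vapply(learners, `[[`, numeric(1), "train_r2")
  keep <- r2 > r2_gate
  if (!any(keep))
    stop("no base learner reached train R^2 > ", r2_gate,
         "; inspect the data, the feature selection, or try other seeds")
  r2 <- pmin(r2[keep], 1 - 1e-12)  # guard log(Inf) for a perfect fit
  raw <- 0.5 * log(r2 / (1 - r2))
  list(learners = learners[keep], weights = raw / sum(raw))
}

#' Assemble an ensemble clock from weighted linear learners
#'
#' @param learners Retained `linear_learner` list.
#' @param weights Normalized weights (sum 1).
#' @param selected_features Integrated feature set shared by the learners.
#' @param model_kind `"balanced"` or `"bootstrapped"`.
#' @param config Training provenance (seed, bin plan, alpha grid, ...).
#' @return An object of class `ensemble_clock`.
#' @export
ensemble_clock <- function(learners, weights, selected_features,
                           model_kind = c("balanced", "bootstrapped"),
                           config = list()) {
  model_kind <- match.arg(model_kind)
  if (length(learners) != length(weights))
    stop("one weight per learner required")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  structure(list(
    model_kind = model_kind,
    learners = learners,
    weights = weights,
    selected_features = selected_features,
    config = config
  ), class = "ensemble_clock")
}

#' @export
print.ensemble_clock <- function(x, ...) {
  cat(sprintf("ensemble_clock (%s): %d base learners, %d features, weights %s\n",
              x$model_kind, length(x$learners), length(x$selected_features),
              paste(sprintf("%.3f", x$weights), collapse = "/")))
  invisible(x)
}

#' @export
predict.ensemble_clock <- function(object, beta, ...) {
  preds <- vapply(object$learners, predict, numeric(ncol(beta)), beta)
  preds <- matrix(preds, nrow = ncol(beta))
  stats::setNames(as.numeric(preds %*% object$weights), colnames(beta))
}

#' Predict ages for new samples with a trained clock
#'
#' Works for both model kinds: a weighted-sum ensemble clock or a single
#' elastic-net clock. The input must contain every feature the model
#' requires (by ID); extra features are ignored.
#'
#' @param model An `ensemble_clock` or `enet_learner`.
#' @param beta A [beta_matrix()] of new samples.
#' @return Named numeric vector of predicted ages (DNAm ages).
#' @export
predict_ensemble <- function(model, beta) {
  if (!inherits(model, c("ensemble_clock", "enet_learner", "linear_learner")))
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  predict(model, beta)
}
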