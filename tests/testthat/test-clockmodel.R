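test_that("the 1-SE rule never chooses a lambda below the CV minimum", {
  for (s in 1:3) {
    d <- linear_dataset(n = 80, p = 40, n_signal = 3, sigma = 2, seed = s)
    fit <- fit_elastic_net_learner(d$beta, d$ages, alphas = 0.5, seed = s)
    expect_gte(fit$lambda, fit$lambda_min)
    expect_true(fit$lambda %in% fit$cv_curve$lambda)
  }
})

test_that("a strong linear signal is recovered with high hold-out accuracy", {
  d <- linear_dataset(n = 120, p = 200, n_signal = 1, sigma = 1, seed = 11)
  tr <- 1:90; te <- 91:120
  sub <- function(idx) list(
    beta = beta_matrix(unclass(d$beta)[, idx, drop = FALSE]),
    ages = age_vector(as.numeric(d$ages)[idx], colnames(d$beta)[idx], "years"))
  fit <- fit_elastic_net_learner(sub(tr)$beta, sub(tr)$ages, seed = 1)
  expect_true(d$signal %in% names(fit$coefficients))
  expect_gt(fit$coefficients[[d$signal]], 0)
  pred <- predict(fit, sub(te)$beta)
  expect_gt(cor(pred, as.numeric(sub(te)$ages))^2, 0.9)
})

test_that("a near-unpenalized fit on noiseless data recovers the generating coefficients", {
  d <- linear_dataset(n = 100, p = 5, n_signal = 2, sigma = 0, seed = 4,
                      slope = 30, intercept = 40)
  fit <- fit_elastic_net_learner(d$beta, d$ages, alphas = 0, seed = 2)
  full <- stats::setNames(numeric(5), rownames(d$beta))
  full[names(fit$coefficients)] <- fit$coefficients
  expect_equal(unname(full[d$signal]), c(30, 30), tolerance = 1e-1)
  expect_gt(cor(predict(fit, d$beta), as.numeric(d$ages))^2, 0.999)
})

test_that("elastic-net fitting validates its inputs", {
  d <- linear_dataset(n = 30, p = 10, seed = 1)
  expect_error(fit_elastic_net_learner(d$beta, d$ages, alphas = numeric(0)),
               "empty alpha")
  expect_error(fit_elastic_net_learner(d$beta, d$ages, alphas = 1.5), "\\[0,1\\]")
  expect_error(fit_elastic_net_learner(d$beta, d$ages, n_folds = 50),
               "at least n_folds")
})

test_that("feature scores follow (F+ - F-) * mean coefficient", {
  u <- c("p1", "p2", "p3")
  mk <- function(...) stub_enet(c(...), u)
  # K=2, both coefficients +1: F+ = 1, score = 1
  t1 <- score_features(list(mk(p1 = 1), mk(p1 = 1)))
  expect_equal(t1$score[t1$feature_id == "p1"], 1)
  expect_equal(t1[t1$feature_id == "p1", c("f_plus", "f_minus")],
               data.frame(f_plus = 1, f_minus = 0), ignore_attr = TRUE)
  # K=4, (2,-2,2,-2): symmetric cancellation
  t2 <- score_features(list(mk(p2 = 2), mk(p2 = -2), mk(p2 = 2), mk(p2 = -2)))
  expect_equal(t2$score[t2$feature_id == "p2"], 0)
  expect_equal(t2$f_plus[t2$feature_id == "p2"], 0.5)
  # K=3, (3,1,-1): F+ = 2/3, F- = 1/3, beta_bar = 1, score = 1/3
  t3 <- score_features(list(mk(p3 = 3), mk(p3 = 1), mk(p3 = -1)))
  expect_equal(t3$score[t3$feature_id == "p3"], 1 / 3)
  # absent features count as zero coefficients in the average
  expect_equal(t3$beta_bar[t3$feature_id == "p1"], 0)
  expect_error(score_features(list(mk(p1 = 1), stub_enet(c(q = 1), c("q")))),
               "universes")
})

test_that("feature scoring agrees with a brute-force double-loop oracle", {
  set.seed(30)
  for (rep in 1:10) {
    K <- sample(2:5, 1); P <- sample(5:20, 1)
    u <- paste0("f", seq_len(P))
    learners <- lapply(seq_len(K), function(k) {
      nz <- sample(P, sample(0:P, 1))
      stub_enet(stats::setNames(round(rnorm(length(nz)), 3), u[nz]), u)
    })
    tab <- score_features(learners)
    for (p in seq_len(P)) {
      cfs <- vapply(learners, function(l) {
        v <- l$coefficients[u[p]]
        if (is.na(v)) 0 else unname(v)
      }, numeric(1))
      fp <- sum(cfs > 0) / K; fm <- sum(cfs < 0) / K
      expect_equal(tab$score[tab$feature_id == u[p]],
                   (fp - fm) * mean(cfs), tolerance = 1e-12)
    }
  }
})

test_that("top features rank by absolute score with deterministic ties", {
  tab <- data.frame(feature_id = c("a", "b", "c"),
                    score = c(0.9, -0.8, 0.1))
  expect_equal(select_top_features(tab, 2), c("a", "b"))
  expect_equal(select_top_features(tab, 10), c("a", "b", "c"))
  tie <- data.frame(feature_id = c("z", "y"), score = c(0.5, -0.5))
  expect_equal(select_top_features(tie, 1), "y")  # |score| tie -> ID order
  zero <- data.frame(feature_id = "a", score = 0)
  expect_warning(out <- select_top_features(zero, 3), "zero")
  expect_length(out, 0)
  expect_error(select_top_features(tab, 0), "n_top")
})

test_that("linear learners interpolate exact data and handle rank deficiency", {
  b <- toy_beta(3, 10, seed = 17)
  y <- 2 * unclass(b)[1, ] + 5
  ages <- age_vector(y, colnames(b), "years")
  rs <- simple_boot(b, ages, seed = 1)
  ll <- fit_linear_learner(rs, "cg00001", b, ages)
  expect_equal(unname(ll$coefficients), 2, tolerance = 1e-8)
  expect_equal(ll$intercept, 5, tolerance = 1e-8)
  expect_equal(ll$train_r2, 1, tolerance = 1e-10)

  # duplicated feature: minimum-norm fit predicts like the deduplicated one
  b2v <- rbind(unclass(b), dup = unclass(b)["cg00001", ])
  b2 <- beta_matrix(b2v)
  rs2 <- simple_boot(b2, ages, seed = 1)
  ll2 <- fit_linear_learner(rs2, c("cg00001", "dup"), b2, ages)
  expect_equal(unname(predict(ll2, b2)), unname(predict(ll, b)),
               tolerance = 1e-6)
  expect_error(fit_linear_learner(rs, character(0), b, ages), "empty feature")
})

test_that("train R^2 equals an independent squared-correlation oracle", {
  set.seed(55)
  d <- linear_dataset(n = 40, p = 8, n_signal = 2, sigma = 5, seed = 23)
  rs <- simple_boot(d$beta, d$ages, seed = 2)
  ll <- fit_linear_learner(rs, d$signal, d$beta, d$ages)
  pred <- predict(ll, d$beta)
  y <- as.numeric(d$ages)
  oracle <- (sum((y - mean(y)) * (pred - mean(pred))) /
               sqrt(sum((y - mean(y))^2) * sum((pred - mean(pred))^2)))^2
  expect_equal(ll$train_r2, oracle, tolerance = 1e-10)
})

test_that("learner weights gate at R^2 > 0.5 strictly and normalize to 1", {
  w <- compute_weights(list(stub_linear(0.8), stub_linear(0.8)))
  expect_equal(w$weights, c(0.5, 0.5))
  # strict gate: exactly 0.5 is dropped
  w2 <- compute_weights(list(stub_linear(0.5), stub_linear(0.9)))
  expect_length(w2$learners, 1)
  expect_equal(w2$weights, 1)
  # hand oracle: 0.5*ln(4)=0.6931, 0.5*ln(9)=1.0986, sum 1.7918
  w3 <- compute_weights(list(stub_linear(0.8), stub_linear(0.9)))
  expect_equal(w3$weights, c(0.6931472, 1.0986123) / 1.7917595,
               tolerance = 1e-6)
  expect_error(compute_weights(list(stub_linear(0.3))), "no base learner")
})

test_that("normalized weights are invariant to the logarithm base and monotone in R^2", {
  r2 <- c(0.6, 0.7, 0.85, 0.99)
  w <- compute_weights(lapply(r2, stub_linear))$weights
  w10 <- 0.5 * log10(r2 / (1 - r2)); w10 <- w10 / sum(w10)
  expect_equal(w, w10, tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(diff(w) > 0))
})

test_that("ensemble predictions are the weighted sum of learner predictions", {
  l10 <- stub_linear(0.9, "f1"); l10$intercept <- 10; l10$coefficients[] <- 0
  l20 <- stub_linear(0.9, "f1"); l20$intercept <- 20; l20$coefficients[] <- 0
  b <- beta_matrix(matrix(0.5, 1, 3, dimnames = list("f1", c("a", "b", "c"))))
  m <- ensemble_clock(list(l10, l20), c(0.25, 0.75), "f1", "balanced")
  expect_equal(unname(predict(m, b)), rep(17.5, 3))
  # K identical learners: prediction equals any single learner's
  m2 <- ensemble_clock(list(l10, l10, l10), rep(1, 3) / 3, "f1", "balanced")
  expect_equal(predict(m2, b), predict(l10, b))
  # convex combination: within the learners' prediction range
  set.seed(71)
  b2 <- toy_beta(4, 15, seed = 31)
  lls <- lapply(1:3, function(k) {
    ll <- stub_linear(0.9, rownames(b2)[1:2])
    ll$intercept <- rnorm(1); ll$coefficients[] <- rnorm(2)
    ll
  })
  wts <- c(0.2, 0.3, 0.5)
  m3 <- ensemble_clock(lls, wts, rownames(b2)[1:2], "bootstrapped")
  preds <- vapply(lls, predict, numeric(15), b2)
  ens <- predict(m3, b2)
  expect_true(all(ens >= apply(preds, 1, min) - 1e-12))
  expect_true(all(ens <= apply(preds, 1, max) + 1e-12))
  # missing features are reported by name
  other <- beta_matrix(matrix(0.5, 2, 2, dimnames = list(c("x1", "x2"),
                                                         c("a", "b"))))
  expect_error(predict(m3, other), "missing required features")
})
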