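test_that("bin width adapts to the smallest width giving >= 2 samples per bin", {
  # one sample per integer age: width 1 leaves singleton bins, width 2 works
  a <- age_vector(1:10, paste0("s", 1:10), units = "years")
  plan <- adapt_bin_width(a, initial_width = 1, step = 1)
  expect_equal(plan$width, 2)
  expect_equal(plan$n_bins, 5)
  expect_equal(lengths(plan$member_indices), rep(2L, 5))

  # width 1 already valid when every bin holds 2
  a2 <- age_vector(c(1, 1, 2, 2), paste0("s", 1:4), units = "years")
  plan2 <- adapt_bin_width(a2, initial_width = 1)
  expect_equal(plan2$width, 1)
  expect_equal(plan2$n_bins, 2)
  expect_equal(lengths(plan2$member_indices), c(2L, 2L))

  expect_error(adapt_bin_width(age_vector(rep(5, 4), paste0("s", 1:4))),
               "zero age range")
  expect_error(adapt_bin_width(age_vector(3, "s1")), "at least 2")

  # an age gap (empty middle bins) forces widening until the gap is spanned
  a3 <- age_vector(c(1, 1, 9, 9), paste0("s", 1:4), units = "years")
  plan3 <- adapt_bin_width(a3, initial_width = 1)
  expect_gte(min(lengths(plan3$member_indices)), 2)
})

test_that("every bin contributes exactly the target count on resampling", {
  # bins of sizes {6, 2}: target ceil(8/2) = 4; big bin bootstraps down to 4,
  # small bin keeps its 2 originals and synthesizes 2
  b <- toy_beta(4, 8)
  ages <- age_vector(c(rep(10, 6), rep(15, 2)), colnames(b), "weeks")
  plan <- adapt_bin_width(ages, initial_width = 5)
  expect_equal(lengths(plan$member_indices), c(6L, 2L))
  rs <- resample_bin(b, ages, plan, seed = 99)
  expect_equal(length(rs$kept) + nrow(rs$synthesized),
               plan$n_bins * plan$target_count)
  expect_equal(nrow(rs$synthesized), 2)
  expect_true(all(rs$kept[1:4] %in% 1:6))
  expect_true(all(7:8 %in% rs$kept))
  expect_true(all(rs$synthesized$source_index %in% 7:8))
  # synthesized ages equal their source's age
  expect_equal(rs$synthesized$age,
               as.numeric(ages)[rs$synthesized$source_index])
  expect_equal(ncol(rs$beta), length(as.numeric(rs$ages)))
})

test_that("a bin already at target size passes through unchanged", {
  b <- toy_beta(3, 6)
  ages <- age_vector(c(10, 10, 10, 20, 20, 20), colnames(b), "weeks")
  plan <- adapt_bin_width(ages, initial_width = 10)
  expect_equal(plan$target_count, 3L)
  rs <- resample_bin(b, ages, plan, seed = 1)
  expect_equal(sort(rs$kept), 1:6)
  expect_equal(nrow(rs$synthesized), 0)
  expect_identical(unname(unclass(rs$beta)), unname(unclass(b)))
})

test_that("resampling is deterministic under a fixed seed and varies across seeds", {
  b <- toy_beta(5, 12, seed = 3)
  ages <- toy_ages(b, c(rep(38, 9), 12, 20, 28))
  plan <- adapt_bin_width(ages)
  r1 <- resample_bin(b, ages, plan, seed = 5)
  r2 <- resample_bin(b, ages, plan, seed = 5)
  expect_identical(r1$kept, r2$kept)
  expect_identical(r1$synthesized, r2$synthesized)
  expect_identical(unclass(r1$beta), unclass(r2$beta))
  kept_other <- lapply(1:10, function(s) resample_bin(b, ages, plan, seed = s)$kept)
  expect_true(any(!vapply(kept_other, identical, logical(1), r1$kept)))
})

test_that("SMOTE interpolation follows x + r*(nn - x) with the source's age", {
  out <- smote_synthesize(c(0.2, 0.4), c(0.4, 0.8), r = 0.5, age_x = 33)
  expect_equal(out$values, c(0.3, 0.6))
  expect_equal(out$age, 33)
  expect_equal(smote_synthesize(c(0.2, 0.4), c(0.4, 0.8), 0, 33)$values,
               c(0.2, 0.4))
  neg <- smote_synthesize(c(0.2, 0.4), c(0.4, 0.8), -0.5, 33)
  expect_equal(neg$values, c(0.1, 0.2))
  expect_error(smote_synthesize(c(0.1), c(0.2), 0.6, 1), "\\[-0.5, 0.5\\]")
  expect_error(smote_synthesize(c(0.1), c(0.2, 0.3), 0.1, 1), "same length")
  # optional clipping
  expect_equal(smote_synthesize(0.9, -0.9, -0.5, 1, clip = TRUE)$values, 1)
})

test_that("synthesized records verify against their recorded provenance", {
  set.seed(21)
  for (case in 1:20) {
    p <- sample(3:8, 1); n <- sample(8:16, 1)
    b <- toy_beta(p, n, seed = 100 + case)
    ages <- toy_ages(b, c(rep(39, n - 3), 12, 18, 25), seed = case)
    plan <- adapt_bin_width(ages)
    rs <- resample_bin(b, ages, plan, seed = case)
    expect_equal(length(rs$kept) + nrow(rs$synthesized),
                 plan$n_bins * plan$target_count)
    if (nrow(rs$synthesized)) {
      syn_cols <- unclass(rs$beta)[, length(rs$kept) + seq_len(nrow(rs$synthesized)),
                                   drop = FALSE]
      for (i in seq_len(nrow(rs$synthesized))) {
        s <- rs$synthesized[i, ]
        expect_true(s$r >= -0.5 && s$r <= 0.5)
        x <- unclass(b)[, s$source_index]
        nn <- unclass(b)[, s$neighbor_index]
        expect_equal(unname(syn_cols[, i]), unname(x + s$r * (nn - x)),
                     tolerance = 1e-12)
        # value bound: within x +/- 0.5|nn - x|
        expect_true(all(syn_cols[, i] >= pmin(x, x + 0.5 * (nn - x), x - 0.5 * (nn - x)) - 1e-12))
        expect_true(all(abs(syn_cols[, i] - x) <= 0.5 * abs(nn - x) + 1e-12))
        # age provenance: an original in-bin age
        bin <- plan$assignment[s$source_index]
        expect_true(s$age %in% as.numeric(ages)[plan$member_indices[[bin]]])
      }
    }
  }
})

test_that("nearest-neighbor search agrees with an exhaustive oracle", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(3:20, 1)
    vals <- matrix(runif(4 * n), 4, n)
    j <- sample(n, 1)
    d <- apply(vals, 2, function(v) sqrt(sum((v - vals[, j])^2)))
    d[j] <- Inf
    expect_equal(bagclock:::nearest_neighbor(vals, j), which.min(d))
  }
})

test_that("plain bootstrap keeps size N with no synthesis and is seed-stable", {
  b <- toy_beta(3, 100, seed = 2)
  ages <- toy_ages(b)
  r1 <- simple_boot(b, ages, seed = 4)
  expect_equal(length(r1$kept), 100)
  expect_equal(nrow(r1$synthesized), 0)
  expect_identical(r1$kept, simple_boot(b, ages, seed = 4)$kept)
  empty <- beta_matrix(matrix(numeric(0), 1, 0), feature_ids = "f",
                       sample_ids = character(0))
  expect_error(simple_boot(empty, age_vector(numeric(0), character(0))),
               "empty")
})

test_that("bootstrap distinct-sample fraction matches 1 - 1/e", {
  b <- toy_beta(2, 1000, seed = 6)
  ages <- toy_ages(b)
  fr <- vapply(1:50, function(s)
    length(unique(simple_boot(b, ages, seed = s)$kept)) / 1000, numeric(1))
  expect_lt(abs(mean(fr) - (1 - exp(-1))), 0.03)
})

test_that("balance index matches a straight-loop KDE oracle", {
  set.seed(13)
  a <- age_vector(round(runif(30, 8, 42), 3), paste0("s", 1:30), "weeks")
  expect_equal(balance_index(a), balance_index_oracle(a), tolerance = 1e-8)
})

test_that("balance index is shift-invariant and errors on degenerate input", {
  set.seed(14)
  a <- runif(100, 0, 80)
  expect_equal(balance_index(a), balance_index(a + 17.3), tolerance = 1e-10)
  expect_error(balance_index(rep(4, 10)), "zero age range")
  expect_error(balance_index(3), "at least 2")
})

test_that("flatter age distributions score a higher balance index", {
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    unif <- runif(500, 0, 80)
    skew <- c(runif(450, 70, 80), runif(50, 0, 70))
    balance_index(unif) > balance_index(skew)
  }, logical(1))
  expect_true(all(wins))
})
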