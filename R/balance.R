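#' Adapt the age bin width until every bin holds at least 2 samples
#'
#' Divides the age range \[min, max\] into consecutive equal-width bins and
#' widens the bins stepwise until each holds at least 2 original samples.
#' The initial width is 1 week for gestational age and 1 year for lifespan
#' age; if any bin (including an empty one) holds fewer than 2 samples the
#' width is increased by `step` and the binning is redone. Termination is
#' guaranteed: a single bin covering the whole range holds all N >= 2
#' samples.
#'
#' Bins are half-open \[low, high) with bin membership
#' `floor((age - min) / width) + 1`, so when the range is an exact multiple
#' of the width the maximum age forms the start of a final bin of its own.
#'
#' @param ages An [age_vector()] (or plain numeric vector).
#' @param initial_width Starting bin width in age units; defaults to 1 (week
#'   or year, per the units of `ages`).
#' @param step Width increment per adaptation round; defaults to
#'   `initial_width`.
#' @return An object of class `bin_plan`: list with `width`, `edges`,
#'   `assignment` (bin index per sample), `member_indices` (per-bin sample
#'   index list), `n_bins`, and `target_count = ceiling(N / n_bins)`.
#' @export
adapt_bin_width <- function(ages, initial_width = 1, step = initial_width) {
  a <- as.numeric(ages)
  n <- length(a)
  if (n < 2) stop("need at least 2 samples to bin")
  rng <- range(a)
  if (rng[1] == rng[2]) stop("zero age range: all ages are equal")
  if (initial_width <= 0 || step <= 0) stop("width and step must be positive")
  width <- initial_width
  repeat {
    plan <- bin_ages(a, width)
    if (min(lengths(plan$member_indices)) >= 2) {
      plan$initial_width <- initial_width
      plan$step <- step
      return(plan)
    }
    width <- width + step
  }
}

# Equal-width binning of [min, max]; bin index floor((a - min)/width) + 1.
# A small relative tolerance keeps ages sitting on an edge (up to fp error)
# in the upper bin, so exact-multiple ranges behave predictably.
bin_ages <- function(a, width) {
  lo <- min(a)
  span <- max(a) - lo
  eps <- 1e-9 * max(1, abs(span))
  idx <- as.integer(floor((a - lo + eps) / width)) + 1L
  n_bins <- max(idx)
  structure(list(
    width = width,
    edges = lo + width * (0:n_bins),
    assignment = idx,
    member_indices = lapply(seq_len(n_bins), function(b) which(idx == b)),
    n_bins = n_bins,
    target_count = as.integer(ceiling(length(a) / n_bins))
  ), class = "bin_plan")
}

#' @export
print.bin_plan <- function(x, ...) {
  cat(sprintf("bin_plan: %d bins of width %g, target %d samples/bin (sizes: %s)\n",
              x$n_bins, x$width, x$target_count,
              paste(lengths(x$member_indices), collapse = ", ")))
  invisible(x)
}

#' Interpolate one synthetic sample between a sample and a neighbor
#'
#' The regression-SMOTE step: the synthetic feature vector is
#' `x + r * (nn - x)` with `r` in \[-0.5, 0.5\], and the synthetic age is the
#' age of the source sample `x`. Values are not clipped to \[0,1\] (the
#' interpolation formula is applied as stated); pass `clip = TRUE` to force a
#' valid beta range.
#'
#' @param x Source feature vector.
#' @param nn Nearest-neighbor feature vector (same length).
#' @param r Interpolation factor in \[-0.5, 0.5\].
#' @param age_x Age of the source sample.
#' @param clip Clip the result to \[0,1\]? Default `FALSE`.
#' @return List with `values` (numeric vector) and `age`.
#' @export
smote_synthesize <- function(x, nn, r, age_x, clip = FALSE) {
  if (length(x) != length(nn)) stop("x and nn must have the same length")
  if (!is.finite(r) || r < -0.5 || r > 0.5)
    stop("interpolation factor r must lie in [-0.5, 0.5]")
  v <- x + r * (nn - x)
  if (clip) v <- pmin(1, pmax(0, v))
  list(values = v, age = age_x)
}

# Nearest in-bin neighbor by Euclidean distance over all features; self is
# excluded and ties break to the lowest sample index.
nearest_neighbor <- function(values, j) {
  d <- sqrt(colSums((values - values[, j])^2))
  d[j] <- Inf
  which.min(d)  # which.min returns the first (lowest-index) minimum
}

#' Rebalance a biased age distribution by per-bin resampling
#'
#' Every age bin is brought to exactly `target_count = ceiling(N / n_bins)`
#' samples. Bins above target are under-sampled by bootstrapping (drawn with
#' replacement by default); bins already at target pass through unchanged;
#' bins below target keep all their originals and add SMOTE-synthesized
#' samples: a random in-bin source is paired with its nearest in-bin neighbor
#' (Euclidean distance over all features), a factor `r ~ Uniform(-0.5, 0.5)`
#' is drawn, and the interpolated vector [smote_synthesize()] enters the
#' subset with the source's age.
#'
#' @param beta A [beta_matrix()] (features x samples).
#' @param ages Ages aligned to `beta`'s samples.
#' @param plan A `bin_plan` from [adapt_bin_width()] built from these ages.
#' @param seed Integer seed; the output is a pure function of
#'   (beta, ages, plan, seed).
#' @param replace Under-sample with replacement (bootstrapping, default) or
#'   without.
#' @param clip Clip synthesized values to \[0,1\]? Default `FALSE`.
#' @return An object of class `resampled_set`: list with `beta` (features x
#'   m realized matrix), `ages`, `kept` (original sample indices, repeats
#'   allowed), `synthesized` (data.frame: source_index, neighbor_index, r,
#'   age), `seed`, and `plan`.
#' @export
resample_bin <- function(beta, ages, plan = NULL, seed = 1L, replace = TRUE,
                         clip = FALSE) {
  ages <- align_ages(beta, ages)
  if (is.null(plan))
    plan <- adapt_bin_width(ages, initial_width = default_bin_width(ages))
  if (length(plan$assignment) != ncol(beta))
    stop("bin plan was not built from these samples")
  target <- plan$target_count
  withr::local_seed(seed)
  kept <- integer(0)
  synth <- list()
  for (b in seq_len(plan$n_bins)) {
    members <- plan$member_indices[[b]]
    sz <- length(members)
    if (sz < 2)
      stop("bin ", b, " holds ", sz,
           " original samples; widen the bins with adapt_bin_width()")
    if (sz >= target) {
      kept <- c(kept, if (sz == target) members
                else sort(sample(members, target, replace = replace)))
    } else {
      kept <- c(kept, members)
      vals <- unclass(beta)[, members, drop = FALSE]
      for (s in seq_len(target - sz)) {
        j <- sample.int(sz, 1)
        nn <- nearest_neighbor(vals, j)
        r <- stats::runif(1, -0.5, 0.5)
        synth[[length(synth) + 1L]] <- list(
          source_index = members[j], neighbor_index = members[nn], r = r,
          values = smote_synthesize(vals[, j], vals[, nn], r,
                                    ages[members[j]], clip = clip)$values)
      }
    }
  }
  synth_df <- if (length(synth)) {
    data.frame(source_index = vapply(synth, `[[`, integer(1), "source_index"),
               neighbor_index = vapply(synth, `[[`, integer(1), "neighbor_index"),
               r = vapply(synth, `[[`, numeric(1), "r"),
               age = as.numeric(ages)[vapply(synth, `[[`, integer(1), "source_index")])
  } else {
    data.frame(source_index = integer(0), neighbor_index = integer(0),
               r = numeric(0), age = numeric(0))
  }
  out_vals <- cbind(unclass(beta)[, kept, drop = FALSE],
                    if (length(synth))
                      vapply(synth, `[[`, numeric(nrow(beta)), "values")
                    else NULL)
  out_ids <- make.unique(c(colnames(beta)[kept],
                           if (length(synth))
                             paste0("syn_", colnames(beta)[synth_df$source_index])
                           else character(0)), sep = ".")
  colnames(out_vals) <- out_ids
  out_ages <- age_vector(c(as.numeric(ages)[kept], synth_df$age), out_ids,
                         units = age_units(ages))
  structure(list(
    beta = beta_matrix(out_vals, feature_level = feature_level(beta)),
    ages = out_ages,
    kept = kept,
    synthesized = synth_df,
    seed = seed,
    plan = plan
  ), class = "resampled_set")
}

default_bin_width <- function(ages) 1

#' @export
print.resampled_set <- function(x, ...) {
  cat(sprintf("resampled_set: %d kept + %d synthesized = %d samples (seed %d)\n",
              length(x$kept), nrow(x$synthesized),
              length(x$kept) + nrow(x$synthesized), x$seed))
  invisible(x)
}

#' Plain bootstrap of the training set
#'
#' Draws N sample indices uniformly with replacement and realizes the
#' bootstrapped matrix; no distribution adjustment and no synthesis. Used to
#' build the plain bagging ("bootstrapped") clock.
#'
#' @inheritParams resample_bin
#' @return A `resampled_set` with an empty `synthesized` table.
#' @export
simple_boot <- function(beta, ages, seed = 1L) {
  n <- ncol(beta)
  if (n < 1) stop("empty input")
  ages <- align_ages(beta, ages)
  withr::local_seed(seed)
  kept <- sample.int(n, n, replace = TRUE)
  out_vals <- unclass(beta)[, kept, drop = FALSE]
  out_ids <- make.unique(colnames(beta)[kept], sep = ".")
  colnames(out_vals) <- out_ids
  structure(list(
    beta = beta_matrix(out_vals, feature_level = feature_level(beta)),
    ages = age_vector(as.numeric(ages)[kept], out_ids, units = age_units(ages)),
    kept = kept,
    synthesized = data.frame(source_index = integer(0), neighbor_index = integer(0),
                             r = numeric(0), age = numeric(0)),
    seed = seed,
    plan = NULL
  ), class = "resampled_set")
}

#' Balance index of an age distribution
#'
#' A Gaussian-kernel density estimate of the ages (Silverman's rule-of-thumb
#' bandwidth, the default of [stats::bw.nrd0()]) is evaluated at 512 equally
#' spaced points spanning exactly \[min(ages), max(ages)\], and the balance
#' index is `-log10` of the sample variance (n-1 denominator) of those 512
#' density values. A flat (balanced) distribution gives near-constant density
#' values, a small variance, and hence a large index; a biased distribution
#' gives a small index.
#'
#' @param ages An [age_vector()] or numeric vector with at least 2 distinct
#'   values.
#' @return Numeric scalar, the balance index.
#' @export
balance_index <- function(ages) {
  a <- as.numeric(ages)
  if (length(a) < 2) stop("need at least 2 samples")
  rng <- range(a)
  if (rng[1] == rng[2]) stop("zero age range: all ages are equal")
  grid <- seq(rng[1], rng[2], length.out = 512)
  h <- stats::bw.nrd0(a)
  # exact Gaussian KDE (no FFT binning): f(g) = mean(dnorm(g - a, sd = h))
  dens <- rowMeans(outer(grid, a, function(g, x) stats::dnorm(g - x, sd = h)))
  -log10(stats::var(dens))
}
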