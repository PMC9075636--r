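# Small in-code fixtures shared across the suite.

# Deterministic toy beta matrix: p features x n samples, values in [0,1].
toy_beta <- function(p = 5, n = 8, seed = 42, level = "probe") {
  set.seed(seed)
  m <- matrix(round(runif(p * n), 6), p, n,
              dimnames = list(sprintf("cg%05d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  beta_matrix(m, feature_level = level)
}

toy_ages <- function(beta, ages = NULL, units = "weeks", seed = 7) {
  if (is.null(ages)) {
    set.seed(seed)
    ages <- round(runif(ncol(beta), 10, 40), 2)
  }
  age_vector(ages, colnames(beta), units = units)
}

# A dataset where age is an exact (or noisy) linear function of a few
# features; useful for recovery and R^2 checks without the full simulator.
linear_dataset <- function(n = 120, p = 50, n_signal = 1, sigma = 0,
                           seed = 11, slope = 30, intercept = 40) {
  set.seed(seed)
  ids <- sprintf("f%03d", seq_len(p))
  sids <- sprintf("s%03d", seq_len(n))
  x <- matrix(runif(p * n), p, n, dimnames = list(ids, sids))
  y <- intercept + slope * colSums(x[seq_len(n_signal), , drop = FALSE]) +
    rnorm(n, 0, sigma)
  list(beta = beta_matrix(x, feature_level = "probe"),
       ages = age_vector(y, sids, units = "years"),
       signal = ids[seq_len(n_signal)])
}

# Manifest with hand-placed positions for the DMR gap-rule fixture.
dmr_fixture_manifest <- function() {
  manifest_table(
    probe_id = paste0("cg0000", 1:5),
    chromosome = "chr1",
    position = c(100, 400, 1200, 1600, 2500),
    gene_names = c("GENEA", "GENEA", "GENEB", "GENEB", "GENEC"),
    gene_groups = c("TSS200", "Body", "TSS1500", "1stExon", "TSS200"),
    island_relation = c("Island", "N_Shore", "OpenSea", "S_Shelf", "Island"))
}

# Independent straight-loop KDE oracle for the balance index.
balance_index_oracle <- function(ages) {
  a <- as.numeric(ages)
  h <- stats::bw.nrd0(a)
  grid <- seq(min(a), max(a), length.out = 512)
  dens <- numeric(512)
  for (i in seq_len(512)) {
    s <- 0
    for (x in a) s <- s + exp(-0.5 * ((grid[i] - x) / h)^2) / (h * sqrt(2 * pi))
    dens[i] <- s / length(a)
  }
  -log10(sum((dens - mean(dens))^2) / 511)
}

# Minimal enet_learner stub for feature-score tests.
stub_enet <- function(coefs, universe) {
  structure(list(alpha = 0.5, lambda = 1, intercept = 0,
                 coefficients = coefs, feature_universe = universe,
                 cv_curve = NULL, config = list()),
            class = "enet_learner")
}

stub_linear <- function(r2, features = "f1") {
  structure(list(features = features, intercept = 0,
                 coefficients = stats::setNames(rep(1, length(features)), features),
                 train_r2 = r2),
            class = "linear_learner")
}
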