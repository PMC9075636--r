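#' Configuration for the synthetic methylation dataset generator
#'
#' The generator emulates the situation the balanced clock is designed for:
#' a methylation matrix in which a few features track age linearly on the
#' beta scale while most are age-independent noise, and a sample set whose
#' age distribution is strongly biased toward the top of the range (as with
#' placental gestational-age collections, where most deliveries are near
#' term). A fraction `skew_fraction` of samples is drawn uniformly from the
#' narrow upper band `[upper_band_start, age_max]` and the remainder
#' uniformly from the broad lower band `[age_min, upper_band_start)`.
#'
#' Signal features follow
#' `beta = clip_01(intercept + slope * age_norm + N(0, noise_sd))` with
#' `age_norm = (age - age_min) / (age_max - age_min)`; null features are
#' Beta(2, 2) draws, independent of age, mimicking the bounded spread of
#' methylation fractions.
#'
#' @param n_samples,n_features,n_signal_features Dataset dimensions;
#'   defaults 300 samples x 1000 features with 10 age-linked features.
#' @param age_min,age_max,units Age range; default gestational 8-42 weeks.
#' @param skew_fraction Fraction of samples in the upper band; default 0.8.
#' @param upper_band_start Lower edge of the dense upper band; default the
#'   top fifth of the range, `age_min + 0.8 * (age_max - age_min)`.
#' @param noise_sd Gaussian noise SD on the beta scale; default 0.05.
#' @param slope_range Absolute slope range for signal features (per unit of
#'   normalized age); default \[0.2, 0.5\], sign random.
#' @param intercept_range Signal intercept range; default \[0.25, 0.55\],
#'   keeping most signal values inside \[0,1\] before clipping.
#' @param seed Integer seed.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_samples = 300L, n_features = 1000L,
                       n_signal_features = 10L,
                       age_min = 8, age_max = 42, units = "weeks",
                       skew_fraction = 0.8,
                       upper_band_start = age_min + 0.8 * (age_max - age_min),
                       noise_sd = 0.05,
                       slope_range = c(0.2, 0.5),
                       intercept_range = c(0.25, 0.55),
                       seed = 1L) {
  stopifnot(n_samples >= 2, n_features >= 1,
            n_signal_features >= 0, n_signal_features <= n_features,
            age_max > age_min, noise_sd >= 0,
            skew_fraction > 0, skew_fraction < 1,
            upper_band_start > age_min, upper_band_start < age_max)
  structure(list(
    n_samples = as.integer(n_samples), n_features = as.integer(n_features),
    n_signal_features = as.integer(n_signal_features),
    age_min = age_min, age_max = age_max, units = units,
    skew_fraction = skew_fraction, upper_band_start = upper_band_start,
    noise_sd = noise_sd, slope_range = slope_range,
    intercept_range = intercept_range, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a methylation-like dataset with known ground truth
#'
#' @param config A [sim_config()].
#' @return List with `beta` (a probe-level [beta_matrix()]), `ages` (an
#'   [age_vector()]), and `truth` (data.frame: feature_id, intercept, slope
#'   — the generating parameters of the signal features, slope per unit of
#'   normalized age).
#' @export
simulate_dataset <- function(config = sim_config()) {
  cf <- config
  withr::local_seed(cf$seed)
  n <- cf$n_samples
  n_hi <- round(cf$skew_fraction * n)
  ages <- c(stats::runif(n_hi, cf$upper_band_start, cf$age_max),
            stats::runif(n - n_hi, cf$age_min, cf$upper_band_start))
  ages <- sample(ages)  # shuffle so band membership is not positional
  sample_ids <- sprintf("s%03d", seq_len(n))
  age_norm <- (ages - cf$age_min) / (cf$age_max - cf$age_min)

  feature_ids <- sprintf("cg%05d", seq_len(cf$n_features))
  signal_ids <- if (cf$n_signal_features)
    sort(sample(feature_ids, cf$n_signal_features)) else character(0)
  slopes <- stats::runif(length(signal_ids), cf$slope_range[1], cf$slope_range[2]) *
    sample(c(-1, 1), length(signal_ids), replace = TRUE)
  intercepts <- stats::runif(length(signal_ids), cf$intercept_range[1],
                             cf$intercept_range[2])
  # negative-slope features start high so they stay in range as age rises
  intercepts[slopes < 0] <- intercepts[slopes < 0] - slopes[slopes < 0] * 0.5

  vals <- matrix(stats::rbeta(cf$n_features * n, 2, 2), cf$n_features, n,
                 dimnames = list(feature_ids, sample_ids))
  for (i in seq_along(signal_ids)) {
    raw <- intercepts[i] + slopes[i] * age_norm +
      stats::rnorm(n, 0, cf$noise_sd)
    vals[signal_ids[i], ] <- pmin(1, pmax(0, raw))
  }
  list(
    beta = beta_matrix(vals, feature_level = "probe"),
    ages = age_vector(ages, sample_ids, units = cf$units),
    truth = data.frame(feature_id = signal_ids, intercept = intercepts,
                       slope = slopes, stringsAsFactors = FALSE)
  )
}

#' Simulate an Illumina-style probe manifest
#'
#' Probes are placed along chromosomes with controlled inter-probe gaps so
#' the expected DMR clustering is computable in closed form; gene names and
#' region groups cycle through all six Illumina categories; island relations
#' are sampled from the standard six.
#'
#' @param n_probes Number of probes (ignored when `chrom_layout` is given).
#' @param n_genes Number of distinct gene names to cycle through.
#' @param chrom_layout Optional named list of numeric gap vectors: each
#'   element is one chromosome, placing `length(gaps) + 1` probes with the
#'   given consecutive gaps (bp). When `NULL`, probes are spread over two
#'   chromosomes with gaps drawn uniformly from 50-1500 bp.
#' @param start Position of the first probe on each chromosome; default
#'   1000.
#' @param seed Integer seed.
#' @return A `manifest_table` whose probe IDs are `cg00001, cg00002, ...` in
#'   layout order.
#' @export
simulate_manifest <- function(n_probes = 100L, n_genes = 20L,
                              chrom_layout = NULL, start = 1000L, seed = 1L) {
  withr::local_seed(seed)
  if (is.null(chrom_layout)) {
    if (n_probes < 2) stop("need at least 2 probes")
    half <- n_probes %/% 2
    chrom_layout <- list(
      chr1 = round(stats::runif(max(half - 1, 0), 50, 1500)),
      chr2 = round(stats::runif(max(n_probes - half - 1, 0), 50, 1500)))
  }
  if (!length(chrom_layout) || is.null(names(chrom_layout)))
    stop("chrom_layout must be a named list of gap vectors")
  if (any(unlist(chrom_layout, use.names = FALSE) <= 0) &&
      length(unlist(chrom_layout)))
    stop("gaps must be positive")
  chroms <- rep(names(chrom_layout), vapply(chrom_layout, length, integer(1)) + 1L)
  positions <- unlist(lapply(chrom_layout, function(g) start + cumsum(c(0, g))),
                      use.names = FALSE)
  n <- length(chroms)
  if (n_genes < 1) stop("need at least one gene")
  gene_names <- sprintf("GENE%03d", ((seq_len(n) - 1L) %% n_genes) + 1L)
  region_groups <- VALID_REGION_GROUPS[((seq_len(n) - 1L) %% 6L) + 1L]
  islands <- sample(c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                      "OpenSea"), n, replace = TRUE)
  manifest_table(
    probe_id = sprintf("cg%05d", seq_len(n)),
    chromosome = chroms, position = positions,
    gene_names = gene_names, gene_groups = region_groups,
    island_relation = islands)
}
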