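#' Construct a beta matrix
#'
#' The universal container of the package: a dense numeric matrix of
#' methylation beta values with features (probes, genes, or DMRs) in rows and
#' samples in columns. Beta values are methylation fractions, nominally in
#' \[0,1\], but the container does not enforce the bounds because downstream
#' synthesis (see [smote_synthesize()]) can legitimately step outside them.
#'
#' @param values Numeric matrix, features x samples.
#' @param feature_ids Character vector of unique feature identifiers
#'   (defaults to `rownames(values)`).
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to `colnames(values)`).
#' @param feature_level One of `"probe"`, `"gene"`, `"dmr"`.
#' @param impute If `TRUE`, missing values are replaced by the per-feature
#'   mean; if `FALSE` (default) any missing or non-finite value is an error.
#' @return An object of class `beta_matrix`: the numeric matrix with dimnames
#'   set and a `feature_level` attribute.
#' @export
beta_matrix <- function(values, feature_ids = rownames(values),
                        sample_ids = colnames(values),
                        feature_level = c("probe", "gene", "dmr"),
                        impute = FALSE) {
  feature_level <- match.arg(feature_level)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("feature and sample IDs are required")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values))
    stop("length(feature_ids) != nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) != ncol(values)")
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup))
    stop("duplicated feature IDs: ", paste(utils::head(dup, 5), collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicated sample IDs: ", paste(utils::head(dup, 5), collapse = ", "))
  bad <- !is.finite(values)
  if (any(bad)) {
    if (!impute) {
      i <- which(bad, arr.ind = TRUE)[1, ]
      stop("non-finite beta value at feature '", feature_ids[i[1]],
           "', sample '", sample_ids[i[2]],
           "' (set impute = TRUE for per-feature mean imputation)")
    }
    for (r in unique(which(bad, arr.ind = TRUE)[, 1])) {
      row <- values[r, ]
      m <- mean(row[is.finite(row)])
      if (!is.finite(m))
        stop("feature '", feature_ids[r], "' has no finite values to impute from")
      values[r, !is.finite(row)] <- m
    }
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(values, feature_level = feature_level, class = c("beta_matrix", "matrix", "array"))
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d %s features x %d samples\n",
              nrow(x), attr(x, "feature_level"), ncol(x)))
  invisible(x)
}

feature_level <- function(beta) attr(beta, "feature_level") %||% "probe"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an age vector
#'
#' The per-sample response of a clock model: chronological age in weeks
#' (gestational age) or years (lifespan age). Units drive the default initial
#' bin width of the distribution-balancing step (1 week or 1 year).
#'
#' @param ages Finite numeric vector.
#' @param sample_ids Character vector, same length, unique.
#' @param units `"weeks"` or `"years"`.
#' @return An object of class `age_vector` (a named numeric vector with a
#'   `units` attribute).
#' @export
age_vector <- function(ages, sample_ids = names(ages), units = c("weeks", "years")) {
  units <- match.arg(units)
  if (is.null(sample_ids)) stop("sample IDs are required")
  sample_ids <- as.character(sample_ids)
  ages <- as.numeric(ages)
  if (length(ages) != length(sample_ids))
    stop("length(ages) != length(sample_ids)")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample IDs in age vector")
  if (!all(is.finite(ages))) stop("ages must be finite")
  names(ages) <- sample_ids
  structure(ages, units = units, class = c("age_vector", "numeric"))
}

age_units <- function(ages) attr(ages, "units") %||% "years"

# Align an age vector to the column order of a beta matrix; errors on mismatch.
align_ages <- function(beta, ages) {
  sids <- colnames(beta)
  if (is.null(names(ages))) {
    if (length(ages) != ncol(beta)) stop("ages length != sample count")
    return(age_vector(as.numeric(ages), sids, units = age_units(ages)))
  }
  missing <- setdiff(sids, names(ages))
  if (length(missing))
    stop("samples without ages: ", paste(utils::head(missing, 5), collapse = ", "))
  age_vector(as.numeric(ages[sids]), sids, units = age_units(ages))
}

#' Read a beta matrix from delimited text
#'
#' Reads a TSV/CSV table with a header row and an ID column (the first
#' column), in either orientation, and canonicalizes it to features x samples.
#'
#' @param path File path to a delimited text file (separator auto-detected).
#' @param orientation `"features_in_rows"` (default; GEO series-matrix
#'   convention) or `"samples_in_rows"`.
#' @param feature_level Passed to [beta_matrix()].
#' @param impute Passed to [beta_matrix()]; default `FALSE` (missing values
#'   are a hard error rather than silently invented).
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, orientation = c("features_in_rows", "samples_in_rows"),
                             feature_level = c("probe", "gene", "dmr"),
                             impute = FALSE) {
  orientation <- match.arg(orientation)
  feature_level <- match.arg(feature_level)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(dt) < 2) stop("expected an ID column plus at least one data column")
  ids <- as.character(dt[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated row IDs in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  num <- dt[, -1, drop = FALSE]
  notnum <- !vapply(num, is.numeric, logical(1))
  if (any(notnum))
    stop("non-numeric columns: ", paste(names(num)[notnum], collapse = ", "))
  m <- as.matrix(num)
  rownames(m) <- ids
  if (orientation == "samples_in_rows") m <- t(m)
  beta_matrix(m, feature_level = feature_level, impute = impute)
}

#' Write a beta matrix to delimited text
#'
#' @param beta A [beta_matrix()].
#' @param path Output path; `.csv` extension selects comma separation,
#'   anything else tab.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  dt <- data.table::data.table(feature_id = rownames(beta))
  dt <- cbind(dt, data.table::as.data.table(unclass(beta)))
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

#' Read ages from delimited text
#'
#' Expects two columns: sample ID and age (header optional but recommended:
#' `sample_id,age`).
#'
#' @param path File path.
#' @param units `"weeks"` or `"years"`.
#' @return An [age_vector()].
#' @export
read_ages <- function(path, units = c("weeks", "years")) {
  units <- match.arg(units)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2) stop("expected columns: sample ID, age")
  age_vector(as.numeric(dt[[2]]), as.character(dt[[1]]), units = units)
}

VALID_REGION_GROUPS <- c("TSS200", "TSS1500", "1stExon", "5'UTR", "3'UTR", "Body")

#' Read an Illumina-style probe manifest
#'
#' Parses a manifest table with the columns `IlmnID`, `CHR`, `MAPINFO`,
#' `UCSC_RefGene_Name`, `UCSC_RefGene_Group`, and
#' `Relation_to_UCSC_CpG_Island`. Gene name and gene region-group columns may
#' hold several semicolon-separated entries; the two lists must align
#' pairwise and are exploded into one (gene, group) pair per entry.
#' Positions follow the Illumina MAPINFO convention: 1-based point
#' coordinates, with inter-probe distance the absolute position difference.
#'
#' @param path File path to the delimited manifest.
#' @return An object of class `manifest_table`: a list with `probes`
#'   (data.frame: probe_id, chromosome, position, island_relation) and
#'   `gene_map` (data.frame: probe_id, gene_name, region_group — one row per
#'   exploded gene entry).
#' @export
read_manifest <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  need <- c("IlmnID", "CHR", "MAPINFO", "UCSC_RefGene_Name",
            "UCSC_RefGene_Group", "Relation_to_UCSC_CpG_Island")
  missing <- setdiff(need, names(dt))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  manifest_table(
    probe_id = as.character(dt$IlmnID),
    chromosome = as.character(dt$CHR),
    position = dt$MAPINFO,
    gene_names = as.character(dt$UCSC_RefGene_Name),
    gene_groups = as.character(dt$UCSC_RefGene_Group),
    island_relation = as.character(dt$Relation_to_UCSC_CpG_Island)
  )
}

#' Construct a manifest table from vectors
#'
#' @param probe_id,chromosome,position,island_relation Per-probe vectors.
#' @param gene_names,gene_groups Semicolon-separated, pairwise-aligned gene
#'   name / region-group strings (may be `NA` or empty for intergenic probes).
#' @return A `manifest_table` (see [read_manifest()]).
#' @export
manifest_table <- function(probe_id, chromosome, position,
                           gene_names = NA_character_,
                           gene_groups = NA_character_,
                           island_relation = "OpenSea") {
  n <- length(probe_id)
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id))
    stop("duplicated probe IDs: ",
         paste(utils::head(unique(probe_id[duplicated(probe_id)]), 5), collapse = ", "))
  pos_num <- suppressWarnings(as.numeric(position))
  if (any(!is.finite(pos_num)) || any(pos_num != floor(pos_num)))
    stop("positions must be integers")
  position <- as.integer(pos_num)
  if (any(position < 1)) stop("positions must be >= 1 (1-based)")
  gene_names <- rep_len(as.character(gene_names), n)
  gene_groups <- rep_len(as.character(gene_groups), n)
  island_relation <- rep_len(as.character(island_relation), n)
  chromosome <- rep_len(as.character(chromosome), n)

  maps <- vector("list", n)
  for (i in seq_len(n)) {
    gn <- gene_names[i]; gg <- gene_groups[i]
    if (is.na(gn) || gn == "") next
    genes <- strsplit(gn, ";", fixed = TRUE)[[1]]
    groups <- if (is.na(gg)) character(0) else strsplit(gg, ";", fixed = TRUE)[[1]]
    if (length(genes) != length(groups))
      stop("probe '", probe_id[i], "': ", length(genes), " gene names but ",
           length(groups), " region groups")
    bad <- setdiff(groups, VALID_REGION_GROUPS)
    if (length(bad))
      stop("probe '", probe_id[i], "': unknown region group(s): ",
           paste(bad, collapse = ", "))
    maps[[i]] <- data.frame(probe_id = probe_id[i], gene_name = genes,
                            region_group = groups, stringsAsFactors = FALSE)
  }
  gene_map <- do.call(rbind, maps)
  if (is.null(gene_map))
    gene_map <- data.frame(probe_id = character(0), gene_name = character(0),
                           region_group = character(0), stringsAsFactors = FALSE)
  structure(list(
    probes = data.frame(probe_id = probe_id, chromosome = chromosome,
                        position = position, island_relation = island_relation,
                        stringsAsFactors = FALSE),
    gene_map = gene_map
  ), class = "manifest_table")
}

#' @export
print.manifest_table <- function(x, ...) {
  cat(sprintf("manifest_table: %d probes, %d gene entries, %d chromosomes\n",
              nrow(x$probes), nrow(x$gene_map), length(unique(x$probes$chromosome))))
  invisible(x)
}

MODEL_SCHEMA_VERSION <- 1L

#' Save a trained clock model as JSON
#'
#' Serializes an ensemble clock or a single elastic-net clock to a JSON
#' document with an explicit schema-version field. Coefficients and weights
#' are written at full floating precision, so a reloaded model predicts
#' identically to the original.
#'
#' @param model An `ensemble_clock` or `enet_learner`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "ensemble_clock")) {
    doc <- list(
      schema_version = MODEL_SCHEMA_VERSION,
      model_kind = model$model_kind,
      selected_features = model$selected_features,
      weights = model$weights,
      learners = lapply(model$learners, function(l) list(
        features = l$features, intercept = l$intercept,
        coefficients = as.list(l$coefficients), train_r2 = l$train_r2)),
      config = model$config
    )
  } else if (inherits(model, "enet_learner")) {
    doc <- list(
      schema_version = MODEL_SCHEMA_VERSION,
      model_kind = "normal",
      alpha = model$alpha, lambda = model$lambda,
      intercept = model$intercept,
      coefficients = as.list(model$coefficients),
      feature_universe = model$feature_universe,
      config = model$config
    )
  } else stop("unsupported model class: ", paste(class(model), collapse = "/"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a clock model saved by [save_model()]
#'
#' @param path Path to the JSON archive.
#' @return The reconstructed model object.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version) || doc$schema_version != MODEL_SCHEMA_VERSION)
    stop("unsupported model archive schema version: ",
         doc$schema_version %||% "missing")
  kind <- doc$model_kind
  if (is.null(kind) || !kind %in% c("balanced", "bootstrapped", "normal"))
    stop("unknown model_kind: ", kind %||% "missing")
  unlist_num <- function(x) vapply(x, as.numeric, numeric(1))
  if (kind %in% c("balanced", "bootstrapped")) {
    learners <- lapply(doc$learners, function(l) {
      structure(list(
        features = vapply(l$features, as.character, character(1)),
        intercept = as.numeric(l$intercept),
        coefficients = unlist_num(l$coefficients),
        train_r2 = as.numeric(l$train_r2)
      ), class = "linear_learner")
    })
    structure(list(
      model_kind = kind,
      learners = learners,
      weights = as.numeric(unlist(doc$weights)),
      selected_features = vapply(doc$selected_features, as.character, character(1)),
      config = doc$config
    ), class = "ensemble_clock")
  } else {
    structure(list(
      alpha = as.numeric(doc$alpha), lambda = as.numeric(doc$lambda),
      intercept = as.numeric(doc$intercept),
      coefficients = unlist_num(doc$coefficients),
      feature_universe = vapply(doc$feature_universe, as.character, character(1)),
      config = doc$config
    ), class = "enet_learner")
  }
}
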