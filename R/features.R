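#' Summarize probe beta values to gene beta values
#'
#' For each gene, the beta values of the probes annotated to it within the
#' chosen gene-region groups are averaged (unweighted mean, per sample) to
#' give the gene's beta value. The default groups — TSS200, TSS1500, and
#' 1stExon — capture promoter-proximal methylation; any subset of the six
#' Illumina region groups may be chosen. A probe annotated to several genes
#' contributes to each of them; a probe annotated to the same gene through
#' several qualifying groups is counted once. Genes with no qualifying probe
#' in the matrix are absent from the output.
#'
#' @param beta A probe-level [beta_matrix()].
#' @param manifest A `manifest_table` (see [read_manifest()]).
#' @param groups Character subset of
#'   `c("TSS200", "TSS1500", "1stExon", "5'UTR", "3'UTR", "Body")`.
#' @return A gene-level [beta_matrix()] (genes sorted by ID).
#' @export
probe_to_gene <- function(beta, manifest,
                          groups = c("TSS200", "TSS1500", "1stExon")) {
  if (feature_level(beta) != "probe") stop("input must be probe-level")
  if (!length(groups)) stop("empty region-group set")
  bad <- setdiff(groups, VALID_REGION_GROUPS)
  if (length(bad)) stop("unknown region group(s): ", paste(bad, collapse = ", "))
  gm <- manifest$gene_map
  gm <- gm[gm$region_group %in% groups & gm$probe_id %in% rownames(beta), ,
           drop = FALSE]
  gm <- unique(gm[, c("probe_id", "gene_name")])
  if (!nrow(gm))
    stop("no gene has a qualifying probe in the chosen groups")
  genes <- sort(unique(gm$gene_name))
  vals <- t(vapply(genes, function(g) {
    probes <- gm$probe_id[gm$gene_name == g]
    colMeans(unclass(beta)[probes, , drop = FALSE])
  }, numeric(ncol(beta))))
  if (ncol(beta) == 1) vals <- matrix(vals, ncol = 1)  # vapply drops to vector
  rownames(vals) <- genes
  colnames(vals) <- colnames(beta)
  beta_matrix(vals, feature_level = "gene")
}

#' Cluster probes into DMRs and summarize beta values per DMR
#'
#' Probes are sorted by genomic position within each chromosome; two
#' consecutive probes with a positional gap strictly less than `max_gap`
#' (default 500 bp) join the same cluster, a gap of `max_gap` or more starts
#' a new one, and each cluster — singletons included — is a DMR. The DMR beta
#' value per sample is the unweighted mean over its member probes. Positions
#' are 1-based points (Illumina MAPINFO); the reported DMR span is
#' \[min, max\] of member positions, inclusive.
#'
#' @param beta A probe-level [beta_matrix()]. Probes absent from the manifest
#'   are dropped with a warning.
#' @param manifest A `manifest_table`.
#' @param max_gap Gap threshold in bp; default 500. Must be positive.
#' @return List with `beta` (a dmr-level [beta_matrix()]) and `dmr_table`
#'   (data.frame: dmr_id, chromosome, start, end, n_probes, probe_ids
#'   (semicolon-joined in position order), genes (semicolon-joined union of
#'   member probes' gene names)).
#' @export
probe_to_dmr <- function(beta, manifest, max_gap = 500L) {
  if (feature_level(beta) != "probe") stop("input must be probe-level")
  if (max_gap <= 0) stop("max_gap must be positive")
  pr <- manifest$probes
  present <- rownames(beta) %in% pr$probe_id
  if (!all(present)) {
    warning(sum(!present), " probe(s) absent from the manifest were dropped")
    if (!any(present)) stop("no probe in the matrix is in the manifest")
  }
  ann <- pr[match(rownames(beta)[present], pr$probe_id), ]
  ann <- ann[order(ann$chromosome, ann$position, ann$probe_id), ]
  new_cluster <- c(TRUE, ann$chromosome[-1] != ann$chromosome[-nrow(ann)] |
                     diff(ann$position) >= max_gap)
  cluster <- cumsum(new_cluster)
  gm <- manifest$gene_map
  rows <- lapply(split(seq_len(nrow(ann)), cluster), function(ix) {
    a <- ann[ix, ]
    genes <- sort(unique(gm$gene_name[gm$probe_id %in% a$probe_id]))
    data.frame(
      chromosome = a$chromosome[1],
      start = min(a$position), end = max(a$position),
      n_probes = nrow(a),
      probe_ids = paste(a$probe_id, collapse = ";"),
      genes = paste(genes, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- cbind(dmr_id = paste0(tab$chromosome, ":", tab$start, "-", tab$end),
               tab)
  rownames(tab) <- NULL
  vals <- t(vapply(strsplit(tab$probe_ids, ";", fixed = TRUE), function(p)
    colMeans(unclass(beta)[p, , drop = FALSE]), numeric(ncol(beta))))
  if (ncol(beta) == 1) vals <- matrix(vals, ncol = 1)
  rownames(vals) <- tab$dmr_id
  colnames(vals) <- colnames(beta)
  list(beta = beta_matrix(vals, feature_level = "dmr"), dmr_table = tab)
}

#' Annotate model-selected features from the manifest
#'
#' Resolves a set of selected feature IDs to genomic annotation records at
#' the appropriate level: probes get chromosome, position, CpG-island
#' relation, and their gene/region-group pairs; genes get the positional
#' span \[min, max\] of their qualifying probes plus the member probe list;
#' DMRs get their `dmr_table` row. IDs that cannot be resolved are returned
#' in an `unannotated` attribute rather than raising an error.
#'
#' @param ids Character vector of feature IDs.
#' @param level `"probe"`, `"gene"`, or `"dmr"`.
#' @param manifest A `manifest_table` (required for probes and genes).
#' @param dmr_table The `dmr_table` from [probe_to_dmr()] (required for
#'   DMRs).
#' @param groups Region groups defining gene membership (gene level only);
#'   default `c("TSS200", "TSS1500", "1stExon")`.
#' @return A data.frame of annotation records (one row per resolved ID, in
#'   input order) with attribute `unannotated` listing unresolved IDs.
#' @export
annotate_features <- function(ids, level = c("probe", "gene", "dmr"),
                              manifest = NULL, dmr_table = NULL,
                              groups = c("TSS200", "TSS1500", "1stExon")) {
  level <- match.arg(level)
  ids <- as.character(ids)
  if (level == "probe") {
    if (is.null(manifest)) stop("a manifest is required to annotate probes")
    pr <- manifest$probes
    hit <- ids %in% pr$probe_id
    a <- pr[match(ids[hit], pr$probe_id), ]
    gm <- manifest$gene_map
    pairs <- vapply(a$probe_id, function(p) {
      g <- gm[gm$probe_id == p, ]
      if (!nrow(g)) "" else paste(g$gene_name, g$region_group,
                                  sep = ":", collapse = ";")
    }, character(1))
    out <- data.frame(feature_id = a$probe_id, chromosome = a$chromosome,
                      position = a$position,
                      island_relation = a$island_relation,
                      genes = unname(pairs), stringsAsFactors = FALSE)
  } else if (level == "gene") {
    if (is.null(manifest)) stop("a manifest is required to annotate genes")
    gm <- manifest$gene_map
    gm <- gm[gm$region_group %in% groups, , drop = FALSE]
    pr <- manifest$probes
    hit <- ids %in% gm$gene_name
    out <- do.call(rbind, lapply(ids[hit], function(g) {
      probes <- unique(gm$probe_id[gm$gene_name == g])
      pa <- pr[pr$probe_id %in% probes, ]
      data.frame(feature_id = g, chromosome = pa$chromosome[1],
                 start = min(pa$position), end = max(pa$position),
                 n_probes = nrow(pa),
                 probe_ids = paste(sort(pa$probe_id), collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(out))
      out <- data.frame(feature_id = character(0), chromosome = character(0),
                        start = integer(0), end = integer(0),
                        n_probes = integer(0), probe_ids = character(0),
                        stringsAsFactors = FALSE)
  } else {
    if (is.null(dmr_table)) stop("a dmr_table is required to annotate DMRs")
    hit <- ids %in% dmr_table$dmr_id
    out <- dmr_table[match(ids[hit], dmr_table$dmr_id), ]
    rownames(out) <- NULL
  }
  attr(out, "unannotated") <- ids[!hit]
  out
}

#' Extract the features selected by a trained clock model
#'
#' @param model An `ensemble_clock` (integrated selected features) or an
#'   `enet_learner` (features with nonzero coefficients).
#' @return Character vector of feature IDs.
#' @export
extract_features <- function(model) {
  if (inherits(model, "ensemble_clock")) model$selected_features
  else if (inherits(model, "enet_learner")) names(model$coefficients)
  else stop("unsupported model class: ", paste(class(model), collapse = "/"))
}

#' Write a DMR table as a BED-like TSV
#'
#' Columns: chrom, start, end, id, probes, genes. Coordinates are the
#' 1-based inclusive point positions from the manifest (not 0-based BED),
#' as documented in the header comment line.
#'
#' @param dmr_table From [probe_to_dmr()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_table <- function(dmr_table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive probe positions (Illumina MAPINFO)", con)
  utils::write.table(
    dmr_table[, c("chromosome", "start", "end", "dmr_id", "probe_ids", "genes")],
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
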