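# One-call orchestration of the comparative pipeline:
# filter -> greedy cluster per family -> presence matrices -> Jaccard ->
# merge -> hierarchical clustering -> cut at k -> phenotype concordance.
# Every stage result is returned (and optionally persisted with a manifest
# echoing the resolved configuration), so runs are reproducible and
# auditable.

#' Run the full profiling pipeline
#'
#' @param records Record tibble covering one or more families (a `family`
#'   column is required), e.g. row-bound outputs of [read_fasta()] or
#'   `simulate_dataset()$records`.
#' @param labels Optional label tibble (`species`, `label`).  When absent,
#'   the concordance stage is skipped with a warning.
#' @param threshold_pct Identity threshold for greedy clustering (default
#'   60).
#' @param k Number of species clusters to cut (default 10).
#' @param linkage Linkage for hierarchical clustering (default average).
#' @param merge_mode `"average"`: element-wise mean of per-family Jaccard
#'   matrices; `"concat"`: concatenate binary profiles, one Jaccard.
#' @param tie_rule Majority-vote tie policy (see [majority_vote_map()]).
#' @param assign Centroid assignment rule (see [greedy_cluster()]).
#' @param apply_filters Run [filter_records()] first (default TRUE).
#' @param out_dir Optional directory; when given, every intermediate is
#'   written (cluster tables, presence and distance matrices as TSV, the
#'   dendrogram as Newick, the partition and report, and a JSON manifest).
#' @return An object of class `pipeline_result`: list with `clusterings`
#'   (per family), `presence` (per family), `distances` (per family),
#'   `merged` (species_dist), `dendrogram`, `partition`, `report` (or NULL),
#'   `filter_counts` and `config`.
#' @export
run_pipeline <- function(records, labels = NULL,
                         threshold_pct = 60, k = 10,
                         linkage = "average",
                         merge_mode = c("average", "concat"),
                         tie_rule = "noncleaver",
                         assign = "first",
                         apply_filters = TRUE,
                         out_dir = NULL) {
  merge_mode <- match.arg(merge_mode)
  check_records(records)
  if (!"family" %in% names(records)) abort("`records` must have a family column")

  fcounts <- c(fragment = 0L, multispecies = 0L)
  if (apply_filters) {
    records <- filter_records(records)
    fcounts <- filter_counts(records)
  }
  fams <- unique(records$family)
  canonical_species <- sort(unique(records$species))

  clusterings <- lapply(fams, function(f) {
    greedy_cluster(records[records$family == f, ],
      threshold_pct = threshold_pct, assign = assign
    )
  })
  names(clusterings) <- fams
  presence <- lapply(clusterings, build_presence_matrix, canonical_species = canonical_species)
  distances <- lapply(presence, jaccard_distances)
  merged <- if (merge_mode == "average") {
    merge_distance_matrices(distances)
  } else {
    jaccard_distances(concat_presence_matrices(presence))
  }
  dendro <- hierarchical_cluster(merged, linkage = linkage)
  partition <- cut_dendrogram(dendro, k = k)

  report <- NULL
  if (is.null(labels)) {
    warn("no labels supplied; skipping the concordance stage")
  } else {
    report <- majority_vote_map(partition, labels, tie_rule = tie_rule)
  }

  config <- list(
    threshold_pct = threshold_pct, k = k, linkage = linkage,
    merge_mode = merge_mode, tie_rule = tie_rule, assign = assign,
    apply_filters = apply_filters, families = fams,
    n_species = length(canonical_species), n_records = nrow(records)
  )
  result <- structure(
    list(
      clusterings = clusterings, presence = presence, distances = distances,
      merged = merged, dendrogram = dendro, partition = partition,
      report = report, filter_counts = fcounts, config = config
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' Persist every pipeline stage to a directory
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  if (!inherits(result, "pipeline_result")) abort("`result` must be a pipeline_result")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in names(result$clusterings)) {
    write_cluster_table(result$clusterings[[f]], file.path(dir, paste0("clusters_", f, ".tsv")))
    write_matrix_tsv(result$presence[[f]], file.path(dir, paste0("presence_", f, ".tsv")))
    write_matrix_tsv(result$distances[[f]], file.path(dir, paste0("jaccard_", f, ".tsv")))
  }
  write_matrix_tsv(result$merged, file.path(dir, "merged_distance.tsv"))
  write_newick(result$dendrogram, file.path(dir, "dendrogram.nwk"))
  write.table(result$partition, file.path(dir, "partition.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(result$report)) {
    write_concordance_report(result$report, file.path(dir, "concordance.tsv"))
  }
  jsonlite::write_json(result$config, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "Pipeline over %d species, families %s: threshold %g%%, k=%d, %s linkage, merge=%s\n",
    x$config$n_species, paste(x$config$families, collapse = "+"),
    x$config$threshold_pct, x$config$k, x$config$linkage, x$config$merge_mode
  ))
  for (f in names(x$clusterings)) {
    g <- glance(x$clusterings[[f]])
    cat(sprintf("  %s: %d sequences -> %d clusters\n", f, g$n_records, g$n_clusters))
  }
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
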