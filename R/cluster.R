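# Greedy centroid (UCLUST-style) clustering of one enzyme family's protein
# sequences.  Records are processed in length-descending order (ties broken
# by id, ascending); each record joins the first existing centroid it matches
# at or above the identity threshold, otherwise it founds a new centroid.
# No k-mer prefilter: every candidate is aligned exactly against the
# centroids, which removes a heuristic degree of freedom at desk scale.

#' Greedy centroid clustering of an enzyme family
#'
#' @param records Record tibble; all rows must share one non-empty `family`.
#' @param threshold_pct Identity acceptance threshold in (0, 100].
#' @param assign `"first"` (UCLUST convention: join the first centroid at or
#'   above threshold, in centroid discovery order) or `"best"` (join the
#'   highest-identity centroid at or above threshold; ties go to the earlier
#'   centroid).
#' @param gap_open,gap_extend,substitution_matrix Alignment scoring passed to
#'   the global aligner (see [align_global()]).
#' @return An object of class `family_clustering`: a list with `family`,
#'   `threshold_pct`, `assign`, `centroids` (tibble: `cluster`,
#'   `centroid_id`) and `members` (tibble: `cluster`, `role`, `id`,
#'   `species`, `identity_to_centroid`).  `tidy()` returns the member table,
#'   `glance()` a one-row summary.
#' @examples
#' recs <- tibble::tibble(
#'   id = c("a", "b"), species = "Bacteroides sp.", strain = NA,
#'   family = "PL8", description = "", residues = c("MKLVRAAE", "MKLVRAAE")
#' )
#' glance(greedy_cluster(recs, threshold_pct = 60))$n_clusters # 1
#' @export
greedy_cluster <- function(records, threshold_pct = 60,
                           assign = c("first", "best"),
                           gap_open = 11, gap_extend = 1,
                           substitution_matrix = NULL) {
  assign <- match.arg(assign)
  check_records(records)
  if (nrow(records) == 0) abort("`records` is empty")
  if (!("family" %in% names(records))) abort("`records` must carry a family column")
  fams <- unique(records$family)
  if (length(fams) != 1 || is.na(fams) || !nzchar(fams)) {
    abort(paste0("all records must share one non-empty family; got: ", paste(fams, collapse = ", ")))
  }
  if (!is.numeric(threshold_pct) || threshold_pct <= 0 || threshold_pct > 100) {
    abort("`threshold_pct` must be in (0, 100]")
  }
  if (!("species" %in% names(records))) records$species <- NA_character_

  ord <- order(-nchar(records$residues), records$id)
  recs <- records[ord, , drop = FALSE]

  cent_idx <- integer()       # row index (in recs) of each centroid
  member_of <- integer(nrow(recs))
  ident <- numeric(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    hit <- 0L
    if (length(cent_idx) > 0) {
      ids <- align_many(
        recs$residues[cent_idx], recs$residues[i],
        type = "global", gap_open = gap_open, gap_extend = gap_extend,
        substitution_matrix = substitution_matrix
      )$identity_pct
      ok <- which(ids >= threshold_pct)
      if (length(ok) > 0) {
        hit <- if (assign == "first") ok[1] else ok[which.max(ids[ok])]
      }
    }
    if (hit > 0L) {
      member_of[i] <- hit
      ident[i] <- ids[hit]
    } else {
      cent_idx <- c(cent_idx, i)
      member_of[i] <- length(cent_idx)
      ident[i] <- 100
    }
  }

  members <- tibble(
    cluster = member_of,
    role = ifelse(seq_len(nrow(recs)) %in% cent_idx, "centroid", "member"),
    id = recs$id,
    species = recs$species,
    identity_to_centroid = ident
  ) |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$role == "centroid"), .data$id)
  structure(
    list(
      family = fams,
      threshold_pct = threshold_pct,
      assign = assign,
      centroids = tibble(cluster = seq_along(cent_idx), centroid_id = recs$id[cent_idx]),
      members = members
    ),
    class = "family_clustering"
  )
}

#' @exportS3Method generics::tidy
tidy.family_clustering <- function(x, ...) x$members

#' @exportS3Method generics::glance
glance.family_clustering <- function(x, ...) {
  sizes <- table(x$members$cluster)
  tibble(
    family = x$family,
    threshold_pct = x$threshold_pct,
    n_records = nrow(x$members),
    n_clusters = nrow(x$centroids),
    max_cluster_size = as.integer(max(sizes))
  )
}

#' @export
print.family_clustering <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Greedy clustering of family %s at %g%% identity: %d records in %d clusters (largest %d)\n",
    g$family, g$threshold_pct, g$n_records, g$n_clusters, g$max_cluster_size
  ))
  invisible(x)
}

#' Cluster-count sweep over identity thresholds
#'
#' Runs [greedy_cluster()] at each threshold and tabulates the number of
#' clusters and the largest cluster size.  The default grid is 40-80% in
#' steps of 10.
#'
#' @inheritParams greedy_cluster
#' @param thresholds Numeric vector of identity thresholds in (0, 100].
#' @return A tibble of class `threshold_sweep` with columns `threshold_pct`,
#'   `n_clusters`, `max_cluster_size`.
#' @export
sweep_thresholds <- function(records, thresholds = seq(40, 80, by = 10),
                             assign = "first",
                             gap_open = 11, gap_extend = 1,
                             substitution_matrix = NULL) {
  if (any(thresholds <= 0 | thresholds > 100)) abort("`thresholds` must be in (0, 100]")
  rows <- purrr::map(thresholds, function(t) {
    glance(greedy_cluster(records, t,
      assign = assign, gap_open = gap_open,
      gap_extend = gap_extend, substitution_matrix = substitution_matrix
    ))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::select("threshold_pct", "n_clusters", "max_cluster_size")
  class(out) <- c("threshold_sweep", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.threshold_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$threshold_pct, .data$n_clusters)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "identity threshold (%)", y = "number of clusters",
      title = "Greedy clustering resolution across identity thresholds"
    )
}

#' Export a clustering as a flat cluster table
#'
#' Tab-delimited table with columns cluster, role, record id, species and
#' identity to centroid, mirroring a UC-style flat file.
#'
#' @param clustering A `family_clustering` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clustering, path) {
  write.table(tidy(clustering), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
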