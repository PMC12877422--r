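# Hierarchical clustering of species on a merged Jaccard distance matrix,
# and cutting the dendrogram into k labelled groups.  Average linkage
# (UPGMA) is the default; Ward is refused because it presumes squared
# Euclidean geometry, which Jaccard distances do not have.

#' Hierarchical clustering of species
#'
#' Agglomerative clustering of a `species_dist` matrix via [stats::hclust()].
#'
#' @param dist A `species_dist` matrix ([jaccard_distances()] or
#'   [merge_distance_matrices()]).
#' @param linkage One of `"average"` (UPGMA, default), `"complete"`,
#'   `"single"`.  Ward linkage is rejected.
#' @return An object of class `species_dendrogram`: list with the `hclust`
#'   fit, the linkage and the species.
#' @export
hierarchical_cluster <- function(dist, linkage = c("average", "complete", "single")) {
  if (is.character(linkage) && any(grepl("^ward", linkage)) && length(linkage) == 1) {
    abort("Ward linkage is not meaningful on Jaccard distances; use average/complete/single")
  }
  linkage <- match.arg(linkage)
  if (!inherits(dist, "species_dist")) abort("`dist` must be a species_dist matrix")
  if (nrow(dist) < 2) abort("need at least 2 species to cluster")
  h <- hclust(as.dist(unclass(dist)), method = linkage)
  structure(
    list(hclust = h, linkage = linkage, species = rownames(dist)),
    class = "species_dendrogram"
  )
}

#' Cut a species dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges and labels the resulting groups C1..Ck in
#' dendrogram leaf order, so labels are reproducible across runs and
#' comparable to a plotted tree up to relabeling.
#'
#' @param dendro A `species_dendrogram`.
#' @param k Number of clusters, between 1 and the number of species.
#' @return A partition tibble with columns `species` and `cluster`
#'   (factor C1..Ck).
#' @export
cut_dendrogram <- function(dendro, k) {
  if (!inherits(dendro, "species_dendrogram")) abort("`dendro` must be a species_dendrogram")
  n <- length(dendro$species)
  if (!is.numeric(k) || k < 1 || k > n) abort(paste0("`k` must be in [1, ", n, "]"))
  grp <- cutree(dendro$hclust, k = k)
  leaf_order <- dendro$hclust$labels[dendro$hclust$order]
  first_seen <- unique(grp[leaf_order])
  relabel <- setNames(paste0("C", seq_along(first_seen)), first_seen)
  tibble(
    species = names(grp),
    cluster = factor(relabel[as.character(grp)], levels = paste0("C", seq_len(k)))
  )
}

#' Export a species dendrogram in Newick format
#'
#' Merge heights become branch lengths via [ape::as.phylo()].
#'
#' @param dendro A `species_dendrogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendro, path) {
  if (!inherits(dendro, "species_dendrogram")) abort("`dendro` must be a species_dendrogram")
  ape::write.tree(ape::as.phylo(dendro$hclust), file = path)
  invisible(path)
}

#' @export
print.species_dendrogram <- function(x, ...) {
  cat(sprintf(
    "Species dendrogram (%s linkage) over %d species; merge heights %.3f-%.3f\n",
    x$linkage, length(x$species), min(x$hclust$height), max(x$hclust$height)
  ))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.species_dendrogram <- function(object, ...) {
  h <- object$hclust
  n <- length(h$labels)
  # x position of each observation = its rank in the leaf order
  leaf_x <- setNames(seq_len(n), h$order)
  node_x <- numeric(nrow(h$merge))
  node_y <- h$height
  xc <- function(id) if (id < 0) leaf_x[as.character(-id)] else node_x[id]
  yc <- function(id) if (id < 0) 0 else node_y[id]
  segs <- vector("list", nrow(h$merge))
  for (i in seq_len(nrow(h$merge))) {
    a <- h$merge[i, 1]
    b <- h$merge[i, 2]
    xa <- xc(a)
    xb <- xc(b)
    node_x[i] <- (xa + xb) / 2
    segs[[i]] <- tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(yc(a), yc(b), node_y[i]), yend = c(node_y[i], node_y[i], node_y[i])
    )
  }
  labs <- tibble(x = unname(leaf_x), label = h$labels[h$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = dplyr::bind_rows(segs),
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend)
    ) +
    ggplot2::geom_text(
      data = labs,
      ggplot2::aes(x = .data$x, y = 0, label = .data$label),
      angle = 90, hjust = 1.05, size = 2.5
    ) +
    ggplot2::scale_y_continuous("merge height (Jaccard distance)") +
    ggplot2::scale_x_continuous(NULL, breaks = NULL) +
    ggplot2::coord_cartesian(clip = "off") +
    ggplot2::theme_minimal()
}
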