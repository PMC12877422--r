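# Species-by-cluster presence/absence profiles and Jaccard distances.
#
# A presence matrix is a tibble whose first column is `species` (in the
# canonical order shared across families) followed by one binary column per
# sequence cluster, named <family>_C<k> in centroid discovery order.  A cell
# is 1 iff at least one sequence of that species fell in that cluster
# (presence, not paralog count).

#' Build a species x cluster presence/absence matrix
#'
#' @param clustering A `family_clustering` from [greedy_cluster()].
#' @param canonical_species Ordered character vector of species shared across
#'   families; must cover every species in the clustering.  Species without
#'   any sequence in this family get all-zero rows.
#' @return A tibble of class `presence_matrix`: column `species` plus one
#'   binary integer column per cluster, with attribute `"family"`.
#' @export
build_presence_matrix <- function(clustering, canonical_species) {
  if (!inherits(clustering, "family_clustering")) abort("`clustering` must be a family_clustering")
  mem <- clustering$members
  missing <- setdiff(unique(mem$species[!is.na(mem$species)]), canonical_species)
  if (length(missing) > 0) {
    abort(paste0(
      "species in clustering absent from canonical list: ",
      paste(missing, collapse = ", ")
    ))
  }
  k <- nrow(clustering$centroids)
  m <- matrix(0L, nrow = length(canonical_species), ncol = k)
  hit <- unique(mem[!is.na(mem$species), c("species", "cluster")])
  m[cbind(match(hit$species, canonical_species), hit$cluster)] <- 1L
  colnames(m) <- paste0(clustering$family, "_C", seq_len(k))
  out <- dplyr::bind_cols(tibble(species = canonical_species), as_tibble(m))
  class(out) <- c("presence_matrix", class(out))
  attr(out, "family") <- clustering$family
  out
}

presence_as_matrix <- function(presence) {
  if (!is.data.frame(presence) || names(presence)[1] != "species") {
    abort("`presence` must be a presence matrix tibble (first column species)")
  }
  m <- as.matrix(presence[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- presence$species
  m
}

#' Jaccard distance matrix between species presence profiles
#'
#' `d(i, j) = 1 - |row_i AND row_j| / |row_i OR row_j|`.  Two all-zero
#' profiles are at distance 0; an all-zero profile is at distance 1 from any
#' non-empty profile.  This convention keeps species that lack a family
#' entirely placeable in the species tree.
#'
#' @param presence A presence matrix ([build_presence_matrix()]), or any
#'   tibble with a leading `species` column and binary columns.
#' @return A symmetric numeric matrix of class `species_dist` with species
#'   dimnames, entries in \[0, 1\] and zero diagonal.
#' @export
jaccard_distances <- function(presence) {
  m <- presence_as_matrix(presence)
  inter <- tcrossprod(m)
  rs <- rowSums(m)
  union <- outer(rs, rs, "+") - inter
  d <- ifelse(union > 0, 1 - inter / union, 0)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  class(d) <- c("species_dist", class(d))
  d
}

#' Merge per-family distance matrices by (weighted) element-wise mean
#'
#' @param matrices List of `species_dist` matrices over the same species in
#'   the same order.
#' @param weights Optional non-negative weights, one per matrix (default
#'   equal).
#' @return A single `species_dist` matrix.
#' @export
merge_distance_matrices <- function(matrices, weights = NULL) {
  if (length(matrices) == 0) abort("`matrices` is empty")
  sp <- rownames(matrices[[1]])
  for (m in matrices) {
    if (!identical(rownames(m), sp)) abort("species order mismatch across distance matrices")
  }
  if (is.null(weights)) weights <- rep(1, length(matrices))
  if (length(weights) != length(matrices) || any(weights < 0) || sum(weights) == 0) {
    abort("`weights` must be non-negative, one per matrix, not all zero")
  }
  acc <- Reduce(`+`, purrr::map2(matrices, weights, function(m, w) unclass(m) * w))
  d <- acc / sum(weights)
  class(d) <- c("species_dist", class(d))
  d
}

#' Concatenate presence matrices across families
#'
#' Alternative merge mode: bind the per-family binary profiles column-wise
#' and compute a single Jaccard distance on the concatenated profiles.
#'
#' @param presences List of presence matrices over the same canonical species
#'   order.
#' @return A combined presence matrix tibble.
#' @export
concat_presence_matrices <- function(presences) {
  if (length(presences) == 0) abort("`presences` is empty")
  sp <- presences[[1]]$species
  for (p in presences) {
    if (!identical(p$species, sp)) abort("species order mismatch across presence matrices")
  }
  cols <- purrr::map(presences, function(p) p[, -1, drop = FALSE])
  out <- dplyr::bind_cols(tibble(species = sp), cols)
  class(out) <- c("presence_matrix", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.species_dist <- function(x, ...) {
  sp <- rownames(x)
  as_tibble(as.data.frame(as.table(unclass(x)))) |>
    setNames(c("species_a", "species_b", "distance")) |>
    dplyr::mutate(dplyr::across(1:2, as.character))
}

#' Write a presence or distance matrix as TSV
#'
#' @param x A presence matrix tibble or a `species_dist` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  if (inherits(x, "species_dist")) {
    df <- data.frame(species = rownames(x), unclass(x), check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
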