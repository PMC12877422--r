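# Agreement between the species partition and literature phenotype labels.
#
# Labels are Cleaver / NonCleaver / Mixed / NA.  Mixed and NA species are
# excluded before any metric is computed.  ARI and NMI compare the cluster
# partition against the binary phenotype partition on the labeled subset;
# the majority-vote map turns clusters into predicted phenotypes, with
# Cleaver as the positive class throughout.

LABEL_LEVELS <- c("Cleaver", "NonCleaver", "Mixed")

normalize_label <- function(x) {
  key <- gsub("[^a-z]", "", tolower(x))
  out <- dplyr::case_when(
    key == "cleaver" ~ "Cleaver",
    key %in% c("noncleaver", "nondegrader") ~ "NonCleaver",
    key == "mixed" ~ "Mixed",
    key %in% c("na", "") | is.na(x) ~ NA_character_,
    TRUE ~ "unknown"
  )
  out
}

#' Load a species-to-phenotype label table
#'
#' Reads a two-column tab-delimited file (species, label), with or without a
#' header row.  Labels are case-normalized to Cleaver / NonCleaver / Mixed;
#' `NA`, empty or unrecognized strings become `NA` (unrecognized ones with a
#' warning).  Duplicate species rows with conflicting labels are an error.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `species` and `label` (`NA` for no label).
#' @export
load_labels <- function(path) {
  if (!file.exists(path)) abort(paste0("label file not found: ", path))
  raw <- tryCatch(
    read.delim(path, header = FALSE, colClasses = "character", na.strings = NULL),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0) {
    return(tibble(species = character(), label = character()))
  }
  if (ncol(raw) < 2) abort(paste0("label file must have two tab-delimited columns: ", path))
  raw <- raw[, 1:2]
  names(raw) <- c("species", "label")
  # header detection: first row's label does not normalize to anything known
  first <- normalize_label(raw$label[1])
  if (identical(first, "unknown") && tolower(raw$label[1]) %in% c("label", "phenotype")) {
    raw <- raw[-1, , drop = FALSE]
  }
  norm <- normalize_label(raw$label)
  if (any(norm == "unknown", na.rm = TRUE)) {
    bad <- unique(raw$label[which(norm == "unknown")])
    warn(paste0("unrecognized label(s) treated as NA: ", paste(bad, collapse = ", ")))
    norm[which(norm == "unknown")] <- NA_character_
  }
  out <- tibble(species = trimws(raw$species), label = norm)
  dup <- out |>
    dplyr::distinct() |>
    dplyr::count(.data$species) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "conflicting labels for species: ",
      paste(dup$species, collapse = ", ")
    ))
  }
  dplyr::distinct(out)
}

partition_vector <- function(p, arg = "partition") {
  if (is.data.frame(p)) {
    if (!all(c("species", "cluster") %in% names(p))) {
      abort(paste0("`", arg, "` tibble must have columns species and cluster"))
    }
    return(setNames(as.character(p$cluster), p$species))
  }
  if (is.null(names(p))) abort(paste0("`", arg, "` vector must be named by species"))
  setNames(as.character(p), names(p))
}

#' Adjusted Rand Index between two partitions
#'
#' Hubert-Arabie chance-corrected Rand index computed from the contingency
#' table.  Equals 1 for identical partitions and has expectation 0 for random
#' independent labelings.  When the index is degenerate (both partitions
#' place all pairs identically, e.g. two single-cluster partitions), 1 is
#' returned for identical partitions and 0 otherwise, with a warning.
#'
#' @param p,q Partition tibbles (`species`, `cluster`) over the same species,
#'   or equal-length label vectors (paired by position, or by species names
#'   when both are named).
#' @return A single numeric value.
#' @export
adjusted_rand_index <- function(p, q) {
  pq <- align_partitions(p, q)
  x <- pq$x
  y <- pq$y
  n <- length(x)
  if (n < 2) abort("need at least 2 species to compare partitions")
  tab <- table(x, y)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- ch2(as.vector(tab))
  sum_a <- ch2(rowSums(tab))
  sum_b <- ch2(colSums(tab))
  total <- n * (n - 1) / 2
  expected <- sum_a * sum_b / total
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) {
    warn("degenerate partitions for ARI; returning 1 if identical else 0")
    return(if (same_partition(x, y)) 1 else 0)
  }
  (sum_ij - expected) / denom
}

#' Normalized Mutual Information between two partitions
#'
#' Mutual information of the two labelings normalized by a mean of the two
#' entropies (arithmetic by default).  Lies in \[0, 1\]; equals 1 for
#' identical partitions up to relabeling.  When both entropies are zero the
#' partitions are both trivial: 1 is returned if they are identical else 0,
#' with a warning.
#'
#' @inheritParams adjusted_rand_index
#' @param normalization `"arithmetic"` (default), `"geometric"`, `"min"` or
#'   `"max"` mean of the two entropies.
#' @return A single numeric value in \[0, 1\].
#' @export
normalized_mutual_information <- function(p, q,
                                          normalization = c("arithmetic", "geometric", "min", "max")) {
  normalization <- match.arg(normalization)
  pq <- align_partitions(p, q)
  x <- pq$x
  y <- pq$y
  n <- length(x)
  if (n < 2) abort("need at least 2 species to compare partitions")
  joint <- table(x, y) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 && hy == 0) {
    warn("both partitions trivial for NMI; returning 1 if identical else 0")
    return(if (same_partition(x, y)) 1 else 0)
  }
  norm <- switch(normalization,
    arithmetic = (hx + hy) / 2,
    geometric = sqrt(hx * hy),
    min = min(hx, hy),
    max = max(hx, hy)
  )
  if (norm == 0) {
    return(0)
  }
  min(max(mi / norm, 0), 1)
}

# identical up to relabeling: first-occurrence canonical coding
same_partition <- function(x, y) {
  identical(
    unname(as.integer(factor(x, levels = unique(x)))),
    unname(as.integer(factor(y, levels = unique(y))))
  )
}

align_partitions <- function(p, q) {
  x <- partition_vector(p, "p")
  y <- partition_vector(q, "q")
  if (!is.null(names(x)) && !is.null(names(y)) &&
    all(nzchar(names(x))) && all(nzchar(names(y)))) {
    common <- intersect(names(x), names(y))
    if (length(common) != length(x) || length(common) != length(y)) {
      abort("partitions must cover the same species set")
    }
    y <- y[names(x)]
  } else if (length(x) != length(y)) {
    abort("partitions must have the same length")
  }
  list(x = unname(x), y = unname(y))
}

#' Majority-vote concordance between a partition and phenotype labels
#'
#' Mixed/NA species are excluded first.  Each cluster is mapped to the
#' phenotype held by the majority of its labeled members; ties are resolved
#' by `tie_rule` (default: predict NonCleaver, the conservative choice for a
#' Cleaver-positive evaluation; alternatives: predict Cleaver, or exclude the
#' tied cluster's species from the confusion counts).  Clusters with no
#' labeled members are marked Unlabeled and contribute no evaluated species.
#' Every labeled species in a mapped cluster receives its cluster's predicted
#' label; precision, recall, F1 and accuracy are computed with Cleaver as the
#' positive class.  ARI and NMI compare the cluster partition with the binary
#' phenotype partition over all labeled species.
#'
#' @param partition Partition tibble (`species`, `cluster`) from
#'   [cut_dendrogram()].
#' @param labels Label tibble (`species`, `label`) from [load_labels()] or
#'   the simulator.  Species missing from `labels` count as NA.
#' @param tie_rule `"noncleaver"`, `"cleaver"` or `"exclude"`.
#' @return An object of class `concordance_report`: list with `ari`, `nmi`,
#'   `cluster_map` (tibble: cluster, n_cleaver, n_noncleaver, mapped_label),
#'   `predictions` (per labeled species), `confusion` (TP/FP/FN/TN),
#'   `precision`, `recall`, `f1`, `accuracy`, `n_labeled`, `n_excluded`,
#'   `n_evaluated` and `tie_rule`.  `glance()` returns the metrics as one
#'   row; `tidy()` the cluster map.
#' @export
majority_vote_map <- function(partition, labels,
                              tie_rule = c("noncleaver", "cleaver", "exclude")) {
  if (is.character(tie_rule) && length(tie_rule) == 1 &&
    !tie_rule %in% c("noncleaver", "cleaver", "exclude")) {
    abort(paste0("unknown tie policy: ", tie_rule))
  }
  tie_rule <- match.arg(tie_rule)
  part <- tibble(species = partition_vector(partition) |> names(),
                 cluster = unname(partition_vector(partition)))
  lab <- labels
  if (!all(c("species", "label") %in% names(lab))) {
    abort("`labels` must have columns species and label")
  }
  joined <- dplyr::left_join(part, lab, by = "species")
  labeled <- dplyr::filter(joined, .data$label %in% c("Cleaver", "NonCleaver"))
  n_excluded <- nrow(joined) - nrow(labeled)
  if (nrow(labeled) == 0) abort("no labeled species left after excluding Mixed/NA")

  counts <- labeled |>
    dplyr::count(.data$cluster, .data$label) |>
    tidyr::pivot_wider(
      names_from = "label", values_from = "n",
      values_fill = 0L
    )
  for (col in c("Cleaver", "NonCleaver")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  all_clusters <- unique(part$cluster)
  cluster_map <- tibble(cluster = all_clusters) |>
    dplyr::left_join(counts, by = "cluster") |>
    dplyr::mutate(
      n_cleaver = dplyr::coalesce(.data$Cleaver, 0L),
      n_noncleaver = dplyr::coalesce(.data$NonCleaver, 0L),
      mapped_label = dplyr::case_when(
        n_cleaver + n_noncleaver == 0 ~ "Unlabeled",
        n_cleaver > n_noncleaver ~ "Cleaver",
        n_cleaver < n_noncleaver ~ "NonCleaver",
        tie_rule == "noncleaver" ~ "NonCleaver",
        tie_rule == "cleaver" ~ "Cleaver",
        TRUE ~ "Tie"
      )
    ) |>
    dplyr::select("cluster", "n_cleaver", "n_noncleaver", "mapped_label")

  preds <- labeled |>
    dplyr::left_join(cluster_map[, c("cluster", "mapped_label")], by = "cluster") |>
    dplyr::rename(predicted = "mapped_label")
  evaluated <- dplyr::filter(preds, .data$predicted %in% c("Cleaver", "NonCleaver"))
  tp <- sum(evaluated$predicted == "Cleaver" & evaluated$label == "Cleaver")
  fp <- sum(evaluated$predicted == "Cleaver" & evaluated$label == "NonCleaver")
  fn <- sum(evaluated$predicted == "NonCleaver" & evaluated$label == "Cleaver")
  tn <- sum(evaluated$predicted == "NonCleaver" & evaluated$label == "NonCleaver")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  accuracy <- if (nrow(evaluated) > 0) (tp + tn) / nrow(evaluated) else NA_real_

  pl <- tibble(species = labeled$species, cluster = labeled$cluster)
  ql <- tibble(species = labeled$species, cluster = labeled$label)
  ari <- if (nrow(labeled) >= 2) adjusted_rand_index(pl, ql) else NA_real_
  nmi <- if (nrow(labeled) >= 2) normalized_mutual_information(pl, ql) else NA_real_

  structure(
    list(
      ari = ari, nmi = nmi,
      cluster_map = cluster_map,
      predictions = preds,
      confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
      precision = precision, recall = recall, f1 = f1, accuracy = accuracy,
      n_labeled = nrow(labeled), n_excluded = n_excluded,
      n_evaluated = nrow(evaluated), tie_rule = tie_rule
    ),
    class = "concordance_report"
  )
}

#' @exportS3Method generics::glance
glance.concordance_report <- function(x, ...) {
  tibble(
    ari = x$ari, nmi = x$nmi,
    precision = x$precision, recall = x$recall, f1 = x$f1,
    accuracy = x$accuracy,
    n_labeled = x$n_labeled, n_excluded = x$n_excluded,
    n_evaluated = x$n_evaluated, tie_rule = x$tie_rule
  )
}

#' @exportS3Method generics::tidy
tidy.concordance_report <- function(x, ...) x$cluster_map

#' @export
print.concordance_report <- function(x, ...) {
  cat("Partition-phenotype concordance (positive class: Cleaver)\n")
  cat(sprintf("  ARI %.3f  NMI %.3f\n", x$ari, x$nmi))
  cat(sprintf(
    "  precision %.3f  recall %.3f  F1 %.3f  accuracy %.3f\n",
    x$precision, x$recall, x$f1, x$accuracy
  ))
  cat(sprintf(
    "  %d labeled, %d excluded (Mixed/NA), %d evaluated; tie rule: %s\n",
    x$n_labeled, x$n_excluded, x$n_evaluated, x$tie_rule
  ))
  cat(sprintf(
    "  confusion TP=%d FP=%d FN=%d TN=%d\n",
    x$confusion["TP"], x$confusion["FP"], x$confusion["FN"], x$confusion["TN"]
  ))
  invisible(x)
}

#' Write a concordance report as a flat key-value TSV
#'
#' @param report A `concordance_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concordance_report <- function(report, path) {
  g <- glance(report)
  kv <- data.frame(
    key = c(names(g), names(report$confusion)),
    value = c(unlist(lapply(g, as.character)), as.character(report$confusion))
  )
  write.table(kv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
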