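# Strain-level homolog conservation screen.  Each query protein is aligned
# locally (Smith-Waterman, mimicking BLASTp) against every protein of every
# strain proteome; the top-scoring hit per (query, strain) is retained, with
# score ties broken by the lexicographically smallest subject id.  A hit is
# kept when it passes the identity and query-coverage filters (defaults 60%
# and 30%, chosen to exclude partial or truncated sequences).

#' Best local-alignment hit of one query in one proteome
#'
#' @param query A one-row record tibble or residue string (named `query` id
#'   taken from the record when available).
#' @param proteome Record tibble of the strain's proteins.
#' @param min_identity,min_coverage Filters (percent) deciding the `kept`
#'   flag.
#' @return A one-row tibble (`query_id`, `subject_id`, `matches`,
#'   `aligned_columns`, `identity_pct`, `query_coverage_pct`, `score`,
#'   `kept`), or `NULL` when no alignment scores above 0.
#' @export
best_hit <- function(query, proteome, min_identity = 60, min_coverage = 30) {
  check_records(proteome, "proteome")
  if (nrow(proteome) == 0) abort("`proteome` is empty")
  qid <- if (is.data.frame(query)) query$id else NA_character_
  qres <- as_residues(query, "query")
  hits <- align_many(proteome$residues, qres,
    type = "local",
    cov_side = "subject"
  ) |>
    dplyr::mutate(subject_id = proteome$id)
  hits <- hits[hits$score > 0, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(NULL)
  }
  best <- hits |>
    dplyr::arrange(dplyr::desc(.data$score), .data$subject_id) |>
    dplyr::slice(1)
  tibble(
    query_id = qid,
    subject_id = best$subject_id,
    matches = best$matches,
    aligned_columns = best$aligned_columns,
    identity_pct = best$identity_pct,
    query_coverage_pct = best$query_coverage_pct,
    score = best$score,
    kept = best$identity_pct >= min_identity & best$query_coverage_pct >= min_coverage
  )
}

#' Screen query proteins against strain proteomes
#'
#' Runs [best_hit()] for every query against every strain and assembles the
#' full hit table plus the binary presence/absence matrix (cell 1 iff the
#' best hit passed both filters).
#'
#' @param queries Record tibble of query proteins (unique ids).
#' @param proteomes Named list of record tibbles, one per strain (names are
#'   the strain ids), or a single record tibble with a `strain` column.
#' @inheritParams best_hit
#' @return An object of class `conservation_screen`: list with `hits`
#'   (tibble: query_id, strain_id, subject_id, identity_pct,
#'   query_coverage_pct, score, kept), `presence` (tibble: query_id plus one
#'   binary column per strain), `strains`, `min_identity`, `min_coverage`.
#'   `tidy()` returns the hit table.
#' @export
screen_homologs <- function(queries, proteomes, min_identity = 60, min_coverage = 30) {
  check_records(queries, "queries")
  if (nrow(queries) == 0) abort("need at least one query")
  if (anyDuplicated(queries$id)) abort("duplicate query ids")
  if (is.data.frame(proteomes)) {
    if (!"strain" %in% names(proteomes)) abort("`proteomes` tibble must have a strain column")
    proteomes <- split(proteomes, proteomes$strain)
  }
  if (length(proteomes) == 0) abort("`proteomes` is empty")
  if (is.null(names(proteomes)) || any(!nzchar(names(proteomes)))) {
    abort("`proteomes` must be named by strain id")
  }
  if (anyDuplicated(names(proteomes))) abort("duplicate strain ids")
  strains <- names(proteomes)

  rows <- purrr::map(strains, function(st) {
    prot <- proteomes[[st]]
    per_query <- purrr::map(seq_len(nrow(queries)), function(i) {
      bh <- best_hit(queries[i, ], prot,
        min_identity = min_identity,
        min_coverage = min_coverage
      )
      if (is.null(bh)) {
        tibble(
          query_id = queries$id[i], subject_id = NA_character_,
          matches = NA_integer_, aligned_columns = NA_integer_,
          identity_pct = NA_real_, query_coverage_pct = NA_real_,
          score = NA_real_, kept = FALSE
        )
      } else {
        bh
      }
    })
    dplyr::bind_rows(per_query) |> dplyr::mutate(strain_id = st, .after = "query_id")
  })
  hits <- dplyr::bind_rows(rows)

  pres <- hits |>
    dplyr::mutate(present = as.integer(.data$kept)) |>
    dplyr::select("query_id", "strain_id", "present") |>
    tidyr::pivot_wider(names_from = "strain_id", values_from = "present") |>
    dplyr::arrange(match(.data$query_id, queries$id))

  structure(
    list(
      hits = hits, presence = pres, strains = strains,
      min_identity = min_identity, min_coverage = min_coverage
    ),
    class = "conservation_screen"
  )
}

#' @exportS3Method generics::tidy
tidy.conservation_screen <- function(x, ...) x$hits

#' @export
print.conservation_screen <- function(x, ...) {
  cat(sprintf(
    "Conservation screen: %d queries x %d strains (identity >= %g%%, coverage >= %g%%); %d/%d kept hits\n",
    length(unique(x$hits$query_id)), length(x$strains),
    x$min_identity, x$min_coverage, sum(x$hits$kept), nrow(x$hits)
  ))
  invisible(x)
}

#' Per-query conservation summary
#'
#' For each query: the fraction of strains with a kept homolog, and the mean
#' and sample standard deviation (n - 1 denominator) of the identity over
#' kept hits.  A single kept hit reports SD 0; a query with no kept hits
#' reports presence 0 and `NA` mean/SD.
#'
#' @param screen A `conservation_screen` from [screen_homologs()], or its
#'   hit table.
#' @return A tibble with columns `query_id`, `n_strains`, `n_present`,
#'   `presence_fraction`, `mean_identity_pct`, `identity_sd_pct`.
#' @export
conservation_summary <- function(screen) {
  hits <- if (inherits(screen, "conservation_screen")) screen$hits else screen
  if (!all(c("query_id", "strain_id", "identity_pct", "kept") %in% names(hits))) {
    abort("`screen` must be a conservation_screen or its hit table")
  }
  hits |>
    dplyr::group_by(.data$query_id) |>
    dplyr::summarise(
      n_strains = dplyr::n_distinct(.data$strain_id),
      n_present = sum(.data$kept),
      presence_fraction = n_present / n_strains,
      mean_identity_pct = if (any(.data$kept)) mean(.data$identity_pct[.data$kept]) else NA_real_,
      identity_sd_pct = if (sum(.data$kept) > 1) {
        sd(.data$identity_pct[.data$kept])
      } else if (sum(.data$kept) == 1) 0 else NA_real_,
      .groups = "drop"
    )
}

#' Write conservation screen outputs as TSV files
#'
#' Writes the hit table (BLAST outfmt-6-like columns), the binary presence
#' matrix and the per-query summary.
#'
#' @param screen A `conservation_screen`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_conservation_tsvs <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(screen$hits, file.path(dir, "hits.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write.table(screen$presence, file.path(dir, "presence_matrix.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write.table(conservation_summary(screen), file.path(dir, "conservation_summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}
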