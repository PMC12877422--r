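#' Remove fragmented and multi-species records
#'
#' Drops records whose description carries a fragment marker (default the
#' substring `"(Fragment)"`, case-insensitive) and records whose species
#' field names more than one taxon (any of the configured delimiters found in
#' the species string).  A record matching the fragment rule is counted as a
#' fragment only; the multispecies rule is applied to the remainder.
#'
#' @param records Record tibble ([read_fasta()]).
#' @param drop_fragments,drop_multispecies Logical switches for the two rules.
#' @param fragment_marker Substring marking a fragment (matched literally,
#'   case-insensitively) in the description.
#' @param multispecies_delims Character vector of delimiters whose presence in
#'   the species field marks a multi-species record.
#' @return The retained records, with attribute `"filter_counts"`, a named
#'   integer vector `c(fragment = , multispecies = )`.
#' @export
filter_records <- function(records,
                           drop_fragments = TRUE,
                           drop_multispecies = TRUE,
                           fragment_marker = "(Fragment)",
                           multispecies_delims = c("/", ";", " x ")) {
  check_records(records)
  n <- nrow(records)
  is_frag <- rep(FALSE, n)
  if (drop_fragments && n > 0) {
    desc <- records$description
    desc[is.na(desc)] <- ""
    is_frag <- grepl(tolower(fragment_marker), tolower(desc), fixed = TRUE)
  }
  is_multi <- rep(FALSE, n)
  if (drop_multispecies && n > 0) {
    sp <- records$species
    sp[is.na(sp)] <- ""
    for (d in multispecies_delims) {
      is_multi <- is_multi | grepl(d, sp, fixed = TRUE)
    }
    is_multi <- is_multi & !is_frag
  }
  out <- records[!is_frag & !is_multi, , drop = FALSE]
  attr(out, "filter_counts") <- c(
    fragment = sum(is_frag),
    multispecies = sum(is_multi)
  )
  out
}

#' Per-rule removal counts from [filter_records()]
#'
#' @param records A tibble returned by [filter_records()].
#' @return Named integer vector with elements `fragment` and `multispecies`.
#' @export
filter_counts <- function(records) {
  cnt <- attr(records, "filter_counts")
  if (is.null(cnt)) abort("no filter_counts attribute; was this produced by filter_records()?")
  cnt
}
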