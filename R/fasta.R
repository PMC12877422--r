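# Sequence records are plain tibbles: one row per protein with columns
# id, species, strain, family, description, residues.  Residues use the
# 20-letter amino-acid alphabet plus X; ambiguity codes B/J/Z/U/O are
# collapsed to X on read and stop codons ('*') are dropped.

AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
AA_ALLOWED <- c(AA_STANDARD, "X")

sanitize_residues <- function(x) {
  x <- toupper(gsub("[ \t\r]", "", x))
  x <- gsub("\\*", "", x)
  chartr("BJZUO", "XXXXX", x)
}

#' Default FASTA header parser for species and strain
#'
#' Extracts the organism from a UniProt-style `OS=` field when present
#' (species = first two words, strain = any remainder); otherwise falls back
#' to the first two whitespace-separated tokens after the accession.
#'
#' @param header Character vector of FASTA headers (without the leading `>`).
#' @return A tibble with columns `species` and `strain` (`NA` when absent).
#' @export
parse_species_default <- function(header) {
  os <- regmatches(header, regexpr("OS=.*?(?=\\s+[A-Z][A-Z0-9]+=|$)", header, perl = TRUE))
  has_os <- grepl("OS=", header)
  species <- strain <- rep(NA_character_, length(header))
  if (any(has_os)) {
    val <- sub("^OS=", "", os)
    words <- strsplit(trimws(val), "\\s+")
    species[has_os] <- vapply(words, function(w) paste(head(w, 2), collapse = " "), "")
    strain[has_os] <- vapply(words, function(w) {
      if (length(w) > 2) paste(w[-(1:2)], collapse = " ") else NA_character_
    }, "")
  }
  if (any(!has_os)) {
    toks <- strsplit(header[!has_os], "\\s+")
    species[!has_os] <- vapply(toks, function(w) {
      if (length(w) >= 3) paste(w[2:3], collapse = " ") else NA_character_
    }, "")
  }
  tibble(species = species, strain = strain)
}

#' Read a protein FASTA file into a record tibble
#'
#' Parses a (possibly line-wrapped) protein FASTA file and extracts species
#' and strain annotations from the headers.  The record id is the first
#' whitespace-separated token of the header; the rest is kept as the
#' description.  Residues are upper-cased, ambiguity codes B/J/Z/U/O are
#' mapped to X and `*` is dropped; any remaining character outside the
#' 20-letter alphabet plus X is a parse error reported with its line number,
#' as is a header with no sequence.
#'
#' @param path Path to a FASTA file.
#' @param family Optional enzyme-family tag (e.g. `"PL8"`) stored on every
#'   record.
#' @param species_parser Function mapping a character vector of headers to a
#'   tibble with columns `species` and `strain`.  Defaults to
#'   [parse_species_default()].
#' @return A tibble with columns `id`, `species`, `strain`, `family`,
#'   `description`, `residues`, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, family = NA_character_, species_parser = parse_species_default) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  hdr_at <- grep("^>", lines)
  if (length(hdr_at) == 0) {
    if (any(nzchar(trimws(lines)))) {
      abort(paste0("malformed FASTA (no header before sequence) at line 1 of ", path))
    }
    return(tibble(
      id = character(), species = character(), strain = character(),
      family = character(), description = character(), residues = character()
    ))
  }
  if (any(nzchar(trimws(lines[seq_len(hdr_at[1] - 1)])))) {
    abort(paste0("malformed FASTA (sequence before first header) at line 1 of ", path))
  }
  bounds <- c(hdr_at, length(lines) + 1L)
  headers <- sub("^>", "", lines[hdr_at])
  residues <- character(length(hdr_at))
  for (i in seq_along(hdr_at)) {
    from <- hdr_at[i] + 1L
    to <- bounds[i + 1L] - 1L
    seq_lines <- if (to >= from) lines[from:to] else character()
    res <- sanitize_residues(paste(seq_lines, collapse = ""))
    if (!nzchar(res)) {
      abort(paste0("malformed FASTA (header without sequence) at line ", hdr_at[i], " of ", path))
    }
    bad <- setdiff(unique(strsplit(res, "")[[1]]), AA_ALLOWED)
    if (length(bad) > 0) {
      off <- which(vapply(seq_lines, function(l) any(strsplit(sanitize_residues(l), "")[[1]] %in% bad), TRUE))[1]
      abort(paste0(
        "illegal residue character(s) ", paste(bad, collapse = ""),
        " at line ", hdr_at[i] + off, " of ", path
      ))
    }
    residues[i] <- res
  }
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate record id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  desc <- trimws(sub("^\\S+\\s*", "", headers))
  sp <- species_parser(headers)
  tibble(
    id = ids, species = sp$species, strain = sp$strain,
    family = family, description = desc, residues = residues
  )
}

#' Write a record tibble to FASTA
#'
#' Headers are `id description`; sequences are wrapped at `width` columns.
#'
#' @param records Record tibble as returned by [read_fasta()].
#' @param path Output file path.
#' @param width Maximum sequence line width (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 80) {
  check_records(records)
  set <- Biostrings::AAStringSet(records$residues)
  desc <- records$description
  desc[is.na(desc)] <- ""
  names(set) <- trimws(paste(records$id, desc))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

check_records <- function(records, arg = "records") {
  need <- c("id", "residues")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    abort(paste0("`", arg, "` must be a record tibble with at least columns id and residues"))
  }
  invisible(records)
}
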