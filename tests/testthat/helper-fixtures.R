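# Fixture builders shared across test files.  Everything is generated in
# code; no data files.

make_records <- function(ids, residues, species = NA_character_,
                         family = "PL8", description = "") {
  tibble::tibble(
    id = ids,
    species = rep_len(species, length(ids)),
    strain = NA_character_,
    family = rep_len(family, length(ids)),
    description = rep_len(description, length(ids)),
    residues = residues
  )
}

# Three archetypes at 57% identity to a common base, each with two orthologs
# at 95% identity to the archetype.  With the frozen seed every cross-group
# sequence sits at >= 52% identity to the first archetype and every
# cross-group pair below 58.5%, so greedy clustering yields one cluster at
# thresholds 40-50 and three at 60-80.  The generating margins are
# re-verified by the test that uses the fixture.
three_archetype_family <- function(seed = 23, length = 300) {
  withr::with_seed(seed, {
    a1 <- cazyclust::random_protein(length)
    a2 <- cazyclust::mutate_to_identity(a1, 57)
    a3 <- cazyclust::mutate_to_identity(a1, 57)
    grp <- function(a, tag) {
      make_records(
        ids = sprintf("GH88_%s_%02d", tag, 0:2),
        residues = c(a, cazyclust::mutate_to_identity(a, 95), cazyclust::mutate_to_identity(a, 95)),
        species = sprintf("Bacteroides %s%d", tag, 1:3),
        family = "GH88"
      )
    }
    dplyr::bind_rows(grp(a1, "a1"), grp(a2, "a2"), grp(a3, "a3"))
  })
}

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_tmp_labels <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(rows, path)
  path
}
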