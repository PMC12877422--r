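# Synthetic data with known ground truth for every stage of the pipeline.
#
# The mutation model is substitution-only: mutating a length-L sequence to a
# target identity t substitutes exactly round(L * (1 - t/100)) positions to a
# different residue, so the realized global identity equals the target
# exactly (indel realism is deliberately traded for analytic testability).
# Residues are drawn uniformly over the 20 standard amino acids.
#
# Species gene content is organized in "content blocks": block b carries a
# contiguous window of archetypes, the same window in every family, and the
# phenotype is causal - a species is a Cleaver iff its block carries every
# pathway archetype (archetype 1 of each family by default; only block 1
# does).  Labels can then be degraded with flip noise and a Mixed/NA
# fraction, emulating the sparse labeling of real phenotype compilations.

#' Random protein sequence
#'
#' @param length Number of residues.
#' @return A residue string drawn uniformly over the 20 standard amino acids.
#' @export
random_protein <- function(length) {
  paste(sample(AA_STANDARD, length, replace = TRUE), collapse = "")
}

#' Mutate a sequence to an exact target identity
#'
#' Substitutes exactly `round(L * (1 - target/100))` positions, each to a
#' residue different from the original, so the pairwise global identity
#' between input and output equals the realized substitution fraction
#' exactly (no indels).
#'
#' @param residues Residue string.
#' @param target_identity_pct Target identity in (0, 100].
#' @return The mutated residue string.
#' @export
mutate_to_identity <- function(residues, target_identity_pct) {
  if (!is.numeric(target_identity_pct) || target_identity_pct <= 0 ||
    target_identity_pct > 100) {
    abort("`target_identity_pct` must be in (0, 100]")
  }
  chars <- strsplit(residues, "")[[1]]
  len <- length(chars)
  k <- round(len * (1 - target_identity_pct / 100))
  if (k == 0) {
    return(residues)
  }
  pos <- sample.int(len, k)
  for (p in pos) {
    chars[p] <- sample(setdiff(AA_STANDARD, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

draw_archetypes <- function(n, protein_length, between_identity_max_pct,
                            max_attempts = 1000) {
  arch <- character(0)
  attempts <- 0
  while (length(arch) < n) {
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      abort(paste0(
        "could not draw ", n, " archetypes mutually below ",
        between_identity_max_pct, "% identity in ", max_attempts,
        " attempts; use longer proteins"
      ))
    }
    cand <- random_protein(protein_length)
    if (length(arch) == 0 ||
      all(align_many(arch, cand, type = "global")$identity_pct <=
        between_identity_max_pct)) {
      arch <- c(arch, cand)
    }
  }
  arch
}

#' Simulate a multi-species enzyme-family dataset with causal phenotype
#'
#' Generates, per family, `n_archetypes` mutually divergent archetype
#' sequences (rejection-sampled below `between_identity_max_pct` pairwise
#' identity), assigns species round-robin to `n_blocks` content blocks
#' (block b carries archetypes `b .. b + archetypes_per_block - 1`), and
#' emits one ortholog per carried archetype per species, mutated to
#' `within_identity_pct` identity.  The true phenotype is Cleaver iff the
#' species' block carries archetype `pathway_archetype` of every family.
#' Emitted labels flip with probability `label_noise` and a
#' `mixed_na_fraction` of species is relabeled Mixed or NA (alternating).
#'
#' @param n_species Number of species.
#' @param family_tags Character vector of enzyme-family tags.
#' @param n_archetypes Archetypes per family.
#' @param within_identity_pct Ortholog-to-archetype identity (percent).
#' @param between_identity_max_pct Maximum archetype-to-archetype identity.
#' @param n_blocks Number of species content blocks.
#' @param archetypes_per_block Archetypes carried per block.
#' @param pathway_archetype Archetype index (per family) whose joint presence
#'   defines the Cleaver phenotype.
#' @param label_noise Probability a true label is flipped before emission.
#' @param mixed_na_fraction Fraction of species whose emitted label is
#'   replaced by Mixed or NA.
#' @param protein_length Archetype length in residues.
#' @param seed Optional RNG seed for reproducibility.
#' @return An object of class `sim_dataset`: list with `records` (record
#'   tibble over all families), `labels` (species, label), `truth` (species,
#'   block, true_phenotype, emitted label), and `config`.
#' @export
simulate_dataset <- function(n_species = 40,
                             family_tags = c("PL8", "GH88"),
                             n_archetypes = 5,
                             within_identity_pct = 90,
                             between_identity_max_pct = 40,
                             n_blocks = 2,
                             archetypes_per_block = 3,
                             pathway_archetype = 1,
                             label_noise = 0,
                             mixed_na_fraction = 0.64,
                             protein_length = 150,
                             seed = NULL) {
  stopifnot(
    n_species >= n_blocks, n_blocks >= 1,
    within_identity_pct > 0, within_identity_pct <= 100,
    between_identity_max_pct > 0,
    within_identity_pct > between_identity_max_pct,
    label_noise >= 0, label_noise <= 1,
    mixed_na_fraction >= 0, mixed_na_fraction <= 1
  )
  if (n_archetypes < n_blocks + archetypes_per_block - 1) {
    abort("need n_archetypes >= n_blocks + archetypes_per_block - 1 for distinct blocks")
  }
  if (!is.null(seed)) set.seed(seed)

  species <- sprintf("Bacteroides synsp%02d", seq_len(n_species))
  block <- ((seq_len(n_species) - 1L) %% n_blocks) + 1L
  block_content <- lapply(seq_len(n_blocks), function(b) seq(b, b + archetypes_per_block - 1L))

  archetypes <- lapply(family_tags, function(f) {
    draw_archetypes(n_archetypes, protein_length, between_identity_max_pct)
  })
  names(archetypes) <- family_tags

  recs <- list()
  for (f in family_tags) {
    for (i in seq_len(n_species)) {
      sp_i <- species[i]
      for (a in block_content[[block[i]]]) {
        recs[[length(recs) + 1]] <- tibble(
          id = sprintf("%s_a%d_sp%02d", f, a, i),
          species = sp_i,
          strain = NA_character_,
          family = f,
          description = sprintf("synthetic %s archetype %d OS=%s", f, a, sp_i),
          residues = mutate_to_identity(archetypes[[f]][a], within_identity_pct)
        )
      }
    }
  }
  records <- dplyr::bind_rows(recs)

  carries_pathway <- vapply(block_content, function(ct) pathway_archetype %in% ct, TRUE)
  true_phen <- ifelse(carries_pathway[block], "Cleaver", "NonCleaver")
  emitted <- true_phen
  flip <- runif(n_species) < label_noise
  emitted[flip] <- ifelse(true_phen[flip] == "Cleaver", "NonCleaver", "Cleaver")
  n_mna <- round(mixed_na_fraction * n_species)
  if (n_mna > 0) {
    idx <- sample.int(n_species, n_mna)
    emitted[idx] <- rep(c("Mixed", NA_character_), length.out = n_mna)
  }

  structure(
    list(
      records = records,
      labels = tibble(species = species, label = emitted),
      truth = tibble(
        species = species, block = block,
        archetypes = vapply(block_content[block], paste, "", collapse = ","),
        true_phenotype = true_phen, label = emitted
      ),
      config = list(
        n_species = n_species, family_tags = family_tags,
        n_archetypes = n_archetypes,
        within_identity_pct = within_identity_pct,
        between_identity_max_pct = between_identity_max_pct,
        n_blocks = n_blocks, archetypes_per_block = archetypes_per_block,
        pathway_archetype = pathway_archetype, label_noise = label_noise,
        mixed_na_fraction = mixed_na_fraction,
        protein_length = protein_length, seed = seed
      )
    ),
    class = "sim_dataset"
  )
}

#' Write a simulated dataset to disk
#'
#' One FASTA per family, a labels TSV, a truth TSV and a JSON run manifest
#' echoing the configuration.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!inherits(sim, "sim_dataset")) abort("`sim` must be a sim_dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in sim$config$family_tags) {
    write_fasta(
      sim$records[sim$records$family == f, ],
      file.path(dir, paste0(f, ".fasta"))
    )
  }
  lab <- sim$labels
  lab$label[is.na(lab$label)] <- "NA"
  write.table(lab, file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  write.table(sim$truth, file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(sim$config, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
  invisible(dir)
}

#' Simulate strain proteomes diverged from reference proteins
#'
#' Each strain carries each reference protein mutated to `identity_pct`
#' identity unless dropped with probability `dropout_prob`, plus
#' `decoys_per_strain` random decoy proteins.
#'
#' @param references Record tibble of reference proteins (unique ids).
#' @param n_strains Number of strains.
#' @param identity_pct Strain-to-reference identity (percent).
#' @param dropout_prob Per-(strain, reference) dropout probability.
#' @param decoys_per_strain Random decoy proteins added per strain.
#' @param decoy_length Decoy length (default: median reference length).
#' @param seed Optional RNG seed.
#' @return An object of class `sim_proteomes`: list with `proteomes` (named
#'   list of record tibbles, names = strain ids), `truth` (strain_id,
#'   query_id, present) and `config`.
#' @export
simulate_strain_proteomes <- function(references, n_strains = 50,
                                      identity_pct = 97,
                                      dropout_prob = 0.02,
                                      decoys_per_strain = 5,
                                      decoy_length = NULL,
                                      seed = NULL) {
  check_records(references, "references")
  if (nrow(references) == 0) abort("`references` is empty")
  if (identity_pct <= 0 || identity_pct > 100) abort("`identity_pct` must be in (0, 100]")
  stopifnot(dropout_prob >= 0, dropout_prob <= 1, n_strains >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(decoy_length)) decoy_length <- round(stats::median(nchar(references$residues)))

  strains <- sprintf("strain_%03d", seq_len(n_strains))
  truth <- list()
  proteomes <- lapply(strains, function(st) {
    present <- runif(nrow(references)) >= dropout_prob
    truth[[st]] <<- tibble(
      strain_id = st, query_id = references$id,
      present = present
    )
    kept <- references[present, , drop = FALSE]
    homs <- if (nrow(kept) > 0) {
      tibble(
        id = sprintf("%s|%s", st, kept$id),
        species = NA_character_, strain = st, family = NA_character_,
        description = sprintf("homolog of %s", kept$id),
        residues = vapply(kept$residues, mutate_to_identity, "",
          target_identity_pct = identity_pct
        )
      )
    } else {
      NULL
    }
    decoys <- if (decoys_per_strain > 0) {
      tibble(
        id = sprintf("%s|decoy%02d", st, seq_len(decoys_per_strain)),
        species = NA_character_, strain = st, family = NA_character_,
        description = "random decoy protein",
        residues = vapply(seq_len(decoys_per_strain), function(i) {
          random_protein(decoy_length)
        }, "")
      )
    } else {
      NULL
    }
    dplyr::bind_rows(homs, decoys)
  })
  names(proteomes) <- strains
  structure(
    list(
      proteomes = proteomes,
      truth = dplyr::bind_rows(truth),
      config = list(
        n_strains = n_strains, identity_pct = identity_pct,
        dropout_prob = dropout_prob, decoys_per_strain = decoys_per_strain,
        decoy_length = decoy_length, seed = seed
      )
    ),
    class = "sim_proteomes"
  )
}

#' Write simulated strain proteomes as per-strain FASTA files
#'
#' File name = strain id, matching the input convention of the conservation
#' screen.
#'
#' @param sim A `sim_proteomes`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_strain_proteomes <- function(sim, dir) {
  if (!inherits(sim, "sim_proteomes")) abort("`sim` must be a sim_proteomes")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (st in names(sim$proteomes)) {
    write_fasta(sim$proteomes[[st]], file.path(dir, paste0(st, ".fasta")))
  }
  invisible(dir)
}

#' Simulate a protein quantification table with known true DE set
#'
#' Per protein, replicate log2 intensities are drawn for two conditions from
#' normal distributions with common SD `noise_sd`; for the `n_true_de` true
#' DE proteins the condition means differ by `log2fc_effect` (alternating
#' sign).  The per-protein p-value is a pooled-variance two-sample t-test (exact under the equal-variance generative model) and the
#' reported log2 fold change is the difference of condition means
#' (condition B minus A).
#'
#' @param n_proteins Number of proteins.
#' @param n_true_de Number of truly differential proteins.
#' @param log2fc_effect True absolute difference of condition means.
#' @param n_replicates Replicates per condition (>= 2).
#' @param noise_sd Replicate noise SD on the log2 scale.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `protein_id`, `log2fc`, `pvalue`,
#'   `true_de`, `true_direction` (+1/-1/0).
#' @export
simulate_quant_table <- function(n_proteins = 500, n_true_de = 50,
                                 log2fc_effect = 2, n_replicates = 4,
                                 noise_sd = 0.3, seed = NULL) {
  if (n_replicates < 2) abort("`n_replicates` must be >= 2")
  if (n_true_de > n_proteins) abort("`n_true_de` must be <= `n_proteins`")
  if (!is.null(seed)) set.seed(seed)
  base <- rnorm(n_proteins, mean = 20, sd = 2)
  dir <- integer(n_proteins)
  if (n_true_de > 0) {
    de_idx <- sample.int(n_proteins, n_true_de)
    dir[de_idx] <- rep(c(1L, -1L), length.out = n_true_de)
  }
  a <- matrix(rnorm(n_proteins * n_replicates, base, noise_sd), nrow = n_proteins)
  b <- matrix(rnorm(n_proteins * n_replicates, base + dir * log2fc_effect, noise_sd),
    nrow = n_proteins
  )
  pvalue <- vapply(seq_len(n_proteins), function(i) {
    t.test(b[i, ], a[i, ], var.equal = TRUE)$p.value
  }, 0)
  tibble(
    protein_id = sprintf("prot%04d", seq_len(n_proteins)),
    log2fc = rowMeans(b) - rowMeans(a),
    pvalue = pvalue,
    true_de = dir != 0L,
    true_direction = dir
  )
}
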