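# Presence/absence profiles, Jaccard distances, merging, hierarchical
# clustering and partition cutting.

fake_clustering <- function(members, family = "PL8") {
  # members: tibble(cluster, id, species)
  structure(
    list(
      family = family, threshold_pct = 60, assign = "first",
      centroids = tibble::tibble(
        cluster = sort(unique(members$cluster)),
        centroid_id = members$id[!duplicated(members$cluster)]
      ),
      members = dplyr::mutate(members, role = "member", identity_to_centroid = 100)
    ),
    class = "family_clustering"
  )
}

test_that("presence matrix is binary with canonical species order", {
  cl <- fake_clustering(tibble::tibble(
    cluster = c(1L, 1L),
    id = c("x1", "x2"),
    species = c("S1", "S2")
  ))
  pm <- build_presence_matrix(cl, c("S1", "S2", "S3"))
  expect_equal(pm$species, c("S1", "S2", "S3"))
  expect_equal(pm$PL8_C1, c(1L, 1L, 0L))

  # paralogs: two sequences of one species in one cluster still give a 1
  cl2 <- fake_clustering(tibble::tibble(
    cluster = c(1L, 1L, 1L, 2L, 2L),
    id = c("p1", "p2", "q1", "p3", "q2"),
    species = c("S1", "S1", "S2", "S1", "S2")
  ))
  pm2 <- build_presence_matrix(cl2, c("S1", "S2"))
  expect_equal(unname(as.matrix(pm2[, -1])), matrix(c(1L, 1L, 1L, 1L), 2))

  cl3 <- fake_clustering(tibble::tibble(
    cluster = c(1L, 1L, 2L),
    id = c("a", "b", "c"),
    species = c("S1", "S2", "S1")
  ))
  pm3 <- build_presence_matrix(cl3, c("S1", "S2"))
  expect_equal(unname(as.matrix(pm3[, -1])), matrix(c(1L, 1L, 1L, 0L), 2))

  expect_error(build_presence_matrix(cl, c("S1")), "S2")
})

test_that("jaccard distances follow the set formula and the empty conventions", {
  pm <- tibble::tibble(
    species = c("A", "B", "C", "D", "E"),
    c1 = c(1L, 1L, 1L, 0L, 0L),
    c2 = c(1L, 1L, 0L, 0L, 0L),
    c3 = c(0L, 0L, 1L, 1L, 0L)
  )
  d <- jaccard_distances(pm)
  expect_equal(unname(d["A", "B"]), 0) # identical non-empty rows
  expect_equal(unname(d["B", "D"]), 1) # disjoint non-empty rows
  expect_equal(unname(d["B", "C"]), 1 - 1 / 3) # (1,1,0) vs (1,0,1)
  expect_equal(unname(d["E", "E"]), 0)
  expect_equal(unname(d["E", "A"]), 1) # empty vs non-empty
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
})

test_that("jaccard agrees with vegan on non-degenerate binary profiles", {
  set.seed(30)
  m <- matrix(rbinom(10 * 12, 1, 0.5), nrow = 10)
  m[rowSums(m) == 0, 1] <- 1L # avoid empty rows, vegan's convention differs
  pm <- dplyr::bind_cols(
    tibble::tibble(species = sprintf("S%02d", 1:10)),
    tibble::as_tibble(as.data.frame(m))
  )
  d <- jaccard_distances(pm)
  ref <- as.matrix(vegan::vegdist(m, method = "jaccard", binary = TRUE))
  expect_equal(unclass(d), ref, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("jaccard distance satisfies the triangle inequality on random triples", {
  set.seed(31)
  for (r in 1:100) {
    m <- matrix(rbinom(3 * 8, 1, 0.4), nrow = 3)
    pm <- dplyr::bind_cols(
      tibble::tibble(species = c("a", "b", "c")),
      tibble::as_tibble(as.data.frame(m))
    )
    d <- jaccard_distances(pm)
    expect_lte(d["a", "c"], d["a", "b"] + d["b", "c"] + 1e-12)
    expect_lte(d["a", "b"], d["a", "c"] + d["c", "b"] + 1e-12)
    expect_lte(d["b", "c"], d["b", "a"] + d["a", "c"] + 1e-12)
  }
})

test_that("merging averages element-wise and respects weights", {
  pm1 <- tibble::tibble(species = c("A", "B"), c1 = c(1L, 0L), c2 = c(1L, 1L))
  pm2 <- tibble::tibble(species = c("A", "B"), k1 = c(1L, 1L), k2 = c(0L, 1L))
  d1 <- jaccard_distances(pm1)
  d2 <- jaccard_distances(pm2)
  expect_equal(unclass(merge_distance_matrices(list(d1))), unclass(d1))
  avg <- merge_distance_matrices(list(d1, d2))
  expect_equal(unname(avg["A", "B"]), (d1["A", "B"] + d2["A", "B"]) / 2, ignore_attr = TRUE)
  w <- merge_distance_matrices(list(d1, d2), weights = c(1, 0))
  expect_equal(unclass(w), unclass(d1))
  # identical inputs merge to themselves
  expect_equal(unclass(merge_distance_matrices(list(d1, d1, d1))), unclass(d1))
  # explicit numeric case: 0.2 and 0.4 average to 0.3
  da <- db <- d1
  da["A", "B"] <- da["B", "A"] <- 0.2
  db["A", "B"] <- db["B", "A"] <- 0.4
  expect_equal(unname(merge_distance_matrices(list(da, db))["A", "B"]), 0.3)
  # species order mismatch is an error
  d3 <- d2
  rownames(d3) <- colnames(d3) <- c("B", "A")
  expect_error(merge_distance_matrices(list(d1, d3)), "mismatch")
})

test_that("UPGMA merges follow hand-computed heights", {
  d <- matrix(c(0, 0.1, 0.8, 0.1, 0, 0.8, 0.8, 0.8, 0), 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  class(d) <- c("species_dist", class(d))
  dn <- hierarchical_cluster(d)
  expect_equal(dn$hclust$height, c(0.1, 0.8))
  p2 <- cut_dendrogram(dn, 2)
  ab <- as.character(p2$cluster[p2$species %in% c("A", "B")])
  expect_equal(ab[1], ab[2]) # A and B merge first
  expect_false(as.character(p2$cluster[p2$species == "C"]) == ab[1])

  # two species: single merge at their distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  class(d2) <- c("species_dist", class(d2))
  h2 <- hierarchical_cluster(d2)
  expect_equal(h2$hclust$height, 0.4)
  expect_error(hierarchical_cluster(d2[1, 1, drop = FALSE]))
  expect_error(hierarchical_cluster(d2, linkage = "ward.D2"), "Ward")
})

test_that("species order permutation yields the same cut partition", {
  set.seed(32)
  m <- matrix(rbinom(6 * 10, 1, 0.5), nrow = 6)
  sp <- sprintf("S%d", 1:6)
  pm <- dplyr::bind_cols(tibble::tibble(species = sp), tibble::as_tibble(as.data.frame(m)))
  perm <- sample(6)
  pmp <- pm[perm, ]
  cut_of <- function(p, k) {
    part <- cut_dendrogram(hierarchical_cluster(jaccard_distances(p)), k)
    setNames(as.character(part$cluster), part$species)
  }
  a <- cut_of(pm, 3)
  b <- cut_of(pmp, 3)
  # same groups up to label names
  for (i in sp) {
    for (j in sp) {
      expect_equal(a[i] == a[j], b[i] == b[j], ignore_attr = TRUE)
    }
  }
})

test_that("cut_dendrogram handles the extremes and validates k", {
  set.seed(33)
  m <- matrix(rbinom(5 * 8, 1, 0.5), nrow = 5)
  pm <- dplyr::bind_cols(
    tibble::tibble(species = sprintf("S%d", 1:5)),
    tibble::as_tibble(as.data.frame(m))
  )
  dn <- hierarchical_cluster(jaccard_distances(pm))
  expect_equal(length(unique(cut_dendrogram(dn, 5)$cluster)), 5)
  expect_equal(length(unique(cut_dendrogram(dn, 1)$cluster)), 1)
  expect_error(cut_dendrogram(dn, 6), "k")
  expect_error(cut_dendrogram(dn, 0), "k")
  # labels C1..Ck are assigned in leaf order
  p3 <- cut_dendrogram(dn, 3)
  leaf <- dn$hclust$labels[dn$hclust$order]
  first_label <- as.character(p3$cluster[match(leaf[1], p3$species)])
  expect_equal(first_label, "C1")
})

test_that("two disjoint content blocks are recovered exactly at k = 2", {
  sim <- simulate_dataset(
    n_species = 12, n_blocks = 2, mixed_na_fraction = 0,
    seed = 34
  )
  res <- run_pipeline(sim$records, sim$labels, k = 2)
  joined <- dplyr::left_join(res$partition, sim$truth, by = "species")
  tab <- table(joined$cluster, joined$block)
  expect_equal(sum(tab > 0), 2) # one-to-one cluster/block correspondence
})

test_that("newick export round-trips through ape", {
  set.seed(35)
  m <- matrix(rbinom(4 * 6, 1, 0.5), nrow = 4)
  pm <- dplyr::bind_cols(
    tibble::tibble(species = sprintf("Sp%d", 1:4)),
    tibble::as_tibble(as.data.frame(m))
  )
  dn <- hierarchical_cluster(jaccard_distances(pm))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(dn, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, pm$species)
})
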