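# Partition-phenotype agreement: label loading, ARI, NMI, majority vote.

test_that("load_labels normalizes labels and handles unknowns, headers, duplicates", {
  p <- write_tmp_labels(c(
    "Bacteroides fragilis\tNonCleaver",
    "Bacteroides finegoldii\tcleaver",
    "Bacteroides ovatus\tMIXED",
    "Bacteroides sp1\tNA",
    "Bacteroides sp2\t"
  ))
  lab <- load_labels(p)
  expect_equal(lab$label, c("NonCleaver", "Cleaver", "Mixed", NA, NA))

  unk <- write_tmp_labels(c("Bacteroides x\tunknownish"))
  expect_warning(lab2 <- load_labels(unk), "unrecognized")
  expect_true(is.na(lab2$label))

  hdr <- write_tmp_labels(c("species\tlabel", "Bacteroides y\tCleaver"))
  lab3 <- load_labels(hdr)
  expect_equal(nrow(lab3), 1)
  expect_equal(lab3$label, "Cleaver")

  empty <- write_tmp_labels(character())
  expect_equal(nrow(load_labels(empty)), 0)

  conflict <- write_tmp_labels(c("Bacteroides z\tCleaver", "Bacteroides z\tNonCleaver"))
  expect_error(load_labels(conflict), "conflict")
  # duplicate but consistent rows collapse silently
  consistent <- write_tmp_labels(c("Bacteroides z\tCleaver", "Bacteroides z\tCleaver"))
  expect_equal(nrow(load_labels(consistent)), 1)
})

test_that("ARI matches the pair-counting oracle on canonical cases", {
  expect_equal(adjusted_rand_index(c(a = 1, b = 1, c = 2, d = 2), c(a = 1, b = 1, c = 2, d = 2)), 1)
  # crossed partitions {ab|cd} vs {ac|bd}: all pair agreements cancel
  p <- c(a = 1, b = 1, c = 2, d = 2)
  q <- c(a = 1, b = 2, c = 1, d = 2)
  expect_equal(adjusted_rand_index(p, q), oracle_ari(unname(p), unname(q)))
  expect_equal(adjusted_rand_index(p, q), -0.5)
  # degenerate cases (both partitions trivial) return 1/0 with a warning
  expect_warning(one <- adjusted_rand_index(c(a = 1, b = 1), c(a = 5, b = 5)), "degenerate")
  expect_equal(one, 1)
  expect_warning(ones <- adjusted_rand_index(c(a = 1, b = 2), c(a = 5, b = 6)), "degenerate")
  expect_equal(ones, 1)
  # single cluster against a non-trivial partition: index is 0 (convention)
  expect_equal(adjusted_rand_index(c(a = 1, b = 1, c = 1), c(a = 5, b = 5, c = 6)), 0)
  expect_error(adjusted_rand_index(c(a = 1), c(a = 1)), "2 species")
})

test_that("NMI is 1 for identical partitions up to relabeling and ~0 for independent ones", {
  x <- c(a = "C1", b = "C1", c = "C2", d = "C2")
  y <- c(a = "red", b = "red", c = "blue", d = "blue")
  expect_equal(normalized_mutual_information(x, y), 1)
  expect_equal(normalized_mutual_information(x, x), 1)
  # independent uniform partitions: mean NMI is small (it is biased up at
  # finite n, so the bound is loose but diagnostic)
  set.seed(40)
  vals <- replicate(100, {
    x <- sample(rep(1:2, each = 30))
    y <- sample(rep(1:2, each = 30))
    normalized_mutual_information(setNames(x, 1:60), setNames(y, 1:60))
  })
  expect_lt(mean(vals), 0.05)
  # all four normalizations stay in [0, 1] and agree at equal entropies
  for (norm in c("arithmetic", "geometric", "min", "max")) {
    v <- normalized_mutual_information(x, y, normalization = norm)
    expect_equal(v, 1)
  }
})

test_that("ARI and NMI are invariant under cluster relabeling", {
  set.seed(41)
  for (r in 1:25) {
    n <- sample(6:12, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:3, n, replace = TRUE)
    xr <- c(7, 5, 9)[x] # arbitrary relabeling
    yr <- c("z", "q", "m")[y]
    nm <- as.character(seq_len(n))
    a1 <- suppressWarnings(adjusted_rand_index(setNames(x, nm), setNames(y, nm)))
    a2 <- suppressWarnings(adjusted_rand_index(setNames(xr, nm), setNames(yr, nm)))
    expect_equal(a1, a2)
    n1 <- suppressWarnings(normalized_mutual_information(setNames(x, nm), setNames(y, nm)))
    n2 <- suppressWarnings(normalized_mutual_information(setNames(xr, nm), setNames(yr, nm)))
    expect_equal(n1, n2)
  }
})

test_that("ARI agrees with mclust on random partitions", {
  set.seed(45)
  for (r in 1:25) {
    n <- sample(8:20, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:3, n, replace = TRUE)
    nm <- as.character(seq_len(n))
    expect_equal(
      suppressWarnings(adjusted_rand_index(setNames(x, nm), setNames(y, nm))),
      mclust::adjustedRandIndex(x, y),
      tolerance = 1e-12
    )
  }
})

mk_partition <- function(...) {
  x <- c(...)
  tibble::tibble(species = names(x), cluster = unname(x))
}
mk_labels <- function(...) {
  x <- c(...)
  tibble::tibble(species = names(x), label = unname(x))
}

test_that("majority vote maps pure clusters perfectly", {
  part <- mk_partition(s1 = "C1", s2 = "C1", s3 = "C1")
  labs <- mk_labels(s1 = "Cleaver", s2 = "Cleaver", s3 = "Cleaver")
  rep1 <- suppressWarnings(majority_vote_map(part, labs)) # one cluster: ARI/NMI degenerate
  expect_equal(tidy(rep1)$mapped_label, "Cleaver")
  g <- glance(rep1)
  expect_equal(g$precision, 1)
  expect_equal(g$recall, 1)
  expect_equal(g$f1, 1)
  expect_equal(g$accuracy, 1)

  part2 <- mk_partition(
    a = "C1", b = "C1", c = "C1",
    d = "C2", e = "C2", f = "C2"
  )
  labs2 <- mk_labels(
    a = "Cleaver", b = "Cleaver", c = "Cleaver",
    d = "NonCleaver", e = "NonCleaver", f = "NonCleaver"
  )
  rep2 <- majority_vote_map(part2, labs2)
  expect_equal(glance(rep2)$accuracy, 1)
  expect_equal(rep2$ari, 1)
})

test_that("ties follow the policy and produce the expected confusion counts", {
  part <- mk_partition(
    a = "C1", b = "C1", c = "C1", d = "C1",
    e = "C2", f = "C2"
  )
  labs <- mk_labels(
    a = "Cleaver", b = "Cleaver", c = "NonCleaver", d = "NonCleaver",
    e = "Cleaver", f = "Cleaver"
  )
  noncl <- majority_vote_map(part, labs, tie_rule = "noncleaver")
  expect_equal(unname(noncl$confusion), c(2L, 0L, 2L, 2L)) # TP FP FN TN
  expect_equal(noncl$n_evaluated, 6)
  cl <- majority_vote_map(part, labs, tie_rule = "cleaver")
  expect_equal(unname(cl$confusion), c(4L, 2L, 0L, 0L))
  excl <- majority_vote_map(part, labs, tie_rule = "exclude")
  expect_equal(excl$n_evaluated, 2) # C1 dropped, only C2 remains
  expect_equal(unname(excl$confusion), c(2L, 0L, 0L, 0L))
  expect_error(majority_vote_map(part, labs, tie_rule = "coinflip"), "tie")
})

test_that("Mixed/NA species are excluded without affecting the rest", {
  part <- mk_partition(
    a = "C1", b = "C1", c = "C1", d = "C2", e = "C2", f = "C3"
  )
  labs <- mk_labels(
    a = "Cleaver", b = "Cleaver", c = "Mixed",
    d = "NonCleaver", e = NA, f = NA
  )
  rep <- majority_vote_map(part, labs)
  expect_equal(rep$n_labeled, 3)
  expect_equal(rep$n_excluded, 3)
  # cluster C3 has no labeled members -> Unlabeled
  expect_equal(tidy(rep)$mapped_label[tidy(rep)$cluster == "C3"], "Unlabeled")
  # excluding species does not change predictions of the remaining ones
  sub <- majority_vote_map(
    part[part$species %in% c("a", "b", "d"), ],
    labs[labs$species %in% c("a", "b", "d"), ]
  )
  both <- dplyr::inner_join(rep$predictions, sub$predictions,
    by = "species", suffix = c("_all", "_sub")
  )
  expect_equal(both$predicted_all, both$predicted_sub)
  # no labeled species at all is an error
  expect_error(
    majority_vote_map(part, mk_labels(a = "Mixed", b = NA, c = NA, d = "Mixed", e = NA, f = NA)),
    "no labeled"
  )
})

test_that("the F1 identity holds on every report", {
  set.seed(42)
  for (r in 1:20) {
    n <- 12
    part <- tibble::tibble(
      species = sprintf("s%d", 1:n),
      cluster = paste0("C", sample(1:3, n, replace = TRUE))
    )
    labs <- tibble::tibble(
      species = sprintf("s%d", 1:n),
      label = sample(c("Cleaver", "NonCleaver", "Mixed", NA), n, replace = TRUE)
    )
    rep <- tryCatch(suppressWarnings(majority_vote_map(part, labs)), error = function(e) NULL)
    if (is.null(rep)) next
    cf <- rep$confusion
    if (!is.na(rep$precision) && !is.na(rep$recall) && rep$precision + rep$recall > 0) {
      expect_equal(rep$f1, 2 * rep$precision * rep$recall / (rep$precision + rep$recall))
    }
    expect_equal(rep$accuracy, unname((cf["TP"] + cf["TN"]) / rep$n_evaluated))
    expect_equal(rep$n_labeled + rep$n_excluded, n)
  }
})
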