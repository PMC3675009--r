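test_that("purity follows the multiset formula and disregards unknowns", {
  p <- label_purity(c("true", "true", "false"))
  expect_equal(p$purity, 2 / 3)
  expect_equal(p$majority, "true")

  fam <- label_purity(c("AGC", "CAMK", "TK"))
  expect_equal(round(fam$purity, 2), 0.33)

  p2 <- label_purity(c("true", "true", "unknown", NA))
  expect_equal(p2$purity, 1.0)
  expect_equal(p2$n_known, 2L)

  # tie resolves to the first label in fixed order (false before true)
  tie <- label_purity(c("true", "false"))
  expect_equal(tie$purity, 0.5)
  expect_equal(tie$majority, "false")

  expect_error(label_purity(c("unknown", NA)), "no known labels")
})

hpc_fixture <- function() {
  # six sequences, one structure each; clusters: {s1,s2,s3} pure true
  # (with s3 unknown), {s4,s5} pure false, {s6} unknown-only singleton
  ids <- paste0("s", 1:6)
  set <- toy_set(ids, families = c("famA", "famB", "famA",
                                   "famA", "famA", "famC"))
  cl <- fake_clusterings(paste0(ids, "_x1"),
                         c(0L, 0L, 0L, 1L, 1L, 2L),
                         cluster_sil = c(`0` = 0.6, `1` = 0.4, `2` = 0))
  labels <- tibble::tibble(
    sequence_id = ids, compound_id = "drug",
    label = c("true", "true", "unknown", "false", "false", "unknown"))
  list(set = set, cl = cl, labels = labels)
}

test_that("HPC selection enforces purity, silhouette and known-label rules", {
  fx <- hpc_fixture()
  hp <- select_hpcs(fx$cl, fx$set, fx$labels, "drug")
  expect_equal(nrow(hp), 2L)
  expect_setequal(hp$majority_label, c("true", "false"))
  true_hpc <- hp[hp$majority_label == "true", ]
  # unknown member rides along in the member sets
  expect_true("s3" %in% true_hpc$member_sequence_ids[[1]])
  expect_equal(true_hpc$n_known, 2L)
  expect_equal(true_hpc$n_families, 2L)

  # negative mean silhouette disqualifies an otherwise pure cluster
  cl2 <- fake_clusterings(paste0(paste0("s", 1:6), "_x1"),
                          c(0L, 0L, 0L, 1L, 1L, 2L),
                          cluster_sil = c(`0` = -0.1, `1` = 0.4, `2` = 0))
  hp2 <- select_hpcs(cl2, fx$set, fx$labels, "drug")
  expect_equal(hp2$majority_label, "false")

  # mixed cluster rejected at full purity threshold
  mixed_labels <- fx$labels
  mixed_labels$label[4] <- "true"   # cluster 1 becomes {true, false}
  hp3 <- select_hpcs(fx$cl, fx$set, mixed_labels, "drug")
  expect_false(any(hp3$cluster_id == 1L))

  expect_error(select_hpcs(fx$cl, fx$set, fx$labels, "nonexistent"),
               "absent")
})

test_that("purity counting is sequence-weighted unless asked otherwise", {
  # sequence sdup has 3 structures in the cluster, all carrying label true;
  # a single false sequence shares the cluster
  sites <- dplyr::bind_rows(purrr::map(
    c("sdup_x1", "sdup_x2", "sdup_x3", "sone_x1"), function(id) {
      tibble::tibble(structure_id = id,
                     sequence_id = sub("_x.*", "", id),
                     family = "famA", column = 0:2, residue = "A",
                     x = 1:3, y = 0, z = 0)
    }))
  set <- aligned_structure_set(sites, 0:2)
  cl <- fake_clusterings(c("sdup_x1", "sdup_x2", "sdup_x3", "sone_x1"),
                         c(0L, 0L, 0L, 0L))
  labels <- tibble::tibble(sequence_id = c("sdup", "sone"),
                           compound_id = "drug",
                           label = c("true", "false"))
  # sequence-weighted: purity 1/2 -> no HPC at threshold 1
  expect_equal(nrow(select_hpcs(cl, set, labels, "drug")), 0L)
  seq_w <- select_hpcs(cl, set, labels, "drug", purity_threshold = 0.5)
  expect_equal(seq_w$purity, 0.5)
  # structure-weighted: 3 true structures vs 1 false -> purity 3/4
  str_w <- select_hpcs(cl, set, labels, "drug", purity_threshold = 0.5,
                       weight = "structure")
  expect_equal(str_w$purity, 0.75)
  expect_equal(str_w$majority_label, "true")
})

test_that("raising the purity threshold never increases the HPC count", {
  d <- synth_generate(synth_config(n_sequences = 14, P = 6,
                                   signal_subsets = list(c(0L, 2L, 4L)),
                                   label_noise_rate = 0.2,
                                   fraction_unlabeled = 0.2), seed = 5)
  cl <- cluster_subsets(d$set, seed = 5)
  counts <- vapply(c(0.5, 0.7, 0.9, 1.0), function(th) {
    nrow(select_hpcs(cl, d$set, d$labels, "cmpd-1",
                     purity_threshold = th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("purity distribution keeps only strict true-majority clusters", {
  ids <- paste0("s", 1:6)
  set <- toy_set(ids, families = c("famA", "famB", "famC",
                                   "famD", "famE", "famA"))
  # cluster 0: 5 true sequences across 5 families; cluster 1: 50/50
  cl <- fake_clusterings(paste0(ids, "_x1"), c(0L, 0L, 0L, 0L, 0L, 1L))
  labels <- tibble::tibble(
    sequence_id = ids, compound_id = "drug",
    label = c("true", "true", "true", "true", "true", "false"))
  pts <- purity_distribution(cl, set, labels, "drug")
  expect_equal(nrow(pts), 1L)
  expect_equal(pts$affinity_purity, 1.0)
  expect_equal(pts$phylo_purity, 0.2)

  # an exactly 50/50 cluster is excluded by the strict-majority rule
  labels5050 <- tibble::tibble(
    sequence_id = ids[1:4], compound_id = "drug",
    label = c("true", "true", "false", "false"))
  cl5050 <- fake_clusterings(paste0(ids[1:4], "_x1"), rep(0L, 4))
  set4 <- toy_set(ids[1:4])
  expect_equal(nrow(purity_distribution(cl5050, set4, labels5050, "drug")),
               0L)

  # an all-true single-family cluster sits at (1, 1)
  labels_all <- tibble::tibble(sequence_id = ids[1:3],
                               compound_id = "drug", label = "true")
  set_one_fam <- toy_set(ids[1:3])
  cl_all <- fake_clusterings(paste0(ids[1:3], "_x1"), rep(0L, 3))
  p_all <- purity_distribution(cl_all, set_one_fam, labels_all, "drug")
  expect_equal(p_all$affinity_purity, 1.0)
  expect_equal(p_all$phylo_purity, 1.0)
})

test_that("cross-family counting matches its definition and is order-invariant", {
  hp <- tibble::tibble(
    majority_label = c("true", "true", "true"),
    n_families = c(1L, 2L, 1L),
    family_set = list("TK", c("TK", "AGC"), "CMGC"))
  expect_equal(count_cross_family_hpcs(hp),
               tibble::tibble(n_true_hpcs = 3L, n_cross_family = 1L))
  shuffled <- hp[c(3, 1, 2), ]
  expect_equal(count_cross_family_hpcs(shuffled),
               count_cross_family_hpcs(hp))
  empty <- hp[0, ]
  expect_equal(count_cross_family_hpcs(empty),
               tibble::tibble(n_true_hpcs = 0L, n_cross_family = 0L))
  # false-majority HPCs never enter the count
  hp_false <- dplyr::mutate(hp, majority_label = "false")
  expect_equal(count_cross_family_hpcs(hp_false)$n_true_hpcs, 0L)
  # spanning count can never exceed the total
  expect_lte(count_cross_family_hpcs(hp)$n_cross_family,
             count_cross_family_hpcs(hp)$n_true_hpcs)
})
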