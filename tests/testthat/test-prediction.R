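vote_fixture <- function(n_per_class = 10, sep = 10, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    structure_id = paste0("s", seq_len(2 * n_per_class), "_x1"),
    sequence_id = paste0("s", seq_len(2 * n_per_class)),
    votes_true = c(round(sep + rnorm(n_per_class)),
                   round(rnorm(n_per_class, sd = 0.5))),
    votes_false = c(round(rnorm(n_per_class, sd = 0.5)),
                    round(sep + rnorm(n_per_class))),
    n_subsets = 100L,
    no_evidence = FALSE,
    label = rep(c("true", "false"), each = n_per_class))
}

test_that("vote tallying counts one vote per HPC membership", {
  ids <- paste0("s", 1:4)
  set <- toy_set(ids)
  struct_ids <- paste0(ids, "_x1")
  # five subsets; s1 sits in a true-HPC in all five, s4 in none
  rows <- purrr::map(1:5, function(k) {
    cl <- fake_clusterings(struct_ids, c(0L, 0L, 1L, 2L))
    cl$subset_id <- as.integer(k)
    cl
  })
  cl_all <- dplyr::bind_rows(rows)
  attr(cl_all, "structure_ids") <- struct_ids
  class(cl_all) <- c("triad_clusterings", class(cl_all))
  hpcs <- tibble::tibble(
    subset_id = 1:5, cluster_id = 0L, majority_label = "true")
  v <- tally_votes(hpcs, cl_all, set)
  expect_equal(v$votes_true[v$structure_id == "s1_x1"], 5L)
  expect_equal(v$votes_false[v$structure_id == "s1_x1"], 0L)
  # never inside an HPC -> all-zero votes, flagged
  expect_true(v$no_evidence[v$structure_id == "s4_x1"])
  # bound: total votes never exceed the number of subsets
  expect_true(all(v$votes_true + v$votes_false <= v$n_subsets))

  # empty HPC table -> everyone flagged
  v0 <- tally_votes(hpcs[0, ], cl_all, set)
  expect_true(all(v0$no_evidence))
})

test_that("the decision boundary separates a separable vote fixture", {
  votes <- vote_fixture()
  m <- train_decision_boundary(votes, seed = 3)
  expect_equal(m$training_accuracy, 1.0)
  preds <- predict(m, votes)
  expect_equal(preds$predicted_label, votes$label)
  expect_true(all(preds$confidence[preds$predicted_label == "true"] > 0.5))

  # swapped labels mirror the decision values
  swapped <- dplyr::mutate(votes,
                           label = ifelse(label == "true", "false", "true"))
  m2 <- train_decision_boundary(swapped, seed = 3)
  p2 <- predict(m2, votes)
  expect_equal(p2$decision_value, -preds$decision_value, tolerance = 1e-6)

  # determinism: identical data and seed give identical weights
  m3 <- train_decision_boundary(votes, seed = 3)
  expect_equal(tidy(m3), tidy(m))

  single <- dplyr::filter(votes, label == "true")
  expect_error(train_decision_boundary(single), "one class")
})

test_that("predictions ignore input order and respect the tie convention", {
  votes <- vote_fixture(seed = 7)
  m <- train_decision_boundary(votes)
  p_fwd <- predict(m, votes)
  p_rev <- predict(m, votes[rev(seq_len(nrow(votes))), ])
  expect_equal(p_rev[rev(seq_len(nrow(votes))), ], p_fwd)

  # zero-vote structures are excluded from scoring but reported
  votes$no_evidence[1] <- TRUE
  p <- predict(m, votes)
  expect_equal(p$predicted_label[1], "no-evidence")
  expect_true(is.na(p$decision_value[1]))
})

test_that("sequence aggregation averages decisions with ties to false", {
  preds <- tibble::tibble(
    sequence_id = c("a", "a", "a", "b", "b", "c", "d"),
    decision_value = c(1, 2, 3, 1, -1, 0.5, NA),
    confidence = c(0.6, 0.7, 0.8, 0.6, 0.4, 0.6, NA),
    predicted_label = c("true", "true", "true", "true", "false", "true",
                        "no-evidence"))
  agg <- aggregate_to_sequence(preds)
  expect_equal(agg$decision_value[agg$sequence_id == "a"], 2)
  expect_equal(agg$predicted_label[agg$sequence_id == "a"], "true")
  # exact zero resolves to false, the conservative call
  expect_equal(agg$decision_value[agg$sequence_id == "b"], 0)
  expect_equal(agg$predicted_label[agg$sequence_id == "b"], "false")
  # single-structure sequences pass through unchanged
  expect_equal(agg$decision_value[agg$sequence_id == "c"], 0.5)
  expect_equal(agg$predicted_label[agg$sequence_id == "d"], "no-evidence")
})

test_that("the rescoring engine reproduces the reference HPC/vote path", {
  d <- synth_generate(synth_config(n_sequences = 14, P = 6,
                                   signal_subsets = list(c(0L, 2L, 4L)),
                                   label_noise_rate = 0.15,
                                   fraction_unlabeled = 0.2), seed = 19)
  cl <- cluster_subsets(d$set, seed = 19)
  eng <- vote_engine(cl, d$set)
  lab <- compound_labels(d$labels, "cmpd-1")
  for (th in c(1.0, 0.75)) {
    hp <- select_hpcs(cl, d$set, d$labels, "cmpd-1",
                      purity_threshold = th)
    slow <- tally_votes(hp, cl, d$set)
    fast <- engine_votes(eng, lab, purity_threshold = th)
    merged <- dplyr::left_join(slow, fast, by = "structure_id",
                               suffix = c("_slow", "_fast"))
    expect_equal(merged$votes_true_slow, merged$votes_true_fast)
    expect_equal(merged$votes_false_slow, merged$votes_false_fast)
    expect_equal(merged$no_evidence_slow, merged$no_evidence_fast)
  }
  # masked labels, as used per cross-validation fold
  masked <- lab
  masked[1:4] <- "unknown"
  masked_tbl <- tibble::tibble(sequence_id = names(masked),
                               compound_id = "cmpd-1",
                               label = unname(masked))
  hp_m <- select_hpcs(cl, d$set, masked_tbl, "cmpd-1")
  slow_m <- tally_votes(hp_m, cl, d$set)
  fast_m <- engine_votes(eng, masked)
  expect_equal(slow_m$votes_true, fast_m$votes_true)
  expect_equal(slow_m$votes_false, fast_m$votes_false)
})

test_that("votes are reproducible from the stored clustering artifacts", {
  fx <- worked_example_fixture()
  cl <- cluster_subsets(fx$set, seed = 2)
  hp <- select_hpcs(cl, fx$set, fx$labels, "toy-compound")
  v1 <- tally_votes(hp, cl, fx$set)
  # recompute memberships from scratch and re-tally
  mem <- membership_tables(cl, fx$set)
  v2 <- tally_votes(hp, mem, fx$set)
  expect_equal(v1, v2)
  expect_true(all(v1$votes_true + v1$votes_false <= nrow(cl)))
})
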