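test_that("identity folds group by single linkage at the threshold", {
  # identical sequences always share a fold
  seqs <- c(a = "AKDF", b = "AKDF", c = "WWWW")
  plan <- build_identity_folds(seqs, 0.7)
  expect_equal(plan$fold[plan$sequence_id == "a"],
               plan$fold[plan$sequence_id == "b"])
  expect_false(plan$fold[plan$sequence_id == "a"] ==
                 plan$fold[plan$sequence_id == "c"])

  # transitive closure: A-B 0.9, B-C 0.8, A-C 0.3 -> one group
  m <- rbind(c(1, 0.9, 0.3), c(0.9, 1, 0.8), c(0.3, 0.8, 1))
  dimnames(m) <- list(c("A", "B", "C"), c("A", "B", "C"))
  p <- build_identity_folds(m, 0.7) |> suppressWarnings()
  expect_equal(length(unique(p$fold)), 1L)

  # identity exactly at the threshold still merges
  m2 <- rbind(c(1, 0.7), c(0.7, 1))
  dimnames(m2) <- list(c("A", "B"), c("A", "B"))
  p2 <- suppressWarnings(build_identity_folds(m2, 0.7))
  expect_equal(length(unique(p2$fold)), 1L)
})

test_that("looser thresholds produce coarser groupings, order-invariantly", {
  set.seed(10)
  seqs <- setNames(
    vapply(1:12, function(i) paste0(sample(c("A", "K", "D", "F"), 20,
                                           replace = TRUE), collapse = ""),
           character(1)),
    paste0("q", 1:12))
  # duplicate a few to create structure
  seqs["q2"] <- seqs["q1"]
  seqs["q5"] <- sub("^.", "K", seqs["q4"])
  p70 <- build_identity_folds(seqs, 0.7)
  p50 <- build_identity_folds(seqs, 0.5)
  # every 0.5-group is a union of 0.7-groups
  merged <- dplyr::left_join(p70, p50, by = "sequence_id",
                             suffix = c("_70", "_50"))
  by70 <- split(merged$fold_50, merged$fold_70)
  expect_true(all(vapply(by70, function(f) length(unique(f)) == 1L,
                         logical(1))))
  # input order does not change the grouping
  shuffled <- build_identity_folds(seqs[sample(names(seqs))], 0.7)
  cmp <- dplyr::left_join(p70, shuffled, by = "sequence_id",
                          suffix = c("_a", "_b"))
  tab <- table(cmp$fold_a, cmp$fold_b)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  expect_error(build_identity_folds(seqs[1]), "at least 2")
})

test_that("ROC AUC matches all-pairs concordance and pROC", {
  expect_equal(roc_pr(c(3, 2, 1), c(TRUE, FALSE, FALSE))$roc_auc, 1)
  expect_equal(roc_pr(c(1, 2, 3), c(TRUE, FALSE, FALSE))$roc_auc, 0)
  concordance <- function(score, truth) {
    pos <- score[truth]; neg <- score[!truth]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    mean(pairs)
  }
  set.seed(50)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    score <- round(rnorm(n), 1)          # rounding induces ties
    truth <- runif(n) < 0.4
    if (!any(truth) || all(truth)) next
    ours <- roc_pr(score, truth)
    expect_equal(ours$roc_auc, concordance(score, truth))
    ref <- suppressMessages(pROC::auc(pROC::roc(truth, score,
                                                quiet = TRUE,
                                                direction = "<")))
    expect_equal(ours$roc_auc, as.numeric(ref))
  }
  expect_error(roc_pr(c(1, 2), c(TRUE, TRUE)), "both classes")
})

test_that("PR AUC is near one for a clean ranking and low for a reversed one", {
  score <- 100:1
  truth <- c(rep(TRUE, 20), rep(FALSE, 80))
  expect_gt(roc_pr(score, truth)$pr_auc, 0.99)
  rev_auc <- roc_pr(-score, truth)$pr_auc
  expect_lt(rev_auc, 0.3)
  expect_true(rev_auc >= 0 && rev_auc <= 1)
})

test_that("enrichment factor follows its formula with a ceiling top bucket", {
  # perfect enrichment: all 5 actives in the top 5 of 100
  score <- 100:1
  truth <- c(rep(TRUE, 5), rep(FALSE, 95))
  ef <- enrichment_factor(score, truth)
  expect_equal(ef$ef, 20)
  expect_equal(ef$ef_max, 20)
  expect_equal(ef$n_top, 5L)

  # no active in the top bucket -> EF 0
  truth0 <- c(rep(FALSE, 95), rep(TRUE, 5))
  expect_equal(enrichment_factor(score, truth0)$ef, 0)

  # random rankings average to EF ~ 1
  set.seed(60)
  efs <- replicate(5000, {
    enrichment_factor(sample(100), truth)$ef
  })
  expect_equal(mean(efs), 1, tolerance = 0.1)

  # 0 <= EF <= EF_max on arbitrary seeded instances
  for (i in 1:20) {
    n <- sample(20:200, 1)
    tr <- runif(n) < runif(1, 0.05, 0.6)
    if (!any(tr)) next
    e <- enrichment_factor(rnorm(n), tr)
    expect_gte(e$ef, 0)
    expect_lte(e$ef, e$ef_max + 1e-12)
  }
  expect_error(enrichment_factor(1:5, rep(FALSE, 5)), "no actives")
})

test_that("cross-validation masks test labels out of purity computations", {
  d <- synth_generate(synth_config(n_sequences = 16, P = 6,
                                   signal_subsets = list(c(0L, 2L, 4L)),
                                   fraction_unlabeled = 0), seed = 9)
  cl <- cluster_subsets(d$set, seed = 9)
  plan <- build_identity_folds(d$sequences, 0.7)
  ev1 <- cross_validate(d$set, d$labels, "cmpd-1", plan, clusterings = cl)
  # flip one sequence's label: its own fold's prediction must not change,
  # because its label is masked before HPC selection in that fold
  flip_seq <- d$labels$sequence_id[1]
  labels2 <- d$labels
  labels2$label[1] <- ifelse(labels2$label[1] == "true", "false", "true")
  ev2 <- cross_validate(d$set, labels2, "cmpd-1", plan, clusterings = cl)
  d1 <- ev1$predictions[ev1$predictions$sequence_id == flip_seq, ]
  d2 <- ev2$predictions[ev2$predictions$sequence_id == flip_seq, ]
  expect_equal(d1$decision_value, d2$decision_value)
  expect_equal(d1$predicted_label, d2$predicted_label)
})

test_that("cross-validation recovers planted signal and collapses under permutation", {
  d <- synth_generate(synth_config(n_sequences = 24, P = 8,
                                   signal_subsets = list(c(1L, 3L, 5L)),
                                   fraction_unlabeled = 0.2), seed = 13)
  cl <- cluster_subsets(d$set, seed = 13)
  plan <- build_identity_folds(d$sequences, 0.7)
  ev <- cross_validate(d$set, d$labels, "cmpd-1", plan, clusterings = cl)
  expect_gte(ev$roc_auc, 0.9)

  # permuted labels destroy the signal
  aucs <- vapply(1:3, function(s) {
    perm <- d$labels
    known <- perm$label != "unknown"
    set.seed(100 + s)
    perm$label[known] <- sample(perm$label[known])
    tryCatch(cross_validate(d$set, perm, "cmpd-1", plan,
                            clusterings = cl)$roc_auc,
             error = function(e) NA_real_)
  }, numeric(1))
  expect_true(mean(aucs, na.rm = TRUE) > 0.2 &&
                mean(aucs, na.rm = TRUE) < 0.8)
})
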