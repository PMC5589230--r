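test_that("auc_from_scores matches hand-counted and degenerate cases", {
  expect_equal(auc_from_scores(c(0.9, 0.7), c(0.8, 0.6)), 0.75)
  expect_equal(auc_from_scores(c(5, 6), c(1, 2)), 1)
  expect_equal(auc_from_scores(rep(1, 4), rep(1, 9)), 0.5)
  expect_error(auc_from_scores(numeric(0), 1), "nonempty")
})

test_that("auc_from_scores equals the brute-force pairwise win fraction", {
  set.seed(31)
  for (i in 1:8) {
    np <- sample(1:120, 1); nn <- sample(1:80, 1)
    # coarse grid forces plenty of ties
    pos <- sample(seq(0, 1, 0.1), np, replace = TRUE)
    neg <- sample(seq(0, 1, 0.1), nn, replace = TRUE)
    expect_equal(auc_from_scores(pos, neg), oracle_auc(pos, neg),
                 tolerance = 1e-12)
  }
})

test_that("roc_curve is anchored, monotone, and integrates to the AUC", {
  roc <- roc_curve(c(3, 4), c(1, 2))
  expect_equal(roc[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(roc$tpr[roc$fpr == 0], c(0, 0.5, 1))

  roc <- roc_curve(rep(1, 3), rep(1, 5))  # all tied
  expect_equal(roc, data.frame(fpr = c(0, 1), tpr = c(0, 1)))

  # single positive above half the negatives: TPR jumps 0 -> 1 at FPR 0.5
  roc <- roc_curve(0.5, c(0.9, 0.8, 0.2, 0.1))
  expect_equal(roc$tpr[roc$fpr == 0.5], c(0, 1))

  set.seed(17)
  for (i in 1:8) {
    pos <- sample(seq(0, 1, 0.05), sample(2:50, 1), replace = TRUE)
    neg <- sample(seq(0, 1, 0.05), sample(2:50, 1), replace = TRUE)
    roc <- roc_curve(pos, neg)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(utils::tail(roc, 1L), data.frame(fpr = 1, tpr = 1),
                 ignore_attr = TRUE)
    area <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
    expect_equal(area, auc_from_scores(pos, neg), tolerance = 1e-12)
  }
})

# small planted-block fixture shared by the CV tests
block_records <- function(seed = 1, p_in = 0.9, p_out = 0.05,
                          nd = 9, nm = 18, blocks = 3)
  generate_block_association(
    block_model_spec(nd, nm, blocks, p_in = p_in, p_out = p_out,
                     seed = seed))

test_that("loocv recovers planted block structure and is deterministic", {
  rec <- block_records()
  cv <- loocv(rec)
  expect_s3_class(cv, "birw_cv")
  expect_gt(cv$auc, 0.5)
  expect_equal(cv$n_positive, nrow(deduplicate(rec)))
  expect_true(all(diff(cv$roc_points$fpr) >= 0) &&
                all(diff(cv$roc_points$tpr) >= 0))
  # rank-based ROC area equals the reported mean per-round AUC
  area <- sum(diff(cv$roc_points$fpr) *
                (head(cv$roc_points$tpr, -1) + cv$roc_points$tpr[-1]) / 2)
  expect_equal(area, cv$auc, tolerance = 1e-12)

  expect_identical(loocv(rec)$auc, cv$auc)  # no randomness in the protocol

  # fast approximate mode runs and stays in range
  fast <- loocv(rec, recompute_similarity = FALSE)
  expect_true(fast$auc >= 0 && fast$auc <= 1)

  expect_error(loocv(records_df(c("d1", "m1"))), "at least 2")
})

test_that("per-disease candidate pooling is available", {
  rec <- block_records(seed = 4)
  cv <- loocv(rec, per_disease = TRUE)
  expect_true(cv$auc >= 0 && cv$auc <= 1)
})

test_that("kfold_cv is seed-reproducible and sane on planted structure", {
  rec <- block_records(seed = 2)
  cv1 <- kfold_cv(rec, k = 5, repeats = 3, seed = 7)
  cv2 <- kfold_cv(rec, k = 5, repeats = 3, seed = 7)
  expect_identical(cv1$per_repeat_auc, cv2$per_repeat_auc)
  expect_equal(cv1$auc_mean, mean(cv1$per_repeat_auc))
  expect_equal(cv1$auc_sd, sd(cv1$per_repeat_auc))
  expect_gt(cv1$auc_mean, 0.5)

  cv3 <- kfold_cv(rec, k = 5, repeats = 3, seed = 8)
  expect_false(identical(cv1$per_repeat_auc, cv3$per_repeat_auc))

  expect_error(kfold_cv(rec, k = 1e6), "exceeds")
  expect_error(kfold_cv(rec, k = 1), "at least 2")
})

test_that("rank_candidates orders unverified microbes by score", {
  # hand-built 3x4 network: d3 shares m1 with d1 and m3 with d2;
  # among d3's candidates, m2 (profile identical to known partner m1)
  # must outrank m4 (associated with nothing)
  rec <- records_df(c("d1", "m1"), c("d1", "m2"), c("d2", "m3"),
                    c("d3", "m1"), c("d3", "m3"), c("d2", "m4"))
  fit <- predict_associations(rec)
  top <- rank_candidates(fit$MD, fit$A, "d3", top_k = 10)
  expect_equal(top$microbe[1], "m2")
  expect_equal(top$rank, seq_len(nrow(top)))
  expect_true(all(diff(top$score) <= 0))
  expect_true(!any(top$microbe %in% c("m1", "m3")))

  # disease with every microbe already associated -> empty table
  rec_full <- records_df(c("d1", "m1"), c("d1", "m2"), c("d2", "m1"))
  fit_full <- predict_associations(rec_full)
  expect_equal(nrow(rank_candidates(fit_full$MD, fit_full$A, "d1")), 0L)

  expect_error(rank_candidates(fit$MD, fit$A, "nope"), "valid names")
})

test_that("write_cv_result exports JSON and ROC TSV", {
  rec <- block_records(seed = 3)
  cv <- loocv(rec)
  path <- withr::local_tempfile(fileext = ".json")
  write_cv_result(cv, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$auc, cv$auc)
  expect_equal(back$params$alpha, 0.4)
  roc <- utils::read.table(paste0(path, ".roc.tsv"), header = TRUE)
  expect_equal(nrow(roc), nrow(cv$roc_points))
})
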