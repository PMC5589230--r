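#' Mann-Whitney AUC from positive and negative scores
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, counting ties as one half; identical to the trapezoidal area
#' under the threshold-swept ROC curve.
#'
#' @param positive_scores,negative_scores nonempty numeric vectors.
#' @return scalar in \[0, 1\].
#' @export
auc_from_scores <- function(positive_scores, negative_scores) {
  np <- length(positive_scores)
  nn <- length(negative_scores)
  if (np == 0L || nn == 0L)
    stop("both score vectors must be nonempty")
  r <- rank(c(positive_scores, negative_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Threshold-swept ROC curve
#'
#' One point per distinct score threshold, swept from +Inf downwards, plus
#' the anchors (0, 0) and (1, 1). Tied scores are grouped at one threshold,
#' so the trapezoidal area equals [auc_from_scores()] exactly.
#'
#' @inheritParams auc_from_scores
#' @return data frame with nondecreasing columns `fpr`, `tpr`.
#' @export
roc_curve <- function(positive_scores, negative_scores) {
  if (length(positive_scores) == 0L || length(negative_scores) == 0L)
    stop("both score vectors must be nonempty")
  scores <- c(positive_scores, negative_scores)
  labels <- rep(c(1L, 0L), c(length(positive_scores), length(negative_scores)))
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]; labels <- labels[ord]
  last <- cumsum(rle(scores)$lengths)  # last index of each threshold group
  tpr <- c(0, cumsum(labels)[last] / sum(labels))
  fpr <- c(0, cumsum(1L - labels)[last] / sum(1L - labels))
  data.frame(fpr = fpr, tpr = tpr)
}

trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

# Rank-based ROC for cross-validation: each held-out positive contributes
# its per-round false-positive fraction f_i (share of that round's
# candidates scoring above it, ties half). The curve is the empirical CDF
# of f, emitted as a staircase (both corners of every jump) so that its
# trapezoidal area is exactly mean(1 - f), the mean per-round AUC.
rank_roc <- function(fpr_per_positive) {
  f <- sort(fpr_per_positive)
  jump <- unique(f)
  before <- vapply(jump, function(x) mean(f < x), 0)
  after <- vapply(jump, function(x) mean(f <= x), 0)
  fpr <- c(0, rep(jump, each = 2L), 1)
  tpr <- c(0, as.numeric(rbind(before, after)), 1)
  keep <- !duplicated(cbind(fpr, tpr))
  data.frame(fpr = fpr[keep], tpr = tpr[keep])
}

#' Leave-one-out cross validation of the walk-based predictor
#'
#' Each known association is hidden in turn: its adjacency entry is set to
#' 0, both similarity matrices are recomputed from the reduced matrix, the
#' bi-random walk is rerun, and the held-out pair's score is compared with
#' the scores of all unverified pairs (entries that are 0 in the full
#' matrix) from the same round. Each round contributes the fraction of
#' candidates it outranks (ties half); the reported AUC is the mean over
#' rounds, i.e. the pooled probability that a held-out association outscores
#' a random unverified pair.
#'
#' With `per_disease = TRUE` the candidate pool of a round is restricted to
#' the unverified pairs of the held-out association's disease.
#'
#' @param records deduplicated association records (data frame with columns
#'   `disease`, `microbe`); at least 2 rows.
#' @inheritParams predict_associations
#' @param per_disease restrict candidates to the held-out disease's row.
#' @param recompute_similarity recompute SM/SD in every round (default,
#'   the faithful protocol); `FALSE` reuses the full-matrix similarities, a
#'   fast approximation for testing only.
#' @return object of class `"birw_cv"`: list with `auc`, `test_scores`,
#'   `fpr_per_positive`, `roc_points`, and the parameters used.
#' @export
loocv <- function(records, gamma_m = 1, gamma_d = 1, c = -15, d = log(9999),
                  params = birw_params(), per_disease = FALSE,
                  recompute_similarity = TRUE) {
  A <- build_adjacency(deduplicate(records))
  pos <- which(A == 1, arr.ind = TRUE)
  if (nrow(pos) < 2L)
    stop("leave-one-out cross validation needs at least 2 associations")
  neg_mask <- A == 0

  SM0 <- SD0 <- NULL
  if (!recompute_similarity) {
    SM0 <- microbe_similarity(A, gamma_prime = gamma_m)
    SD0 <- disease_similarity(A, gamma_prime = gamma_d, c = c, d = d)
  }

  fpr <- scores <- numeric(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    Ai <- A
    Ai[pos[i, 1L], pos[i, 2L]] <- 0L
    MD <- if (recompute_similarity) {
      predict_from_adjacency(Ai, gamma_m, gamma_d, c, d, params)$MD
    } else {
      bi_random_walk(Ai, SM0, SD0, params)
    }
    s <- MD[pos[i, 1L], pos[i, 2L]]
    negs <- if (per_disease) MD[pos[i, 1L], ][neg_mask[pos[i, 1L], ]]
            else MD[neg_mask]
    fpr[i] <- mean(negs > s) + 0.5 * mean(negs == s)
    scores[i] <- s
  }
  roc <- rank_roc(fpr)
  structure(list(auc = mean(1 - fpr), test_scores = scores,
                 fpr_per_positive = fpr, roc_points = roc,
                 method = "loocv", params = params,
                 n_positive = nrow(pos), n_candidate = sum(neg_mask)),
            class = "birw_cv")
}

#' Repeated k-fold cross validation
#'
#' Per repeat, the known associations are shuffled with the seeded generator
#' and split into `k` folds of near-equal size (differing by at most one).
#' Each fold's entries are zeroed together, similarities are recomputed, the
#' walk is rerun, and every held-out association is compared against the
#' unverified pairs (zero in the full matrix) of the same round. Per-repeat
#' AUC is the mean over its held-out associations; the mean and standard
#' deviation over repeats are reported.
#'
#' @inheritParams loocv
#' @param k number of folds (>= 2, <= number of associations).
#' @param repeats number of random re-divisions.
#' @param seed integer seed governing all repeats.
#' @return object of class `"birw_cv"` with `auc_mean`, `auc_sd`,
#'   `per_repeat_auc` (and `auc` as an alias of `auc_mean`).
#' @export
kfold_cv <- function(records, gamma_m = 1, gamma_d = 1, c = -15,
                     d = log(9999), params = birw_params(), k = 5L,
                     repeats = 100L, seed = 1L, per_disease = FALSE) {
  A <- build_adjacency(deduplicate(records))
  pos <- which(A == 1, arr.ind = TRUE)
  n <- nrow(pos)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds the number of associations (", n, ")")
  neg_mask <- A == 0

  set.seed(seed)
  per_repeat <- numeric(repeats)
  for (rep_i in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(k), n))
    fpr <- numeric(n)
    for (f in seq_len(k)) {
      held <- which(fold == f)
      Af <- A
      Af[pos[held, , drop = FALSE]] <- 0L
      MD <- predict_from_adjacency(Af, gamma_m, gamma_d, c, d, params)$MD
      for (i in held) {
        s <- MD[pos[i, 1L], pos[i, 2L]]
        negs <- if (per_disease) MD[pos[i, 1L], ][neg_mask[pos[i, 1L], ]]
                else MD[neg_mask]
        fpr[i] <- mean(negs > s) + 0.5 * mean(negs == s)
      }
    }
    per_repeat[rep_i] <- mean(1 - fpr)
  }
  structure(list(auc = mean(per_repeat), auc_mean = mean(per_repeat),
                 auc_sd = stats::sd(per_repeat),
                 per_repeat_auc = per_repeat, method = "kfold",
                 k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed), params = params,
                 n_positive = n, n_candidate = sum(neg_mask)),
            class = "birw_cv")
}

#' @export
print.birw_cv <- function(x, ...) {
  if (x$method == "loocv") {
    cat(sprintf("Leave-one-out CV: AUC %.4f (%d positives vs %d candidates)\n",
                x$auc, x$n_positive, x$n_candidate))
  } else {
    cat(sprintf("%d-fold CV, %d repeats: mean AUC %.4f (sd %.4f)\n",
                x$k, x$repeats, x$auc_mean, x$auc_sd))
  }
  invisible(x)
}

#' Top-ranked candidate microbes for one disease
#'
#' Ranks the microbes with no known association to `disease` by descending
#' prediction score; ties broken by microbe index order.
#'
#' @param MD disease x microbe score matrix (from the walk).
#' @param A the binary adjacency matrix defining which pairs are known.
#' @param disease disease name (must be a row of `A`).
#' @param top_k number of candidates to return, default 10.
#' @return data frame with columns `rank`, `microbe`, `score`.
#' @export
rank_candidates <- function(MD, A, disease, top_k = 10L) {
  check_adjacency(A)
  stopifnot(all(dim(MD) == dim(A)))
  if (!disease %in% rownames(A))
    stop("unknown disease '", disease, "'; valid names: ",
         paste(rownames(A), collapse = ", "))
  cand <- which(A[disease, ] == 0)
  if (length(cand) == 0L)
    return(data.frame(rank = integer(0), microbe = character(0),
                      score = numeric(0)))
  s <- MD[disease, cand]
  ord <- order(-s, seq_along(s))
  keep <- utils::head(ord, top_k)
  data.frame(rank = seq_along(keep),
             microbe = colnames(A)[cand[keep]],
             score = unname(s[keep]))
}

#' Export a cross-validation result as JSON, and ROC points as TSV
#'
#' @param cv a `"birw_cv"` object.
#' @param path output JSON path; if the result carries ROC points they are
#'   written alongside to `<path>.roc.tsv`.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(cv, path) {
  stopifnot(inherits(cv, "birw_cv"))
  out <- cv[intersect(names(cv), c("auc", "auc_mean", "auc_sd",
                                   "per_repeat_auc", "method", "k",
                                   "repeats", "seed",
                                   "n_positive", "n_candidate"))]
  out$params <- unclass(cv$params)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(cv$roc_points))
    utils::write.table(cv$roc_points, paste0(path, ".roc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
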