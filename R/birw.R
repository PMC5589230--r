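#' Bi-random walk parameters
#'
#' @param alpha decay factor in (0, 1]: at each step, weight `alpha` goes to
#'   propagated similarity mass and `1 - alpha` to the original association
#'   matrix, so longer walk paths (longer circular bigraphs) contribute less.
#' @param l step limit for the walk on the microbe similarity network.
#' @param r step limit for the walk on the disease similarity network. The
#'   two limits accommodate the different topologies of the two networks;
#'   `l + r >= 1`.
#' @param normalize_similarity Laplacian-normalize SM and SD before walking
#'   (default `TRUE`, the canonical bi-random-walk formulation).
#' @param normalize_seed scale the seed matrix to unit total mass,
#'   `MD0 = A / sum(A)` (default `TRUE`); the same scaled matrix is used in
#'   the `(1 - alpha)` restart term.
#' @return list of class `"birw_params"`.
#' @export
birw_params <- function(alpha = 0.4, l = 2L, r = 2L,
                        normalize_similarity = TRUE, normalize_seed = TRUE) {
  stopifnot(alpha > 0, alpha <= 1, l >= 0, r >= 0)
  if (l + r < 1) stop("no walk requested: need l + r >= 1")
  structure(list(alpha = alpha, l = as.integer(l), r = as.integer(r),
                 normalize_similarity = isTRUE(normalize_similarity),
                 normalize_seed = isTRUE(normalize_seed)),
            class = "birw_params")
}

#' Symmetric Laplacian normalization of a similarity matrix
#'
#' Returns \eqn{D^{-1/2} S D^{-1/2}} with `D` the diagonal matrix of row
#' sums. Keeps the matrix symmetric while bounding the spectral radius, so
#' repeated walk steps cannot blow up.
#'
#' @param S symmetric nonnegative square matrix with no all-zero row.
#' @return normalized matrix, same dimnames.
#' @export
laplacian_normalize <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  rs <- rowSums(S)
  if (any(rs <= 0)) {
    bad <- which(rs <= 0)[1L]
    nm <- if (!is.null(rownames(S))) rownames(S)[bad] else bad
    stop("cannot normalize: node '", nm, "' has zero total similarity")
  }
  d <- 1 / sqrt(rs)
  S * tcrossprod(d, d)
}

#' Bi-random walk on the heterogeneous microbe-disease network
#'
#' Starting from the seed `MD0` (the association matrix, optionally scaled
#' to unit mass), performs up to `l` steps of a random walk through the
#' microbe similarity network (right-multiplication,
#' `Rm = alpha * MD %*% SM + (1 - alpha) * A0`) and up to `r` steps through
#' the disease similarity network (left-multiplication,
#' `Rd = alpha * SD %*% MD + (1 - alpha) * A0`). While both sides are
#' active the two walk results are averaged; once the shorter side's limit
#' is exhausted the longer side continues alone. The walk runs for exactly
#' `max(l, r)` steps -- no convergence threshold -- and the final matrix MD
#' scores every disease-microbe pair.
#'
#' @param A binary disease x microbe adjacency matrix.
#' @param SM nm x nm microbe similarity matrix.
#' @param SD nd x nd disease similarity matrix.
#' @param params a [birw_params()] object.
#' @return disease x microbe score matrix with the dimnames of `A`.
#' @export
bi_random_walk <- function(A, SM, SD, params = birw_params()) {
  check_adjacency(A)
  stopifnot(inherits(params, "birw_params"))
  nd <- nrow(A); nm <- ncol(A)
  if (!is.matrix(SM) || any(dim(SM) != nm))
    stop("SM must be ", nm, "x", nm, " (one row/column per microbe)")
  if (!is.matrix(SD) || any(dim(SD) != nd))
    stop("SD must be ", nd, "x", nd, " (one row/column per disease)")

  if (params$normalize_similarity) {
    SM <- laplacian_normalize(SM)
    SD <- laplacian_normalize(SD)
  }
  A0 <- if (params$normalize_seed) A / sum(A) else A + 0
  alpha <- params$alpha
  MD <- A0
  for (t in seq_len(max(params$l, params$r))) {
    on_m <- t <= params$l
    on_d <- t <= params$r
    Rm <- if (on_m) alpha * (MD %*% SM) + (1 - alpha) * A0
    Rd <- if (on_d) alpha * (SD %*% MD) + (1 - alpha) * A0
    MD <- if (on_m && on_d) (Rm + Rd) / 2 else if (on_m) Rm else Rd
  }
  dimnames(MD) <- dimnames(A)
  MD
}

#' Full prediction pipeline from association records
#'
#' Composes [build_adjacency()], [microbe_similarity()],
#' [disease_similarity()] and [bi_random_walk()]; deterministic given inputs
#' and parameters.
#'
#' @param records data frame with columns `disease`, `microbe`
#'   (deduplicated).
#' @param gamma_m,gamma_d raw GIP bandwidths for microbes and diseases.
#' @param c,d logistic regulation parameters for the disease similarity.
#' @param params a [birw_params()] object.
#' @return list with the score matrix `MD`, the adjacency `A`, and the
#'   similarity matrices `SM`, `SD`.
#' @export
predict_associations <- function(records, gamma_m = 1, gamma_d = 1,
                                 c = -15, d = log(9999),
                                 params = birw_params()) {
  A <- build_adjacency(records)
  predict_from_adjacency(A, gamma_m, gamma_d, c, d, params)
}

# Same pipeline when the adjacency is already built (used by the CV loops,
# where held-out entries are zeroed in A but indices must not change).
predict_from_adjacency <- function(A, gamma_m = 1, gamma_d = 1,
                                   c = -15, d = log(9999),
                                   params = birw_params()) {
  SM <- microbe_similarity(A, gamma_prime = gamma_m)
  SD <- disease_similarity(A, gamma_prime = gamma_d, c = c, d = d)
  list(MD = bi_random_walk(A, SM, SD, params), A = A, SM = SM, SD = SD)
}
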