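#' Normalized Gaussian interaction-profile kernel bandwidth
#'
#' The raw bandwidth `gamma_prime` is divided by the mean squared norm of the
#' interaction profiles, so the kernel adapts to the overall density of the
#' association network:
#' \deqn{\gamma = \gamma' / \left(\frac{1}{n}\sum_k \|p_k\|^2\right)}
#'
#' @param profiles binary matrix, one interaction profile per row.
#' @param gamma_prime positive raw bandwidth, default 1.
#' @return the normalized bandwidth, a positive scalar.
#' @export
gip_bandwidth <- function(profiles, gamma_prime = 1) {
  stopifnot(is.matrix(profiles), gamma_prime > 0)
  msn <- mean(rowSums(profiles^2))
  if (msn == 0)
    stop("all interaction profiles are zero; kernel bandwidth is undefined")
  gamma_prime / msn
}

#' Gaussian interaction-profile kernel similarity
#'
#' Similarity between two nodes is a Gaussian of the squared Euclidean
#' distance between their binary interaction profiles,
#' \eqn{S_{ij} = \exp(-\gamma \|p_i - p_j\|^2)}, with the bandwidth
#' normalized by [gip_bandwidth()]. The result is symmetric with entries in
#' (0, 1] and an exact unit diagonal.
#'
#' @inheritParams gip_bandwidth
#' @return symmetric similarity matrix over the profile rows, carrying their
#'   rownames.
#' @export
gip_kernel <- function(profiles, gamma_prime = 1) {
  gamma <- gip_bandwidth(profiles, gamma_prime)
  d2 <- as.matrix(stats::dist(profiles, method = "euclidean"))^2
  S <- exp(-gamma * d2)
  diag(S) <- 1
  dimnames(S) <- list(rownames(profiles), rownames(profiles))
  S
}

#' Logistic regulation of a similarity matrix
#'
#' Applies \eqn{SD = 1 / (1 + e^{cK + d})} elementwise. With the default
#' slope `c = -15` and offset `d = log(9999)` (natural log), kernel values
#' near 0 map to ~0 (exactly 1e-4 at K = 0) and values near 1 map to ~1, so
#' the uninformative low-similarity range is suppressed. `c < 0` makes the
#' transform strictly increasing.
#'
#' @param K similarity matrix with entries in \[0, 1\].
#' @param c slope (negative), default -15.
#' @param d offset, default `log(9999)`.
#' @return transformed matrix of the same shape and dimnames.
#' @export
logistic_transform <- function(K, c = -15, d = log(9999)) {
  stopifnot(is.numeric(K))
  if (c >= 0)
    warning("logistic slope c >= 0: transform is not increasing in K")
  1 / (1 + exp(c * K + d))
}

#' Microbe GIP-kernel similarity from the association matrix
#'
#' Microbe interaction profiles are the columns of the disease x microbe
#' adjacency matrix; the similarity is their GIP kernel (no logistic
#' regulation on the microbe side).
#'
#' @param A binary disease x microbe adjacency matrix.
#' @param gamma_prime raw kernel bandwidth, default 1.
#' @return nm x nm symmetric matrix with unit diagonal (SM).
#' @export
microbe_similarity <- function(A, gamma_prime = 1) {
  check_adjacency(A)
  gip_kernel(t(A), gamma_prime)
}

#' Logistic-regulated disease GIP-kernel similarity
#'
#' Disease interaction profiles are the rows of the adjacency matrix. The
#' GIP kernel (KSD) is computed first and then regulated by
#' [logistic_transform()], diagonal included, yielding the final disease
#' similarity SD. The regulated diagonal is ~0.997 rather than 1; since
#' self-similarity never enters candidate ranking this is immaterial.
#'
#' @inheritParams microbe_similarity
#' @param c,d logistic parameters, see [logistic_transform()].
#' @param regulate logical; `FALSE` returns the raw kernel KSD.
#' @return nd x nd symmetric matrix (SD).
#' @export
disease_similarity <- function(A, gamma_prime = 1, c = -15, d = log(9999),
                               regulate = TRUE) {
  check_adjacency(A)
  K <- gip_kernel(A, gamma_prime)
  if (!regulate) return(K)
  logistic_transform(K, c = c, d = d)
}

#' Histogram of off-diagonal similarity values
#'
#' Bin counts of the strict upper-triangle entries over \[0, 1\] in steps of
#' `width`, mirroring the edge-weight frequency summaries of the similarity
#' networks.
#'
#' @param S square similarity matrix.
#' @param width bin width, default 0.1.
#' @return data frame with columns `lower`, `upper`, `count`.
#' @export
similarity_histogram <- function(S, width = 0.1) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  v <- pmin(pmax(S[upper.tri(S)], 0), 1)
  breaks <- seq(0, 1, by = width)
  nb <- length(breaks) - 1L
  bin <- pmin(findInterval(v, breaks, rightmost.closed = TRUE), nb)
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
             count = tabulate(bin, nbins = nb))
}
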