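# Independent brute-force oracles, deliberately written with explicit loops
# so they share no code path with the package implementation.

oracle_gip <- function(profiles, gamma_prime = 1) {
  n <- nrow(profiles)
  msn <- 0
  for (k in seq_len(n)) msn <- msn + sum(profiles[k, ]^2)
  gamma <- gamma_prime / (msn / n)
  S <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    S[i, j] <- exp(-gamma * sum((profiles[i, ] - profiles[j, ])^2))
  S
}

oracle_lapnorm <- function(S) {
  n <- nrow(S)
  rs <- numeric(n)
  for (i in seq_len(n)) rs[i] <- sum(S[i, ])
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- S[i, j] / sqrt(rs[i] * rs[j])
  out
}

# per-entry triple-loop bi-random walk
oracle_birw <- function(A, SM, SD, alpha, l, r,
                        normalize_similarity = TRUE, normalize_seed = TRUE) {
  if (normalize_similarity) {
    SM <- oracle_lapnorm(SM)
    SD <- oracle_lapnorm(SD)
  }
  A0 <- if (normalize_seed) A / sum(A) else A
  nd <- nrow(A); nm <- ncol(A)
  MD <- A0
  for (t in seq_len(max(l, r))) {
    Rm <- Rd <- NULL
    if (t <= l) {
      Rm <- matrix(0, nd, nm)
      for (i in seq_len(nd)) for (j in seq_len(nm)) {
        acc <- 0
        for (k in seq_len(nm)) acc <- acc + MD[i, k] * SM[k, j]
        Rm[i, j] <- alpha * acc + (1 - alpha) * A0[i, j]
      }
    }
    if (t <= r) {
      Rd <- matrix(0, nd, nm)
      for (i in seq_len(nd)) for (j in seq_len(nm)) {
        acc <- 0
        for (k in seq_len(nd)) acc <- acc + SD[i, k] * MD[k, j]
        Rd[i, j] <- alpha * acc + (1 - alpha) * A0[i, j]
      }
    }
    MD <- if (!is.null(Rm) && !is.null(Rd)) (Rm + Rd) / 2
          else if (!is.null(Rm)) Rm else Rd
  }
  MD
}

# pairwise win fraction, ties half
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

random_adjacency <- function(nd, nm, density = 0.3) {
  A <- matrix(as.integer(runif(nd * nm) < density), nd, nm)
  # ensure at least one association so bandwidths are defined
  if (sum(A) == 0) A[sample(nd, 1), sample(nm, 1)] <- 1L
  dimnames(A) <- list(paste0("D", seq_len(nd)), paste0("M", seq_len(nm)))
  A
}

records_df <- function(...) {
  pairs <- list(...)
  data.frame(disease = vapply(pairs, `[[`, "", 1L),
             microbe = vapply(pairs, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}
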