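# Independent oracles used to check the package implementations. Each is a
# deliberately naive, direct transcription of the defining formula or an
# exhaustive enumeration; none shares code with the package.

# Dense-matrix EM over candidate loci, run for a fixed number of iterations.
oracle_em <- function(aln, lambda = 0.1, theta_prior = 200000, n_iter = 10000) {
  frs <- sort(unique(aln$fragment_id))
  los <- sort(unique(aln$locus_id))
  W <- matrix(0, length(frs), length(los), dimnames = list(frs, los))
  for (r in seq_len(nrow(aln))) {
    W[aln$fragment_id[r], aln$locus_id[r]] <- exp(lambda * aln$score[r])
  }
  L <- length(los)
  theta <- theta_prior / L
  pi <- rep(1 / L, L)
  for (it in seq_len(n_iter)) {
    R <- W * rep(pi, each = nrow(W))
    R <- R / rowSums(R)
    pi <- (colSums(R) + theta) / (length(frs) + theta * L)
  }
  stats::setNames(pi, los)
}

# BH step-up by its textbook definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact two-sided Mann-Whitney p-value by enumerating all group assignments
# (tie-free inputs only; matches the exact convention 2*min(tail) capped at 1).
oracle_mw_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(length(pooled), nx)
  us <- apply(idx, 2, function(s) sum(r[s]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Two-sided Fisher exact p by enumerating all 2x2 tables with the observed
# margins (the sum-of-smaller-or-equal-probabilities convention).
oracle_fisher2x2 <- function(a, b, c_, d) {
  m <- a + b
  n_ <- c_ + d
  k <- a + c_
  xs <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(xs, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-sided (greater) hypergeometric overrepresentation p.
oracle_hyper_greater <- function(n_de_in_set, n_de, n_set, n_universe) {
  xs <- n_de_in_set:min(n_de, n_set)
  sum(stats::dhyper(xs, n_de, n_universe - n_de, n_set))
}

# Direct median-of-ratios size factors (all-positive matrices only).
oracle_size_factors <- function(m) {
  geo <- apply(m, 1, function(x) exp(mean(log(x))))
  apply(m, 2, function(col) stats::median(col / geo))
}

# Brute-force nearest-gene distance: minimum interval gap over every gene on
# the HERV's chromosome, NA when the minimum exceeds the window limit.
oracle_nearest_distance <- function(herv, genes, max_window = 10000) {
  g <- genes[genes$chrom == herv$chrom, ]
  if (nrow(g) == 0) return(NA_integer_)
  gaps <- pmax(0L, pmax(g$start - herv$end, herv$start - g$end))
  d <- min(gaps)
  if (d < max_window) d else NA_integer_
}

# Mean pairwise Jaccard similarity of binarized replicate columns, averaged
# over conditions — direct transcription used to check the threshold search.
oracle_jaccard_similarity <- function(m, cond, s) {
  B <- m > s
  mean(sapply(unique(cond), function(cc) {
    cols <- which(cond == cc)
    prs <- utils::combn(cols, 2)
    mean(apply(prs, 2, function(p) {
      un <- sum(B[, p[1]] | B[, p[2]])
      if (un == 0) 1 else sum(B[, p[1]] & B[, p[2]]) / un
    }))
  }))
}
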