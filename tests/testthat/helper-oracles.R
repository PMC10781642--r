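# Dense-matrix oracles, independent of the package's message-passing engine.

# full tip covariance, GLS mean, quadratic form, log-likelihood
dense_bm <- function(tree, x, sigma2 = NULL, root = NULL) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  n <- length(x)
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- root
  if (is.null(mu)) mu <- as.numeric((one %*% Ci %*% x) / (one %*% Ci %*% one))
  Q <- as.numeric(t(x - mu) %*% Ci %*% (x - mu))
  s2 <- sigma2
  if (is.null(s2)) s2 <- Q / n
  ll <- -n / 2 * log(2 * pi * s2) -
    0.5 * as.numeric(determinant(C)$modulus) - Q / (2 * s2)
  list(mu = mu, sigma2 = s2, Q = Q, loglik = ll)
}

# GLS/BLUP ancestral states (means and variances) from the full covariance
dense_anc <- function(tree, x) {
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  C <- ape::vcv(tree)
  ord <- match(tree$tip.label, rownames(C))
  C <- C[ord, ord]
  x <- x[tree$tip.label]
  Ci <- solve(C)
  one <- rep(1, n)
  s1 <- as.numeric(one %*% Ci %*% one)
  mu <- as.numeric((one %*% Ci %*% x) / s1)
  nh <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  est <- numeric(N)
  v <- numeric(N)
  est[1:n] <- x
  for (k in (n + 1):N) {
    ck <- nh[M[k, 1:n]]
    est[k] <- mu + as.numeric(ck %*% Ci %*% (x - mu))
    v[k] <- nh[k] - as.numeric(t(ck) %*% Ci %*% ck) +
      (1 - as.numeric(t(ck) %*% Ci %*% one))^2 / s1
  }
  list(estimate = est, variance = v)
}

# marginal variance of the reconstructed change per branch under the null
dense_eff_len <- function(tree) {
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  C <- ape::vcv(tree)
  ord <- match(tree$tip.label, rownames(C))
  C <- C[ord, ord]
  Ci <- solve(C)
  one <- rep(1, n)
  g1 <- Ci %*% one
  s1 <- as.numeric(one %*% g1)
  nh <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  W <- matrix(0, N, n)
  W[cbind(1:n, 1:n)] <- 1
  for (k in (n + 1):N) {
    ck <- nh[M[k, 1:n]]
    W[k, ] <- as.numeric(t(ck) %*% Ci) +
      as.numeric(1 - t(ck) %*% g1) * as.numeric(t(g1)) / s1
  }
  B <- W %*% C %*% t(W)
  vapply(seq_len(nrow(tree$edge)), function(i) {
    p <- tree$edge[i, 1]
    ch <- tree$edge[i, 2]
    B[ch, ch] + B[p, p] - 2 * B[ch, p]
  }, numeric(1))
}

# exact two-sided Wilcoxon rank-sum p by exhaustive enumeration (no ties)
enum_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combs <- utils::combn(length(pooled), length(a))
  ws <- apply(combs, 2, function(idx) {
    sum(r[idx]) - length(a) * (length(a) + 1) / 2
  })
  mu <- length(a) * length(b) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu))
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

make_named <- function(values, tree) stats::setNames(values, tree$tip.label)

# internal accessor: phylo with generation-scaled edge lengths
gen_tree_phylo_for_test <- function(gtree) {
  tr <- gtree$tree
  tr$edge.length <- gtree$edge_generations
  tr
}
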