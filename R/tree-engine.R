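## Internal Gaussian message-passing engine for Brownian motion on a rooted
## tree. All quantities are per unit sigma^2: branch lengths play the role of
## variances. This single engine backs ancestral_states(), bm_loglik(),
## estimate_sigma_g() and the reconstruction-aware effective branch lengths
## used by branch_rate_ratios().

# postorder edge permutation: index into rows of tree$edge
po_order <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  match(
    paste(po$edge[, 1], po$edge[, 2]),
    paste(tree$edge[, 1], tree$edge[, 2])
  )
}

check_tip_match <- function(tree, x) {
  if (is.null(names(x))) {
    abort("trait values must be named by species (tip labels)")
  }
  missing <- setdiff(tree$tip.label, names(x))
  if (length(missing)) {
    abort(paste0(
      "trait values missing for tips: ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  x[tree$tip.label]
}

## Upward (pruning) pass.
## Returns per-node conditional mean m and extra variance d of the subtree
## message, plus the profile-likelihood ingredients: quadratic form Q (at the
## GLS mean, unit sigma^2) and log-determinant of the tip covariance matrix.
bm_up_pass <- function(tree, x, len = tree$edge.length) {
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  ord <- po_order(tree)
  E <- tree$edge
  m <- numeric(N)
  d <- numeric(N)
  m[seq_len(n)] <- check_tip_match(tree, x)
  W <- numeric(N)  # accumulated precision
  M1 <- numeric(N) # accumulated precision-weighted mean
  M2 <- numeric(N) # accumulated precision-weighted second moment
  L <- numeric(N)  # accumulated log of child edge variances
  Q <- 0
  logV <- 0
  finalize <- function(k) {
    if (W[k] <= 0) abort("internal node with no processed children")
    m[k] <<- M1[k] / W[k]
    d[k] <<- 1 / W[k]
    Q <<- Q + M2[k] - M1[k]^2 / W[k]
    logV <<- logV + L[k] + log(W[k])
  }
  done <- logical(N)
  for (i in ord) {
    p <- E[i, 1]
    ch <- E[i, 2]
    if (ch > n && !done[ch]) {
      finalize(ch)
      done[ch] <- TRUE
    }
    ve <- len[i] + d[ch]
    if (ve <= 0) {
      abort("non-positive edge variance (duplicate zero-length tips?)")
    }
    w <- 1 / ve
    W[p] <- W[p] + w
    M1[p] <- M1[p] + w * m[ch]
    M2[p] <- M2[p] + w * m[ch]^2
    L[p] <- L[p] + log(ve)
  }
  root <- n + 1L
  finalize(root)
  logV <- logV + log(d[root])
  list(m = m, d = d, Q = Q, logV = logV, root = root, n = n, N = N, ord = ord)
}

## Full two-way belief propagation. On top of the upward pass, computes for
## every node the conditional (posterior) mean and variance given the tip data
## with a flat prior on the root state (equivalent to GLS estimation of the
## root), and per-edge quantities needed for effective branch lengths:
## kappa (regression coefficient of child on parent) and the conditional
## variance of the branch change (descendant minus ancestor).
bm_bp <- function(tree, x, len = tree$edge.length) {
  up <- bm_up_pass(tree, x, len)
  n <- up$n
  N <- up$N
  E <- tree$edge
  root <- up$root
  m <- up$m
  d <- up$d

  ## children lists
  kids <- split(seq_len(nrow(E)), E[, 1])

  ## down messages: at node k (non-root), the message from the rest of the
  ## tree has mean u[k] and variance e[k] (Inf precision never occurs for
  ## positive lengths). P = 1/e; root has P = 0 (flat prior).
  u <- numeric(N)
  eP <- numeric(N) # precision of down message
  uP <- numeric(N) # precision-weighted mean of down message
  post_mean <- numeric(N)
  post_var <- numeric(N)

  ## process nodes in preorder (reverse postorder of parents)
  ord <- up$ord
  parents_pre <- rev(unique(E[ord, 1]))
  for (p in parents_pre) {
    es <- kids[[as.character(p)]]
    w <- 1 / (len[es] + d[E[es, 2]])
    wm <- w * m[E[es, 2]]
    totP <- eP[p] + sum(w)
    totM <- uP[p] + sum(wm)
    post_mean[p] <- totM / totP
    post_var[p] <- 1 / totP
    for (j in seq_along(es)) {
      ch <- E[es[j], 2]
      exP <- totP - w[j]
      exM <- totM - wm[j]
      ## message to child ch: (exM/exP) with variance 1/exP + len
      ev <- 1 / exP + len[es[j]]
      eP[ch] <- 1 / ev
      uP[ch] <- (exM / exP) / ev
      u[ch] <- exM / exP
    }
  }
  post_mean[seq_len(n)] <- m[seq_len(n)]
  post_var[seq_len(n)] <- 0

  ## per-edge: conditional variance of (child - parent) given tips
  kappa <- numeric(nrow(E))
  cond_var_delta <- numeric(nrow(E))
  for (i in seq_len(nrow(E))) {
    p <- E[i, 1]
    ch <- E[i, 2]
    if (ch <= n) {
      cond_var_delta[i] <- post_var[p]
      kappa[i] <- NA_real_
    } else {
      k <- (1 / len[i]) / (1 / d[ch] + 1 / len[i])
      ## note: kappa uses only the subtree message of the child; the identity
      ## Cov(child, parent | tips) = kappa * Var(parent | tips) holds because
      ## child is independent of the rest of the tree given its parent and
      ## its own subtree.
      kappa[i] <- k
      cond_var_delta[i] <- post_var[ch] + post_var[p] -
        2 * k * post_var[p]
    }
  }
  eff_len <- pmax(len - cond_var_delta, 0)

  list(
    mean = post_mean, var = post_var, eff_len = eff_len,
    Q = up$Q, logV = up$logV, mu = m[root], root = root, n = n
  )
}

## Profile (maximized) Brownian-motion likelihood on a tree with given edge
## lengths: root state and sigma^2 estimated analytically by GLS.
bm_profile <- function(tree, x, len = tree$edge.length) {
  up <- bm_up_pass(tree, x, len)
  n <- up$n
  sigma2 <- up$Q / n
  loglik <- if (sigma2 > 0) {
    -n / 2 * log(2 * pi * sigma2) - up$logV / 2 - n / 2
  } else {
    Inf
  }
  list(
    mu = up$m[up$root], sigma2 = sigma2, loglik = loglik,
    Q = up$Q, logV = up$logV, n = n
  )
}

#' Brownian-motion log-likelihood on a phylogeny
#'
#' Evaluates the multivariate-normal log-likelihood of a continuous trait
#' under homogeneous Brownian motion on a rooted tree, with trait covariance
#' `sigma2` times the shared path length between tips. Computed by
#' Felsenstein's pruning algorithm in one O(n) pass, so no dense covariance
#' matrix is formed. When `sigma2` or `root` are `NULL` they are profiled
#' analytically (GLS root, maximum-likelihood variance).
#'
#' @param tree a rooted `phylo` tree; branch lengths are the unit of variance.
#' @param trait named numeric vector of tip values (names = tip labels).
#' @param sigma2 Brownian variance per unit branch length, or `NULL` to use
#'   the maximum-likelihood value.
#' @param root root state, or `NULL` to use the GLS estimate.
#' @param scalars optional per-edge multiplicative branch-length scalars
#'   (numeric, one per row of `tree$edge`).
#' @return a list with `loglik`, `sigma2`, `root` (values used), and `profiled`
#'   flags.
#' @examples
#' tr <- ape::rtree(5)
#' x <- stats::setNames(rnorm(5), tr$tip.label)
#' bm_loglik(tr, x)$loglik
#' @export
bm_loglik <- function(tree, trait, sigma2 = NULL, root = NULL, scalars = NULL) {
  len <- tree$edge.length
  if (!is.null(scalars)) {
    stopifnot(length(scalars) == nrow(tree$edge), all(scalars > 0))
    len <- len * scalars
  }
  if (!is.null(sigma2) && sigma2 <= 0) abort("sigma2 must be > 0")
  up <- bm_up_pass(tree, trait, len)
  n <- up$n
  mu <- root %||% up$m[up$root]
  ## quadratic form at arbitrary mean mu: Q(mu) = Q(muhat) + (mu - muhat)^2 / d_root
  Q <- up$Q + (mu - up$m[up$root])^2 / up$d[up$root]
  s2 <- sigma2 %||% (Q / n)
  ll <- -n / 2 * log(2 * pi * s2) - up$logV / 2 - Q / (2 * s2)
  list(
    loglik = ll, sigma2 = s2, root = mu,
    profiled = c(sigma2 = is.null(sigma2), root = is.null(root))
  )
}
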