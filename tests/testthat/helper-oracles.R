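# Independent brute-force oracles and tiny fixtures shared across tests.
# These deliberately re-derive each statistic from its definition with
# plain loops, so they share no code path with the package.

tiny_table <- function() {
  m <- matrix(c(10L, 0L, 2L, 1L,
                4L, 4L, 8L, 0L,
                0L, 6L, 3L, 2L), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("t1", "t2", "t3", "t4")))
  tax <- data.frame(
    phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes", "Bacteroidetes"),
    family = c("Lachnospiraceae", "Ruminococcaceae", "Prevotellaceae",
               "Prevotellaceae"),
    genus = c("t1", "t2", "t3", "t4"),
    row.names = c("t1", "t2", "t3", "t4"))
  feature_table(m, taxonomy = tax)
}

quick_config <- function(...) {
  defaults <- list(n_hosts = 20, n_taxa = 40, n_core_taxa = 8,
                   depth_range = c(800, 1500), seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# ANOSIM R from its definition: midranks over all pairwise distances.
bf_anosim_R <- function(dm, groups) {
  md <- as.matrix(dm)
  n <- nrow(md)
  pairs <- t(combn(n, 2))
  d <- md[pairs]
  rk <- rank(d)   # midranks for ties
  within <- groups[pairs[, 1]] == groups[pairs[, 2]]
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}

# SIMPER contributions from the definition: average over between-group
# pairs of the per-taxon Bray-Curtis numerator share, normalized to 1.
bf_simper <- function(m, groups) {
  g <- unique(groups)
  ia <- which(groups == g[1]); ib <- which(groups == g[2])
  contrib <- rep(0, ncol(m))
  np <- 0
  for (i in ia) for (j in ib) {
    denom <- sum(m[i, ] + m[j, ])
    contrib <- contrib + abs(m[i, ] - m[j, ]) / denom
    np <- np + 1
  }
  contrib <- contrib / np
  stats::setNames(contrib / sum(contrib), colnames(m))
}

# Exhaustive PAM objective: minimum over all k-subsets of medoids of the
# total distance of each point to its nearest medoid.
bf_pam_objective <- function(dm, k) {
  md <- as.matrix(dm)
  n <- nrow(md)
  best <- Inf
  for (med in combn(n, k, simplify = FALSE)) {
    obj <- sum(apply(md[, med, drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

# Silhouette widths from the definition.
bf_silhouette <- function(dm, labels) {
  md <- as.matrix(dm)
  n <- nrow(md)
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(md[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(md[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
}

# UniFrac by explicit enumeration of branches: for every edge, the set of
# descendant tips decides the subtree abundance of each sample.
bf_unifrac <- function(tree, x, y, weighted) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  desc <- function(node) {
    if (node <= n_tip) return(tips[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  px <- x / sum(x); py <- y / sum(y)
  num <- denom <- shared_only <- total_len <- 0
  for (e in seq_len(nrow(tree$edge))) {
    b <- tree$edge.length[e]
    below <- desc(tree$edge[e, 2])
    pa <- sum(px[below]); pb <- sum(py[below])
    num <- num + b * abs(pa - pb)
    denom <- denom + b * (pa + pb)
    present_a <- any(x[below] > 0); present_b <- any(y[below] > 0)
    if (xor(present_a, present_b)) shared_only <- shared_only + b
    if (present_a || present_b) total_len <- total_len + b
  }
  if (weighted) num / denom else shared_only / total_len
}

# Random-walk Metropolis on the marginal likelihood of the variance
# components (beta integrated out under a flat prior), an independent
# route to the posterior of m2 on small problems.
bf_marginal_m2 <- function(y, X, M, nu, S2, n_iter = 20000, seed = 1) {
  set.seed(seed)
  n <- length(y)
  logpost <- function(ls) {
    s2m <- exp(ls[1]); s2e <- exp(ls[2])
    V <- s2m * M + diag(s2e, n)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(-Inf)
    Vi <- chol2inv(cV)
    XtVi <- crossprod(X, Vi)
    A <- XtVi %*% X
    cA <- chol(A)
    bhat <- solve(A, XtVi %*% y)
    r <- y - X %*% bhat
    ll <- -sum(log(diag(cV))) - sum(log(diag(cA))) -
      0.5 * drop(crossprod(r, Vi %*% r))
    # scaled-inv-chi2 priors on the variance scale + log-scale Jacobian
    lp <- function(s2) (-(nu / 2 + 1)) * log(s2) - nu * S2 / (2 * s2) + log(s2)
    ll + lp(s2m) + lp(s2e)
  }
  cur <- log(c(var(y) / 2, var(y) / 2))
  lp <- logpost(cur)
  draws <- matrix(NA_real_, n_iter, 2)
  for (i in seq_len(n_iter)) {
    prop <- cur + rnorm(2, 0, 0.25)
    lpp <- logpost(prop)
    if (log(runif(1)) < lpp - lp) { cur <- prop; lp <- lpp }
    draws[i, ] <- exp(cur)
  }
  draws <- draws[-seq_len(n_iter / 4), ]
  mean(draws[, 1] / rowSums(draws))
}
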