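# Independent brute-force oracles used to check the pruning implementation.
# These deliberately take the dense linear-algebra route (explicit
# shared-path covariance matrices, direct multivariate-normal conditioning)
# rather than any tree recursion.

# Dense covariance (time units) among ALL nodes: cov(i, j) equals the
# root-to-node depth of the most recent common ancestor of i and j.
dense_cov <- function(tree) {
  tr <- tree
  tr$edge.length <- pmax(tr$edge.length, 1e-9)
  depth <- ape::node.depth.edgelength(tr)
  M <- ape::mrca(tr, full = TRUE)
  matrix(depth[M], nrow = nrow(M))
}

# GLS / conditional-normal reconstruction with a flat root prior:
# estimates and variances (sigma2 = 1) for every node given the observed
# tips. Works equally as an imputation oracle (missing tips are just
# unobserved nodes).
oracle_gls <- function(tree, x) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  C <- dense_cov(tree)
  xt <- x[tree$tip.label]
  oi <- which(!is.na(xt))
  xo <- xt[oi]
  Ci <- solve(C[oi, oi, drop = FALSE])
  denom <- sum(Ci)
  mu <- sum(Ci %*% xo) / denom
  est <- numeric(nn)
  vr <- numeric(nn)
  for (i in seq_len(nn)) {
    ci <- C[i, oi]
    w <- as.numeric(Ci %*% ci)
    est[i] <- mu + sum(w * (xo - mu))
    vr[i] <- C[i, i] - sum(ci * w) + (1 - sum(w))^2 / denom
  }
  list(estimates = est, variances = vr, root_mean = mu)
}

# Exhaustive moving-maximum enumeration over a generous range of
# step-anchored half-open bins.
oracle_moving_max <- function(ages, values, window, step, offset) {
  ks <- seq(floor((min(ages) - window) / step) - 2,
            ceiling(max(ages) / step) + 2)
  rep_age <- numeric(0)
  val <- numeric(0)
  for (k in ks) {
    s <- k * step
    sel <- ages >= s & ages < s + window
    if (any(sel)) {
      rep_age <- c(rep_age, s + window / 2 - offset)
      val <- c(val, max(values[sel]))
    }
  }
  o <- order(rep_age, decreasing = TRUE)
  data.frame(reported_age = rep_age[o], value = val[o])
}

# Random test case: seeded Yule tree with BM tip values and optionally one
# masked tip (always leaving >= 2 observed).
random_bm_case <- function(seed, n_min = 2, n_max = 6, mask = FALSE) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  tree <- simulate_yule_tree(n, birth_rate = 0.02, seed = seed + 1000L)
  sim <- simulate_bm_traits(tree, root_state = 100, sigma2 = 0.5,
                            seed = seed + 2000L)
  x <- sim$tips
  if (mask && n > 2) x[sample.int(n, 1)] <- NA_real_
  list(tree = tree, x = x, truth = sim$states)
}
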