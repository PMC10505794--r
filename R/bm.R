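#' @title Brownian-motion reconstruction on timetrees
#' @description Internal engine and user-facing functions for ML ancestral
#'   state reconstruction, missing-tip imputation and REML rate estimation
#'   under Brownian motion (BM). Under BM a trait accrues independent
#'   Gaussian increments of variance `sigma2 * branch length`, so any two
#'   nodes covary by `sigma2` times their shared root-to-node path length.
#' @name bm-reconstruction
#' @keywords internal
NULL

# Branch lengths of exactly zero would make the trait covariance singular;
# they are floored at this value (My).
.MIN_BRANCH_MY <- 1e-9

check_timetree <- function(tree) {
  if (!inherits(tree, "phylo")) {
    stop("'tree' must be an ape \"phylo\" object", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("'tree' must have branch lengths (My)", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("branch lengths must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("tip labels must be unique", call. = FALSE)
  }
  invisible(tree)
}

# Align a named trait vector with the tips of a tree. Tips absent from the
# vector become NA (missing); names not on the tree are an error.
align_observations <- function(tree, x) {
  if (is.null(names(x))) {
    stop("trait observations must be named by tip label", call. = FALSE)
  }
  unknown <- setdiff(names(x), tree$tip.label)
  if (length(unknown)) {
    stop("observation(s) for unknown tip(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop("duplicate tip names in observations", call. = FALSE)
  }
  out <- x[tree$tip.label]
  names(out) <- tree$tip.label
  bad <- !is.na(out) & !is.finite(out)
  if (any(bad)) {
    stop("non-finite trait value(s) at: ",
         paste(tree$tip.label[bad], collapse = ", "), call. = FALSE)
  }
  out
}

node_names <- function(tree) {
  ntip <- length(tree$tip.label)
  inner <- tree$node.label
  if (is.null(inner) || !length(inner) || any(!nzchar(inner))) {
    inner <- paste0("node", ntip + seq_len(tree$Nnode))
  }
  c(tree$tip.label, inner)
}

# Two-pass Gaussian message passing on the tree (post-order pruning then
# pre-order marginalisation). Missing tips carry no information (infinite
# variance). Returns, for every node, the marginal ML estimate and its
# variance in *time units* (multiply by sigma2 for trait units^2), plus the
# standardized independent contrasts accumulated on the way up (the REML
# sufficient statistics for sigma2). All quantities are sigma2-free.
bm_message_pass <- function(tree, x) {
  check_timetree(tree)
  obs <- align_observations(tree, x)
  if (sum(!is.na(obs)) < 2L) {
    stop("at least 2 observed tips are required", call. = FALSE)
  }
  post <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(post$tip.label)
  nn <- ntip + post$Nnode
  parent <- post$edge[, 1L]
  child <- post$edge[, 2L]
  el <- pmax(post$edge.length, .MIN_BRANCH_MY)

  below_mu <- rep(NA_real_, nn)
  below_v <- rep(Inf, nn)
  below_mu[seq_len(ntip)] <- obs
  below_v[seq_len(ntip)] <- ifelse(is.na(obs), Inf, 0)

  # message from each child up through its branch
  msg_mu <- rep(NA_real_, nn)
  msg_v <- rep(Inf, nn)
  contrasts <- numeric(sum(!is.na(obs)) - 1L)
  ic <- 0L

  for (e in seq_along(parent)) {
    p <- parent[e]
    ch <- child[e]
    cv <- below_v[ch] + el[e]
    cm <- below_mu[ch]
    msg_mu[ch] <- cm
    msg_v[ch] <- cv
    if (!is.finite(cv) || is.na(cm)) next
    if (!is.finite(below_v[p])) {            # first informative child
      below_mu[p] <- cm
      below_v[p] <- cv
    } else {                                 # fold in, recording a contrast
      ic <- ic + 1L
      contrasts[ic] <- (cm - below_mu[p]) / sqrt(cv + below_v[p])
      w <- 1 / below_v[p] + 1 / cv
      below_mu[p] <- (below_mu[p] / below_v[p] + cm / cv) / w
      below_v[p] <- 1 / w
    }
  }

  # per-parent totals of informative child messages, for sibling exclusion
  prec <- ifelse(is.finite(msg_v), 1 / msg_v, 0)
  wsum <- ifelse(prec > 0, msg_mu * prec, 0)
  S <- rep(0, nn)
  M <- rep(0, nn)
  for (e in seq_along(parent)) {
    S[parent[e]] <- S[parent[e]] + prec[child[e]]
    M[parent[e]] <- M[parent[e]] + wsum[child[e]]
  }

  above_mu <- rep(NA_real_, nn)
  above_v <- rep(Inf, nn)
  for (e in rev(seq_along(parent))) {        # pre-order
    p <- parent[e]
    ch <- child[e]
    s <- S[p] - prec[ch]
    m <- M[p] - wsum[ch]
    if (is.finite(above_v[p])) {
      s <- s + 1 / above_v[p]
      m <- m + above_mu[p] / above_v[p]
    }
    if (s > 0) {
      above_mu[ch] <- m / s
      above_v[ch] <- 1 / s + el[e]
    }
  }

  marg_mu <- rep(NA_real_, nn)
  marg_v <- rep(NA_real_, nn)
  for (i in seq_len(nn)) {
    pb <- if (is.finite(below_v[i]) && below_v[i] > 0) 1 / below_v[i] else 0
    pa <- if (is.finite(above_v[i]) && above_v[i] > 0) 1 / above_v[i] else 0
    if (is.finite(below_v[i]) && below_v[i] == 0) {   # observed tip
      marg_mu[i] <- below_mu[i]
      marg_v[i] <- 0
    } else if (pb + pa > 0) {
      num <- 0
      if (pb > 0) num <- num + below_mu[i] * pb
      if (pa > 0) num <- num + above_mu[i] * pa
      marg_mu[i] <- num / (pb + pa)
      marg_v[i] <- 1 / (pb + pa)
    }
  }

  list(estimate = marg_mu, v_time = marg_v, contrasts = contrasts,
       observed = !is.na(obs))
}

#' REML estimate of the Brownian-motion rate
#'
#' Estimates the BM diffusion rate `sigma2` (trait units^2 per My) by
#' restricted maximum likelihood from standardized phylogenetically
#' independent contrasts over the observed tips: the mean of the squared
#' standardized contrasts. Missing tips contribute nothing; polytomies are
#' handled natively by sequential folding, which still yields independent
#' standard-normal contrasts under the model. For two tips with branch
#' lengths `t1`, `t2` and values `x1`, `x2` this reduces to
#' `(x1 - x2)^2 / (t1 + t2)`.
#'
#' @param tree a rooted `phylo` timetree with branch lengths in My.
#' @param x named numeric vector of tip values; `NA` = missing. Tips absent
#'   from `x` are treated as missing.
#' @return `sigma2 >= 0` (trait units^2 per My).
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:1);")
#' estimate_bm_rate(tr, c(A = 0, B = 2)) # 2
#' @export
estimate_bm_rate <- function(tree, x) {
  mp <- bm_message_pass(tree, x)
  mean(mp$contrasts^2)
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Reconstructs the marginal ML estimate of the trait at every internal
#' node by two-pass pruning (post-order conditioning on each subtree, then
#' pre-order marginalisation over the rest of the tree). The estimates are
#' identical to the generalized-least-squares solution built on the
#' shared-path-length covariance matrix, but the pruning pass is linear in
#' tree size and handles polytomies without binary resolution. All tips
#' must be observed; run [impute_missing_tips()] first otherwise.
#'
#' Branch lengths of exactly zero are floored at `1e-9` My so the implied
#' covariance stays non-singular.
#'
#' @inheritParams estimate_bm_rate
#' @param sigma2 BM rate for the variance scale; estimated by
#'   [estimate_bm_rate()] when `NULL`. The state estimates themselves do
#'   not depend on `sigma2`.
#' @return an object of class `bm_reconstruction`: a list with `estimates`
#'   and `variances`, named numeric vectors over all tips and internal
#'   nodes (tips have variance 0 and estimate equal to the observation),
#'   plus the `sigma2` used.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' rec <- bm_ancestral_states(tr, c(A = 0, B = 2, C = 4))
#' rec$estimates[["node4"]] # root, 16/7
#' @export
bm_ancestral_states <- function(tree, x, sigma2 = NULL) {
  check_timetree(tree)
  obs <- align_observations(tree, x)
  if (anyNA(obs)) {
    stop("unobserved tip(s): ",
         paste(tree$tip.label[is.na(obs)], collapse = ", "),
         "; run impute_missing_tips() first", call. = FALSE)
  }
  mp <- bm_message_pass(tree, obs)
  if (is.null(sigma2)) sigma2 <- mean(mp$contrasts^2)
  if (sigma2 < 0) stop("'sigma2' must be non-negative", call. = FALSE)
  nm <- node_names(tree)
  est <- mp$estimate
  vr <- mp$v_time * sigma2
  names(est) <- nm
  names(vr) <- nm
  structure(list(estimates = est, variances = vr, sigma2 = sigma2),
            class = "bm_reconstruction")
}

#' @export
print.bm_reconstruction <- function(x, ...) {
  cat("Brownian-motion ancestral state reconstruction\n")
  cat(sprintf("  %d node estimates, sigma2 = %.6g per My\n",
              length(x$estimates), x$sigma2))
  invisible(x)
}

#' Impute missing tip values under Brownian motion
#'
#' Each missing tip receives the conditional expectation of its value given
#' the observed tips under BM — multivariate-normal conditioning on the
#' shared-path-length covariance — computed by the same two-pass pruning as
#' [bm_ancestral_states()], with missing tips carrying no information in
#' the upward pass. Observed tips are returned unchanged.
#'
#' @inheritParams bm_ancestral_states
#' @return a list with `observations` (complete named vector over all
#'   tips), `variance` (conditional variance, trait units^2, for the
#'   imputed tips only), `imputed` (their labels) and `sigma2`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' impute_missing_tips(tr, c(A = 0, B = 2, C = NA))$observations[["C"]] # 1
#' @export
impute_missing_tips <- function(tree, x, sigma2 = NULL) {
  check_timetree(tree)
  obs <- align_observations(tree, x)
  if (all(is.na(obs))) {
    stop("all tips are missing; nothing to condition on", call. = FALSE)
  }
  mp <- bm_message_pass(tree, obs)
  if (is.null(sigma2)) sigma2 <- mean(mp$contrasts^2)
  ntip <- length(tree$tip.label)
  est <- mp$estimate[seq_len(ntip)]
  names(est) <- tree$tip.label
  missing <- is.na(obs)
  out <- obs
  out[missing] <- est[missing]
  vr <- mp$v_time[seq_len(ntip)][missing] * sigma2
  names(vr) <- tree$tip.label[missing]
  list(observations = out, variance = vr,
       imputed = tree$tip.label[missing], sigma2 = sigma2)
}
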