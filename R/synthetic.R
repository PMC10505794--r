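#' Simulate an ultrametric Yule (pure-birth) timetree
#'
#' Forward pure-birth simulation: starting from the root split (two
#' lineages), each epoch with `k` lineages lasts an exponential waiting
#' time with rate `k * birth_rate`, after which a uniformly chosen lineage
#' splits. After the `n_tips`-th lineage appears, one further exponential
#' epoch (rate `n_tips * birth_rate`) elapses before the present, so the
#' expected root age is `sum_{k=2}^{n_tips} 1 / (k * birth_rate)` My. All
#' tips end at the present (the tree is ultrametric).
#'
#' @param n_tips number of tips, at least 2.
#' @param birth_rate speciation rate per lineage per My; positive.
#' @param seed integer seed; the caller's RNG state is restored afterwards.
#'   `NULL` uses (and advances) the current RNG stream.
#' @return an ape `phylo` object with `n_tips` tips labelled
#'   `t1 ... tn` in order of appearance and branch lengths in My.
#' @examples
#' tr <- simulate_yule_tree(8, birth_rate = 0.01, seed = 1)
#' ape::is.ultrametric(tr)
#' @export
simulate_yule_tree <- function(n_tips, birth_rate, seed = NULL) {
  if (!is.numeric(n_tips) || n_tips < 2 || n_tips != round(n_tips)) {
    stop("'n_tips' must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(birth_rate) || birth_rate <= 0) {
    stop("'birth_rate' must be positive (per My)", call. = FALSE)
  }
  n_tips <- as.integer(n_tips)
  with_seed(seed, {
    # Node bookkeeping: each event node records its parent and time.
    n_internal <- n_tips - 1L
    par_of <- integer(0)          # parent internal-node index per node
    time_of <- numeric(0)         # event time per internal node
    par_of[1] <- 0L               # root split at time 0
    time_of[1] <- 0
    active_parent <- c(1L, 1L)    # parent internal node of each open lineage
    t_now <- 0
    next_internal <- 2L
    while (length(active_parent) < n_tips) {
      k <- length(active_parent)
      t_now <- t_now + rexp(1, rate = k * birth_rate)
      i <- sample.int(k, 1L)
      par_of[next_internal] <- active_parent[i]
      time_of[next_internal] <- t_now
      active_parent <- c(active_parent[-i], next_internal, next_internal)
      next_internal <- next_internal + 1L
    }
    t_end <- t_now + rexp(1, rate = n_tips * birth_rate)

    # ape numbering: tips 1..n, internals n+1..2n-1 with root first.
    internal_id <- n_tips + seq_len(n_internal)
    edge <- matrix(0L, nrow = 2L * n_tips - 2L, ncol = 2L)
    elen <- numeric(nrow(edge))
    e <- 0L
    for (j in seq_len(n_internal)[-1L]) {
      e <- e + 1L
      edge[e, ] <- c(internal_id[par_of[j]], internal_id[j])
      elen[e] <- time_of[j] - time_of[par_of[j]]
    }
    for (i in seq_len(n_tips)) {
      e <- e + 1L
      p <- active_parent[i]
      edge[e, ] <- c(internal_id[p], i)
      elen[e] <- t_end - time_of[p]
    }
    tree <- structure(list(edge = edge, edge.length = elen,
                           tip.label = paste0("t", seq_len(n_tips)),
                           Nnode = n_internal),
                      class = "phylo")
    attr(tree, "order") <- NULL
    tree <- ape::reorder.phylo(tree, "cladewise")
    tree
  })
}

#' Simulate a continuous trait under Brownian motion on a timetree
#'
#' States evolve from `root_state` by independent Gaussian increments of
#' variance `sigma2 * branch length` along every branch. An optional clade
#' `shift` multiplies the states of every node in the clade subtended by a
#' selected node (the node itself included) by a constant factor — a
#' stylised version of a discrete gain in organismal complexity within one
#' clade. The full set of true node states is returned so reconstruction
#' accuracy can be scored against the truth.
#'
#' Because complexity metrics are positive, the generator expects
#' `root_state` to dominate the diffusion scale; if any simulated state is
#' non-positive it warns and re-centres all states (adding a constant so
#' the minimum is a small positive fraction of `|root_state|`).
#'
#' @param tree a rooted `phylo` timetree, branch lengths in My.
#' @param root_state trait value at the root.
#' @param sigma2 BM rate (trait units^2 per My), non-negative.
#' @param seed integer seed (see [simulate_yule_tree()]).
#' @param shift optional `list(node = <tip/node label or ape node number>,
#'   multiplier = <positive factor>)`.
#' @return a list: `tips` (named vector of tip states), `states` (named
#'   vector over all nodes, tips first), `shift`, `seed`, `recentred`.
#' @examples
#' tr <- simulate_yule_tree(6, 0.01, seed = 2)
#' sim <- simulate_bm_traits(tr, root_state = 100, sigma2 = 0.05, seed = 3)
#' sim$tips
#' @export
simulate_bm_traits <- function(tree, root_state, sigma2, seed = NULL,
                               shift = NULL) {
  check_timetree(tree)
  if (!is.numeric(sigma2) || sigma2 < 0) {
    stop("'sigma2' must be non-negative", call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  shift_nodes <- integer(0)
  shift_mult <- 1
  if (!is.null(shift)) {
    if (!is.list(shift) || is.null(shift$node) || is.null(shift$multiplier)) {
      stop("'shift' must be list(node = , multiplier = )", call. = FALSE)
    }
    if (!is.numeric(shift$multiplier) || shift$multiplier <= 0) {
      stop("shift multiplier must be positive", call. = FALSE)
    }
    shift_mult <- shift$multiplier
    target <- resolve_node(tree, shift$node)
    shift_nodes <- clade_members(tree, target)
  }
  with_seed(seed, {
    post <- ape::reorder.phylo(tree, "postorder")
    parent <- post$edge[, 1L]
    child <- post$edge[, 2L]
    el <- post$edge.length
    state <- rep(NA_real_, nn)
    state[root] <- root_state
    for (e in rev(seq_along(parent))) {     # pre-order
      inc <- if (sigma2 > 0) rnorm(1, 0, sqrt(sigma2 * el[e])) else 0
      state[child[e]] <- state[parent[e]] + inc
    }
    if (length(shift_nodes)) {
      state[shift_nodes] <- state[shift_nodes] * shift_mult
    }
    recentred <- FALSE
    if (min(state) <= 0) {
      offset <- 1e-3 * max(1, abs(root_state)) - min(state)
      warning("simulated states reached non-positive values; ",
              "re-centred by +", signif(offset, 4),
              " (choose root_state >> sqrt(sigma2 * depth) to avoid this)",
              call. = FALSE)
      state <- state + offset
      recentred <- TRUE
    }
    names(state) <- node_names(tree)
    tips <- state[seq_len(ntip)]
    list(tips = tips, states = state,
         shift = if (length(shift_nodes)) {
           list(node = shift$node, multiplier = shift_mult)
         },
         seed = seed, recentred = recentred)
  })
}

# Resolve a tip/node label or ape node number to a node number.
resolve_node <- function(tree, node) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (node < 1L || node > nn) {
      stop("node number ", node, " out of range 1..", nn, call. = FALSE)
    }
    return(node)
  }
  hit <- match(node, node_names(tree))
  if (is.na(hit)) {
    stop("unknown node selector '", node, "'", call. = FALSE)
  }
  hit
}

# All nodes (tips + internals) in the clade subtended by `node`, inclusive.
clade_members <- function(tree, node) {
  post <- ape::reorder.phylo(tree, "postorder")
  inset <- logical(length(tree$tip.label) + tree$Nnode)
  inset[node] <- TRUE
  for (e in rev(seq_len(nrow(post$edge)))) {  # pre-order
    if (inset[post$edge[e, 1L]]) inset[post$edge[e, 2L]] <- TRUE
  }
  which(inset)
}

#' Mask a fraction of tip observations
#'
#' Sets `floor(missing_fraction * n_tips)` uniformly chosen tips to `NA`,
#' reproducibly by seed. At least two tips must remain observed.
#'
#' @param x named numeric vector of tip values.
#' @param missing_fraction fraction in `[0, 1)`.
#' @param seed integer seed (see [simulate_yule_tree()]).
#' @return `x` with the masked entries set to `NA`.
#' @examples
#' mask_tips(c(a = 1, b = 2, c = 3, d = 4), 0.5, seed = 1)
#' @export
mask_tips <- function(x, missing_fraction, seed = NULL) {
  if (!is.numeric(missing_fraction) || missing_fraction < 0 ||
      missing_fraction >= 1) {
    stop("'missing_fraction' must lie in [0, 1)", call. = FALSE)
  }
  n <- length(x)
  n_mask <- floor(missing_fraction * n)
  if (n - n_mask < 2L) {
    stop("masking would leave fewer than 2 observed tips", call. = FALSE)
  }
  if (n_mask == 0L) return(x)
  with_seed(seed, {
    x[sample.int(n, n_mask)] <- NA_real_
    x
  })
}

#' Simulate a table of published node-age estimates
#'
#' Emulates a literature collection of divergence times for one node:
#' ages are drawn i.i.d. normal around `true_age` with standard deviation
#' `sd` (redrawn if non-positive, i.e. truncated at 0), publication years
#' uniform over `year_range`, and every record gets a distinct study and
#' topology identifier, with `relaxed_clock = TRUE` throughout.
#'
#' @param true_age true node age in Ga; positive.
#' @param n_studies number of simulated studies, at least 2.
#' @param sd between-study standard deviation in Ga; non-negative.
#' @param year_range integer length-2 vector, inclusive; default
#'   `c(2000, 2024)`.
#' @param node_label label used for every record; default `"node"`.
#' @param seed integer seed (see [simulate_yule_tree()]).
#' @return a `published_times` table (see [published_times()]).
#' @examples
#' simulate_published_times(2.2, 5, 0.1, seed = 7)
#' @export
simulate_published_times <- function(true_age, n_studies, sd,
                                     year_range = c(2000, 2024),
                                     node_label = "node", seed = NULL) {
  if (!is.numeric(true_age) || true_age <= 0) {
    stop("'true_age' must be positive (Ga)", call. = FALSE)
  }
  if (!is.numeric(n_studies) || n_studies < 2) {
    stop("'n_studies' must be at least 2", call. = FALSE)
  }
  if (!is.numeric(sd) || sd < 0) {
    stop("'sd' must be non-negative (Ga)", call. = FALSE)
  }
  if (length(year_range) != 2L || any(year_range != round(year_range)) ||
      year_range[1] > year_range[2] || year_range[1] <= 1900) {
    stop("'year_range' must be increasing integer years after 1900",
         call. = FALSE)
  }
  n_studies <- as.integer(n_studies)
  with_seed(seed, {
    ages <- rnorm(n_studies, true_age, sd)
    while (any(ages <= 0)) {
      ages[ages <= 0] <- rnorm(sum(ages <= 0), true_age, sd)
    }
    years <- sample(seq(year_range[1], year_range[2]), n_studies,
                    replace = TRUE)
    published_times(
      node_label = rep(node_label, n_studies),
      age = ages,
      year = years,
      relaxed_clock = rep(TRUE, n_studies),
      source_id = sprintf("study%03d", seq_len(n_studies)),
      topology_id = sprintf("topo%03d", seq_len(n_studies))
    )
  })
}
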