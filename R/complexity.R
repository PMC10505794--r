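#' Ages of all nodes on a timetree
#'
#' Ages are measured back from the youngest tip: each node's age is the
#' maximum root-to-tip path length minus the node's own root-to-node path
#' length, so the root's age equals the tree depth and, on an ultrametric
#' tree, every tip has age 0. Non-ultrametric trees are allowed and follow
#' the same definition.
#'
#' @param tree a rooted `phylo` timetree with branch lengths in My.
#' @return named numeric vector of ages (My before present) over tips and
#'   internal nodes, in node-number order.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' node_ages(tr) # root 2, inner node 1, tips 0
#' @export
node_ages <- function(tree) {
  check_timetree(tree)
  depth <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  ages <- max(depth[seq_len(ntip)]) - depth
  names(ages) <- node_names(tree)
  ages
}

#' Composite complexity from per-metric node values
#'
#' Combines several reconstructed complexity metrics (e.g. cell types,
#' gene count, genome size in Mb) into one dimensionless score per node:
#' each metric is normalized by its mean across nodes, logged (natural
#' logarithm), and the per-metric logs are averaged. Normalization by the
#' mean makes the composite exactly invariant to rescaling any single
#' metric by a positive constant; a node at each metric's mean scores 0.
#'
#' @param per_metric named list, one named numeric vector per metric; all
#'   vectors must cover the same node set and be strictly positive.
#' @return named numeric vector of composite scores over the shared nodes.
#' @examples
#' composite_complexity(list(m1 = c(a = 2, b = 4), m2 = c(a = 20, b = 40)))
#' @export
composite_complexity <- function(per_metric) {
  if (!is.list(per_metric) || !length(per_metric)) {
    stop("'per_metric' must be a non-empty named list of node vectors",
         call. = FALSE)
  }
  nodes <- names(per_metric[[1]])
  if (is.null(nodes)) {
    stop("metric vectors must be named by node", call. = FALSE)
  }
  metric_names <- names(per_metric)
  if (is.null(metric_names)) metric_names <- seq_along(per_metric)
  logs <- vapply(seq_along(per_metric), function(k) {
    v <- per_metric[[k]]
    if (!setequal(names(v), nodes) || length(v) != length(nodes)) {
      stop("metric '", metric_names[k],
           "' does not cover the same node set as the first metric",
           call. = FALSE)
    }
    v <- v[nodes]
    bad <- !is.finite(v) | v <= 0
    if (any(bad)) {
      stop("non-positive value for metric '", metric_names[k],
           "' at node(s): ", paste(nodes[bad], collapse = ", "),
           call. = FALSE)
    }
    log(v / mean(v))
  }, numeric(length(nodes)))
  out <- rowMeans(matrix(logs, nrow = length(nodes)))
  names(out) <- nodes
  out
}

#' Smoothed moving-maximum curve over time bins
#'
#' Slides overlapping half-open age windows `[start, start + window)` of
#' width `window` My, with starts anchored at multiples of `step` My
#' spanning the data range. Each non-empty bin reports the maximum value
#' among the points it contains, placed at the bin midpoint minus
#' `report_offset` My. Empty bins are omitted rather than interpolated.
#'
#' @param ages numeric vector of point ages (My before present).
#' @param values numeric vector of the same length.
#' @param window bin width in My; default 500.
#' @param step offset between consecutive bin starts in My; default 100.
#' @param report_offset subtracted from each reported bin midpoint (My);
#'   default 100. Use 0 for un-shifted midpoints.
#' @return a `data.frame` of class `complexity_curve` with columns
#'   `reported_age` (My, decreasing: oldest bin first) and `value`; bin
#'   parameters are kept as attributes `window`, `step`, `report_offset`.
#'   Empty input yields a zero-row curve.
#' @examples
#' moving_maximum(c(2000, 1800, 1600), c(1, 5, 2))
#' @export
moving_maximum <- function(ages, values, window = 500, step = 100,
                           report_offset = 100) {
  if (window <= 0 || step <= 0) {
    stop("'window' and 'step' must be positive (My)", call. = FALSE)
  }
  if (length(ages) != length(values)) {
    stop("'ages' and 'values' must have equal length", call. = FALSE)
  }
  keep <- is.finite(ages) & is.finite(values)
  ages <- ages[keep]
  values <- values[keep]
  if (!length(ages)) {
    out <- data.frame(reported_age = numeric(0), value = numeric(0))
  } else {
    lo <- min(ages)
    hi <- max(ages)
    # starts s = k * step with s <= hi and s + window > lo
    k_min <- ceiling((lo - window) / step + 1e-12)
    if (k_min * step + window <= lo) k_min <- k_min + 1L
    k_max <- floor(hi / step + 1e-12)
    rep_age <- numeric(0)
    val <- numeric(0)
    for (k in seq(k_min, k_max)) {
      s <- k * step
      inbin <- ages >= s & ages < s + window
      if (!any(inbin)) next
      rep_age <- c(rep_age, s + window / 2 - report_offset)
      val <- c(val, max(values[inbin]))
    }
    out <- data.frame(reported_age = rep_age, value = val)
    out <- out[order(out$reported_age, decreasing = TRUE), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "report_offset") <- report_offset
  class(out) <- c("complexity_curve", "data.frame")
  out
}

#' Complexity through time on a timetree
#'
#' End-to-end pipeline: for each complexity metric, impute missing tips
#' and reconstruct ancestral states under Brownian motion
#' ([impute_missing_tips()], [bm_ancestral_states()]); combine the
#' reconstructions into the composite score ([composite_complexity()]);
#' attach node ages ([node_ages()]); and build the smoothed
#' moving-maximum curve ([moving_maximum()]). Deterministic given its
#' inputs.
#'
#' @param tree a rooted `phylo` timetree, branch lengths in My.
#' @param traits named list of named numeric tip vectors, one per metric
#'   (`NA` = missing); all metrics must be strictly positive where
#'   observed.
#' @param window,step,report_offset passed to [moving_maximum()].
#' @param sigma2 optional named numeric, a BM rate per metric; estimated
#'   per metric from the observed tips when absent.
#' @param drop_extant_from_mean exclude tips of age 0 from the per-node
#'   mean-complexity table (`mean_points`)? Default `TRUE`: extant tips
#'   swamp the through-time signal at time zero. The full table is always
#'   returned in `nodes`.
#' @return a list of class `complexity_profile`:
#'   * `nodes` — data.frame with node, age (My and Ga), one column per
#'     reconstructed metric, and the composite score;
#'   * `mean_points` — the (age, composite) points for the mean-complexity
#'     panel, optionally excluding extant tips;
#'   * `max_curve` — the [moving_maximum()] curve over all nodes;
#'   * `sigma2` — the per-metric BM rates used.
#' @examples
#' tr <- ape::read.tree(text = "((A:100,B:100):100,C:200);")
#' traits <- list(genes = c(A = 2000, B = 2400, C = NA),
#'                genome_mb = c(A = 4, B = 5, C = 3))
#' prof <- complexity_through_time(tr, traits, window = 100, step = 50)
#' prof$nodes
#' @export
complexity_through_time <- function(tree, traits, window = 500, step = 100,
                                    report_offset = 100, sigma2 = NULL,
                                    drop_extant_from_mean = TRUE) {
  check_timetree(tree)
  if (!is.list(traits) || !length(traits) || is.null(names(traits))) {
    stop("'traits' must be a named list of tip-value vectors", call. = FALSE)
  }
  per_metric <- list()
  rates <- numeric(0)
  for (m in names(traits)) {
    x <- traits[[m]]
    pos_ok <- all(is.na(x) | x > 0)
    if (!pos_ok) {
      stop("metric '", m, "' has non-positive observed values", call. = FALSE)
    }
    s2 <- if (!is.null(sigma2) && m %in% names(sigma2)) sigma2[[m]] else NULL
    if (anyNA(x) || length(x) < length(tree$tip.label)) {
      imp <- impute_missing_tips(tree, x, s2)
      x <- imp$observations
      if (is.null(s2)) s2 <- imp$sigma2
    }
    rec <- bm_ancestral_states(tree, x, s2)
    per_metric[[m]] <- rec$estimates
    rates[m] <- rec$sigma2
  }
  composite <- composite_complexity(per_metric)
  ages <- node_ages(tree)
  nodes <- data.frame(node = names(ages),
                      age_my = unname(ages),
                      age_ga = my_to_ga(unname(ages)),
                      stringsAsFactors = FALSE)
  for (m in names(per_metric)) nodes[[m]] <- unname(per_metric[[m]])
  nodes$composite <- unname(composite[nodes$node])

  mean_points <- nodes[, c("node", "age_my", "age_ga", "composite")]
  if (drop_extant_from_mean) {
    ntip <- length(tree$tip.label)
    extant <- seq_len(nrow(mean_points)) <= ntip & mean_points$age_my <= 0
    mean_points <- mean_points[!extant, , drop = FALSE]
  }
  mean_points <- mean_points[order(mean_points$age_my, decreasing = TRUE), ,
                             drop = FALSE]
  rownames(mean_points) <- NULL

  curve <- moving_maximum(nodes$age_my, nodes$composite,
                          window = window, step = step,
                          report_offset = report_offset)
  structure(list(nodes = nodes, mean_points = mean_points,
                 max_curve = curve, sigma2 = rates),
            class = "complexity_profile")
}

#' @export
print.complexity_profile <- function(x, ...) {
  cat("Complexity-through-time profile\n")
  cat(sprintf("  %d nodes, %d metric(s): %s\n",
              nrow(x$nodes), length(x$sigma2),
              paste(names(x$sigma2), collapse = ", ")))
  cat(sprintf("  moving-maximum curve: %d bins (window %g My, step %g My)\n",
              nrow(x$max_curve), attr(x$max_curve, "window"),
              attr(x$max_curve, "step")))
  invisible(x)
}

#' @export
plot.complexity_profile <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(x$mean_points$age_my, x$mean_points$composite,
       xlim = rev(range(x$nodes$age_my)), pch = 16, cex = 0.6,
       xlab = "Age (My before present)", ylab = "Mean complexity", ...)
  plot(x$max_curve$reported_age, x$max_curve$value,
       xlim = rev(range(x$nodes$age_my)), type = "s",
       xlab = "Age (My before present)", ylab = "Moving-maximum complexity",
       ...)
  invisible(x)
}
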