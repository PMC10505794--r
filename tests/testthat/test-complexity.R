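# Composite complexity metric and through-time curves.

test_that("node ages follow the deepest-tip convention", {
  tr <- read_newick("(A:100,B:100);")
  ages <- node_ages(tr)
  expect_equal(unname(ages[c("A", "B")]), c(0, 0))
  expect_equal(unname(ages["node3"]), 100)

  tr <- read_newick("((A:1,B:1):1,C:2);")
  ages <- node_ages(tr)
  expect_equal(unname(ages), c(0, 0, 0, 2, 1))

  # non-ultrametric: ages measured back from the deepest tip
  tr <- read_newick("(A:3,B:1);")
  ages <- node_ages(tr)
  expect_equal(unname(ages), c(0, 2, 3))
})

test_that("composite is the mean log of mean-normalized metrics", {
  # all nodes equal -> ln(1) = 0 everywhere
  expect_equal(unname(composite_complexity(list(m = c(a = 3, b = 3, c = 3)))),
               c(0, 0, 0))

  # a node sitting at e times every metric's mean scores exactly 1:
  # with b = c = 1, a = 2e/(3 - e) satisfies a = e * mean(a, 1, 1)
  a_star <- 2 * exp(1) / (3 - exp(1))
  per <- list(m1 = c(a = a_star, b = 1, c = 1),
              m2 = c(a = 10 * a_star, b = 10, c = 10))
  comp <- composite_complexity(per)
  expect_equal(unname(comp["a"]), 1, tolerance = 1e-12)

  # hand-worked two-node, two-metric oracle
  per <- list(m1 = c(a = 2, b = 4), m2 = c(a = 20, b = 40))
  comp <- composite_complexity(per)
  expect_equal(unname(comp["a"]), (log(2 / 3) + log(20 / 30)) / 2,
               tolerance = 1e-12)
  expect_equal(unname(comp["a"]), -0.405465, tolerance = 1e-5)
  expect_equal(unname(comp["b"]), 0.287682, tolerance = 1e-5)

  expect_error(composite_complexity(list(m = c(a = 1, b = -2))),
               "non-positive.*b")
  expect_error(composite_complexity(list(m1 = c(a = 1), m2 = c(z = 1))),
               "same node set")
})

test_that("composite is invariant to rescaling any single metric", {
  set.seed(5)
  nodes <- paste0("n", 1:30)
  per <- list(
    cell_types = stats::setNames(exp(rnorm(30, 1, 0.5)), nodes),
    gene_count = stats::setNames(exp(rnorm(30, 8, 0.7)), nodes),
    genome_mb = stats::setNames(exp(rnorm(30, 3, 0.6)), nodes)
  )
  base <- composite_complexity(per)
  for (k in seq_along(per)) {
    scaled <- per
    scaled[[k]] <- scaled[[k]] * 1234.5
    expect_equal(composite_complexity(scaled), base, tolerance = 1e-12)
  }
})

test_that("moving maximum matches exhaustive bin enumeration", {
  # a single point is reported by every bin that covers it
  curve <- moving_maximum(2000, 3.0, window = 500, step = 100,
                          report_offset = 100)
  expect_equal(nrow(curve), 5L)
  expect_true(all(curve$value == 3.0))
  expect_equal(curve$reported_age, c(2150, 2050, 1950, 1850, 1750))

  # worked trio against the brute-force oracle
  curve <- moving_maximum(c(2000, 1800, 1600), c(1, 5, 2))
  orc <- oracle_moving_max(c(2000, 1800, 1600), c(1, 5, 2), 500, 100, 100)
  expect_equal(curve$reported_age, orc$reported_age)
  expect_equal(curve$value, orc$value)

  # random point sets, varying window/step/offset
  set.seed(9)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    ages <- runif(n, 0, 4000)
    vals <- rnorm(n)
    window <- sample(c(250, 500, 700), 1)
    step <- sample(c(50, 100, 300), 1)
    off <- sample(c(0, 100), 1)
    curve <- moving_maximum(ages, vals, window, step, off)
    orc <- oracle_moving_max(ages, vals, window, step, off)
    expect_equal(curve$reported_age, orc$reported_age)
    expect_equal(curve$value, orc$value)
    # reported values are a subset of the inputs
    expect_true(all(curve$value %in% vals))
    # curve ages stay within the data range extended by the bin geometry
    expect_true(all(curve$reported_age >= min(ages) - off - window))
    expect_true(all(curve$reported_age <= max(ages) + window))
  }

  empty <- moving_maximum(numeric(0), numeric(0))
  expect_equal(nrow(empty), 0L)
  expect_error(moving_maximum(1, 1, window = 0), "positive")
})

test_that("constant traits give a flat zero profile", {
  tree <- simulate_yule_tree(20, 0.01, seed = 31)
  traits <- list(
    cell_types = stats::setNames(rep(4, 20), tree$tip.label),
    gene_count = stats::setNames(rep(3000, 20), tree$tip.label)
  )
  prof <- complexity_through_time(tree, traits, window = 100, step = 50)
  expect_true(all(abs(prof$nodes$composite) < 1e-10))
  expect_true(all(abs(prof$max_curve$value) < 1e-10))
})

test_that("the pipeline is deterministic and imputes missing tips", {
  tree <- simulate_yule_tree(15, 0.01, seed = 41)
  g <- simulate_bm_traits(tree, 1000, 2, seed = 42)$tips
  c2 <- simulate_bm_traits(tree, 50, 0.1, seed = 43)$tips
  traits <- list(gene_count = mask_tips(g, 0.2, seed = 44), cell_types = c2)
  p1 <- complexity_through_time(tree, traits)
  p2 <- complexity_through_time(tree, traits)
  expect_identical(p1, p2)
  expect_false(anyNA(p1$nodes$gene_count))
  # extant tips excluded from the mean panel by default, kept in the table
  expect_false(any(p1$mean_points$age_my <= 0 &
                     p1$mean_points$node %in% tree$tip.label))
  expect_true(all(tree$tip.label %in% p1$nodes$node))
})

test_that("a clade shift produces a step in the moving maximum", {
  tree <- simulate_yule_tree(40, 0.01, seed = 51)
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  # an internal node subtending a reasonable clade, away from root and tips
  internal <- (ntip + 2):(ntip + tree$Nnode)
  sizes <- vapply(internal, function(n) {
    sum(deepchron:::clade_members(tree, n) <= ntip)
  }, 0L)
  target <- internal[which.min(abs(sizes - ntip / 3))]
  shift_age <- ages[target]

  base_sim <- lapply(1:3, function(k) {
    simulate_bm_traits(tree, 100, 0.02, seed = 60 + k)$tips
  })
  names(base_sim) <- c("cell_types", "gene_count", "genome_mb")
  shift_sim <- lapply(1:3, function(k) {
    simulate_bm_traits(tree, 100, 0.02, seed = 60 + k,
                       shift = list(node = target, multiplier = 8))$tips
  })
  names(shift_sim) <- names(base_sim)

  prof0 <- complexity_through_time(tree, base_sim, window = 100, step = 50)
  prof1 <- complexity_through_time(tree, shift_sim, window = 100, step = 50)

  step_size <- function(curve) {
    pre <- curve$value[curve$reported_age > shift_age]
    post <- curve$value[curve$reported_age <= shift_age]
    max(post) - max(pre)
  }
  # multiplying a fraction f of nodes by m inflates the metric mean by
  # 1 + (m - 1) f, so the composite jump at shifted tips is about
  # log(m) - log(1 + (m - 1) f); require at least half of it
  f <- length(deepchron:::clade_members(tree, target)) /
    (ntip + tree$Nnode)
  expected_jump <- log(8) - log(1 + 7 * f)
  expect_gt(step_size(prof1$max_curve), expected_jump / 2) # clear jump
  expect_lt(abs(step_size(prof0$max_curve)), expected_jump / 2) # absent
})
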