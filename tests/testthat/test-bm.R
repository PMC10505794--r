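# Brownian-motion rate estimation, ancestral states and imputation,
# checked against dense GLS / conditional-normal oracles and against
# independent implementations (ape::pic, phytools::fastAnc).

test_that("REML rate matches the two-tip closed form and degenerate cases", {
  tr <- read_newick("(A:1,B:1);")
  expect_equal(estimate_bm_rate(tr, c(A = 0, B = 2)), 2) # (x1-x2)^2/(t1+t2)
  expect_equal(estimate_bm_rate(tr, c(A = 5, B = 5)), 0)
  tr3 <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(estimate_bm_rate(tr3, c(A = 3, B = 3, C = 3)), 0)
  expect_error(estimate_bm_rate(tr3, c(A = 1, B = NA, C = NA)),
               "at least 2 observed")
})

test_that("REML rate agrees with standardized contrasts via ape::pic", {
  tree <- simulate_yule_tree(12, 0.02, seed = 11)
  sim <- simulate_bm_traits(tree, 50, 0.3, seed = 12)
  pics <- ape::pic(sim$tips[tree$tip.label], tree)
  expect_equal(estimate_bm_rate(tree, sim$tips), mean(pics^2),
               tolerance = 1e-10)
})

test_that("ancestral states reproduce hand-computed GLS solutions", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  rec <- bm_ancestral_states(tr, c(A = 0, B = 2, C = 4))
  expect_equal(unname(rec$estimates["node4"]), 16 / 7, tolerance = 1e-10)
  expect_equal(unname(rec$estimates["node5"]), 10 / 7, tolerance = 1e-10)
  # observed tips are returned untouched with zero variance
  expect_equal(unname(rec$estimates[c("A", "B", "C")]), c(0, 2, 4))
  expect_equal(unname(rec$variances[c("A", "B", "C")]), c(0, 0, 0))

  # constancy: every node equals the common tip value
  rec <- bm_ancestral_states(tr, c(A = 7, B = 7, C = 7))
  expect_true(all(abs(rec$estimates - 7) < 1e-12))

  # symmetry: equal terminal branches average the two tips at the root
  tr2 <- read_newick("(A:3,B:3);")
  rec <- bm_ancestral_states(tr2, c(A = 1, B = 5))
  expect_equal(unname(rec$estimates["node3"]), 3)

  expect_error(bm_ancestral_states(tr, c(A = 1, B = 2, C = NA)),
               "impute_missing_tips")
})

test_that("estimates agree with phytools::fastAnc on a larger tree", {
  tree <- simulate_yule_tree(25, 0.02, seed = 21)
  sim <- simulate_bm_traits(tree, 50, 0.4, seed = 22)
  rec <- bm_ancestral_states(tree, sim$tips)
  fa <- phytools::fastAnc(tree, sim$tips[tree$tip.label])
  ntip <- ape::Ntip(tree)
  expect_equal(unname(rec$estimates[ntip + seq_len(tree$Nnode)]),
               unname(as.numeric(fa)), tolerance = 1e-6)
})

test_that("pruning matches the dense GLS oracle, including polytomies", {
  # hand-built polytomy: pruning must not require binary resolution
  poly <- read_newick("(A:1,B:1,(C:0.5,D:0.5):1.5);")
  x <- c(A = 1, B = 4, C = 2, D = 6)
  rec <- bm_ancestral_states(poly, x, sigma2 = 1)
  orc <- oracle_gls(poly, x)
  expect_equal(unname(rec$estimates), orc$estimates, tolerance = 1e-8)
  expect_equal(unname(rec$variances), orc$variances, tolerance = 1e-8)

  for (seed in 1:25) {
    case <- random_bm_case(seed)
    rec <- bm_ancestral_states(case$tree, case$x, sigma2 = 1)
    orc <- oracle_gls(case$tree, case$x)
    expect_equal(unname(rec$estimates), orc$estimates, tolerance = 1e-8)
    expect_equal(unname(rec$variances), orc$variances, tolerance = 1e-8)
  }
})

test_that("imputation is multivariate-normal conditioning on observed tips", {
  # a missing tip at zero evolutionary distance from an observed one
  # inherits its value
  tr <- read_newick("((A:0,M:0):1,C:2);")
  imp <- impute_missing_tips(tr, c(A = 5, M = NA, C = 7))
  expect_equal(unname(imp$observations["M"]), 5, tolerance = 1e-6)

  # a missing tip sharing no path with the observed pair gets their GLS mean
  tr <- read_newick("((A:1,B:1):1,C:2);")
  imp <- impute_missing_tips(tr, c(A = 0, B = 2, C = NA))
  expect_equal(unname(imp$observations["C"]), 1.0, tolerance = 1e-10)
  expect_identical(imp$imputed, "C")
  expect_equal(unname(imp$observations[c("A", "B")]), c(0, 2))

  # random trees against the direct conditional-normal oracle
  for (seed in 101:125) {
    case <- random_bm_case(seed, n_min = 4, mask = TRUE)
    if (!anyNA(case$x)) next
    imp <- impute_missing_tips(case$tree, case$x, sigma2 = 1)
    orc <- oracle_gls(case$tree, case$x)
    miss <- which(is.na(case$x[case$tree$tip.label]))
    expect_equal(unname(imp$observations[case$tree$tip.label][miss]),
                 orc$estimates[miss], tolerance = 1e-8)
    expect_equal(unname(imp$variance), orc$variances[miss],
                 tolerance = 1e-8)
  }
  expect_error(impute_missing_tips(tr, c(A = NA, B = NA, C = NA)),
               "all tips")
})

test_that("imputing a tip then reconstructing equals marginalizing it", {
  # E[internal | observed, imputed = E[imputed | observed]] is linear in
  # the plugged value, so the two routes coincide exactly.
  for (seed in 201:215) {
    case <- random_bm_case(seed, n_min = 3, n_max = 5, mask = TRUE)
    if (!anyNA(case$x)) next
    marg <- oracle_gls(case$tree, case$x)
    imp <- impute_missing_tips(case$tree, case$x, sigma2 = 1)
    rec <- bm_ancestral_states(case$tree, imp$observations, sigma2 = 1)
    ntip <- ape::Ntip(case$tree)
    internal <- ntip + seq_len(case$tree$Nnode)
    expect_equal(unname(rec$estimates[internal]), marg$estimates[internal],
                 tolerance = 1e-8)
  }
})

test_that("reconstructed values never leave the observed range", {
  for (seed in 301:320) {
    case <- random_bm_case(seed, n_min = 3, mask = TRUE)
    obs <- case$x[!is.na(case$x)]
    imp <- impute_missing_tips(case$tree, case$x)
    rec <- bm_ancestral_states(case$tree, imp$observations, imp$sigma2)
    # imputed tips and internal estimates are positive-weight averages
    expect_true(all(rec$estimates >= min(obs) - 1e-10))
    expect_true(all(rec$estimates <= max(obs) + 1e-10))
  }
})

test_that("input validation catches malformed trees and observations", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_error(bm_ancestral_states(tr, c(1, 2, 3)), "named")
  expect_error(bm_ancestral_states(tr, c(A = 1, B = 2, Z = 3)), "unknown tip")
  expect_error(bm_ancestral_states(tr, c(A = 1, B = Inf, C = 2)),
               "non-finite")
  bad <- tr
  bad$edge.length[1] <- -1
  expect_error(bm_ancestral_states(bad, c(A = 1, B = 2, C = 3)),
               "non-negative")
})
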