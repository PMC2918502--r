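test_that("Newick reading validates topology and tip labels, and round-trips", {
  tr <- read_newick_tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  root_children <- tr$edge[tr$edge[, 1] == ape::Ntip(tr) + 1L, 2]
  expect_length(root_children, 2L)
  expect_error(read_newick_tree(text = "((A:1,A:1):1,C:2);"), "duplicate")
  expect_error(read_newick_tree(text = "((A:1,B:1:1,C:2);"), "parse")

  set.seed(30)
  tr2 <- simulate_tree(12)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick_tree(tr2, f)
  back <- read_newick_tree(f)
  expect_equal(sort(back$tip.label), sort(tr2$tip.label))
  expect_equal(suppressWarnings(as.numeric(ape::dist.topo(back, tr2))), 0)
  co <- ape::cophenetic.phylo(back)[tr2$tip.label, tr2$tip.label]
  expect_equal(co, ape::cophenetic.phylo(tr2), tolerance = 1e-8)
})

test_that("branch-length schemes behave as specified", {
  set.seed(31)
  tr <- simulate_tree(5)
  eq <- apply_branch_scheme(tr, "equal")
  expect_true(all(eq$edge.length == 1))

  bal4 <- read_newick_tree(text = "((A:1,B:1):2,(C:3,D:0.5):1);")
  pr <- apply_branch_scheme(bal4, "proportional")
  depths <- ape::node.depth.edgelength(pr)[1:4]
  expect_equal(depths, rep(1, 4), tolerance = 1e-9)  # ultrametric, unit depth
  # both cherries subtend 2 tips so sit at the same height
  h <- ape::node.depth.edgelength(pr)[6:7]
  expect_equal(h[1], h[2], tolerance = 1e-9)

  for (i in 1:5) {
    trr <- apply_branch_scheme(simulate_tree(sample(4:30, 1)), "proportional")
    d <- ape::node.depth.edgelength(trr)[seq_len(ape::Ntip(trr))]
    expect_lt(diff(range(d)), 1e-9)
  }
  single <- list(edge = matrix(nrow = 0, ncol = 2), tip.label = "A",
                 Nnode = 0L)
  class(single) <- "phylo"
  expect_error(apply_branch_scheme(single, "proportional"), "single-tip")
})

test_that("the phylogenetic covariance holds shared path lengths and is PSD", {
  star <- ape::stree(4, "star")
  star$edge.length <- rep(1, 4)
  expect_equal(unname(phylo_covariance(star)), diag(4))

  tr <- read_newick_tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_covariance(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  expect_equal(C["A", "A"], 2)
  set.seed(32)
  for (i in 1:30) {
    Ci <- phylo_covariance(simulate_tree(sample(4:40, 1)))
    expect_true(isSymmetric(Ci, tol = 1e-10))
    expect_gte(min(eigen(Ci, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("the profiled lambda log-likelihood matches iid and dense-grid oracles", {
  # star tree: off-diagonals are zero, so lambda is irrelevant and the
  # likelihood equals the iid normal likelihood at the ML estimates
  star <- ape::stree(6, "star")
  star$edge.length <- rep(2, 6)
  C <- phylo_covariance(star)
  set.seed(33)
  y <- rnorm(6, 5, 2)
  names(y) <- star$tip.label
  l0 <- as.numeric(lambda_loglik(y, C, 0))
  l1 <- as.numeric(lambda_loglik(y, C, 1))
  # direct iid evaluation: V = 2I, profiled sigma2 = RSS/(2n)
  iid <- -0.5 * (6 * log(2 * pi) + 6 * log(mean((y - mean(y))^2 / 2)) +
                   6 * log(2) + 6)
  expect_equal(l0, l1)
  expect_equal(l0, iid, tolerance = 1e-10)

  # 3-tip tree: profiled value matches a brute-force 2-D grid over (mu, sigma2)
  tr <- read_newick_tree(text = "((A:1,B:1):1,C:2);")
  C3 <- phylo_covariance(tr)
  y3 <- c(A = 1.2, B = 0.8, C = -0.6)
  for (lam in c(0, 0.4, 1)) {
    Cl <- C3 * lam; diag(Cl) <- diag(C3)
    expect_equal(as.numeric(lambda_loglik(y3, C3, lam)),
                 dense_profile_loglik(y3, Cl), tolerance = 1e-4)
  }

  # location invariance
  set.seed(34)
  tr2 <- simulate_tree(8)
  C8 <- phylo_covariance(tr2)
  y8 <- rnorm(8); names(y8) <- tr2$tip.label
  expect_equal(as.numeric(lambda_loglik(y8, C8, 0.5)),
               as.numeric(lambda_loglik(y8 + 100, C8, 0.5)), tolerance = 1e-8)
})

test_that("fit_lambda matches a fine grid scan and is affine-invariant", {
  set.seed(35)
  grid <- seq(0, 1, by = 0.001)
  for (i in 1:4) {
    tr <- simulate_tree(5)
    y <- simulate_traits(tr, 1, runif(1))
    C <- phylo_covariance(tr)
    ll <- vapply(grid, function(l) as.numeric(lambda_loglik(y, C, l)), 0)
    f <- fit_lambda(y, tr)
    expect_lt(abs(f$lambda - grid[which.max(ll)]), 0.01)
    expect_gte(f$lnL + 1e-8, max(ll))
    expect_gte(f$lnL + 1e-8, max(f$lnL0, f$lnL1))
    expect_equal(f$LR1, 2 * (f$lnL - f$lnL1))
    expect_gte(f$LR0, 0)

    f2 <- fit_lambda(3 * y + 7, tr)
    expect_equal(f2$lambda, f$lambda, tolerance = 1e-4)
  }
})

test_that("fit_lambda agrees with an independent phylogenetic-signal implementation", {
  skip_if_not_installed("phytools")
  set.seed(36)
  tr <- simulate_tree(60)
  y <- simulate_traits(tr, 2, 0.6) + 10
  f <- fit_lambda(y, tr)
  ps <- phytools::phylosig(tr, y, method = "lambda", test = TRUE)
  expect_equal(f$lambda, ps$lambda, tolerance = 1e-3)
  expect_equal(f$lnL, ps$logL, tolerance = 1e-6)
  expect_equal(f$lnL0, ps$logL0, tolerance = 1e-6)
})

test_that("lambda is recovered under Brownian motion and destroyed by permutation", {
  set.seed(37)
  lam_bm <- replicate(12, {
    tr <- simulate_tree(100)
    fit_lambda(simulate_traits(tr, 1, 1), tr)$lambda
  })
  expect_gte(mean(lam_bm), 0.85)
  lam_perm <- replicate(12, {
    tr <- simulate_tree(100)
    y <- simulate_traits(tr, 1, 1)
    names(y) <- sample(names(y))
    fit_lambda(y, tr)$lambda
  })
  expect_lte(mean(lam_perm), 0.15)
})

test_that("likelihood-ratio helpers and the exported fit table are consistent", {
  expect_equal(lr_test(-10, -12)$stat, 4)
  expect_equal(lr_test(-10, -12)$p, pchisq(4, 1, lower.tail = FALSE))
  set.seed(38)
  tr <- simulate_tree(20)
  fits <- list(a = fit_lambda(simulate_traits(tr, 1, 0.5), tr, "equal"),
               b = fit_lambda(simulate_traits(tr, 1, 0.5), tr, "proportional"))
  tab <- lambda_table(fits)
  expect_equal(tab$trait, c("a", "b"))
  expect_equal(tab$scheme, c("equal", "proportional"))
  expect_equal(tab$LR1, 2 * (tab$lnL_lambda - tab$lnL1))
  expect_equal(tab$LR0, 2 * (tab$lnL_lambda - tab$lnL0))
})
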