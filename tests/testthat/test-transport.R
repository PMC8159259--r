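test_that("Marcus rates match an independently coded formula", {
  # constants written out separately from the implementation
  hbar <- 6.582119569e-16
  kb <- 8.617333262e-5
  ref <- function(v, lam, dg, t) {
    2 * pi / hbar * v^2 * (4 * pi * lam * kb * t)^(-0.5) *
      exp(-(dg + lam)^2 / (4 * lam * kb * t))
  }
  expect_equal(marcus_rate(0.010, 0.14, 0, 300), ref(0.010, 0.14, 0, 300),
               tolerance = 1e-10)
  expect_equal(marcus_rate(0.02, 0.3, -0.05, 250), ref(0.02, 0.3, -0.05, 250),
               tolerance = 1e-10)
  # quadratic in the coupling
  expect_equal(marcus_rate(0.02, 0.14), 4 * marcus_rate(0.01, 0.14))
  # zero driving force: forward equals reverse
  expect_equal(marcus_rate(0.01, 0.14, 0), marcus_rate(0.01, 0.14, -0))
  expect_error(marcus_rate(0.01, -0.1), "lambda")
})

test_that("Kabsch RMSD recognises rigid transforms and rejects mirrors", {
  set.seed(1)
  p <- matrix(rnorm(15), ncol = 3)
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  q <- p %*% t(rot) + matrix(rep(c(1, -2, 3), each = 5), ncol = 3)
  expect_lt(kabsch_rmsd(p, q), 1e-10)
  # mirror images are not superposable by proper rotations
  expect_gt(kabsch_rmsd(p, p %*% diag(c(1, 1, -1))), 0.1)
  expect_gt(kabsch_rmsd(p, q + c(0.5, rep(0, 14))), 1e-3)
})

test_that("network construction finds contacts, reciprocity and dedup", {
  toy <- make_toy_crystal("stack_1d")
  net <- build_network(toy$crystal, toy$couplings, lambda = toy$lambda)
  # a single stacking contact: two directed edges, one class
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$n_dimer_classes, 1L)
  # reciprocity: reverse edge exists with negated displacement, equal rate
  e <- net$edges
  expect_equal(e$dx[1], -e$dx[2])
  expect_equal(e$rate[1], e$rate[2])
  # couplings scaled by 1.325 before the rate
  expect_equal(e$v_ab_eV[1], 0.010 * 1.325)

  # missing coupling errors, naming the dimer
  expect_error(
    build_network(toy$crystal, toy$couplings[0, ], lambda = toy$lambda),
    "no coupling supplied"
  )
})

test_that("herringbone dimer classes match an all-pairs brute-force count", {
  toy <- make_toy_crystal("herringbone")
  net <- build_network(toy$crystal, toy$couplings, lambda = toy$lambda)
  # brute force: collect every contact dimer again and classify by
  # all-pairs Kabsch comparison (quadratic, no incremental representatives)
  dimers <- local({
    cr <- toy$crystal
    lat <- cr$lattice
    out <- list()
    for (i in 1:2) for (j in i:2) {
      for (n1 in -1:1) for (n2 in -1:1) for (n3 in -1:1) {
        sh <- c(n1, n2, n3)
        if (i == j && !(n1 > 0 || (n1 == 0 && (n2 > 0 || (n2 == 0 && n3 > 0))))) next
        ci <- cr$sites[[i]]$coords
        cj <- sweep(cr$sites[[j]]$coords, 2, as.numeric(sh %*% lat), `+`)
        dmin <- min(as.matrix(stats::dist(rbind(ci, cj)))[1:4, 5:8])
        vdw <- c(C = 1.7, N = 1.55)
        cut <- max(outer(vdw[cr$sites[[i]]$elements], vdw[cr$sites[[j]]$elements], `+`)) + 1.5
        if (dmin < cut) out[[length(out) + 1]] <- rbind(ci, cj)
      }
    }
    out
  })
  n <- length(dimers)
  same <- matrix(FALSE, n, n)
  swap <- c(5:8, 1:4)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    same[a, b] <- kabsch_rmsd(dimers[[a]], dimers[[b]]) < 0.001 ||
      kabsch_rmsd(dimers[[a]], dimers[[b]][swap, ]) < 0.001
  }
  # number of classes = number of distinct rows of the equivalence matrix
  brute_classes <- nrow(unique(same))
  expect_equal(net$n_dimer_classes, brute_classes)
  expect_gt(net$n_dimer_classes, 1L)
})

test_that("translation-related dimers collapse to one coupling evaluation", {
  toy <- make_toy_crystal("cubic")
  calls <- new.env(parent = emptyenv()); calls$n <- 0L
  cp_fun <- function(dimer) { calls$n <- calls$n + 1L; 0.01 }
  net <- build_network(toy$crystal, cp_fun, lambda = 0.14)
  expect_equal(calls$n, net$n_dimer_classes)
  expect_lt(net$n_dimer_classes, nrow(net$edges))
})

test_that("kMC reproduces the closed-form 1-D chain diffusion", {
  toy <- make_toy_crystal("stack_1d", spacing = 3.8, coupling = 0.010)
  net <- build_network(toy$crystal, toy$couplings, lambda = toy$lambda)
  an <- analytic_transport(net)
  # closed form D = k a^2 along the chain, zero across
  k <- marcus_rate(0.010 * 1.325, toy$lambda, 0, 300)
  mu_expected <- k * 3.8^2 * 1e-16 / (8.617333262e-5 * 300)
  expect_equal(an$mu[1, 1], mu_expected, tolerance = 1e-12)
  expect_equal(an$mu_mean, mu_expected / 3, tolerance = 1e-12)
  km <- kmc_mobility(net, n_traj = 3000, n_steps = 400, seed = 21)
  expect_lt(abs(km$mu_mean - an$mu_mean), 3 * km$mu_mean_se)
  expect_equal(km$mu[2, 2], 0)
  # D symmetric and PSD
  expect_equal(km$D, t(km$D))
  expect_true(all(eigen(km$D, symmetric = TRUE)$values > -1e-30))
})

test_that("doubling all rates doubles the diffusion tensor exactly in law", {
  toy <- make_toy_crystal("cubic")
  net <- build_network(toy$crystal, toy$couplings, lambda = toy$lambda)
  net2 <- net
  net2$edges$rate <- net$edges$rate * 2
  k1 <- kmc_mobility(net, n_traj = 500, n_steps = 200, seed = 3)
  k2 <- kmc_mobility(net2, n_traj = 500, n_steps = 200, seed = 3)
  # same seed draws the same hop sequence; only the clock rescales
  expect_equal(k2$D, 2 * k1$D, tolerance = 1e-12)
})

test_that("dominant couplings yield strongly anisotropic mobility", {
  toy <- make_toy_crystal("stack_1d", coupling = 0.010,
                          transverse_coupling = 0.001)
  net <- build_network(toy$crystal, toy$couplings, lambda = toy$lambda)
  km <- kmc_mobility(net, n_traj = 2000, n_steps = 300, seed = 14)
  ev <- sort(eigen(km$mu, symmetric = TRUE)$values, decreasing = TRUE)
  expect_gt(ev[1], 10 * ev[2])
})

test_that("mean mobility is the trace third, rotation invariant", {
  m <- diag(c(30.18, 2.12, 0.30))
  expect_equal(mean_mobility(m), (30.18 + 2.12 + 0.30) / 3)
  expect_equal(mean_mobility(5 * diag(3)), 5)
  th <- 0.4
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(mean_mobility(rot %*% m %*% t(rot)), mean_mobility(m))
})

test_that("isotropic networks give isotropic tensors within sampling error", {
  toy <- make_toy_crystal("cubic")
  net <- build_network(toy$crystal, toy$couplings, lambda = toy$lambda)
  km <- kmc_mobility(net, n_traj = 4000, n_steps = 400, seed = 8)
  d <- diag(km$mu)
  expect_lt(max(d) / min(d), 1.15)
  off <- km$mu - diag(diag(km$mu))
  expect_lt(max(abs(off)), 0.05 * mean(d))
})
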