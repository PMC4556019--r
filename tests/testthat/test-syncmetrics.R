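test_that("order parameter r hits its coherent and incoherent limits", {
  theta <- matrix(0.7, 5, 10) # identical phases at all times
  expect_equal(order_parameter_r(theta), 1)
  antipodal <- matrix(c(0, pi / 2, pi, 3 * pi / 2), 4, 20)
  expect_equal(order_parameter_r(antipodal), 0, tolerance = 1e-12)
  expect_error(order_parameter_r(matrix(0, 3, 0)), "no sampled")
})

test_that("r of iid uniform phases matches the finite-size expectation", {
  # for one time point, E[r] ~ sqrt(pi / N) / 2 (Rayleigh limit of |z|);
  # averaging over many iid time columns is the Monte-Carlo mean
  set.seed(123)
  theta <- matrix(runif(100 * 1e4, -pi, pi), 100, 1e4)
  expect_equal(order_parameter_r(theta), 0.5 * sqrt(pi / 100),
               tolerance = 0.02) # ~2 se of the MC mean, relative
})

test_that("edgewise synchrony distinguishes locked from drifting pairs", {
  nt <- 40
  base <- seq(0, 3, length.out = nt)
  theta <- rbind(base, base, base + 0.9, base + 2 * pi * (1:nt) / nt)
  C <- edgewise_synchrony(theta)
  expect_equal(C[1, 2], 1) # identical phases
  expect_equal(C[1, 3], 1) # constant lag still perfectly synchronized
  expect_equal(C[1, 4], 0, tolerance = 1e-12) # full uniform cycle cancels
  expect_true(isSymmetric(C))
  expect_equal(diag(C), rep(1, 4), ignore_attr = TRUE)
})

test_that("r_link averages off-diagonal synchrony", {
  C1 <- matrix(1, 4, 4)
  expect_equal(r_link(C1), 1)
  C0 <- diag(4)
  expect_equal(r_link(C0), 0)
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- 0.2; C[1, 3] <- C[3, 1] <- 0.4
  C[2, 3] <- C[3, 2] <- 0.6
  expect_equal(r_link(C), 0.4) # 2 * (0.2 + 0.4 + 0.6) / 6
  expect_error(r_link(matrix(1, 1, 1)), "N >= 2")
})

test_that("binarization marks the top pairs and matches the r_link count", {
  C <- matrix(1, 3, 3)
  expect_equal(binarize_synchrony(C), matrix(1L, 3, 3) - diag(3L),
               ignore_attr = TRUE)
  # all-equal C: half the pairs marked, lexicographic tie-break
  C <- matrix(0.5, 3, 3); diag(C) <- 1
  F <- binarize_synchrony(C)
  expect_equal(sum(F) / 2, 2) # round(0.5 * 3) = 2 pairs
  expect_equal(F[1, 2], 1L); expect_equal(F[1, 3], 1L)
  expect_equal(F[2, 3], 0L)
  # ranked example: pair values 0.9, 0.5, 0.1 -> two strongest pairs kept
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- 0.9; C[1, 3] <- C[3, 1] <- 0.5
  C[2, 3] <- C[3, 2] <- 0.1
  F <- binarize_synchrony(C)
  expect_equal(F[1, 2], 1L); expect_equal(F[1, 3], 1L)
  expect_equal(F[2, 3], 0L)
})

test_that("F edge count equals round(r_link * N(N-1)/2) on random C", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    C <- matrix(0, n, n)
    pairs <- which(upper.tri(C), arr.ind = TRUE)
    C[pairs] <- runif(nrow(pairs))
    C <- C + t(C); diag(C) <- 1
    F <- binarize_synchrony(C)
    expect_identical(sum(F) / 2, round(r_link(C) * n * (n - 1) / 2))
    expect_true(isSymmetric(F))
  }
})

test_that("synchronization probability averages trials elementwise", {
  F1 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(sync_probability(list(F1, F1, F1)), F1)
  F0 <- matrix(0, 2, 2)
  r <- sync_probability(c(rep(list(F1), 7), rep(list(F0), 3)))
  expect_equal(r[1, 2], 0.7)
  expect_equal(sync_probability(list(F1)), F1) # n = 1 passes through
  expect_error(sync_probability(list()), "empty")
  expect_error(sync_probability(list(F1, matrix(0, 3, 3))), "inconsistent")
})

test_that("modular synchrony implements the pairwise means", {
  part <- partition(c(1, 1, 2), hubs = integer())
  R <- matrix(1, 3, 3)
  expect_equal(modular_synchrony(R, 1, 2, part = part), 1)
  # module of two nodes with r = 0.6
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.6
  expect_equal(modular_synchrony(R, 1, part = part), 0.6)
  # cross-module mean: (r_ac + r_bc) / 2
  R <- diag(3); R[1, 3] <- R[3, 1] <- 0.2; R[2, 3] <- R[3, 2] <- 0.4
  expect_equal(modular_synchrony(R, 1, 2, part = part), 0.3)
  expect_error(modular_synchrony(R, 2, part = part), "singleton")
  # overlapping sets (hub pseudo-module) exclude self-pairs
  expect_equal(modular_synchrony(R, c(1, 3), c(3, 2), part = NULL),
               (0.2 + 0 + 0.4) / 3)
})

test_that("module influence decomposes the mean field by source group", {
  # node 1 connected to 2,3 (module 1) and 4,5 (module 2)
  conn <- conn_from_edges(5, c(1, 2, 1, 3, 1, 4, 1, 5))
  part <- partition(c(1, 1, 1, 2, 2), hubs = c(2, 4))
  theta <- c(0, 0.4, 0.4, 1, 2)
  mi <- module_influence(theta, conn, part, target = 1)
  m1 <- mi[mi$group == "1", ]
  expect_equal(m1$D, 2L)
  expect_equal(m1$R, 1) # both module-1 neighbours at the same phase
  expect_equal(m1$phi, 0.4)
  expect_true(mi$evaluable[mi$group == "2"]) # two connections
  # hub group: neighbours 2 and 4
  expect_equal(mi$D[mi$group == "hubs"], 2L)
  # single-connection groups are flagged not evaluable
  conn2 <- conn_from_edges(5, c(1, 2, 1, 4, 1, 5))
  mi2 <- module_influence(theta, conn2, part, target = 1)
  expect_false(mi2$evaluable[mi2$group == "1"])
  expect_equal(mi2$R[mi2$group == "1"], 1) # R = 1 identically, uninformative
  expect_error(module_influence(theta, conn_from_edges(5, c(2, 3)), part, 1),
               "isolated")
})

test_that("module contributions reassemble the total mean field exactly", {
  set.seed(41)
  net <- generate_connectome(synth_spec(n_nodes = 40, n_modules = 3,
                                        size_range = c(10, 16), seed = 10))
  conn <- net$connectome; part <- net$partition
  theta <- runif(40, -pi, pi)
  mf <- mean_field(theta, conn)
  for (k in c(1, 7, 23)) {
    mi <- module_influence(theta, conn, part, target = k)
    mods <- mi[mi$group != "hubs" & mi$D > 0, ]
    z <- sum(mods$D * mods$R * exp(1i * mods$phi)) / mf$degree[k]
    expect_equal(Mod(z), mf$R[k], tolerance = 1e-12)
    expect_equal(Arg(z), mf$phi[k], tolerance = 1e-12)
  }
})

test_that("group influences approach 1 on a synchronized trajectory", {
  net <- generate_connectome(synth_spec(n_nodes = 40, n_modules = 3,
                                        size_range = c(10, 16), seed = 10))
  traj <- simulate_kuramoto(net$connectome, lambda = 1.5,
                            cfg = kuramoto_config(seed = 2))
  tab <- group_influence_table(traj, net$connectome, net$partition,
                               stride = 8)
  expect_true(all(tab$R > 0.99, na.rm = TRUE))
  # scalar interface agrees with the table
  one <- group_influence(traj, net$connectome, net$partition,
                         target_module = 1, source = "hubs", stride = 8)
  expect_equal(one, tab$R[tab$target == "1" & tab$source == "hubs"])
})

test_that("uncoupled 100-node dynamics stay below the incoherent bound", {
  net <- generate_connectome(synth_spec(n_nodes = 100, n_modules = 5,
                                        size_range = c(11, 31), seed = 14))
  traj <- simulate_kuramoto(net$connectome, lambda = 0,
                            cfg = kuramoto_config(seed = 3))
  expect_lt(order_parameter_r(traj), 0.25)
  # and a strongly coupled run reaches (near) full coherence
  traj2 <- simulate_kuramoto(net$connectome, lambda = 0.5,
                             cfg = kuramoto_config(seed = 3))
  expect_gt(order_parameter_r(traj2), 0.99)
})

test_that("mean r increases with coupling on the default connectome", {
  net <- default_net()
  lams <- c(0.005, 0.02, 0.04, 0.08)
  n_tr <- 20
  rbar <- matrix(NA_real_, n_tr, length(lams))
  for (li in seq_along(lams)) for (tr in seq_len(n_tr)) {
    traj <- simulate_kuramoto(net$connectome, lams[li],
                              cfg = kuramoto_config(seed = 500 + tr))
    rbar[tr, li] <- order_parameter_r(traj)
  }
  m <- colMeans(rbar); se <- apply(rbar, 2, sd) / sqrt(n_tr)
  for (i in seq_len(length(lams) - 1))
    expect_gt(m[i + 1] - m[i], -(se[i] + se[i + 1])) # non-decreasing up to 1 se
})
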