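test_that("hub-edge suppression removes only edges inside K", {
  conn <- conn_from_edges(3, c(1, 2, 1, 3))
  out <- suppress_edges(conn, K = c(1, 2))
  expect_equal(out$W[1, 2], 0L) # both ends in K: removed
  expect_equal(out$W[1, 3], 1L) # one end outside K: kept
  expect_equal(attr(out, "n_removed"), 1L)
  expect_identical(suppress_edges(conn, integer())$W, conn$W)
  all_gone <- suppress_edges(conn, 1:3)
  expect_equal(n_edges(all_gone), 0L)
})

test_that("random suppression removes the requested number of edges", {
  conn <- default_net()$connectome
  expect_identical(suppress_random_edges(conn, 0, seed = 1)$W, conn$W)
  out <- suppress_random_edges(conn, 25, seed = 1)
  expect_equal(n_edges(conn) - n_edges(out), 25L)
  empty <- suppress_random_edges(conn, n_edges(conn), seed = 1)
  expect_equal(n_edges(empty), 0L)
  expect_error(suppress_random_edges(conn, n_edges(conn) + 1, seed = 1),
               "between 0 and")
  # paired contract: matched removal counts between conditions
  part <- default_net()$partition
  hub_sup <- suppress_edges(conn, part$hubs)
  rnd_sup <- suppress_random_edges(conn, attr(hub_sup, "n_removed"),
                                   seed = 2)
  expect_identical(attr(hub_sup, "n_removed"), attr(rnd_sup, "n_removed"))
})

test_that("frequency perturbation offsets only the selected set", {
  om <- c(0.3, 0.5, 0.7)
  expect_equal(perturb_frequencies(om, 1), c(1.3, 0.5, 0.7))
  expect_equal(perturb_frequencies(om, integer()), om)
  expect_equal(perturb_frequencies(perturb_frequencies(om, 2), 2),
               c(0.3, 2.5, 0.7)) # composable: applied twice adds 2
})

test_that("dominant frequency picks the strongest spectral line", {
  edgeless <- connectome(matrix(0L, 2, 2) + 0L)
  om <- c(0.5, 0.7)
  traj <- simulate_kuramoto(edgeless, 0, omega = om, theta0 = c(0, 0),
                            cfg = kuramoto_config())
  bin <- 2 * pi / 400
  expect_lt(abs(dominant_module_frequency(traj, 1) - 0.5), bin + 1e-9)
  # two uncoupled tones: the dominant bin is one of them, not the mean
  om2 <- c(0.3, 0.7)
  traj2 <- simulate_kuramoto(edgeless, 0, omega = om2, theta0 = c(0, 0),
                             cfg = kuramoto_config())
  f <- dominant_module_frequency(traj2, c(1, 2))
  expect_true(min(abs(f - om2)) < bin + 1e-9)
  expect_gt(abs(f - 0.5), bin) # not the average tone
  # a synchronized group reports the common locked frequency
  two <- conn_from_edges(2, c(1, 2))
  traj3 <- simulate_kuramoto(two, 0.15, omega = c(0.4, 0.6),
                             theta0 = c(0, 0), cfg = kuramoto_config())
  expect_lt(abs(dominant_module_frequency(traj3, c(1, 2)) - 0.5),
            bin + 1e-9)
  expect_error(dominant_module_frequency(traj3, integer()), "empty")
})

test_that("whole-brain synchronization point applies the 5% criterion", {
  mk <- function(lam, fs) data.frame(lambda = lam,
                                     group = seq_along(fs),
                                     frequency = fs)
  expect_equal(whole_brain_sync_point(mk(0.1, c(1.0, 0.96))), 0.1)
  expect_true(is.na(whole_brain_sync_point(mk(0.1, c(1.0, 0.94)))))
  # monotone converging tracks: first crossing wins
  tracks <- rbind(mk(0.01, c(1.5, 0.5)), mk(0.02, c(1.2, 0.9)),
                  mk(0.03, c(1.0, 0.97)), mk(0.04, c(1.0, 0.99)))
  expect_equal(whole_brain_sync_point(tracks), 0.03)
  expect_error(whole_brain_sync_point(tracks[0, ]), "empty")
})

test_that("Bartlett's statistic matches the textbook formula to 1e-8", {
  set.seed(77)
  groups <- list(a = rnorm(12, sd = 1), b = rnorm(20, sd = 2),
                 c = rnorm(9, sd = 0.5))
  ht <- bartlett_frequency_test(groups)
  # hand-computed pooled-variance chi-square statistic
  ni <- vapply(groups, length, 0L); vi <- vapply(groups, var, 0)
  k <- length(groups); Ntot <- sum(ni)
  sp2 <- sum((ni - 1) * vi) / (Ntot - k)
  stat <- ((Ntot - k) * log(sp2) - sum((ni - 1) * log(vi))) /
    (1 + (sum(1 / (ni - 1)) - 1 / (Ntot - k)) / (3 * (k - 1)))
  expect_equal(unname(ht$statistic), stat, tolerance = 1e-8)
  expect_equal(unname(ht$p.value),
               pchisq(stat, k - 1, lower.tail = FALSE), tolerance = 1e-8)
  expect_error(bartlett_frequency_test(list(a = c(1, 1, 1), b = rnorm(5))),
               "zero variance")
  expect_error(bartlett_frequency_test(list(a = rnorm(3))), "2 groups")
})

test_that("Bartlett's test holds its size and detects unequal variances", {
  set.seed(88)
  reps <- 400
  pvals <- vapply(seq_len(reps), function(i) {
    g <- list(rnorm(20), rnorm(20), rnorm(20))
    bartlett_frequency_test(g)$p.value
  }, 0)
  expect_gt(mean(pvals < 0.05), 0.02) # type-I near nominal...
  expect_lt(mean(pvals < 0.05), 0.09) # ...neither degenerate nor inflated
  rejected <- vapply(seq_len(100), function(i) {
    g <- list(rnorm(50, sd = 1), rnorm(50, sd = 5))
    bartlett_frequency_test(g)$p.value < 0.05
  }, TRUE)
  expect_true(all(rejected)) # variance ratio 25 is always detected
})

test_that("permutation p-values match exhaustive enumeration", {
  a <- c(2.1, 3.4, 1.9, 2.8, 3.0)
  b <- c(1.2, 2.0, 1.5, 2.6, 1.1)
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  combos <- combn(10, 5)
  diffs <- apply(combos, 2, function(idx)
    mean(pool[idx]) - mean(pool[-idx]))
  exact <- mean(abs(diffs) >= abs(obs) - 1e-12)
  mc <- permutation_test(a, b, n_perm = 10000, seed = 6)
  expect_lt(abs(mc$p_value - exact), 0.015) # within ~3 MC standard errors
  expect_equal(mc$observed, obs)
  # identical groups: no signal
  same <- permutation_test(1:10, 1:10, n_perm = 500, seed = 1)
  expect_gt(same$p_value, 0.5)
  # disjoint support: smoothing floor 1 / (n_perm + 1)
  floor_p <- permutation_test(101:120, 1:20, n_perm = 10000, seed = 2)
  expect_equal(floor_p$p_value, 1 / 10001)
  expect_error(permutation_test(numeric(), 1:3), "non-empty")
})

test_that("sweeps are reproducible and behave at the coupling extremes", {
  net <- generate_connectome(synth_spec(n_nodes = 10, n_modules = 2,
                                        size_range = c(5, 5), hub_frac = 0.2,
                                        p_intra = 0.8, p_inter = 0.3,
                                        seed = 20))
  cfg <- fast_cfg()
  rec1 <- run_sweep(net$connectome, net$partition, c(0, 0.5), n_trials = 2,
                    cfg = cfg, base_seed = 7)
  rec2 <- run_sweep(net$connectome, net$partition, c(0, 0.5), n_trials = 2,
                    cfg = cfg, base_seed = 7)
  expect_identical(rec1$summary, rec2$summary)
  expect_identical(rec1$r_ij, rec2$r_ij)
  # lambda = 0: incoherent floor; lambda = 0.5: attractor state
  expect_lt(rec1$summary$r_link[1], 0.45)
  expect_gt(rec1$summary$r[2], 0.99)
  # same-sized modules are statistically exchangeable at lambda = 0
  intra <- rec1$modular[rec1$modular$lambda == 0 &
                        rec1$modular$group_a == rec1$modular$group_b &
                        rec1$modular$group_a != "hubs", "sync"]
  expect_lt(abs(diff(intra)), 0.35)
})

test_that("perturbation only shifts the attractor frequency at strong coupling", {
  net <- generate_connectome(synth_spec(n_nodes = 60, n_modules = 4,
                                        size_range = c(11, 20), seed = 30))
  part <- net$partition
  set.seed(55); om <- runif(60); th0 <- runif(60, -pi, pi)
  om_p <- perturb_frequencies(om, part$hubs)
  traj <- simulate_kuramoto(net$connectome, 0.5, omega = om_p, theta0 = th0,
                            cfg = kuramoto_config())
  expect_gt(order_parameter_r(traj), 0.99) # attractor survives perturbation
  f <- dominant_module_frequency(traj, seq_len(60))
  expect_lt(abs(f - mean(om_p)), 2 * pi / 400 + 1e-9) # global frequency = mean omega
})

test_that("frequency tracks carry modules plus the perturbed pseudo-group", {
  net <- generate_connectome(synth_spec(n_nodes = 30, n_modules = 2,
                                        size_range = c(11, 20), seed = 31))
  tk <- run_frequency_track(net$connectome, net$partition,
                            lambda_grid = c(0.05, 0.3), perturb = "hubs",
                            n_trials = 2, cfg = fast_cfg(), base_seed = 3)
  expect_setequal(unique(tk$group), c("1", "2", "perturbed"))
  # perturbing one module adds no extra group
  tk2 <- run_frequency_track(net$connectome, net$partition,
                             lambda_grid = 0.05, perturb = 1,
                             n_trials = 1, cfg = fast_cfg(), base_seed = 3)
  expect_setequal(unique(tk2$group), c("1", "2"))
  # strong coupling entrains every group to one frequency
  agg <- aggregate(frequency ~ group, tk[tk$lambda == 0.3, ], mean)
  expect_lt(max(agg$frequency) - min(agg$frequency), 0.1)
})
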