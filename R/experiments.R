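#' Suppress connectivity within a node set
#'
#' Removes every edge whose BOTH endpoints lie in `K` (e.g. all hub-to-hub
#' "rich club" connections), leaving all other edges untouched, so the
#' targeted nodes remain connected to the rest of the network as normal.
#'
#' @param conn a [connectome()].
#' @param K integer vector of node indices to decouple from each other.
#' @return a new [connectome()] with attribute `"n_removed"`, the number of
#'   removed edges.
#' @export
suppress_edges <- function(conn, K) {
  assert_connectome(conn)
  K <- sort(unique(as.integer(K)))
  if (length(K) && (min(K) < 1 || max(K) > conn$N))
    stopf("node indices in K must lie in 1..N")
  W <- conn$W
  removed <- if (length(K)) sum(W[K, K]) / 2 else 0
  if (length(K)) W[K, K] <- 0L
  out <- connectome(W, conn$labels)
  attr(out, "n_removed") <- as.integer(removed)
  out
}

#' Remove random edges
#'
#' Removes `n_remove` edges drawn uniformly at random, the reference
#' condition matched in edge count to a targeted hub suppression.
#'
#' @param conn a [connectome()].
#' @param n_remove number of edges to remove (<= edge count).
#' @param seed RNG seed.
#' @return a new [connectome()] with attribute `"n_removed"`.
#' @export
suppress_random_edges <- function(conn, n_remove, seed = NULL) {
  assert_connectome(conn)
  n_remove <- as.integer(n_remove)
  pairs <- upper_pairs(conn$N)
  edges <- pairs[conn$W[pairs] == 1L, , drop = FALSE]
  if (n_remove < 0 || n_remove > nrow(edges))
    stopf("n_remove must be between 0 and the edge count (%d)", nrow(edges))
  W <- conn$W
  if (n_remove > 0) {
    drop <- with_seed(seed, sample.int(nrow(edges), n_remove))
    sel <- edges[drop, , drop = FALSE]
    W[sel] <- 0L
    W[sel[, c(2, 1), drop = FALSE]] <- 0L
  }
  out <- connectome(W, conn$labels)
  attr(out, "n_removed") <- n_remove
  out
}

#' Perturb internal frequencies of a node set
#'
#' Offsets the internal angular frequency of the selected nodes by `delta`
#' (default +1, i.e. the frequencies are increased by one). Applying the
#' perturbation twice offsets twice.
#'
#' @param omega frequency vector.
#' @param K node indices to perturb.
#' @param delta frequency offset (default 1).
#' @return perturbed frequency vector.
#' @export
perturb_frequencies <- function(omega, K, delta = 1) {
  K <- as.integer(K)
  if (length(K) && (min(K) < 1 || max(K) > length(omega)))
    stopf("node indices in K must lie in 1..length(omega)")
  omega[K] <- omega[K] + delta
  omega
}

sweep_groups <- function(part) {
  g <- as.list(setNames(as.character(part$module_ids), part$module_ids))
  if (length(part$hubs)) g <- c(g, list(hubs = "hubs"))
  g
}

#' Coupling-strength sweep with trial averaging
#'
#' Runs `n_trials` independent simulations (fresh random initial phases and
#' frequencies per trial) at every coupling strength in `lambda_grid`, and
#' aggregates the synchronization observables: the phase-coherence order
#' parameter r, the synchronized-pair fraction r_link, the trial-averaged
#' synchronization probability matrix r_ij, the modular synchronization
#' table over all module pairs plus the hub pseudo-module, and (optionally)
#' the group-level mean-field influences. Trial l at the i-th coupling uses
#' seed `base_seed + (i-1)*n_trials + (l-1)`, making the whole sweep
#' reproducible and trials independent.
#'
#' @param conn a [connectome()].
#' @param part a [partition()] (its hub set defines the hub pseudo-module).
#' @param lambda_grid numeric vector of coupling strengths.
#' @param n_trials trials per coupling (default 100).
#' @param cfg a [kuramoto_config()] (its `seed` field is ignored here).
#' @param base_seed integer seed anchoring all trials.
#' @param condition free-text label stored on the record (e.g. `"normal"`,
#'   `"hub_suppressed"`).
#' @param omega_transform optional function `omega -> omega` applied to the
#'   drawn frequencies before integration (used by perturbation
#'   experiments so the random draws stay aligned across conditions).
#' @param compute_influence also accumulate [group_influence_table()]
#'   averages (default FALSE; adds cost).
#' @param influence_stride time-sample stride for influence averaging.
#' @param keep_r_ij store the r_ij matrix per coupling (default TRUE).
#' @return object of class `sweep_record`: list with `summary` (per-lambda
#'   r and r_link), `modular` (per-lambda group-pair synchrony), per-trial
#'   tables `trial_metrics` and `module_trials`, `influence`, `r_ij`,
#'   and the run metadata.
#' @export
run_sweep <- function(conn, part, lambda_grid, n_trials = 100,
                      cfg = kuramoto_config(), base_seed = 1,
                      condition = "normal", omega_transform = NULL,
                      compute_influence = FALSE, influence_stride = 8,
                      keep_r_ij = TRUE) {
  assert_connectome(conn); assert_partition(part)
  if (length(lambda_grid) == 0) stopf("lambda_grid is empty")
  if (n_trials < 1) stopf("n_trials must be >= 1")
  groups <- sweep_groups(part)
  gid <- names(groups)

  summary_rows <- list(); modular_rows <- list(); trial_rows <- list()
  module_trial_rows <- list(); infl_rows <- list(); r_ij_list <- list()

  for (li in seq_along(lambda_grid)) {
    lam <- lambda_grid[li]
    F_sum <- matrix(0, conn$N, conn$N)
    infl_sum <- NULL; infl_n <- NULL
    for (tr in seq_len(n_trials)) {
      seed_t <- base_seed + (li - 1L) * n_trials + (tr - 1L)
      draw <- with_seed(seed_t, list(theta0 = runif(conn$N, -pi, pi),
                                     omega = runif(conn$N)))
      omega <- draw$omega
      if (!is.null(omega_transform)) omega <- omega_transform(omega)
      traj <- tryCatch(
        simulate_kuramoto(conn, lam, omega = omega, theta0 = draw$theta0,
                          cfg = cfg),
        error = function(e) stopf("lambda = %g, trial %d: %s", lam, tr,
                                  conditionMessage(e)))
      C <- edgewise_synchrony(traj)
      rl <- r_link(C)
      F <- binarize_synchrony(C, rl)
      F_sum <- F_sum + F

      intra <- vapply(gid, function(g)
        modular_synchrony(F, groups[[g]], part = part), 0)
      mods <- setdiff(gid, "hubs")
      glob <- mean(F[row(F) != col(F)])
      trial_rows[[length(trial_rows) + 1]] <- data.frame(
        lambda = lam, trial = tr, r = order_parameter_r(traj), r_link = rl,
        global_sync = glob,
        intra_hub = if ("hubs" %in% gid) intra[["hubs"]] else NA_real_,
        mean_intra_module = mean(intra[mods]),
        ratio = if (glob > 0) mean(intra[mods]) / glob else NA_real_)
      module_trial_rows[[length(module_trial_rows) + 1]] <- data.frame(
        lambda = lam, trial = tr, group = gid, sync = unname(intra))

      if (compute_influence) {
        tab <- group_influence_table(traj, conn, part,
                                     stride = influence_stride)
        if (is.null(infl_sum)) {
          infl_sum <- ifelse(is.na(tab$R), 0, tab$R)
          infl_n <- as.integer(!is.na(tab$R))
          infl_key <- tab[, c("target", "source")]
        } else {
          infl_sum <- infl_sum + ifelse(is.na(tab$R), 0, tab$R)
          infl_n <- infl_n + as.integer(!is.na(tab$R))
        }
      }
    }
    r_ij <- F_sum / n_trials
    dimnames(r_ij) <- dimnames(conn$W)
    if (keep_r_ij) r_ij_list[[as.character(lam)]] <- r_ij

    tm <- do.call(rbind, trial_rows)
    tm <- tm[tm$lambda == lam, ]
    summary_rows[[li]] <- data.frame(
      lambda = lam, r = mean(tm$r), r_link = mean(tm$r_link),
      global_sync = mean(tm$global_sync))

    for (ai in seq_along(gid)) for (bi in ai:length(gid)) {
      modular_rows[[length(modular_rows) + 1]] <- data.frame(
        lambda = lam, group_a = gid[ai], group_b = gid[bi],
        sync = modular_synchrony(r_ij, groups[[gid[ai]]],
                                 groups[[gid[bi]]], part = part))
    }
    if (compute_influence) {
      infl_rows[[length(infl_rows) + 1]] <- data.frame(
        lambda = lam, infl_key,
        R = ifelse(infl_n > 0, infl_sum / infl_n, NA_real_))
    }
  }

  structure(list(
    lambda_grid = lambda_grid, condition = condition, n_trials = n_trials,
    base_seed = base_seed, cfg = cfg,
    summary = do.call(rbind, summary_rows),
    modular = do.call(rbind, modular_rows),
    trial_metrics = do.call(rbind, trial_rows),
    module_trials = do.call(rbind, module_trial_rows),
    influence = if (compute_influence) do.call(rbind, infl_rows) else NULL,
    r_ij = if (keep_r_ij) r_ij_list else NULL),
    class = "sweep_record")
}

#' @export
print.sweep_record <- function(x, ...) {
  cat(sprintf("<sweep_record> condition '%s': %d lambda values x %d trials\n",
              x$condition, length(x$lambda_grid), x$n_trials))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Intramodular-to-global synchrony ratio
#'
#' The ratio between the average intramodular synchrony of the functional
#' modules and the whole-brain synchrony, per coupling strength. Rising
#' ratios indicate an elevated modular state (modules synchronized
#' internally but not with each other).
#'
#' @param record a [run_sweep()] record.
#' @param per_trial if TRUE, return one ratio per (lambda, trial) computed
#'   from that trial's binary synchrony matrix, suitable for permutation
#'   tests; otherwise one aggregated ratio per lambda from r_ij.
#' @return data.frame with `lambda` (and `trial`) and `ratio`; `NA` where
#'   the global synchrony is zero.
#' @export
modularity_ratio <- function(record, per_trial = FALSE) {
  if (!inherits(record, "sweep_record")) stopf("expected a sweep_record")
  if (per_trial)
    return(record$trial_metrics[, c("lambda", "trial", "ratio")])
  mod <- record$modular
  intra <- mod[mod$group_a == mod$group_b & mod$group_a != "hubs", ]
  out <- lapply(split(intra, intra$lambda), function(d) {
    lam <- d$lambda[1]
    glob <- record$summary$global_sync[record$summary$lambda == lam]
    data.frame(lambda = lam,
               ratio = if (glob > 0) mean(d$sync) / glob else NA_real_)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$lambda), ]
  rownames(res) <- NULL
  res
}

#' Dominant oscillation frequency of a node group
#'
#' Fourier analysis of the group-mean phasor signal
#' `s(t) = (1/N_g) sum_{j in g} exp(i theta_j(t))` over the post-transient
#' window: returns the angular frequency of the maximal-power DFT bin, the
#' DC bin excluded. The frequency resolution is `2*pi / window length`.
#'
#' @param traj a [simulate_kuramoto()] trajectory.
#' @param group node index vector, or module id / `"hubs"` resolved via
#'   `part`.
#' @param part optional [partition()] used to resolve `group`.
#' @return dominant angular frequency (>= 0, radians per time unit).
#' @export
dominant_module_frequency <- function(traj, group, part = NULL) {
  theta <- as_theta(traj)
  members <- resolve_members(group, part)
  if (length(members) == 0) stopf("empty node group")
  nt <- ncol(theta)
  if (nt < 2) stopf("need at least 2 sampled time points")
  s <- colMeans(exp(1i * theta[members, , drop = FALSE]))
  power <- Mod(fft(s))^2
  sample_dt <- if (inherits(traj, "kuramoto_trajectory"))
    traj$cfg$sample_dt else 1
  bins <- 0:(nt - 1)
  freq <- 2 * pi * ifelse(bins <= nt / 2, bins, bins - nt) / (nt * sample_dt)
  power[1] <- -Inf # exclude DC
  abs(freq[which.max(power)])
}

#' Track modular frequencies across a coupling grid
#'
#' For each coupling strength and trial, simulates the (optionally
#' frequency-perturbed) system and extracts the dominant oscillation
#' frequency of every functional module; when the perturbed set is not
#' itself a module it is tracked as an extra group `"perturbed"`. The
#' perturbation is applied after the random initial conditions are drawn,
#' so conditions sharing `base_seed` are paired draw-for-draw.
#'
#' @param conn a [connectome()].
#' @param part a [partition()].
#' @param lambda_grid coupling strengths (ascending).
#' @param perturb `NULL` (no perturbation), `"hubs"`, a module id, or an
#'   integer node index vector whose frequencies are offset by `delta`.
#' @param delta frequency offset applied to the perturbed set (default 1).
#' @param n_trials trials per coupling (default 20).
#' @param cfg a [kuramoto_config()].
#' @param base_seed integer seed anchoring all trials.
#' @return object of class `frequency_track`: data.frame with columns
#'   `lambda`, `trial`, `group`, `frequency`, plus attributes recording the
#'   perturbed set and condition label.
#' @export
run_frequency_track <- function(conn, part, lambda_grid, perturb = NULL,
                                delta = 1, n_trials = 20,
                                cfg = kuramoto_config(), base_seed = 1) {
  assert_connectome(conn); assert_partition(part)
  if (length(lambda_grid) == 0) stopf("lambda_grid is empty")
  K <- if (is.null(perturb)) integer() else resolve_members(perturb, part)
  groups <- as.list(setNames(as.character(part$module_ids), part$module_ids))
  is_module <- length(K) > 0 &&
    any(vapply(part$modules, function(m) setequal(m, K), TRUE))
  if (length(K) && !is_module) groups <- c(groups, list(perturbed = K))

  rows <- list()
  for (li in seq_along(lambda_grid)) {
    lam <- lambda_grid[li]
    for (tr in seq_len(n_trials)) {
      seed_t <- base_seed + (li - 1L) * n_trials + (tr - 1L)
      draw <- with_seed(seed_t, list(theta0 = runif(conn$N, -pi, pi),
                                     omega = runif(conn$N)))
      omega <- perturb_frequencies(draw$omega, K, delta)
      traj <- simulate_kuramoto(conn, lam, omega = omega,
                                theta0 = draw$theta0, cfg = cfg)
      f <- vapply(groups, function(g)
        dominant_module_frequency(traj, g, part = part), 0)
      rows[[length(rows) + 1]] <- data.frame(
        lambda = lam, trial = tr, group = names(groups),
        frequency = unname(f))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "perturbed") <- K
  attr(out, "condition") <- if (is.null(perturb)) "normal"
    else paste0("perturbed:", paste(format(perturb), collapse = ","))
  class(out) <- c("frequency_track", class(out))
  out
}

#' Whole-brain synchronization point
#'
#' The smallest coupling strength at which the lowest group frequency is
#' within 5% of the highest (`min >= (1 - tol) * max`), i.e. all tracked
#' groups oscillate at essentially one frequency. Per-trial tracks are
#' first averaged per (lambda, group).
#'
#' @param tracks a [run_frequency_track()] result, or any data.frame with
#'   columns `lambda`, `group`, `frequency` (and optionally `trial`).
#' @param tol relative tolerance (default 0.05).
#' @return the crossing coupling strength, or `NA` if never reached.
#' @export
whole_brain_sync_point <- function(tracks, tol = 0.05) {
  tracks <- as.data.frame(tracks)
  if (nrow(tracks) == 0) stopf("empty frequency track")
  agg <- stats::aggregate(frequency ~ lambda + group, data = tracks,
                          FUN = mean)
  for (lam in sort(unique(agg$lambda))) {
    f <- agg$frequency[agg$lambda == lam]
    if (min(f) >= (1 - tol) * max(f)) return(lam)
  }
  NA_real_
}

#' Bartlett's test on modular frequency samples
#'
#' Tests homogeneity of variance of dominant-frequency samples across
#' groups (typically the per-trial dominant frequencies of each unperturbed
#' module at the coupling immediately prior to whole-brain
#' synchronization). A group with zero variance makes the statistic
#' undefined and raises an error.
#'
#' @param groups named list of numeric vectors, one per group, each with at
#'   least 2 values.
#' @return `htest` object (statistic `Bartlett's K-squared`, df, p-value).
#' @export
bartlett_frequency_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stopf("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2))
    stopf("every group needs at least 2 values")
  if (any(vapply(groups, sd, 0) == 0))
    stopf("a group has zero variance; Bartlett's statistic is undefined")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  bartlett.test(values, labels)
}

#' Two-sided permutation test on a mean difference
#'
#' Label-shuffle test: the observed difference in group means is compared
#' with its distribution under `n_perm` random reassignments of the pooled
#' values to the two groups. The p-value uses add-one smoothing,
#' `p = (1 + #{|perm| >= |obs|}) / (n_perm + 1)`, so it is bounded below by
#' `1/(n_perm + 1)`.
#'
#' @param values_a,values_b numeric samples.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list with `p_value`, `observed` (mean difference), `n_perm`.
#' @export
permutation_test <- function(values_a, values_b, n_perm = 10000,
                             seed = NULL) {
  if (length(values_a) == 0 || length(values_b) == 0)
    stopf("both groups must be non-empty")
  if (n_perm < 1) stopf("n_perm must be >= 1")
  obs <- mean(values_a) - mean(values_b)
  pool <- c(values_a, values_b)
  na <- length(values_a)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pool), na)
      abs(mean(pool[idx]) - mean(pool[-idx])) >= abs(obs)
    }, TRUE))
  })
  list(p_value = (1 + exceed) / (n_perm + 1), observed = obs,
       n_perm = n_perm)
}
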