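#' Global phase-coherence order parameter r
#'
#' The modulus of the population-mean unit phasor,
#' `z(t) = (1/N) sum_j exp(i theta_j(t))`, averaged over the sampled time
#' window. r = 1 at full phase synchrony, r near 0 for incoherent phases.
#'
#' @param traj a [simulate_kuramoto()] trajectory or a node-by-time phase
#'   matrix.
#' @return scalar in \[0, 1\].
#' @export
order_parameter_r <- function(traj) {
  theta <- as_theta(traj)
  if (ncol(theta) < 1) stopf("trajectory has no sampled time points")
  mean(Mod(colMeans(exp(1i * theta))))
}

#' Edgewise synchrony matrix C
#'
#' For every node pair, the modulus of the time-averaged phasor of the
#' phase difference: `C_ij = |mean_t exp(i (theta_i(t) - theta_j(t)))|`.
#' C_ij = 1 when the pair keeps a fixed phase relation (including a
#' constant lag) and tends to 0 when the phase difference drifts through
#' full cycles. Together the C_ij form the simulated functional
#' connectivity matrix.
#'
#' @inheritParams order_parameter_r
#' @return symmetric N x N matrix with unit diagonal.
#' @export
edgewise_synchrony <- function(traj) {
  theta <- as_theta(traj)
  nt <- ncol(theta)
  if (nt < 1) stopf("trajectory has no sampled time points")
  Z <- exp(1i * theta)
  C <- Mod(Z %*% Conj(t(Z))) / nt
  C <- (C + t(C)) / 2
  C[C > 1] <- 1
  diag(C) <- 1
  C
}

#' Synchronized-pair fraction r_link
#'
#' Mean of the off-diagonal edgewise synchrony values, interpreted as the
#' fraction of node pairs that are in synchrony.
#'
#' @param C edgewise synchrony matrix from [edgewise_synchrony()].
#' @return scalar in \[0, 1\].
#' @export
r_link <- function(C) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (n < 2 || ncol(C) != n) stopf("C must be a square matrix with N >= 2")
  mean(C[row(C) != col(C)])
}

#' Binarize edgewise synchrony
#'
#' Constructs the binary synchronization matrix F marking the most
#' synchronized pairs: of the N(N-1)/2 unordered pairs, the
#' `round(r_link * N(N-1)/2)` pairs with the largest C values are set to 1
#' (mirrored symmetrically), so the number of edges in F matches the number
#' of synchronized connections predicted by r_link. Ties at the cutoff are
#' broken by (C descending, row ascending, column ascending).
#'
#' @param C edgewise synchrony matrix.
#' @param rl optional precomputed r_link; recomputed from `C` when `NULL`.
#' @return binary symmetric matrix with zero diagonal.
#' @export
binarize_synchrony <- function(C, rl = NULL) {
  C <- as.matrix(C)
  n <- nrow(C)
  rl <- rl %||% r_link(C)
  pairs <- upper_pairs(n)
  vals <- C[pairs]
  m <- round(rl * n * (n - 1) / 2)
  F <- matrix(0L, n, n, dimnames = dimnames(C))
  if (m > 0) {
    ord <- order(-vals, pairs[, 1], pairs[, 2])
    top <- pairs[ord[seq_len(min(m, length(vals)))], , drop = FALSE]
    F[top] <- 1L
    F[top[, c(2, 1), drop = FALSE]] <- 1L
  }
  F
}

#' Trial-averaged synchronization probability
#'
#' Elementwise mean of binary synchronization matrices over trials;
#' `r_ij` estimates the probability that regions i and j are synchronized.
#'
#' @param F_list list of binary matrices from [binarize_synchrony()], one
#'   per trial.
#' @return numeric matrix with entries in \[0, 1\].
#' @export
sync_probability <- function(F_list) {
  if (length(F_list) == 0) stopf("empty trial list")
  dims <- vapply(F_list, function(f) dim(as.matrix(f)), integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)
    stopf("trial matrices have inconsistent shapes")
  Reduce(`+`, lapply(F_list, as.matrix)) / length(F_list)
}

resolve_members <- function(x, part) {
  if (is.numeric(x) && length(x) > 1 ||
      (is.numeric(x) && is.null(part))) return(sort(unique(as.integer(x))))
  if (identical(x, "hubs")) {
    if (is.null(part) || length(part$hubs) == 0)
      stopf("no hub set available in the partition")
    return(part$hubs)
  }
  if (is.null(part)) stopf("a partition is required to resolve module ids")
  module_members(part, x)
}

#' Modular synchronization
#'
#' Average synchronization probability between two groups of nodes: the
#' mean of `r_ij` over pairs i in group a, j in group b with i != j. For
#' two disjoint modules this is the intermodular synchrony
#' `(1/(N_a N_b)) sum r_ij`; for a == b it is the intramodular synchrony
#' with denominator `N_a (N_a - 1)` (self-pairs excluded so module size
#' does not bias the value). Groups may be module ids resolved through
#' `part`, the string `"hubs"` for the designated hub set, or explicit node
#' index vectors, so intra-hub and hub-module synchrony reuse the same
#' estimator with the hub set as a pseudo-module.
#'
#' @param r_ij synchronization probability matrix (or a single-trial binary
#'   F matrix).
#' @param a,b module id, `"hubs"`, or integer node index vector; `b`
#'   defaults to `a` (intra-group synchrony).
#' @param part a [partition()], required when `a`/`b` are module ids or
#'   `"hubs"`.
#' @return scalar in \[0, 1\].
#' @export
modular_synchrony <- function(r_ij, a, b = a, part = NULL) {
  r_ij <- as.matrix(r_ij)
  A <- resolve_members(a, part)
  B <- resolve_members(b, part)
  if (length(A) == 0 || length(B) == 0) stopf("empty node group")
  common <- intersect(A, B)
  denom <- length(A) * length(B) - length(common)
  if (denom == 0)
    stopf("intra-group synchrony is undefined for a singleton group")
  s <- sum(r_ij[A, B])
  if (length(common)) s <- s - sum(r_ij[cbind(common, common)])
  s / denom
}

#' Mean-field influence of node groups on one node
#'
#' Decomposes the mean field felt by a target node by source group: for
#' each module (and the hub set) the neighbours of the target inside that
#' group contribute `D_kg` connections and a partial centroid
#' `R_kg exp(i phi_kg)`, the mean phasor of those neighbours. `R_kg`
#' measures how coherently group g drives the target. Groups contributing
#' at most one connection are flagged not evaluable, since a single
#' neighbour gives `R = 1` identically and carries no coherence
#' information.
#'
#' @param theta_t phase vector at one time point.
#' @param conn a [connectome()].
#' @param part a [partition()].
#' @param target node index with degree >= 1.
#' @return data.frame with columns `group` (module ids plus `"hubs"` when
#'   present), `D`, `R`, `phi`, `evaluable`.
#' @export
module_influence <- function(theta_t, conn, part, target) {
  assert_connectome(conn); assert_partition(part)
  if (length(theta_t) != conn$N) stopf("theta_t must have length N")
  nb <- which(conn$W[target, ] == 1)
  if (length(nb) == 0) stopf("target node %d is isolated", target)
  groups <- c(as.list(setNames(part$module_ids, part$module_ids)),
              if (length(part$hubs)) list(hubs = "hubs"))
  rows <- lapply(names(groups), function(g) {
    mem <- if (identical(g, "hubs")) part$hubs else module_members(part, g)
    sel <- intersect(nb, mem)
    d <- length(sel)
    if (d > 0) {
      z <- mean(exp(1i * theta_t[sel]))
      data.frame(group = g, D = d, R = Mod(z), phi = Arg(z),
                 evaluable = d > 1)
    } else {
      data.frame(group = g, D = 0L, R = NA_real_, phi = NA_real_,
                 evaluable = FALSE)
    }
  })
  do.call(rbind, rows)
}

# Per-node influence radii of one source group along a trajectory:
# R_kg(t) = |sum_{j in g} W_kj exp(i theta_j(t))| / D_kg, rows with
# D_kg <= 1 set to NA. Returns list(D = vector, R = N x n_times matrix).
influence_radii <- function(theta, conn, members, stride = 1) {
  cols <- seq(1, ncol(theta), by = stride)
  Wg <- conn$W[, members, drop = FALSE]
  D <- rowSums(Wg)
  Z <- Wg %*% exp(1i * theta[members, cols, drop = FALSE])
  R <- Mod(Z) / ifelse(D > 0, D, NA_real_)
  R[D <= 1, ] <- NA_real_
  list(D = D, R = R)
}

#' Group-level mean-field influence
#'
#' The average influence `R_{beta,source}` that a source group (module or
#' hub set) exerts on the nodes of a target module: the per-node influence
#' radii `R_{k,source}` are computed at every sampled time point (optionally
#' strided), restricted to evaluable nodes (more than one connection into
#' the source group), averaged over those nodes and then over time.
#'
#' @param traj a [simulate_kuramoto()] trajectory.
#' @param conn a [connectome()].
#' @param part a [partition()].
#' @param target_module module id whose nodes receive the influence.
#' @param source module id, `"hubs"`, or node index vector exerting it.
#' @param stride keep every `stride`-th time sample (default 1).
#' @return scalar influence in \[0, 1\], or `NA` when no node is evaluable.
#' @export
group_influence <- function(traj, conn, part, target_module, source,
                            stride = 1) {
  assert_connectome(conn); assert_partition(part)
  theta <- as_theta(traj)
  src <- resolve_members(source, part)
  tgt <- module_members(part, target_module)
  ir <- influence_radii(theta, conn, src, stride = stride)
  vals <- ir$R[tgt, , drop = FALSE]
  if (all(is.na(vals))) return(NA_real_)
  mean(colMeans(vals, na.rm = TRUE))
}

#' All pairwise group influences along a trajectory
#'
#' Convenience wrapper computing [group_influence()] for every target
#' module against every source module and the hub set.
#'
#' @inheritParams group_influence
#' @return data.frame with columns `target`, `source`, `R`.
#' @export
group_influence_table <- function(traj, conn, part, stride = 1) {
  theta <- as_theta(traj)
  sources <- c(as.character(part$module_ids),
               if (length(part$hubs)) "hubs")
  rows <- list()
  for (s in sources) {
    mem <- if (identical(s, "hubs")) part$hubs else module_members(part, s)
    ir <- influence_radii(theta, conn, mem, stride = stride)
    for (tm in part$module_ids) {
      vals <- ir$R[module_members(part, tm), , drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        target = as.character(tm), source = s,
        R = if (all(is.na(vals))) NA_real_
            else mean(colMeans(vals, na.rm = TRUE)))
    }
  }
  do.call(rbind, rows)
}
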