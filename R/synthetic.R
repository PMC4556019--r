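#' Specification for a synthetic rich-club connectome
#'
#' Describes a planted-partition network with an embedded hub set: nodes
#' are split into modules wired densely inside (`p_intra`) and sparsely
#' between (`p_inter`); a fraction `hub_frac` of nodes, spread over every
#' module, is additionally densified among themselves (`p_hub_hub`) and
#' towards the rest of the network (`p_hub_out`) so that the planted hubs
#' dominate the degree ranking and form a rich club. Extra wiring
#' probabilities combine with the base probabilities as unions
#' (`1 - (1-p_base)(1-p_extra)`).
#'
#' Defaults emulate the structure of a 219-region cortical consensus
#' network: 11 modules with sizes drawn from 11 to 31 nodes, 18% hubs,
#' module-internal density well above the network-wide density, and a
#' hub-hub density on par with the module-internal density (the hubs'
#' rich-club character comes from their degree, spread and mutual wiring,
#' not from an implausibly dense clique).
#'
#' @param n_nodes total node count (default 219).
#' @param n_modules number of modules (default 11).
#' @param size_range inclusive range module sizes are drawn from
#'   (default c(11, 31)); sizes are adjusted within the range to sum to
#'   `n_nodes`.
#' @param p_intra within-module edge probability (default 0.30).
#' @param p_inter between-module edge probability (default 0.06).
#' @param hub_frac fraction of nodes promoted to hubs (default 0.18).
#' @param p_hub_hub extra hub-hub edge probability (default 0.35).
#' @param p_hub_out extra hub-to-nonhub edge probability (default 0.10).
#' @param seed RNG seed.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_nodes = 219, n_modules = 11,
                       size_range = c(11, 31), p_intra = 0.30,
                       p_inter = 0.06, hub_frac = 0.18, p_hub_hub = 0.35,
                       p_hub_out = 0.10, seed = 1) {
  probs <- c(p_intra, p_inter, hub_frac, p_hub_hub, p_hub_out)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (n_modules * size_range[1] > n_nodes ||
      n_modules * size_range[2] < n_nodes)
    stopf("size_range cannot cover n_nodes with %d modules", n_modules)
  n_hubs <- round(hub_frac * n_nodes)
  if (n_hubs < n_modules)
    stopf("infeasible spec: fewer hubs (%d) than modules (%d); every module needs a hub",
          n_hubs, n_modules)
  structure(list(n_nodes = n_nodes, n_modules = n_modules,
                 size_range = size_range, p_intra = p_intra,
                 p_inter = p_inter, hub_frac = hub_frac,
                 p_hub_hub = p_hub_hub, p_hub_out = p_hub_out, seed = seed),
            class = "synth_spec")
}

# size-1-safe uniform draw from a vector (sample() treats scalars as 1:n)
pick <- function(x, k = 1) x[sample.int(length(x), k)]

# draw module sizes uniformly in range, then nudge random modules by +/-1
# within the range until the sizes sum to n_nodes (expects a seeded RNG)
draw_module_sizes <- function(n_nodes, n_modules, size_range) {
  span <- size_range[2] - size_range[1] + 1L
  sizes <- size_range[1] + sample.int(span, n_modules, replace = TRUE) - 1L
  while (sum(sizes) != n_nodes) {
    if (sum(sizes) < n_nodes) {
      i <- pick(which(sizes < size_range[2]))
      sizes[i] <- sizes[i] + 1L
    } else {
      i <- pick(which(sizes > size_range[1]))
      sizes[i] <- sizes[i] - 1L
    }
  }
  sizes
}

# allocate n_hubs across modules: one each, remainder by largest fractional
# share of module size
allocate_hubs <- function(sizes, n_hubs) {
  k <- length(sizes)
  alloc <- rep(1L, k)
  rem <- n_hubs - k
  if (rem > 0) {
    share <- sizes / sum(sizes) * rem
    alloc <- alloc + floor(share)
    left <- rem - sum(floor(share))
    if (left > 0) {
      ord <- order(share - floor(share), decreasing = TRUE)
      alloc[ord[seq_len(left)]] <- alloc[ord[seq_len(left)]] + 1L
    }
  }
  pmin(alloc, sizes)
}

# ensure connectivity by bridging components with random edges
connect_components <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected")
  comp <- igraph::components(g)
  added <- 0L
  while (comp$no > 1) {
    main <- which(comp$membership == which.max(comp$csize))
    other <- which(comp$membership != which.max(comp$csize))
    i <- other[sample.int(length(other), 1)]
    j <- main[sample.int(length(main), 1)]
    W[i, j] <- W[j, i] <- 1L
    added <- added + 1L
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected")
    comp <- igraph::components(g)
  }
  attr(W, "n_bridged") <- added
  W
}

planted_network <- function(n, module_of, hubs, p_intra, p_inter,
                            p_hub_hub, p_hub_out) {
  same <- outer(module_of, module_of, `==`)
  p <- ifelse(same, p_intra, p_inter)
  is_hub <- seq_len(n) %in% hubs
  hub_pair <- outer(is_hub, is_hub, `&`)
  hub_out <- xor(outer(is_hub, is_hub, `|`), hub_pair)
  p[hub_pair] <- 1 - (1 - p[hub_pair]) * (1 - p_hub_hub)
  p[hub_out] <- 1 - (1 - p[hub_out]) * (1 - p_hub_out)
  pairs <- upper_pairs(n)
  W <- matrix(0L, n, n)
  hit <- pairs[runif(nrow(pairs)) < p[pairs], , drop = FALSE]
  W[hit] <- 1L
  W[hit[, c(2, 1), drop = FALSE]] <- 1L
  W
}

#' Generate a synthetic rich-club connectome with planted modules
#'
#' Realizes a [synth_spec()]: draws module sizes, plants one module per
#' block with dense internal wiring, spreads the hub set across all
#' modules, and densifies hub wiring so the realized top-degree nodes
#' overlap the planted hubs and the network exhibits rich-club
#' organization. Disconnected realizations are repaired by adding minimal
#' random bridging edges (count stored as attribute `"n_bridged"` on the
#' adjacency).
#'
#' @param spec a [synth_spec()].
#' @return list with elements `connectome` (a [connectome()]) and
#'   `partition` (a [partition()] whose `hubs` are the planted hub nodes).
#' @examples
#' net <- generate_connectome(synth_spec(n_nodes = 60, n_modules = 4,
#'                                       size_range = c(10, 20), seed = 7))
#' net$connectome
#' @export
generate_connectome <- function(spec = synth_spec()) {
  if (!inherits(spec, "synth_spec")) stopf("expected a synth_spec")
  with_seed(spec$seed, {
    sizes <- draw_module_sizes(spec$n_nodes, spec$n_modules, spec$size_range)
    module_of <- rep(seq_along(sizes), sizes)
    n_hubs <- round(spec$hub_frac * spec$n_nodes)
    alloc <- allocate_hubs(sizes, n_hubs)
    hubs <- unlist(lapply(seq_along(sizes), function(m) {
      members <- which(module_of == m)
      sort(pick(members, alloc[m]))
    }))
    W <- planted_network(spec$n_nodes, module_of, hubs, spec$p_intra,
                         spec$p_inter, spec$p_hub_hub, spec$p_hub_out)
    W <- connect_components(W)
    n_bridged <- attr(W, "n_bridged"); attr(W, "n_bridged") <- NULL
    conn <- connectome(W)
    attr(conn, "n_bridged") <- n_bridged
    list(connectome = conn,
         partition = partition(module_of, hubs = hubs))
  })
}

#' Generate subject-level matrices around a template
#'
#' Each synthetic subject keeps every template edge with probability
#' `p_keep` and gains each absent connection (a spurious streamline) with
#' probability `p_spurious`, emulating the variability that group consensus
#' thresholding is designed to remove.
#'
#' @param template a [connectome()].
#' @param n_subjects number of subjects (default 40).
#' @param p_keep probability a true edge survives in a subject
#'   (default 0.9).
#' @param p_spurious probability a non-edge appears (default 0.005).
#' @param seed RNG seed.
#' @return a [subject_stack()].
#' @export
generate_subject_stack <- function(template, n_subjects = 40, p_keep = 0.9,
                                   p_spurious = 0.005, seed = 1) {
  assert_connectome(template)
  if (p_keep < 0 || p_keep > 1 || p_spurious < 0 || p_spurious > 1)
    stopf("probabilities must lie in [0, 1]")
  pairs <- upper_pairs(template$N)
  is_edge <- template$W[pairs] == 1L
  mats <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      keep <- runif(nrow(pairs)) < ifelse(is_edge, p_keep, p_spurious)
      W <- matrix(0L, template$N, template$N)
      sel <- pairs[keep, , drop = FALSE]
      W[sel] <- 1L
      W[sel[, c(2, 1), drop = FALSE]] <- 1L
      W
    })
  })
  subject_stack(mats)
}

#' Generate a macaque-style connectome
#'
#' A 78-node, 6-module planted network (all modules at least `min_size`
#' nodes) with a 19% hub set, adjusted edge-by-edge to a target density of
#' 27.6%: after the planted wiring is drawn, randomly chosen intermodular
#' non-hub-pair edges are added or removed until the realized density
#' matches `round(density * N(N-1)/2)` edges, so the module and hub
#' structure is preserved while the global density is met by construction.
#'
#' @param n_nodes node count (default 78).
#' @param n_modules module count (default 6).
#' @param min_size minimum module size (default 8).
#' @param density target edge density (default 0.276).
#' @param seed RNG seed.
#' @param size_range band module sizes are drawn from; kept narrow so node
#'   degree is driven by hub status rather than module size.
#' @param p_intra,p_inter,p_hub_hub,p_hub_out wiring probabilities; the
#'   defaults put module-internal and hub-hub densities well above the
#'   intermodular background (the tight density budget of a 27.6%-dense
#'   78-node network otherwise drowns the planted blocks in intermodular
#'   edges).
#' @param hub_frac hub fraction (default 15/78).
#' @return list with `connectome` and `partition` as in
#'   [generate_connectome()].
#' @export
generate_macaque_like <- function(n_nodes = 78, n_modules = 6, min_size = 8,
                                  density = 0.276, seed = 1,
                                  size_range = c(10, 16), p_intra = 0.9,
                                  p_inter = 0.12, p_hub_hub = 0.55,
                                  p_hub_out = 0.10, hub_frac = 15 / 78) {
  if (size_range[1] < min_size)
    stopf("size_range must respect min_size")
  if (n_modules * size_range[1] > n_nodes ||
      n_modules * size_range[2] < n_nodes)
    stopf("size_range cannot cover n_nodes with %d modules", n_modules)
  with_seed(seed, {
    sizes <- draw_module_sizes(n_nodes, n_modules, size_range)
    module_of <- rep(seq_along(sizes), sizes)
    n_hubs <- round(hub_frac * n_nodes)
    alloc <- allocate_hubs(sizes, n_hubs)
    hubs <- unlist(lapply(seq_along(sizes), function(m) {
      members <- which(module_of == m)
      sort(pick(members, alloc[m]))
    }))
    W <- planted_network(n_nodes, module_of, hubs, p_intra, p_inter,
                         p_hub_hub, p_hub_out)

    target <- round(density * n_nodes * (n_nodes - 1) / 2)
    pairs <- upper_pairs(n_nodes)
    is_hub <- seq_len(n_nodes) %in% hubs
    adjustable <- module_of[pairs[, 1]] != module_of[pairs[, 2]] &
      !(is_hub[pairs[, 1]] & is_hub[pairs[, 2]])
    repeat {
      e <- sum(W) / 2
      if (e == target) break
      if (e > target) {
        cand <- which(adjustable & W[pairs] == 1L)
        if (length(cand) == 0) cand <- which(W[pairs] == 1L)
        flip <- 0L
      } else {
        cand <- which(adjustable & W[pairs] == 0L)
        if (length(cand) == 0) cand <- which(W[pairs] == 0L)
        flip <- 1L
      }
      take <- cand[sample.int(length(cand), min(length(cand),
                                                abs(e - target)))]
      sel <- pairs[take, , drop = FALSE]
      W[sel] <- flip
      W[sel[, c(2, 1), drop = FALSE]] <- flip
    }
    W <- connect_components(W)
    n_bridged <- attr(W, "n_bridged"); attr(W, "n_bridged") <- NULL
    if (abs(sum(W) / 2 / (n_nodes * (n_nodes - 1) / 2) - density) > 0.02)
      stopf("could not reach the target density")
    conn <- connectome(W)
    attr(conn, "n_bridged") <- n_bridged
    list(connectome = conn,
         partition = partition(module_of, hubs = hubs))
  })
}
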