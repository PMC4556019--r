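#' Node partition into functional modules, with a designated hub set
#'
#' @param module_of integer vector assigning each node (by index) to a
#'   module id; every node belongs to exactly one module.
#' @param hubs integer vector of node indices designated as hubs (may be
#'   empty); hubs typically span several modules.
#' @param n_nodes total node count; defaults to `length(module_of)`.
#' @return object of class `partition`: list with `module_of`, `modules`
#'   (named list of member index vectors), `module_ids`, `hubs`, `N`.
#' @examples
#' p <- partition(c(1, 1, 2, 2), hubs = c(1, 3))
#' module_members(p, 2)
#' @export
partition <- function(module_of, hubs = integer(), n_nodes = length(module_of)) {
  module_of <- as.integer(module_of)
  if (length(module_of) != n_nodes || anyNA(module_of))
    stopf("module_of must assign every node to a module")
  hubs <- sort(unique(as.integer(hubs)))
  if (length(hubs) && (min(hubs) < 1 || max(hubs) > n_nodes))
    stopf("hub indices must lie in 1..N")
  ids <- sort(unique(module_of))
  modules <- lapply(ids, function(a) which(module_of == a))
  names(modules) <- as.character(ids)
  structure(list(module_of = module_of, modules = modules,
                 module_ids = ids, hubs = hubs, N = n_nodes),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  sz <- vapply(x$modules, length, 0L)
  cat(sprintf("<partition> %d nodes, %d modules (sizes %s), %d hubs\n",
              x$N, length(x$modules), paste(sz, collapse = "/"),
              length(x$hubs)))
  invisible(x)
}

assert_partition <- function(x) {
  if (!inherits(x, "partition")) stopf("expected a 'partition' object")
  invisible(x)
}

#' Member node indices of a module
#' @param part a [partition()].
#' @param id module id.
#' @return integer vector of node indices.
#' @export
module_members <- function(part, id) {
  assert_partition(part)
  m <- part$modules[[as.character(id)]]
  if (is.null(m)) stopf("no module with id '%s'", id)
  m
}

#' Assign modules by majority vote
#'
#' Given a node-by-module table of nonnegative counts (e.g. how many of a
#' node's voxels fall inside each resting-state network map), assigns each
#' node to the module with the largest count. Ties are broken towards the
#' lowest module id (first column).
#'
#' @param vote_counts numeric matrix, nodes in rows, modules in columns;
#'   every node needs at least one positive count.
#' @param hubs optional hub index vector stored on the result.
#' @return a [partition()] with module ids 1..ncol(vote_counts).
#' @export
majority_vote_modules <- function(vote_counts, hubs = integer()) {
  m <- as.matrix(vote_counts)
  if (anyNA(m) || any(m < 0)) stopf("vote counts must be nonnegative")
  zero <- which(rowSums(m) == 0)
  if (length(zero))
    stopf("node(s) %s have all-zero vote counts", paste(zero, collapse = ", "))
  partition(max.col(m, ties.method = "first"), hubs = hubs, n_nodes = nrow(m))
}

#' Detect modules by modularity maximization
#'
#' Partitions the network into modules that maximize the number of
#' within-group edges relative to chance (Newman modularity), using
#' multi-restart Louvain optimization (best of `restarts` runs), then
#' enforces a minimum module size: any module smaller than `min_size` is
#' merged into the neighbouring module it shares the most edges with,
#' repeatedly, until all modules reach the minimum.
#'
#' @param conn a [connectome()].
#' @param min_size minimum nodes per module (default 8).
#' @param seed RNG seed for the restarts (Louvain's node order is random).
#' @param restarts optimization restarts, the best-modularity solution is
#'   kept (default 10).
#' @return a [partition()] with consecutively numbered modules.
#' @export
detect_modules <- function(conn, min_size = 8, seed = NULL, restarts = 10) {
  assert_connectome(conn)
  min_size <- as.integer(min_size)
  if (min_size < 1) stopf("min_size must be >= 1")
  if (min_size > conn$N) stopf("min_size exceeds the number of nodes")
  g <- igraph::graph_from_adjacency_matrix(conn$W, mode = "undirected")
  mem <- with_seed(seed, {
    best <- NULL; best_q <- -Inf
    for (i in seq_len(restarts)) {
      cl <- igraph::cluster_louvain(g)
      q <- igraph::modularity(cl)
      if (q > best_q) { best_q <- q; best <- cl }
    }
    as.integer(igraph::membership(best))
  })

  repeat {
    sizes <- table(mem)
    small <- as.integer(names(sizes)[sizes < min_size])
    if (length(small) == 0) break
    if (length(unique(mem)) == 1)
      stopf("cannot satisfy min_size = %d", min_size)
    a <- small[which.min(sizes[as.character(small)])]
    others <- setdiff(unique(mem), a)
    links <- vapply(others, function(b)
      sum(conn$W[mem == a, mem == b, drop = FALSE]), 0)
    target <- if (all(links == 0)) min(others) else others[which.max(links)]
    mem[mem == a] <- target
  }
  partition(match(mem, sort(unique(mem))), n_nodes = conn$N)
}

#' Agreement between two partitions
#'
#' Fraction of nodes whose labels agree under the best greedy one-to-one
#' matching of module ids (confusion-matrix matching, largest overlaps
#' first). 1 means identical partitions up to relabelling.
#'
#' @param a,b [partition()] objects or integer membership vectors.
#' @return agreement fraction in \[0, 1\].
#' @export
partition_agreement <- function(a, b) {
  ma <- if (inherits(a, "partition")) a$module_of else as.integer(a)
  mb <- if (inherits(b, "partition")) b$module_of else as.integer(b)
  if (length(ma) != length(mb)) stopf("partitions cover different node sets")
  tab <- table(ma, mb)
  matched <- 0
  while (length(tab) && any(tab > 0)) {
    ij <- which(tab == max(tab), arr.ind = TRUE)[1, , drop = TRUE]
    matched <- matched + tab[ij[1], ij[2]]
    tab <- tab[-ij[1], -ij[2], drop = FALSE]
  }
  as.numeric(matched) / length(ma)
}
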