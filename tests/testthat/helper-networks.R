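# small graph builders used across test files (all built in code, no fixtures)

conn_from_edges <- function(n, edges) {
  W <- matrix(0L, n, n)
  if (length(edges)) {
    e <- matrix(edges, ncol = 2, byrow = TRUE)
    W[e] <- 1L
    W[e[, c(2, 1), drop = FALSE]] <- 1L
  }
  connectome(W)
}

triangle_conn <- function() conn_from_edges(3, c(1, 2, 2, 3, 1, 3))

star_conn <- function(n_leaves = 4) {
  conn_from_edges(n_leaves + 1, as.vector(rbind(1, 1 + seq_len(n_leaves))))
}

path_conn <- function(n = 3) {
  conn_from_edges(n, as.vector(rbind(seq_len(n - 1), 2:n)))
}

complete_conn <- function(n) {
  W <- matrix(1L, n, n); diag(W) <- 0L
  connectome(W)
}

# two k-cliques optionally joined by a single bridge edge (node k -- k+1)
two_cliques <- function(k, bridge = TRUE) {
  W <- matrix(0L, 2 * k, 2 * k)
  W[1:k, 1:k] <- 1L
  W[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1L
  diag(W) <- 0L
  if (bridge) W[k, k + 1] <- W[k + 1, k] <- 1L
  connectome(W)
}

# the package-default synthetic rich-club world, generated once per test run
default_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_connectome(synth_spec())
    cache
  }
})

# short simulation protocol for tests that only need qualitative dynamics
fast_cfg <- function(seed = NULL, t_total = 150, t_transient = 50) {
  kuramoto_config(t_total = t_total, t_transient = t_transient, seed = seed)
}
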