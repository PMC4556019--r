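#' Binary structural connectome
#'
#' Wraps a symmetric binary adjacency matrix `W` describing anatomical
#' connections between brain regions. Entries must be 0/1, the diagonal all
#' zero (no self-loops) and the matrix symmetric (undirected connections).
#'
#' @param W square numeric/integer matrix of 0s and 1s.
#' @param labels optional character vector of node identifiers; defaults to
#'   existing `dimnames` or `"n1"..."nN"`.
#' @return an object of class `connectome`: a list with elements `W`
#'   (integer adjacency), `labels` and `N`.
#' @examples
#' W <- matrix(0L, 3, 3); W[1, 2] <- W[2, 1] <- 1L
#' conn <- connectome(W)
#' node_degrees(conn)
#' @export
connectome <- function(W, labels = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stopf("adjacency matrix must be square")
  n <- nrow(W)
  if (n < 2) stopf("a connectome needs at least 2 nodes")
  if (anyNA(W) || !all(W %in% c(0, 1)))
    stopf("adjacency entries must all be 0 or 1")
  if (any(diag(W) != 0)) stopf("diagonal must be zero (no self-loops)")
  if (!isTRUE(all.equal(W, t(W), check.attributes = FALSE)))
    stopf("adjacency matrix must be symmetric")
  labels <- labels %||% rownames(W) %||% paste0("n", seq_len(n))
  if (length(labels) != n) stopf("labels must have length N")
  storage.mode(W) <- "integer"
  dimnames(W) <- list(labels, labels)
  structure(list(W = W, labels = as.character(labels), N = n),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  e <- sum(x$W) / 2
  cat(sprintf("<connectome> %d nodes, %d edges (density %.3f)\n",
              x$N, e, e / choose(x$N, 2)))
  invisible(x)
}

is_connectome <- function(x) inherits(x, "connectome")

assert_connectome <- function(x) {
  if (!is_connectome(x)) stopf("expected a 'connectome' object")
  invisible(x)
}

#' Number of edges in a connectome
#' @param conn a [connectome()].
#' @return integer edge count (unordered pairs).
#' @export
n_edges <- function(conn) {
  assert_connectome(conn)
  as.integer(sum(conn$W) / 2)
}

#' Stack of subject-level connectivity matrices
#'
#' Holds per-subject binary adjacency matrices prior to group consensus
#' thresholding. All matrices must share dimensions and satisfy the
#' [connectome()] invariants.
#'
#' @param matrices list of N x N binary symmetric matrices (or `connectome`
#'   objects).
#' @return object of class `subject_stack` with elements `matrices`
#'   (list of integer matrices), `S` (subject count) and `N`.
#' @export
subject_stack <- function(matrices) {
  if (length(matrices) == 0) stopf("subject stack is empty")
  mats <- lapply(matrices, function(m) {
    if (is_connectome(m)) m$W else connectome(m)$W
  })
  n <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, 0L) == n))
    stopf("all subject matrices must have the same number of nodes")
  structure(list(matrices = mats, S = length(mats), N = n),
            class = "subject_stack")
}

#' Group consensus connectome
#'
#' Builds the binary group matrix from a stack of subject-level matrices:
#' a connection is kept when it is present in at least `frac` of the
#' subjects (inclusive threshold).
#'
#' @param stack a [subject_stack()].
#' @param frac minimum fraction of subjects, in (0, 1]; default 0.4.
#' @return a [connectome()].
#' @export
consensus_matrix <- function(stack, frac = 0.4) {
  if (!inherits(stack, "subject_stack")) stack <- subject_stack(stack)
  if (!is.numeric(frac) || length(frac) != 1 || frac <= 0 || frac > 1)
    stopf("frac must be a single value in (0, 1]")
  count <- Reduce(`+`, stack$matrices)
  W <- (count / stack$S >= frac) * 1L
  diag(W) <- 0L
  connectome(W)
}

#' Node degrees
#'
#' @param conn a [connectome()].
#' @return named integer vector of node degrees (number of connections).
#' @export
node_degrees <- function(conn) {
  assert_connectome(conn)
  d <- rowSums(conn$W)
  storage.mode(d) <- "integer"
  names(d) <- conn$labels
  d
}

#' Select hub nodes by degree
#'
#' Returns the `n_hubs` nodes with the highest number of connections. Ties
#' at the degree cutoff are broken deterministically by node index
#' (ascending), so the selection is reproducible and nested:
#' `select_hubs(conn, a)` is a subset of `select_hubs(conn, b)` for a <= b.
#'
#' @param conn a [connectome()].
#' @param n_hubs number of hubs, between 1 and N.
#' @return sorted integer vector of node indices.
#' @export
select_hubs <- function(conn, n_hubs) {
  assert_connectome(conn)
  n_hubs <- as.integer(n_hubs)
  if (n_hubs < 1 || n_hubs > conn$N)
    stopf("n_hubs must be between 1 and N = %d", conn$N)
  d <- node_degrees(conn)
  ord <- order(-d, seq_len(conn$N))
  sort(ord[seq_len(n_hubs)])
}

#' Normalized rich-club coefficient
#'
#' For each degree threshold `k`, computes the edge density phi(k) among the
#' nodes of degree > k and normalizes it by the mean of the same quantity
#' over `n_null` degree-preserving rewired null networks (double-edge swaps,
#' `10 * E` swap attempts per null). Normalized values above 1 indicate
#' rich-club organization: hubs are more densely interconnected than
#' expected from the degree sequence alone.
#'
#' @param conn a [connectome()].
#' @param k integer vector of degree thresholds; defaults to every degree
#'   value present in the network except the maximum.
#' @param n_null number of null networks (>= 1).
#' @param seed RNG seed for the null ensemble.
#' @return data.frame with columns `k`, `phi` (raw density), `phi_null`
#'   (mean null density) and `phi_norm` (normalized coefficient). Rows where
#'   fewer than 2 nodes survive the threshold, or the null density is zero,
#'   carry `NA` ("not evaluable").
#' @export
rich_club_coefficient <- function(conn, k = NULL, n_null = 100, seed = NULL) {
  assert_connectome(conn)
  if (n_null < 1) stopf("n_null must be >= 1")
  d <- node_degrees(conn)
  if (is.null(k)) {
    ks <- sort(unique(d))
    k <- ks[ks < max(ks)]
    if (length(k) == 0) k <- max(ks) - 1L
  }
  k <- as.integer(k)

  phi_of <- function(W, deg) {
    vapply(k, function(kk) {
      keep <- which(deg > kk)
      m <- length(keep)
      if (m < 2) return(NA_real_)
      sum(W[keep, keep]) / (m * (m - 1))
    }, 0)
  }

  phi <- phi_of(conn$W, d)
  g <- igraph::graph_from_adjacency_matrix(conn$W, mode = "undirected")
  n_swap <- 10 * n_edges(conn)
  null_phi <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swap))
      Wr <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
      phi_of(Wr, d) # degree sequence preserved by construction
    }, numeric(length(k)))
  })
  null_mean <- if (length(k) == 1) mean(null_phi) else rowMeans(null_phi)
  norm <- ifelse(is.na(phi) | is.na(null_mean) | null_mean == 0,
                 NA_real_, phi / null_mean)
  data.frame(k = k, phi = phi, phi_null = null_mean, phi_norm = norm)
}
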