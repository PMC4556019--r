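# File conventions: node indices are 0-based in all files, undirected
# edges listed once with i < j, '#' starts a comment line.

read_clean_lines <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  if (length(ln) == 0) stopf("%s: no data lines", path)
  ln
}

#' Read a binary adjacency matrix
#'
#' Accepts either a whitespace-delimited N x N 0/1 matrix or a 2-column
#' edge list (0-based node indices, one undirected edge per line). With
#' `format = "auto"` a square token layout is read as a matrix, a 2-column
#' layout as an edge list.
#'
#' @param path input file.
#' @param format `"auto"`, `"matrix"` or `"edges"`.
#' @param n_nodes node count, required for edge lists that do not mention
#'   the highest-index node.
#' @return a [connectome()]; invalid input fails loudly.
#' @export
read_adjacency <- function(path, format = c("auto", "matrix", "edges"),
                           n_nodes = NULL) {
  format <- match.arg(format)
  ln <- read_clean_lines(path)
  toks <- strsplit(trimws(ln), "\\s+")
  ncols <- unique(lengths(toks))
  if (format == "auto") {
    format <- if (length(ncols) == 1 && ncols == length(ln)) "matrix"
      else if (length(ncols) == 1 && ncols == 2) "edges"
      else stopf("%s: cannot infer format (rows of %s fields)", path,
                 paste(ncols, collapse = "/"))
  }
  if (format == "matrix") {
    if (length(ncols) != 1 || ncols != length(ln))
      stopf("%s: not a square matrix", path)
    W <- do.call(rbind, lapply(toks, as.numeric))
    if (anyNA(W)) stopf("%s: non-numeric entries", path)
    connectome(W)
  } else {
    if (length(ncols) != 1 || ncols != 2)
      stopf("%s: edge list must have exactly 2 columns", path)
    e <- do.call(rbind, lapply(toks, as.integer)) + 1L
    if (anyNA(e) || any(e < 1)) stopf("%s: bad node indices", path)
    n <- n_nodes %||% max(e)
    if (max(e) > n) stopf("%s: node index exceeds n_nodes", path)
    if (any(e[, 1] == e[, 2])) stopf("%s: self-loop in edge list", path)
    W <- matrix(0L, n, n)
    W[e] <- 1L
    W[e[, c(2, 1), drop = FALSE]] <- 1L
    connectome(W)
  }
}

#' Write a binary adjacency matrix
#'
#' @param conn a [connectome()].
#' @param path output file.
#' @param format `"matrix"` (N x N 0/1 table) or `"edges"` (2-column
#'   0-based edge list, i < j).
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(conn, path, format = c("matrix", "edges")) {
  assert_connectome(conn)
  format <- match.arg(format)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# hubsync adjacency (%s, 0-based indices)", format),
             con)
  if (format == "matrix") {
    write.table(conn$W, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else {
    pairs <- upper_pairs(conn$N)
    e <- pairs[conn$W[pairs] == 1L, , drop = FALSE] - 1L
    write.table(e, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Validate an adjacency file
#'
#' Parses `path` as an N x N matrix and checks squareness, binarity,
#' zero diagonal and symmetry, reporting every violation with its
#' coordinates (0-based, matching the file convention).
#'
#' @param path input file.
#' @return list with `ok` (logical), `connectome` (or `NULL`), and
#'   `diagnostics` (character vector of violations).
#' @export
validate_adjacency <- function(path) {
  diag_msgs <- character()
  ln <- read_clean_lines(path)
  toks <- strsplit(trimws(ln), "\\s+")
  if (length(unique(lengths(toks))) != 1 ||
      lengths(toks)[1] != length(ln)) {
    return(list(ok = FALSE, connectome = NULL,
                diagnostics = sprintf("%s: not a square matrix", path)))
  }
  W <- do.call(rbind, lapply(toks, as.numeric))
  n <- nrow(W)
  bad <- which(is.na(W) | !(W %in% c(0, 1)), arr.ind = TRUE)
  for (r in seq_len(nrow(bad)))
    diag_msgs <- c(diag_msgs,
                   sprintf("non-binary value %s at (%d,%d)",
                           format(W[bad[r, 1], bad[r, 2]]),
                           bad[r, 1] - 1L, bad[r, 2] - 1L))
  dg <- which(diag(W) != 0)
  for (i in dg)
    diag_msgs <- c(diag_msgs, sprintf("nonzero diagonal at (%d,%d)",
                                      i - 1L, i - 1L))
  asym <- which(W != t(W) & upper.tri(W), arr.ind = TRUE)
  for (r in seq_len(nrow(asym)))
    diag_msgs <- c(diag_msgs,
                   sprintf("asymmetric pair (%d,%d)",
                           asym[r, 1] - 1L, asym[r, 2] - 1L))
  if (length(diag_msgs))
    return(list(ok = FALSE, connectome = NULL, diagnostics = diag_msgs))
  list(ok = TRUE, connectome = connectome(W), diagnostics = character())
}

#' Read / write a node-to-module partition table
#'
#' TSV with header columns `node_id` (0-based) and `module_id`; the hub
#' set travels in a separate one-id-per-line file.
#'
#' @param path input/output file.
#' @param hubs_path optional hub-list file read alongside the partition.
#' @return `read_partition`: a [partition()].
#' @export
read_partition <- function(path, hubs_path = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("node_id", "module_id") %in% names(df)))
    stopf("%s: need columns node_id and module_id", path)
  n <- nrow(df)
  if (!setequal(df$node_id, 0:(n - 1)))
    stopf("%s: node_id must cover 0..N-1 exactly once", path)
  module_of <- integer(n)
  module_of[df$node_id + 1L] <- as.integer(df$module_id)
  hubs <- if (is.null(hubs_path)) integer() else read_hubs(hubs_path)
  partition(module_of, hubs = hubs)
}

#' @rdname read_partition
#' @param part a [partition()].
#' @export
write_partition <- function(part, path) {
  assert_partition(part)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# hubsync partition (0-based node ids)", con)
  write.table(data.frame(node_id = seq_len(part$N) - 1L,
                         module_id = part$module_of),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_partition
#' @export
read_hubs <- function(path) {
  ln <- read_clean_lines(path)
  h <- as.integer(ln)
  if (anyNA(h) || any(h < 0)) stopf("%s: bad hub ids", path)
  sort(h) + 1L
}

#' @rdname read_partition
#' @param hubs integer hub index vector (1-based in memory; written
#'   0-based).
#' @export
write_hubs <- function(hubs, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# hubsync hub set (0-based node ids)", con)
  writeLines(as.character(sort(as.integer(hubs)) - 1L), con)
  invisible(path)
}

#' End-to-end pipeline run
#'
#' Orchestrates one condition of the analysis from files (or a generated
#' synthetic network) to per-coupling output tables: loads/creates the
#' connectome, partition and hub set, applies the condition
#' (hub/random edge suppression or frequency perturbation), runs the
#' coupling sweep, and writes TSV outputs plus a manifest of file
#' checksums. Reruns with identical configuration reproduce identical
#' files.
#'
#' @param out_dir output directory (created if missing).
#' @param adjacency,partition_file,hubs_file input paths; when `adjacency`
#'   is `NULL` a synthetic network from `spec` is generated and written
#'   alongside the outputs.
#' @param spec a [synth_spec()] used when no adjacency is given.
#' @param condition one of `"normal"`, `"hub_suppressed"`,
#'   `"random_suppressed"`, `"perturbed_hubs"`.
#' @param lambda_grid coupling strengths (default `seq(0.005, 0.075,
#'   by = 0.005)`, covering the transition regime).
#' @param n_trials trials per coupling.
#' @param cfg a [kuramoto_config()].
#' @param base_seed integer seed anchoring all randomness.
#' @return invisibly, a list with the `sweep_record` and the manifest
#'   data.frame (`file`, `md5`).
#' @export
run_pipeline <- function(out_dir, adjacency = NULL, partition_file = NULL,
                         hubs_file = NULL, spec = synth_spec(),
                         condition = c("normal", "hub_suppressed",
                                       "random_suppressed",
                                       "perturbed_hubs"),
                         lambda_grid = seq(0.005, 0.075, by = 0.005),
                         n_trials = 10, cfg = kuramoto_config(),
                         base_seed = 1) {
  condition <- match.arg(condition)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()

  if (is.null(adjacency)) {
    net <- generate_connectome(spec)
    conn <- net$connectome
    part <- net$partition
    write_adjacency(conn, file.path(out_dir, "adjacency.tsv"))
    write_partition(part, file.path(out_dir, "partition.tsv"))
    write_hubs(part$hubs, file.path(out_dir, "hubs.txt"))
    written <- c(written, file.path(out_dir, c("adjacency.tsv",
                                               "partition.tsv",
                                               "hubs.txt")))
  } else {
    if (is.null(partition_file)) stopf("missing partition file")
    conn <- read_adjacency(adjacency)
    part <- read_partition(partition_file, hubs_path = hubs_file)
    if (part$N != conn$N) stopf("partition does not match the network size")
  }

  omega_transform <- NULL
  run_conn <- conn
  message(sprintf("[hubsync] condition '%s': N = %d, %d edges", condition,
                  conn$N, n_edges(conn)))
  if (condition == "hub_suppressed") {
    run_conn <- suppress_edges(conn, part$hubs)
    message(sprintf("[hubsync] removed %d hub-hub edges",
                    attr(run_conn, "n_removed")))
  } else if (condition == "random_suppressed") {
    hub_sup <- suppress_edges(conn, part$hubs)
    run_conn <- suppress_random_edges(conn, attr(hub_sup, "n_removed"),
                                      seed = base_seed)
    message(sprintf("[hubsync] removed %d random edges",
                    attr(run_conn, "n_removed")))
  } else if (condition == "perturbed_hubs") {
    omega_transform <- function(om) perturb_frequencies(om, part$hubs)
  }

  rec <- run_sweep(run_conn, part, lambda_grid, n_trials = n_trials,
                   cfg = cfg, base_seed = base_seed, condition = condition)

  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    con <- file(p, "w"); on.exit(close(con))
    writeLines(sprintf("# hubsync %s | condition=%s seed=%d n_trials=%d",
                       name, condition, base_seed, n_trials), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  written <- c(written,
               tsv(rec$summary, "sweep_summary.tsv"),
               tsv(rec$modular, "modular_synchrony.tsv"),
               tsv(rec$trial_metrics, "trial_metrics.tsv"),
               tsv(modularity_ratio(rec), "modularity_ratio.tsv"))
  for (lam in names(rec$r_ij)) {
    p <- file.path(out_dir, sprintf("r_ij_lambda_%s.tsv", lam))
    con <- file(p, "w")
    writeLines(sprintf("# hubsync r_ij at lambda=%s", lam), con)
    write.table(rec$r_ij[[lam]], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    close(con)
    written <- c(written, p)
  }

  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("[hubsync] wrote %d files to %s", nrow(manifest), out_dir))
  invisible(list(record = rec, manifest = manifest))
}
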