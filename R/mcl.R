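#' Column-normalise a non-negative matrix
#'
#' Rescales every column to sum to 1, producing a column-stochastic matrix.
#' This is the elementary step of the Markov Cluster algorithm: columns are
#' interpreted as the transition probabilities of a random walk leaving each
#' node.
#'
#' @param m A numeric matrix or sparse `Matrix` with non-negative entries and
#'   no all-zero column.
#' @return A matrix of the same class with all column sums equal to 1
#'   (within 1e-12).
#' @examples
#' column_normalize(matrix(c(2, 2, 1, 3), 2))
#' @export
column_normalize <- function(m) {
  if (any(m < 0)) stop("matrix has negative entries")
  cs <- Matrix::colSums(m)
  if (any(cs == 0)) stop("matrix has an all-zero column")
  if (inherits(m, "sparseMatrix")) {
    m %*% Matrix::Diagonal(ncol(m), 1 / cs)
  } else {
    sweep(m, 2, cs, "/")
  }
}

# Coerce edge-list / dense / sparse input into a symmetric sparse adjacency
# matrix with character dimnames. Edge lists are 3-column (node_a, node_b,
# weight) data frames, the on-disk graph dialect.
as_adjacency <- function(graph) {
  if (is.data.frame(graph)) {
    stopifnot(ncol(graph) >= 3)
    nodes <- sort(unique(c(as.character(graph[[1]]), as.character(graph[[2]]))))
    i <- match(as.character(graph[[1]]), nodes)
    j <- match(as.character(graph[[2]]), nodes)
    w <- as.numeric(graph[[3]])
    adj <- Matrix::sparseMatrix(
      i = c(i, j), j = c(j, i), x = c(w, w),
      dims = c(length(nodes), length(nodes)),
      dimnames = list(nodes, nodes), use.last.ij = TRUE
    )
    return(adj)
  }
  if (is.matrix(graph)) graph <- Matrix::Matrix(graph, sparse = TRUE)
  # symmetric storage keeps only one triangle; expand to general form so
  # per-column scans see every entry
  if (inherits(graph, "symmetricMatrix") || inherits(graph, "triangularMatrix")) {
    graph <- methods::as(graph, "generalMatrix")
  }
  if (!inherits(graph, "CsparseMatrix")) {
    graph <- methods::as(graph, "CsparseMatrix")
  }
  if (is.null(rownames(graph))) {
    dimnames(graph) <- list(as.character(seq_len(nrow(graph))),
                            as.character(seq_len(ncol(graph))))
  }
  graph
}

#' Markov clustering (MCL) of a weighted undirected graph
#'
#' Runs the Markov Cluster algorithm: the column-normalised adjacency matrix
#' is alternately expanded (matrix power) and inflated (entrywise power
#' followed by renormalisation) until the flow matrix converges to an
#' attractor structure, whose basins are read off as clusters. Used both for
#' ortholog grouping on similarity graphs and for expression-profile
#' clustering on |Pearson r| graphs.
#'
#' Nodes with no incident edge in the input graph are reported in
#' `unclustered` rather than as singleton clusters. Ties in attraction are
#' broken deterministically: a node attracted to several attractor systems is
#' assigned to the system containing the lexicographically smallest attractor
#' node.
#'
#' @param graph A symmetric non-negative adjacency matrix (dense or sparse,
#'   with dimnames), or a 3-column data frame (node_a, node_b, weight).
#' @param inflation Inflation exponent (> 1). Larger values give finer
#'   clusters. Default 2.
#' @param expansion Integer matrix-power used for expansion (>= 2). Default 2.
#' @param self_loops If `TRUE` (default), each node receives a self-loop with
#'   weight equal to its maximum incident edge weight before clustering.
#' @param prune_threshold Entries below this value are zeroed after each
#'   inflation to keep the flow matrix sparse. Default 1e-5.
#' @param max_iter Maximum number of expansion/inflation iterations.
#' @param tol Convergence tolerance on the maximum absolute entry change.
#' @return An object of class `cluster_set`: a list with `clusters` (list of
#'   character vectors, ordered by decreasing size then smallest member) and
#'   `unclustered` (character vector of isolated nodes).
#' @examples
#' g <- data.frame(
#'   a = c("a1", "a1", "a2", "b1", "b1", "b2"),
#'   b = c("a2", "a3", "a3", "b2", "b3", "b3"),
#'   w = 1
#' )
#' mcl(g)$clusters
#' @export
mcl <- function(graph, inflation = 2, expansion = 2, self_loops = TRUE,
                prune_threshold = 1e-5, max_iter = 200, tol = 1e-6) {
  adj <- as_adjacency(graph)
  if (nrow(adj) == 0L) stop("graph is empty")
  if (inflation <= 1) stop("inflation must be > 1")
  if (expansion < 2) stop("expansion must be >= 2")
  if (!Matrix::isSymmetric(adj, tol = 1e-8)) stop("graph must be symmetric")
  if (any(adj@x < 0)) stop("graph has negative edge weights")
  nodes <- rownames(adj)
  Matrix::diag(adj) <- 0
  adj <- Matrix::drop0(adj)

  deg <- Matrix::colSums(adj > 0)
  isolated <- nodes[deg == 0]
  keep <- nodes[deg > 0]
  if (length(keep) == 0L) {
    return(new_cluster_set(list(), unclustered = isolated))
  }
  m <- adj[keep, keep, drop = FALSE]
  if (self_loops) {
    loop <- apply_max_col(m)
    Matrix::diag(m) <- loop
  } else {
    # zero diagonal with no self loop can starve a column; keep a minimal loop
    Matrix::diag(m) <- pmax(apply_max_col(m) * 0, 1e-12)
  }
  m <- column_normalize(m)

  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m2 <- m
    for (e in seq_len(expansion - 1L)) m2 <- m2 %*% m
    m2@x <- m2@x^inflation
    m2 <- column_normalize(m2)
    m2@x[m2@x < prune_threshold] <- 0
    m2 <- Matrix::drop0(m2)
    m2 <- column_normalize(m2)
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter,
            " iterations; returning clusters from current state")
  }
  labels <- mcl_read_clusters(m)
  clusters <- split(keep, labels)
  new_cluster_set(unname(clusters), unclustered = isolated)
}

# maximum off-diagonal entry per column of a sparse symmetric matrix
apply_max_col <- function(m) {
  s <- Matrix::summary(m)
  s <- s[s$i != s$j, , drop = FALSE]
  out <- numeric(ncol(m))
  if (nrow(s)) {
    agg <- tapply(s$x, s$j, max)
    out[as.integer(names(agg))] <- agg
  }
  out
}

# Read clusters off a converged MCL flow matrix. Attractors are nodes with
# positive return flow (positive diagonal); attractor systems are connected
# components of the symmetrised flow restricted to attractors; every node is
# assigned to the system of the lexicographically smallest attractor it flows
# to.
mcl_read_clusters <- function(m) {
  n <- ncol(m)
  nodes <- rownames(m)
  attractors <- which(Matrix::diag(m) > 0)
  if (length(attractors) == 0L) attractors <- seq_len(n)
  # components among attractors on symmetrised support
  s <- (m + Matrix::t(m))[attractors, attractors, drop = FALSE]
  comp <- components_sparse(s > 0)
  # canonical system id = lexicographically smallest attractor node name
  sys_name <- tapply(nodes[attractors], comp, function(x) min(x))
  comp_of_attr <- stats::setNames(as.character(sys_name[as.character(comp)]),
                                  nodes[attractors])
  labels <- character(n)
  supp <- Matrix::summary(m)
  flows_to <- split(supp$i, supp$j) # column j flows to rows i
  attr_set <- attractors
  for (j in seq_len(n)) {
    tgt <- intersect(flows_to[[as.character(j)]], attr_set)
    if (length(tgt) == 0L) {
      # no attractor reached (fully pruned column): keep node on its own
      labels[j] <- nodes[j]
    } else {
      labels[j] <- min(comp_of_attr[nodes[tgt]])
    }
  }
  labels
}

# connected components of a symmetric sparse pattern matrix via label
# propagation; returns integer component labels
components_sparse <- function(s) {
  n <- ncol(s)
  lab <- seq_len(n)
  idx <- Matrix::summary(s)
  if (nrow(idx) == 0) return(lab)
  repeat {
    mins <- tapply(lab[idx$i], idx$j, min)
    new <- pmin(lab, mins[as.character(seq_len(n))], na.rm = TRUE)
    # two-hop: also pull column minima back through rows
    mins2 <- tapply(new[idx$j], idx$i, min)
    new <- pmin(new, mins2[as.character(seq_len(n))], na.rm = TRUE)
    if (identical(new, lab)) break
    lab <- new
  }
  match(lab, sort(unique(lab)))
}

#' Construct a cluster-set object
#'
#' @param clusters List of disjoint non-empty character vectors of node ids.
#' @param unclustered Character vector of nodes outside all clusters.
#' @return An object of class `cluster_set`; clusters are sorted internally
#'   and ordered by decreasing size, ties broken by smallest member id.
#' @export
new_cluster_set <- function(clusters, unclustered = character()) {
  clusters <- lapply(clusters, function(x) sort(as.character(x)))
  if (any(lengths(clusters) == 0L)) stop("empty cluster")
  all_members <- unlist(clusters)
  if (anyDuplicated(all_members)) stop("clusters are not disjoint")
  ord <- order(-lengths(clusters),
               vapply(clusters, function(x) x[1], character(1)))
  structure(
    list(clusters = clusters[ord], unclustered = sort(as.character(unclustered))),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters,",
      sum(lengths(x$clusters)), "nodes clustered,",
      length(x$unclustered), "unclustered\n")
  invisible(x)
}

#' Cluster membership as a named vector
#'
#' @param cs A `cluster_set`.
#' @return Named integer vector mapping each clustered node to its cluster
#'   index (1 = largest cluster); unclustered nodes are absent.
#' @export
cluster_labels <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  labs <- rep(seq_along(cs$clusters), lengths(cs$clusters))
  stats::setNames(labs, unlist(cs$clusters))
}

#' Read / write the 3-column graph dialect
#'
#' Weighted undirected graphs are exchanged as TSV with columns
#' node_a, node_b, weight (one line per undirected edge).
#'
#' @param path File path.
#' @return `read_graph_tsv` returns the edge data frame.
#' @export
read_graph_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("node_a", "node_b", "weight")
  df
}

#' @param edges 3-column edge data frame (node_a, node_b, weight).
#' @rdname read_graph_tsv
#' @export
write_graph_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cluster set as a two-column TSV (node, cluster_id)
#'
#' @param cs A `cluster_set`.
#' @param path File path. Unclustered nodes are written with cluster_id 0.
#' @export
write_cluster_tsv <- function(cs, path) {
  lab <- cluster_labels(cs)
  df <- data.frame(
    node = c(names(lab), cs$unclustered),
    cluster_id = c(unname(lab), rep(0L, length(cs$unclustered)))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
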