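#' Expression matrix with sample metadata
#'
#' Couples a genes x samples abundance matrix (RPKM or counts) with a sample
#' metadata table carrying the seed-development stage, stage order,
#' replicate, and accession of every library.
#'
#' @param values Numeric genes x samples matrix, non-negative, with row and
#'   column names.
#' @param sample_meta Data frame with columns sample_id, stage, stage_order,
#'   replicate, accession; one row per column of `values`.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, sample_meta) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (any(values < 0)) stop("abundance values must be non-negative")
  need <- c("sample_id", "stage", "stage_order", "replicate", "accession")
  if (!all(need %in% names(sample_meta))) {
    stop("sample_meta needs columns: ", paste(need, collapse = ", "))
  }
  if (!setequal(colnames(values), sample_meta$sample_id) ||
      anyDuplicated(sample_meta$sample_id)) {
    stop("sample_meta rows must match matrix columns one-to-one")
  }
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ]
  rownames(sample_meta) <- NULL
  structure(list(values = values, sample_meta = sample_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples (",
      length(unique(x$sample_meta$stage)), "stages,",
      length(unique(x$sample_meta$accession)), "accession(s) )\n")
  invisible(x)
}

#' Read / write an expression matrix with its metadata sidecar
#'
#' The matrix is a TSV of genes x samples (first column gene ids); the
#' sidecar is a TSV with columns sample_id, stage, stage_order, replicate,
#' accession.
#'
#' @param values_path,meta_path File paths.
#' @return `read_expression` returns an `expr_matrix`.
#' @export
read_expression <- function(values_path, meta_path) {
  v <- utils::read.table(values_path, header = TRUE, sep = "\t",
                         row.names = 1, check.names = FALSE)
  m <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  expression_matrix(as.matrix(v), m)
}

#' @param em An `expr_matrix`.
#' @rdname read_expression
#' @export
write_expression <- function(em, values_path, meta_path) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(em$sample_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(values_path)
}

#' Reads Per Kilobase per Million mapped reads
#'
#' RPKM = 1e9 * count / (gene_length * library_size). Linear in counts and
#' invariant under simultaneous scaling of counts and library size.
#'
#' @param count Non-negative read count (vectorised).
#' @param gene_length Gene model length in bp (> 0).
#' @param library_size Total mapped reads in the library (> 0).
#' @return Numeric RPKM values.
#' @examples
#' rpkm(10, 1000, 1e6) # 10
#' @export
rpkm <- function(count, gene_length, library_size) {
  if (any(gene_length <= 0)) stop("gene_length must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  if (any(count < 0)) stop("count must be non-negative")
  1e9 * count / (gene_length * library_size)
}

#' Per-stage mean profiles (replicates averaged)
#'
#' @param em An `expr_matrix`.
#' @param log2p1 If `TRUE`, profiles are log2(abundance + 1) before
#'   averaging replicates (the default scale for clustering).
#' @param accession Optionally restrict to one accession.
#' @return Genes x stages matrix, columns ordered by stage_order and named
#'   by stage label.
#' @export
stage_profiles <- function(em, log2p1 = FALSE, accession = NULL) {
  meta <- em$sample_meta
  v <- em$values
  if (!is.null(accession)) {
    sel <- meta$accession == accession
    meta <- meta[sel, ]
    v <- v[, sel, drop = FALSE]
  }
  if (log2p1) v <- log2(v + 1)
  stages <- unique(meta[order(meta$stage_order), c("stage", "stage_order")])
  prof <- vapply(stages$stage, function(s) {
    rowMeans(v[, meta$stage == s, drop = FALSE])
  }, numeric(nrow(v)))
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = nrow(v))
  dimnames(prof) <- list(rownames(v), stages$stage)
  prof
}

#' Expressed-gene filter
#'
#' A gene is called expressed when its abundance reaches `min_rpkm` in at
#' least one stage; with `require_both_replicates` (the default) the
#' threshold must be met by every replicate of that stage.
#'
#' @param em An `expr_matrix`.
#' @param min_rpkm Abundance threshold (default 1).
#' @param require_both_replicates Require all replicates of the qualifying
#'   stage to pass (default `TRUE`).
#' @return Character vector of expressed gene ids.
#' @export
expressed_filter <- function(em, min_rpkm = 1, require_both_replicates = TRUE) {
  meta <- em$sample_meta
  v <- em$values
  key <- paste(meta$accession, meta$stage, sep = "\r")
  pass_stage <- vapply(unique(key), function(k) {
    cols <- v[, key == k, drop = FALSE] >= min_rpkm
    if (require_both_replicates) apply(cols, 1, all) else apply(cols, 1, any)
  }, logical(nrow(v)))
  if (is.null(dim(pass_stage))) pass_stage <- matrix(pass_stage, nrow = nrow(v))
  rownames(v)[apply(pass_stage, 1, any)]
}

#' Up-regulation call over a stage window
#'
#' A gene is up-regulated when its maximum per-stage mean inside the window
#' is at least `fold` times its mean over ALL stages. `fold = 1` is the
#' "higher than average" rule; `fold = 2` the "twice average" rule. The
#' called set is monotone decreasing in `fold`.
#'
#' @param profiles Genes x stages matrix of per-stage means (see
#'   [stage_profiles()]).
#' @param window Stage names or column indices defining the window.
#' @param fold Fold threshold (>= comparison), default 1.
#' @return Named logical vector per gene.
#' @export
upregulated <- function(profiles, window, fold = 1) {
  if (length(window) == 0L) stop("empty stage window")
  if (is.character(window) && !all(window %in% colnames(profiles))) {
    stop("window stages not in profile columns")
  }
  w <- profiles[, window, drop = FALSE]
  apply(w, 1, max) >= fold * rowMeans(profiles)
}

#' Absolute-correlation co-expression graph
#'
#' Edges connect gene pairs whose absolute Pearson correlation across the
#' stage profile strictly exceeds the threshold; the edge weight is |r|.
#' Constant profiles are excluded with a warning (their correlation is
#' undefined).
#'
#' @param profiles Genes x stages matrix (>= 3 stages).
#' @param threshold Absolute-correlation threshold, strict (default 0.7).
#' @return Sparse symmetric adjacency matrix over the non-constant genes.
#' @export
correlation_graph <- function(profiles, threshold = 0.7) {
  if (ncol(profiles) < 3) stop("need >= 3 stages")
  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant profile(s) excluded from the graph")
    profiles <- profiles[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(profiles))
  w <- abs(r)
  w[w <= threshold] <- 0
  diag(w) <- 0
  Matrix::Matrix(w, sparse = TRUE)
}

#' Cluster expression profiles with MCL
#'
#' Builds the |r| > threshold graph on per-stage mean profiles and clusters
#' it with MCL. Genes left out of the graph (constant profiles or no edge
#' above threshold) are reported as unclustered, mirroring the handful of
#' genes that fall outside the main clusters in seed-transcriptome data.
#'
#' @param profiles Genes x stages matrix (typically log2(RPKM + 1) stage
#'   means).
#' @param threshold Absolute-correlation edge threshold (default 0.7).
#' @param inflation MCL inflation (default 2).
#' @param ... Further arguments to [mcl()].
#' @return List with `clusters` (a `cluster_set`), `labels` (named integer
#'   vector), and `profiles` (cluster x stage matrix of mean profiles,
#'   rows ordered as the clusters).
#' @export
cluster_expression <- function(profiles, threshold = 0.7, inflation = 2, ...) {
  g <- correlation_graph(profiles, threshold)
  cs <- mcl(g, inflation = inflation, ...)
  # genes dropped before graph construction count as unclustered too
  dropped <- setdiff(rownames(profiles), c(unlist(cs$clusters), cs$unclustered))
  cs <- new_cluster_set(cs$clusters, unclustered = c(cs$unclustered, dropped))
  lab <- cluster_labels(cs)
  cl_prof <- t(vapply(cs$clusters, function(g) {
    colMeans(profiles[g, , drop = FALSE])
  }, numeric(ncol(profiles))))
  rownames(cl_prof) <- paste0("cluster", seq_along(cs$clusters))
  list(clusters = cs, labels = lab, profiles = cl_prof)
}

#' Average-linkage hierarchical clustering of samples
#'
#' Samples are clustered on the distance 1 - r between their log2(x + 1)
#' expression vectors (Pearson r), with average linkage. Used to ask whether
#' accessions separate before developmental stages.
#'
#' @param values Genes x samples matrix (abundance scale), or an
#'   `expr_matrix`.
#' @param log2p1 Apply log2(x + 1) first (default `TRUE`).
#' @return An object of class `hclust`.
#' @export
sample_hclust <- function(values, log2p1 = TRUE) {
  if (inherits(values, "expr_matrix")) values <- values$values
  if (ncol(values) < 2) stop("need >= 2 samples")
  v <- if (log2p1) log2(values + 1) else values
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant sample vector(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(v))
  stats::hclust(d, method = "average")
}

#' Serialise a sample dendrogram as newick
#'
#' @param hc An `hclust` object.
#' @return A newick string (with merge heights as branch lengths).
#' @export
hclust_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
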