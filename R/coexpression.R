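#' Pearson product-moment correlation of two profiles
#'
#' @param x,y Numeric vectors of equal length >= 3; neither constant.
#' @return The correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 3) stop("need >= 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant profile")
  }
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Standard test of zero correlation: t = |r| sqrt((n-2)/(1-r^2)) referred
#' to a t distribution with n - 2 degrees of freedom, two-sided. The
#' p-value is 1 at r = 0, 0 at |r| = 1, and strictly decreasing in |r|.
#'
#' @param r Correlation coefficient(s), |r| <= 1.
#' @param n Number of points the correlation was computed from (>= 3).
#' @return Two-sided p-value(s) in (0, 1].
#' @examples
#' corr_pvalue(0.9728, 8) # ~ 4.93e-5
#' @export
corr_pvalue <- function(r, n) {
  if (any(n < 3)) stop("n must be >= 3")
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) == 1, 0,
              2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2))
  pmin(p, 1)
}

#' All significant co-expression edges between two gene sets
#'
#' Computes Pearson r between every query gene and every target gene over
#' their stage profiles, with the two-sided t-test p-value. Significance is
#' sign-agnostic: strongly negative correlations count. Self-pairs are
#' excluded; constant profiles are dropped with a warning.
#'
#' @param profiles Genes x stages matrix covering both gene sets.
#' @param query,targets Character vectors of gene ids (rows of `profiles`).
#' @param p_thresh Keep edges with p < `p_thresh` (default 1, i.e. all).
#' @return Data frame gene_a (query), gene_b (target), r, p, n.
#' @export
coexpression_edges <- function(profiles, query, targets, p_thresh = 1) {
  query <- intersect(query, rownames(profiles))
  targets <- intersect(targets, rownames(profiles))
  sds <- apply(profiles, 1, stats::sd)
  const <- rownames(profiles)[sds == 0]
  if (length(intersect(const, c(query, targets)))) {
    warning("constant profiles excluded: ",
            length(intersect(const, c(query, targets))))
    query <- setdiff(query, const)
    targets <- setdiff(targets, const)
  }
  if (length(query) == 0L || length(targets) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), p = numeric(), n = integer()))
  }
  n <- ncol(profiles)
  r <- stats::cor(t(profiles[query, , drop = FALSE]),
                  t(profiles[targets, , drop = FALSE]))
  df <- data.frame(
    gene_a = rep(query, times = length(targets)),
    gene_b = rep(targets, each = length(query)),
    r = as.vector(r),
    stringsAsFactors = FALSE
  )
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  df$p <- corr_pvalue(df$r, n)
  df$n <- n
  df <- df[df$p < p_thresh, , drop = FALSE]
  df[order(df$gene_a, df$p, df$gene_b), , drop = FALSE]
}

#' Pathway-level co-expression (PLC) candidate prediction
#'
#' A query gene is a candidate pathway member when it is significantly
#' co-expressed (two-sided, |r|-based, p < `p_thresh`) with at least
#' `min_partners` known pathway genes. The full partner edge list is
#' attached for audit, so every `passes` decision can be reproduced.
#'
#' @param profiles Genes x stages matrix.
#' @param query Genes to screen.
#' @param pathway Known pathway gene ids.
#' @param p_thresh Per-edge significance threshold (default 1e-4).
#' @param min_partners Minimum number of pathway partners, inclusive
#'   (default 2).
#' @return Data frame (gene, n_partners, min_p, partner_list, passes),
#'   ranked by n_partners then min_p, with the audit edge list as
#'   attribute `"edges"`.
#' @export
plc_candidates <- function(profiles, query, pathway, p_thresh = 1e-4,
                           min_partners = 2) {
  edges <- coexpression_edges(profiles, query, setdiff(pathway, NULL),
                              p_thresh = p_thresh)
  query <- intersect(query, rownames(profiles))
  by_gene <- split(edges, edges$gene_a)
  res <- data.frame(
    gene = query,
    n_partners = integer(length(query)),
    min_p = rep(NA_real_, length(query)),
    partner_list = character(length(query)),
    stringsAsFactors = FALSE
  )
  idx <- match(names(by_gene), res$gene)
  res$n_partners[idx] <- vapply(by_gene, nrow, integer(1))
  res$min_p[idx] <- vapply(by_gene, function(e) min(e$p), numeric(1))
  res$partner_list[idx] <- vapply(by_gene, function(e) {
    paste(e$gene_b, collapse = ",")
  }, character(1))
  res$passes <- res$n_partners >= min_partners
  res <- res[order(-res$n_partners, res$min_p, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "edges") <- edges
  res
}

#' Transcription-factor co-expression screens
#'
#' The same machinery as [plc_candidates()] with the two presets used for
#' TF screening: the stringent preset (p < 1e-4, >= 2 core-pathway
#' partners) for discovering candidate regulators among all TFs, and the
#' permissive preset (p < 0.05, > 10 partners) for ranking known
#' lipid-related TFs against the core enzymes.
#'
#' @param profiles Genes x stages matrix.
#' @param tfs TF gene ids to screen.
#' @param core Core pathway (enzyme) gene ids.
#' @param preset `"stringent"` (1e-4, >= 2) or `"permissive"` (0.05, >= 11);
#'   ignored when `p_thresh`/`min_partners` are given explicitly.
#' @param p_thresh,min_partners Optional explicit thresholds.
#' @return As [plc_candidates()], ranked by n_partners then min_p.
#' @export
tf_screen <- function(profiles, tfs, core,
                      preset = c("stringent", "permissive"),
                      p_thresh = NULL, min_partners = NULL) {
  preset <- match.arg(preset)
  if (is.null(p_thresh)) p_thresh <- if (preset == "stringent") 1e-4 else 0.05
  if (is.null(min_partners)) min_partners <- if (preset == "stringent") 2 else 11
  plc_candidates(profiles, tfs, core, p_thresh = p_thresh,
                 min_partners = min_partners)
}

#' Write a candidate table as TSV
#'
#' @param candidates Output of [plc_candidates()] / [tf_screen()].
#' @param path File path.
#' @export
write_candidates_tsv <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
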