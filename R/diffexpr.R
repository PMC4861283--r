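#' Two-sided Fisher exact test for two sequencing libraries
#'
#' Tests whether a gene's read count differs in proportion between two
#' libraries, conditioning on the 2x2 table
#' `[count_a, lib_a - count_a; count_b, lib_b - count_b]`. The two-sided
#' p-value is the point-probability method: the sum of hypergeometric point
#' probabilities not exceeding that of the observed table (with a 1 + 1e-7
#' relative slack for floating-point ties), matching the convention of
#' common Fisher implementations. Symmetric under swapping the libraries.
#'
#' All arguments are vectorised over genes; library sizes may be scalars.
#' Genes sharing the same margins share one hypergeometric computation, so
#' full count tables are tested quickly.
#'
#' @param count_a,count_b Non-negative integer read counts.
#' @param lib_a,lib_b Library sizes (total reads), counts <= libs.
#' @return Two-sided p-value(s) in (0, 1].
#' @examples
#' fisher_de(2, 10, 8, 10) # 4252/184756
#' @export
fisher_de <- function(count_a, lib_a, count_b, lib_b) {
  k <- max(length(count_a), length(count_b))
  count_a <- rep_len(count_a, k); count_b <- rep_len(count_b, k)
  lib_a <- rep_len(lib_a, k); lib_b <- rep_len(lib_b, k)
  if (any(lib_a <= 0) || any(lib_b <= 0)) stop("zero or negative library size")
  if (any(count_a < 0) || any(count_b < 0)) stop("negative count")
  if (any(count_a > lib_a) || any(count_b > lib_b)) stop("count exceeds library size")
  s <- count_a + count_b
  p <- numeric(k)
  grp <- paste(lib_a, lib_b, s, sep = "\r")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    la <- lib_a[idx[1]]; lb <- lib_b[idx[1]]; tot <- s[idx[1]]
    support <- max(0, tot - lb):min(tot, la)
    probs <- stats::dhyper(support, la, lb, tot)
    o <- order(probs)
    sorted <- probs[o]
    cs <- cumsum(sorted)
    obs <- probs[match(count_a[idx], support)]
    pos <- findInterval(obs * (1 + 1e-7), sorted)
    p[idx] <- cs[pos]
  }
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Call differentially expressed genes between two accessions
#'
#' Runs the per-stage Fisher exact test gene by gene between two count
#' tables and aggregates over stages: by default a gene is a DEG when
#' significant in at least one stage (`rule = "any"`); `rule = "all"`
#' requires every shared stage.
#'
#' @param counts_a,counts_b Genes x stages integer matrices with matching
#'   row and column names.
#' @param lib_a,lib_b Per-stage library sizes (named by stage, or in column
#'   order); default the column sums.
#' @param alpha Significance level (default 0.01).
#' @param rule `"any"` (default) or `"all"` stage aggregation.
#' @return List with `degs` (character vector), `p` (genes x stages p-value
#'   matrix), `flags` (logical genes x stages), `alpha`, `rule`.
#' @export
call_degs <- function(counts_a, counts_b, lib_a = colSums(counts_a),
                      lib_b = colSums(counts_b), alpha = 0.01,
                      rule = c("any", "all")) {
  rule <- match.arg(rule)
  stages <- intersect(colnames(counts_a), colnames(counts_b))
  if (length(stages) == 0L) stop("no shared stage")
  genes <- intersect(rownames(counts_a), rownames(counts_b))
  if (!is.null(names(lib_a))) lib_a <- lib_a[stages] else lib_a <- rep_len(lib_a, length(stages))
  if (!is.null(names(lib_b))) lib_b <- lib_b[stages] else lib_b <- rep_len(lib_b, length(stages))
  p <- vapply(seq_along(stages), function(j) {
    fisher_de(counts_a[genes, stages[j]], lib_a[j],
              counts_b[genes, stages[j]], lib_b[j])
  }, numeric(length(genes)))
  if (is.null(dim(p))) p <- matrix(p, nrow = length(genes))
  dimnames(p) <- list(genes, stages)
  flags <- p < alpha
  hit <- if (rule == "any") apply(flags, 1, any) else apply(flags, 1, all)
  list(degs = sort(genes[hit]), p = p, flags = flags, alpha = alpha, rule = rule)
}

#' Common DEGs of two comparisons
#'
#' @param set_1,set_2 Character vectors of DEG ids (or outputs of
#'   [call_degs()]).
#' @return List with `common` (sorted intersection), `only_1`, `only_2`.
#' @export
common_degs <- function(set_1, set_2) {
  if (is.list(set_1)) set_1 <- set_1$degs
  if (is.list(set_2)) set_2 <- set_2$degs
  list(
    common = sort(intersect(set_1, set_2)),
    only_1 = sort(setdiff(set_1, set_2)),
    only_2 = sort(setdiff(set_2, set_1))
  )
}
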