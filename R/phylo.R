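#' Pairwise protein distances from an alignment
#'
#' p-distance (mismatches over compared sites) or its Poisson correction
#' -ln(1 - p), with pairwise deletion of gap sites ('-' or '.').
#'
#' @param aln Named character vector of equal-length aligned sequences, or
#'   an `AAStringSet`.
#' @param model `"poisson"` (default, amino-acid Poisson correction) or
#'   `"p"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
protein_distance <- function(aln, model = c("poisson", "p")) {
  model <- match.arg(model)
  if (inherits(aln, "XStringSet")) {
    aln <- stats::setNames(as.character(aln), names(aln))
  }
  if (length(unique(nchar(aln))) != 1L) stop("sequences are not aligned (unequal lengths)")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  gap <- m == "-" | m == "."
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) stop("no comparable sites for pair ", names(aln)[i], " / ", names(aln)[j])
      p <- mean(m[i, ok] != m[j, ok])
      dij <- if (model == "p") p else {
        if (p >= 1) stop("Poisson correction undefined at p = 1 for pair ",
                         names(aln)[i], " / ", names(aln)[j])
        -log(1 - p)
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining gene tree
#'
#' Saitou-Nei agglomeration on a distance matrix. Additive matrices are
#' reconstructed exactly (topology and branch lengths). Taxa are sorted
#' before joining so the result does not depend on input order.
#'
#' @param d Symmetric distance matrix (or `dist`) over >= 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs taxon labels")
  if (nrow(d) < 3) stop("need >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  ord <- order(rownames(d))
  ape::nj(stats::as.dist(d[ord, ord]))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and scores every internal edge of the full-data tree by
#' the percentage of replicates containing the same bipartition. Supports
#' are written to the tree's node labels.
#'
#' @param aln Named character vector of aligned sequences (or
#'   `AAStringSet`).
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Integer RNG seed; the result is deterministic given the seed.
#' @param model Distance model (see [protein_distance()]).
#' @return The NJ tree on the full alignment with node labels holding the
#'   bootstrap percentages (root label empty).
#' @export
bootstrap_support <- function(aln, n_reps = 100, seed = 1,
                              model = c("poisson", "p")) {
  model <- match.arg(model)
  if (inherits(aln, "XStringSet")) {
    aln <- stats::setNames(as.character(aln), names(aln))
  }
  if (n_reps < 1) stop("n_reps must be >= 1")
  base <- neighbor_joining(protein_distance(aln, model))
  chars <- strsplit(aln, "")
  L <- length(chars[[1]])
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    res <- vapply(chars, function(x) paste(x[cols], collapse = ""), character(1))
    reps[[b]] <- neighbor_joining(protein_distance(res, model))
  }
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps)
  base$node.label <- as.character(support)
  # the basal node of an unrooted tree is not a bipartition; leave it blank
  base$node.label[1] <- ""
  base
}

#' Species tag of gene-tree leaves
#'
#' @param labels Leaf labels.
#' @param split_regex Regex separating the species prefix from the rest
#'   (default: first underscore or pipe).
#' @return Character vector of species codes.
#' @export
leaf_species <- function(labels, split_regex = "[_|]") {
  vapply(strsplit(labels, split_regex), `[`, character(1), 1)
}

#' Label gene-tree nodes as duplications or speciations
#'
#' Species-overlap rule: after rooting (midpoint by default), an internal
#' node is a duplication if and only if the species sets of its two child
#' subtrees intersect. Every leaf must carry a parseable species tag.
#'
#' @param tree A `phylo` gene tree; rooted trees are used as-is, unrooted
#'   trees are midpoint-rooted first (or rooted on `outgroup`).
#' @param split_regex Regex for the species prefix of leaf labels.
#' @param outgroup Optional leaf label(s) to root on instead of midpoint.
#' @return List with `tree` (rooted, node labels `"D"`/`"S"`), `events`
#'   (data frame node, event), and `n_duplications`.
#' @export
label_duplications <- function(tree, split_regex = "[_|]", outgroup = NULL) {
  if (!ape::is.rooted(tree)) {
    tree <- if (!is.null(outgroup)) {
      ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    } else {
      phangorn::midpoint(tree)
    }
  }
  sp <- vapply(strsplit(tree$tip.label, split_regex), `[`, character(1), 1)
  if (any(is.na(sp) | sp == "")) {
    stop("leaf without parseable species tag: ",
         paste(tree$tip.label[is.na(sp) | sp == ""], collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  species_sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) species_sets[[i]] <- sp[i]
  event <- character(nnode)
  # postorder: process an internal node once all its children are resolved
  done <- c(rep(TRUE, ntip), rep(FALSE, nnode))
  todo <- unique(tree$edge[, 1])
  while (length(todo)) {
    progressed <- FALSE
    for (nd in todo) {
      kids <- tree$edge[tree$edge[, 1] == nd, 2]
      if (all(done[kids])) {
        sets <- lapply(kids, function(k) species_sets[[k]])
        species_sets[[nd]] <- unique(unlist(sets))
        overlap <- FALSE
        if (length(sets) >= 2) {
          for (a in seq_len(length(sets) - 1)) {
            for (b in (a + 1):length(sets)) {
              if (length(intersect(sets[[a]], sets[[b]]))) overlap <- TRUE
            }
          }
        }
        event[nd - ntip] <- if (overlap) "D" else "S"
        done[nd] <- TRUE
        progressed <- TRUE
      }
    }
    todo <- todo[!done[todo]]
    if (!progressed) stop("malformed tree edges")
  }
  tree$node.label <- event
  list(
    tree = tree,
    events = data.frame(node = ntip + seq_len(nnode), event = event,
                        stringsAsFactors = FALSE),
    n_duplications = sum(event == "D")
  )
}

#' Read / write newick trees
#'
#' Wrappers over ape; support/event annotations travel as internal node
#' labels.
#'
#' @param path File path (for `read_newick`) or text via `text=`.
#' @param text Optional newick string instead of a file.
#' @return `read_newick` returns a `phylo`.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  raw <- if (!is.null(text)) text else paste(readLines(path), collapse = "")
  depth <- cumsum(vapply(strsplit(raw, "")[[1]], function(c) {
    if (c == "(") 1L else if (c == ")") -1L else 0L
  }, integer(1)))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0)) {
    pos <- if (any(depth < 0)) which(depth < 0)[1] else length(depth)
    stop("malformed newick: unbalanced parenthesis near position ", pos)
  }
  tr <- ape::read.tree(text = raw)
  if (is.null(tr)) stop("malformed newick")
  tr
}

#' @param tree A `phylo`.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) ape::write.tree(tree) else {
    ape::write.tree(tree, file = path)
    invisible(path)
  }
}
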