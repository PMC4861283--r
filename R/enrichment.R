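#' Parse a minimal OBO ontology
#'
#' Reads `[Term]` stanzas with id, name, namespace, is_a, subset and
#' is_obsolete fields — the subset of OBO needed for GO enrichment and
#' GO-slim summaries. Obsolete terms are skipped with a warning; an `is_a`
#' cycle is an error naming the cycle.
#'
#' @param path Path to an OBO file (or a character vector of its lines).
#' @param slim_subset Name of the subset flag marking slim terms
#'   (default `"goslim_plant"`; any subset line containing it counts).
#' @return An object of class `ontology`: list with `terms` (data frame id,
#'   name, namespace, slim), `parents` (named list id -> is_a parent ids).
#' @export
parse_obo <- function(path, slim_subset = "goslim_plant") {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  # split into stanzas
  starts <- which(lines == "[Term]")
  terms <- list()
  for (k in seq_along(starts)) {
    from <- starts[k] + 1L
    to <- if (k < length(starts)) starts[k + 1L] - 1L else length(lines)
    block <- lines[from:to]
    block <- block[!grepl("^\\[", block)]
    get <- function(key) {
      v <- block[startsWith(block, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", v))
    }
    id <- get("id")[1]
    if (is.na(id) || !nzchar(id)) next
    if (any(grepl("true", get("is_obsolete")))) {
      warning("obsolete term skipped: ", id)
      next
    }
    isa <- get("is_a")
    isa <- sub("\\s*!.*$", "", isa) # strip trailing comments
    terms[[id]] <- list(
      id = id,
      name = if (length(get("name"))) get("name")[1] else id,
      namespace = if (length(get("namespace"))) get("namespace")[1] else NA_character_,
      slim = any(grepl(slim_subset, get("subset"), fixed = TRUE)),
      parents = isa
    )
  }
  ids <- names(terms)
  parents <- lapply(terms, function(t) intersect(t$parents, ids))
  ont <- structure(
    list(
      terms = data.frame(
        id = ids,
        name = vapply(terms, `[[`, character(1), "name"),
        namespace = vapply(terms, `[[`, character(1), "namespace"),
        slim = vapply(terms, `[[`, logical(1), "slim"),
        row.names = NULL, stringsAsFactors = FALSE
      ),
      parents = parents
    ),
    class = "ontology"
  )
  check_ontology_acyclic(ont)
  ont
}

# Topological check: error with an explicit cycle if is_a is not a DAG.
check_ontology_acyclic <- function(ont) {
  state <- stats::setNames(rep(0L, nrow(ont$terms)), ont$terms$id) # 0 new 1 open 2 done
  stack <- character()
  visit <- function(id) {
    if (state[[id]] == 1L) {
      cyc <- c(stack[which(stack == id)[1]:length(stack)], id)
      stop("is_a cycle: ", paste(cyc, collapse = " -> "))
    }
    if (state[[id]] == 2L) return(invisible())
    state[[id]] <<- 1L
    stack <<- c(stack, id)
    for (p in ont$parents[[id]]) visit(p)
    stack <<- stack[-length(stack)]
    state[[id]] <<- 2L
  }
  for (id in ont$terms$id) visit(id)
  invisible(ont)
}

#' @export
print.ontology <- function(x, ...) {
  cat("ontology:", nrow(x$terms), "terms,", sum(x$terms$slim), "slim terms\n")
  invisible(x)
}

#' Ancestors of a term (transitive is_a closure, term excluded)
#'
#' @param ont An `ontology`.
#' @param id Term id.
#' @return Character vector of ancestor term ids (deduplicated).
#' @export
term_ancestors <- function(ont, id) {
  seen <- character()
  frontier <- ont$parents[[id]]
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(ont$parents[frontier])), seen)
  }
  seen
}

#' Propagate gene annotations to all ancestors (true-path rule)
#'
#' Each gene annotated to a term is also annotated to every ancestor of that
#' term. Idempotent. Unknown terms are skipped with a warning.
#'
#' @param annotations Data frame with columns gene_id, term_id.
#' @param ont An `ontology`.
#' @return Data frame gene_id, term_id: the annotation closure, deduplicated
#'   and sorted.
#' @export
propagate_annotations <- function(annotations, ont) {
  known <- annotations$term_id %in% ont$terms$id
  if (any(!known)) {
    warning("unknown terms skipped: ",
            paste(unique(annotations$term_id[!known]), collapse = ", "))
    annotations <- annotations[known, , drop = FALSE]
  }
  if (nrow(annotations) == 0L) {
    return(data.frame(gene_id = character(), term_id = character(),
                      stringsAsFactors = FALSE))
  }
  anc <- lapply(unique(annotations$term_id), function(t) c(t, term_ancestors(ont, t)))
  names(anc) <- unique(annotations$term_id)
  closure <- anc[annotations$term_id]
  out <- data.frame(
    gene_id = rep(annotations$gene_id, lengths(closure)),
    term_id = unlist(closure, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  out <- out[order(out$gene_id, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric GO over-representation test
#'
#' For every term annotating at least one universe gene, tests whether the
#' study set is enriched: p = P(X >= k) where X is hypergeometric with K
#' term genes among N universe genes and n study draws. Counting is done on
#' the annotation closure (annotations are propagated internally).
#'
#' @param study Character vector of study gene ids (subset of universe).
#' @param universe Character vector of universe gene ids.
#' @param annotations Data frame gene_id, term_id (direct annotations).
#' @param ont An `ontology`.
#' @param p_thresh Report terms with p < `p_thresh` (default 0.01).
#' @return Data frame (term_id, name, k, K, n, N, p), sorted by ascending p
#'   then term id.
#' @export
hypergeom_enrich <- function(study, universe, annotations, ont,
                             p_thresh = 0.01) {
  study <- unique(study)
  universe <- unique(universe)
  if (length(study) == 0L || length(universe) == 0L) {
    stop("study and universe must be non-empty")
  }
  if (!all(study %in% universe)) stop("study set is not a subset of the universe")
  closure <- propagate_annotations(annotations, ont)
  closure <- closure[closure$gene_id %in% universe, , drop = FALSE]
  N <- length(universe)
  n <- length(study)
  genes_by_term <- split(closure$gene_id, closure$term_id)
  K <- lengths(genes_by_term)
  k <- vapply(genes_by_term, function(g) sum(g %in% study), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(
    term_id = names(genes_by_term),
    name = ont$terms$name[match(names(genes_by_term), ont$terms$id)],
    k = k, K = unname(K), n = n, N = N, p = unname(p),
    row.names = NULL, stringsAsFactors = FALSE
  )
  res <- res[res$p < p_thresh, , drop = FALSE]
  res[order(res$p, res$term_id), , drop = FALSE]
}

#' Summarise enriched terms by their nearest GO-slim ancestors
#'
#' Each term maps to its minimal slim ancestors: slim terms lying on an
#' is_a path above the term (the term itself if it is a slim term) that
#' have no other mapped slim term below them. Terms without any slim
#' ancestor fall into the namespace root bucket.
#'
#' @param term_ids Enriched term ids.
#' @param ont An `ontology` (slim flags from its `terms$slim`).
#' @return Data frame (term_id, slim_id): one row per (term, slim ancestor)
#'   pair; `slim_id` is `root:<namespace>` for unmapped terms.
#' @export
goslim_summarize <- function(term_ids, ont) {
  slims <- ont$terms$id[ont$terms$slim]
  if (length(slims) == 0L) stop("ontology has no slim terms")
  rows <- lapply(term_ids, function(t) {
    cand <- intersect(c(t, term_ancestors(ont, t)), slims)
    if (length(cand) == 0L) {
      ns <- ont$terms$namespace[ont$terms$id == t]
      return(data.frame(term_id = t, slim_id = paste0("root:", ns),
                        stringsAsFactors = FALSE))
    }
    # minimal: drop slim ancestors that are ancestors of another candidate
    minimal <- cand[vapply(cand, function(s) {
      !any(vapply(setdiff(cand, s), function(o) s %in% term_ancestors(ont, o),
                  logical(1)))
    }, logical(1))]
    data.frame(term_id = t, slim_id = sort(minimal), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
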