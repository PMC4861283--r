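# Independent oracle implementations used to cross-check the package.
# These are deliberately naive (dense base-R loops) and share no code with
# the package internals.

# --- naive dense MCL ------------------------------------------------------
naive_mcl <- function(adj, inflation = 2, prune = 1e-5, tol = 1e-6,
                      max_iter = 200) {
  nodes <- rownames(adj)
  m <- as.matrix(adj)
  diag(m) <- 0
  deg <- colSums(m > 0)
  isolated <- nodes[deg == 0]
  keep <- which(deg > 0)
  if (length(keep) == 0) {
    return(list(partition = list(), unclustered = sort(isolated)))
  }
  m <- m[keep, keep, drop = FALSE]
  for (i in seq_len(nrow(m))) m[i, i] <- max(m[, i])
  m <- sweep(m, 2, colSums(m), "/")
  for (it in seq_len(max_iter)) {
    m2 <- m %*% m
    m2 <- m2^inflation
    m2 <- sweep(m2, 2, colSums(m2), "/")
    m2[m2 < prune] <- 0
    m2 <- sweep(m2, 2, colSums(m2), "/")
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) break
  }
  nm <- rownames(m)
  attractors <- which(diag(m) > 0)
  # attractor systems: components among attractors on symmetrised support
  s <- (m + t(m))[attractors, attractors, drop = FALSE] > 0
  na <- length(attractors)
  comp <- seq_len(na)
  repeat {
    changed <- FALSE
    for (a in seq_len(na)) {
      nb <- which(s[a, ])
      if (length(nb) && min(comp[nb]) < comp[a]) {
        comp[a] <- min(comp[nb])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sys_of <- vapply(split(nm[attractors], comp), min, character(1))
  lab <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    tgt <- intersect(which(m[, j] > 0), attractors)
    lab[j] <- if (length(tgt) == 0) nm[j] else {
      min(sys_of[as.character(comp[match(tgt, attractors)])])
    }
  }
  part <- split(nm, lab)
  list(partition = unname(lapply(part, sort)), unclustered = sort(isolated))
}

# canonical string form of a partition (order-free comparison)
partition_key <- function(clusters) {
  paste(sort(vapply(clusters, function(x) paste(sort(x), collapse = ","),
                    character(1))), collapse = ";")
}

random_graph <- function(n, p = 0.25) {
  adj <- matrix(0, n, n, dimnames = list(sprintf("n%02d", 1:n),
                                         sprintf("n%02d", 1:n)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- round(runif(1, 0.1, 1), 3)
    }
  }
  adj
}

# --- hand enumeration of lineage classes ----------------------------------
# independent truth table: classification from first principles
truth_class <- function(sp, panel) {
  dic <- panel$species[panel$lineage_of == "dicot"]
  gra <- panel$species[panel$lineage_of == "grass"]
  nd <- sum(sp %in% dic)
  ng <- sum(sp %in% gra)
  if (nd > 0 && ng > 0) "shared"
  else if (ng == 0 && nd == length(dic)) "dicot_specific"
  else if (ng == 0) "dicot_partial"
  else if (nd == 0 && ng == length(gra)) "grass_specific"
  else "grass_partial"
}

# --- choose()-based Fisher oracle (point-probability two-sided) ------------
oracle_fisher_group <- function(la, lb, s) {
  sup <- max(0, s - lb):min(s, la)
  pr <- choose(la, sup) * choose(lb, s - sup) / choose(la + lb, s)
  keep <- outer(pr, pr * (1 + 1e-7), "<=")
  p <- colSums(keep * pr)
  names(p) <- as.character(sup)
  pmin(p, 1)
}

# --- brute-force average-linkage agglomeration ----------------------------
naive_average_linkage <- function(d) {
  n <- nrow(d)
  labs <- as.list(rownames(d))
  active <- seq_len(n)
  dd <- d
  merges <- list()
  heights <- numeric()
  while (length(active) > 1) {
    best <- c(NA, NA)
    bh <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (a < b) {
          h <- dd[active[a], active[b]]
          if (h < bh) {
            bh <- h
            best <- c(active[a], active[b])
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    merged <- sort(c(labs[[i]], labs[[j]]))
    merges[[length(merges) + 1]] <- merged
    heights <- c(heights, bh)
    # average linkage update (weighted by cluster sizes)
    ni <- length(labs[[i]]); nj <- length(labs[[j]])
    for (k in active) {
      if (k != i && k != j) {
        dd[i, k] <- dd[k, i] <- (ni * dd[i, k] + nj * dd[j, k]) / (ni + nj)
      }
    }
    labs[[i]] <- merged
    active <- setdiff(active, j)
  }
  list(merges = merges, heights = heights)
}

# small helper: expression matrix fixture with explicit values
make_em <- function(values, stages = NULL, accession = "W82") {
  ns <- ncol(values) / 2
  if (is.null(stages)) stages <- paste0("s", seq_len(ns))
  sample_id <- c(paste0(stages, "_r1"), paste0(stages, "_r2"))
  colnames(values) <- sample_id
  meta <- data.frame(
    sample_id = sample_id,
    stage = rep(stages, 2),
    stage_order = rep(seq_len(ns), 2),
    replicate = rep(1:2, each = ns),
    accession = accession,
    stringsAsFactors = FALSE
  )
  expression_matrix(values, meta)
}
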