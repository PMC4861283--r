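#' Default expression archetype table
#'
#' Eight cluster archetypes (rows) of mean log2 abundance over the seven
#' seed-development stages (columns): an early steep decline (cluster 1), a
#' dry-seed peak (cluster 2), peaks at each of stages 4, 5 and 6 (clusters
#' 3-5, the oil-accumulation window), two further monotone declines
#' (clusters 6-7) and an early stage-2 peak (cluster 8). The curves are
#' qualitative illustrations of the cluster shapes seen in seed
#' transcriptomes, not calibrated to any measured profile; their free
#' parameters were chosen once so that no two archetypes exceed |Pearson r|
#' = 0.65, which keeps the planted partition identifiable at the |r| > 0.7
#' edge rule.
#'
#' @return An 8 x 7 numeric matrix with cluster and stage dimnames.
#' @export
default_archetypes <- function() {
  stages <- c("4DAF", "12-14DAF", "22-24DAF", "5-6mg", "100-200mg",
              "400-500mg", "dry")
  a <- rbind(
    c(7.0, 2.0, 2.0, 2.0, 2.0, 2.0, 2.0),
    c(2.0, 2.0, 2.0, 2.5, 2.5, 2.7, 7.5),
    c(2.0, 4.0, 4.2, 7.5, 4.4, 3.3, 2.2),
    c(2.0, 2.4, 4.0, 5.8, 8.3, 4.7, 2.8),
    c(2.5, 2.5, 2.5, 2.9, 3.5, 9.0, 3.0),
    c(8.5, 8.5, 2.0, 2.0, 2.0, 2.0, 2.0),
    c(7.0, 6.9, 6.8, 5.7, 3.2, 2.0, 2.0),
    c(2.6, 8.1, 4.5, 2.3, 2.2, 2.0, 2.0)
  )
  dimnames(a) <- list(paste0("cluster", 1:8), stages)
  a
}

#' The oil-accumulation stage window
#'
#' Stages 4-6 of the seven (5-6 mg through 400-500 mg seed weight), the
#' period of rapid lipid accumulation.
#'
#' @return Character vector of stage names.
#' @export
oil_window_stages <- function() c("5-6mg", "100-200mg", "400-500mg")

#' Default species tree over the 7-species panel
#'
#' A fixed dated topology for the four dicots and three grasses, branch
#' lengths on an amino-acid substitutions/site scale. Used by the
#' gene-family simulator.
#'
#' @return A rooted `phylo` with a root edge.
#' @export
default_species_tree <- function() {
  tr <- ape::read.tree(text = paste0(
    "(((Gma:0.10,Gra:0.10):0.05,(Rco:0.12,Ath:0.12):0.03):0.10,",
    "((Sbi:0.08,Sit:0.08):0.06,Osa:0.12):0.11);"
  ))
  tr$root.edge <- 0.05
  tr
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with the study
#' defaults: a 7-species panel (4 dicots, 3 grasses), ortholog groups in six
#' species-composition classes, 3,000 expression genes over 7 stages x 2
#' replicates in 8 planted archetype clusters, Poisson count tables for 3
#' accessions x 4 stages with planted fold-changes, 2-kb promoters with
#' planted AW-boxes, and gene families evolved with duplications/losses on
#' the species tree. The seed fully determines every output.
#'
#' @param seed Integer RNG seed.
#' @param n_ogs Number of ortholog groups.
#' @param composition_probs Named probability vector over the classes
#'   shared, dicot_specific, grass_specific, dicot_partial, grass_partial,
#'   other; must sum to 1.
#' @param member_geom_p Geometric parameter for per-species member counts
#'   (count = 1 + Geom(p); default 0.7, mean ~1.43 members).
#' @param n_genes_expr Number of genes in the expression matrix.
#' @param n_clusters Number of expression clusters (must match
#'   `archetype_table` rows).
#' @param archetype_table Cluster x stage matrix of mean log2 abundance.
#' @param sigma_gene Per-gene per-stage log2 noise SD.
#' @param sigma_rep Per-replicate log2 noise SD.
#' @param sigma_offset Per-gene constant log2 offset SD.
#' @param n_pathway,n_core Pathway genes and the core-enzyme subset.
#' @param n_tf,n_seed_tf TF genes and the seed-specific subset.
#' @param n_regulators Planted pathway-coupled regulator genes (PLC truth).
#' @param n_de_genes Genes in the count tables.
#' @param de_fraction Fraction of count-table genes with a planted
#'   fold-change.
#' @param fold_change Planted fold-change (> 0) in the high-oil accession.
#' @param lib_size Expected reads per library.
#' @param n_promoters Number of promoter sequences.
#' @param promoter_length Promoter length in bp (>= 14).
#' @param planted_motifs_per_promoter AW-boxes planted per promoter.
#' @param n_families Gene families to simulate.
#' @param family_dup_rate Duplication rate per lineage per species-tree
#'   branch.
#' @param family_loss_rate Loss probability per lineage per branch.
#' @param family_seq_len Alignment length for simulated family proteins.
#' @param panel A `species_panel`.
#' @param species_tree Species tree for the family simulator.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_ogs = 5000,
                       composition_probs = c(shared = 0.60,
                                             dicot_specific = 0.053,
                                             grass_specific = 0.040,
                                             dicot_partial = 0.120,
                                             grass_partial = 0.087,
                                             other = 0.100),
                       member_geom_p = 0.7,
                       n_genes_expr = 3000,
                       n_clusters = 8,
                       archetype_table = default_archetypes(),
                       sigma_gene = 0.2,
                       sigma_rep = 0.2,
                       sigma_offset = 0.5,
                       n_pathway = 150,
                       n_core = 60,
                       n_tf = 300,
                       n_seed_tf = 30,
                       n_regulators = 30,
                       n_de_genes = 2000,
                       de_fraction = 0.1,
                       fold_change = 4,
                       lib_size = 2e5,
                       n_promoters = 200,
                       promoter_length = 2000,
                       planted_motifs_per_promoter = 1,
                       n_families = 20,
                       family_dup_rate = 0.3,
                       family_loss_rate = 0.2,
                       family_seq_len = 200,
                       panel = default_species_panel(),
                       species_tree = default_species_tree()) {
  cfg <- as.list(environment())
  classes <- c("shared", "dicot_specific", "grass_specific",
               "dicot_partial", "grass_partial", "other")
  if (!setequal(names(composition_probs), classes)) {
    stop("composition_probs must cover exactly the classes: ",
         paste(classes, collapse = ", "))
  }
  if (any(composition_probs < 0) ||
      abs(sum(composition_probs) - 1) > 1e-8) {
    stop("composition_probs must be a probability vector summing to 1")
  }
  if (sigma_gene < 0 || sigma_rep < 0 || sigma_offset < 0) {
    stop("noise SDs must be >= 0")
  }
  if (fold_change <= 0) stop("fold_change must be > 0")
  if (lib_size <= 0) stop("lib_size must be > 0")
  if (n_clusters != nrow(archetype_table)) {
    stop("n_clusters does not match archetype_table rows")
  }
  if (promoter_length < 14) stop("promoter_length must be >= 14")
  if (n_core > n_pathway) stop("n_core must be <= n_pathway")
  if (n_seed_tf > n_tf) stop("n_seed_tf must be <= n_tf")
  structure(cfg, class = "sim_config")
}

# deterministic sub-seed per generator; keeps every stream independent of
# the others while fully determined by config$seed
sub_seed <- function(config, offset) (config$seed + offset) %% .Machine$integer.max

#' Simulate an ortholog-group table with known composition classes
#'
#' Draws a composition class per OG, selects the species present according
#' to the class definition (e.g. dicot-specific: all four dicots, no
#' grass), and gives each present species 1 + Geom(p) members. `other` OGs
#' are single-species singletons.
#'
#' @param config A `sim_config`.
#' @return List with `ogs` (data frame og_id, species, gene_id) and `truth`
#'   (list with `og_class_by_id`).
#' @export
simulate_og_table <- function(config) {
  set.seed(sub_seed(config, 101L))
  panel <- config$panel
  dic <- panel$species[panel$lineage_of == "dicot"]
  gra <- panel$species[panel$lineage_of == "grass"]
  n <- config$n_ogs
  if (n == 0L) {
    return(list(
      ogs = data.frame(og_id = character(), species = character(),
                       gene_id = character(), stringsAsFactors = FALSE),
      truth = list(og_class_by_id = stats::setNames(character(), character()))
    ))
  }
  cls <- sample(names(config$composition_probs), n, replace = TRUE,
                prob = config$composition_probs)
  og_id <- sprintf("OG%05d", seq_len(n))
  counters <- stats::setNames(integer(length(panel$species)), panel$species)
  rows_sp <- vector("list", n)
  rows_cnt <- vector("list", n)
  for (i in seq_len(n)) {
    present <- switch(cls[i],
      shared = {
        repeat {
          p <- panel$species[stats::runif(length(panel$species)) < 0.7]
          if (any(p %in% dic) && any(p %in% gra)) break
        }
        p
      },
      dicot_specific = dic,
      grass_specific = gra,
      dicot_partial = sort(sample(dic, sample.int(length(dic) - 1L, 1L))),
      grass_partial = sort(sample(gra, sample.int(length(gra) - 1L, 1L))),
      other = sample(panel$species, 1L)
    )
    cnt <- if (cls[i] == "other") rep(1L, length(present)) else {
      1L + stats::rgeom(length(present), config$member_geom_p)
    }
    rows_sp[[i]] <- present
    rows_cnt[[i]] <- cnt
  }
  n_per_og <- vapply(rows_cnt, sum, numeric(1))
  species <- rep(unlist(rows_sp), unlist(rows_cnt))
  # globally unique per-species gene numbering
  gene_no <- integer(length(species))
  for (sp in unique(species)) {
    idx <- which(species == sp)
    gene_no[idx] <- seq_along(idx)
  }
  ogs <- data.frame(
    og_id = rep(og_id, n_per_og),
    species = species,
    gene_id = sprintf("%sG%05d", species, gene_no),
    stringsAsFactors = FALSE
  )
  list(ogs = ogs,
       truth = list(og_class_by_id = stats::setNames(cls, og_id)))
}

#' Simulate a seed-development expression matrix with planted clusters
#'
#' Each gene is assigned an archetype cluster; its log2 abundance at a
#' stage is archetype + per-gene offset + N(0, sigma_gene^2), and each of
#' the two replicates adds N(0, sigma_rep^2). Values are back-transformed
#' to the abundance (RPKM-like) scale.
#'
#' @param config A `sim_config`.
#' @param gene_ids Optional gene ids (default `g00001`...).
#' @param labels Optional integer cluster assignment per gene (default
#'   uniform random over clusters).
#' @return List with `expression` (an `expr_matrix`) and `truth` (list with
#'   `cluster_label_by_gene`).
#' @export
simulate_expression <- function(config, gene_ids = NULL, labels = NULL) {
  set.seed(sub_seed(config, 202L))
  arch <- config$archetype_table
  n <- if (is.null(gene_ids)) config$n_genes_expr else length(gene_ids)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(n))
  if (is.null(labels)) labels <- sample.int(nrow(arch), n, replace = TRUE)
  stopifnot(length(labels) == n, all(labels %in% seq_len(nrow(arch))))
  stages <- colnames(arch)
  ns <- length(stages)
  offset <- stats::rnorm(n, 0, config$sigma_offset)
  mu <- arch[labels, , drop = FALSE] + offset +
    matrix(stats::rnorm(n * ns, 0, config$sigma_gene), n, ns)
  vals <- cbind(
    2^(mu + matrix(stats::rnorm(n * ns, 0, config$sigma_rep), n, ns)),
    2^(mu + matrix(stats::rnorm(n * ns, 0, config$sigma_rep), n, ns))
  )
  sample_id <- c(paste0(stages, "_r1"), paste0(stages, "_r2"))
  dimnames(vals) <- list(gene_ids, sample_id)
  meta <- data.frame(
    sample_id = sample_id,
    stage = rep(stages, 2),
    stage_order = rep(seq_len(ns), 2),
    replicate = rep(1:2, each = ns),
    accession = "W82",
    stringsAsFactors = FALSE
  )
  list(
    expression = expression_matrix(vals, meta),
    truth = list(cluster_label_by_gene = stats::setNames(labels, gene_ids))
  )
}

#' Simulate Poisson count tables with planted fold-changes
#'
#' Three accessions (one high-oil, two low-oil) x four stages. Gene
#' baseline weights are log-normal with shared mild stage effects; planted
#' genes are multiplied (direction `up`) or divided (`down`) by
#' `fold_change` in the high-oil accession. Each library's expected
#' abundances are rescaled to `lib_size` before Poisson sampling, so
#' planting induces the usual small compositional shift on null genes.
#'
#' @param config A `sim_config`.
#' @param gene_ids Optional gene ids (default `g00001`...).
#' @param de_genes Optional character vector of planted genes (default: the
#'   first `de_fraction` share after a random draw).
#' @param de_direction Optional named vector `"up"`/`"down"` for
#'   `de_genes`; default alternates to balance the mass shift.
#' @return List with `counts` (list of genes x stages matrices per
#'   accession), `lib_sizes` (accession x stage matrix of realized totals),
#'   and `truth` (list `de_gene_flags`, `de_direction`).
#' @export
simulate_counts_de <- function(config, gene_ids = NULL, de_genes = NULL,
                               de_direction = NULL) {
  set.seed(sub_seed(config, 303L))
  n <- if (is.null(gene_ids)) config$n_de_genes else length(gene_ids)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(n))
  stages <- c("15DAF", "25DAF", "35DAF", "55DAF")
  accessions <- c("HD5", "LO1", "LO2")
  if (is.null(de_genes)) {
    k <- round(config$de_fraction * n)
    de_genes <- sort(sample(gene_ids, k))
  }
  if (is.null(de_direction)) {
    de_direction <- stats::setNames(
      rep(c("up", "down"), length.out = length(de_genes)), de_genes)
  }
  w <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  names(w) <- gene_ids
  stage_eff <- stats::rlnorm(length(stages), 0, 0.2)
  fold <- rep(1, n)
  names(fold) <- gene_ids
  fold[de_genes] <- ifelse(de_direction[de_genes] == "up",
                           config$fold_change, 1 / config$fold_change)
  counts <- list()
  lib_sizes <- matrix(0, length(accessions), length(stages),
                      dimnames = list(accessions, stages))
  for (acc in accessions) {
    lam_gene <- if (acc == "HD5") w * fold else w
    m <- matrix(0L, n, length(stages), dimnames = list(gene_ids, stages))
    for (j in seq_along(stages)) {
      lam <- lam_gene * stage_eff[j]
      lam <- lam / sum(lam) * config$lib_size
      m[, j] <- stats::rpois(n, lam)
    }
    counts[[acc]] <- m
    lib_sizes[acc, ] <- colSums(m)
  }
  list(
    counts = counts,
    lib_sizes = lib_sizes,
    truth = list(
      de_gene_flags = stats::setNames(gene_ids %in% de_genes, gene_ids),
      de_direction = de_direction
    )
  )
}

#' Simulate promoter sequences with planted AW-boxes
#'
#' Uniform-random ACGT sequences; the requested number of AW-box instances
#' is planted per promoter at recorded, non-overlapping 0-based positions
#' (fixed motif positions C/T/G/C/G, free positions random).
#'
#' @param config A `sim_config`.
#' @param gene_ids Optional promoter ids (default `p0001`...).
#' @return List with `promoters` (named character vector) and `truth`
#'   (list `motif_positions_by_promoter`, 0-based starts).
#' @export
simulate_promoters <- function(config, gene_ids = NULL) {
  set.seed(sub_seed(config, 404L))
  n <- if (is.null(gene_ids)) config$n_promoters else length(gene_ids)
  if (is.null(gene_ids)) gene_ids <- sprintf("p%04d", seq_len(n))
  L <- config$promoter_length
  k <- config$planted_motifs_per_promoter
  width <- nchar(awbox_pattern())
  if (k * width > L) stop("too many motifs to place without overlap")
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  pos_list <- vector("list", n)
  for (i in seq_len(n)) {
    seq <- sample(bases, L, replace = TRUE)
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < k) {
      cand <- sample.int(L - width + 1L, 1L) - 1L # 0-based
      if (!any(abs(cand - starts) < width)) {
        starts <- c(starts, cand)
      }
      tries <- tries + 1L
      if (tries > 1000L) stop("could not place ", k,
                              " non-overlapping motifs in length ", L)
    }
    starts <- sort(starts)
    for (s in starts) {
      inst <- sample(bases, width, replace = TRUE)
      inst[c(1, 3, 5, 13, 14)] <- c("C", "T", "G", "C", "G")
      seq[(s + 1):(s + width)] <- inst
    }
    out[i] <- paste(seq, collapse = "")
    pos_list[[i]] <- starts
  }
  names(out) <- gene_ids
  names(pos_list) <- gene_ids
  list(promoters = out,
       truth = list(motif_positions_by_promoter = pos_list))
}

# --- gene-family simulator ----------------------------------------------

# internal recursive representation: list(leaf=, species=, children=,
# root_len=, event=)
fam_enter_edge <- function(sp_node, edge_len, dup_rate, loss_rate) {
  if (stats::runif(1) < loss_rate) return(NULL)
  if (stats::runif(1) < 1 - exp(-dup_rate)) {
    u <- stats::runif(1) * edge_len
    left <- fam_continue(sp_node, edge_len - u, dup_rate, loss_rate)
    right <- fam_continue(sp_node, edge_len - u, dup_rate, loss_rate)
    kids <- Filter(Negate(is.null), list(left, right))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) {
      kids[[1]]$root_len <- kids[[1]]$root_len + u
      return(kids[[1]])
    }
    return(list(leaf = FALSE, children = kids, root_len = u, event = "D"))
  }
  fam_continue(sp_node, edge_len, dup_rate, loss_rate)
}

fam_continue <- function(sp_node, remaining, dup_rate, loss_rate) {
  if (is.character(sp_node)) { # species-tree leaf
    return(list(leaf = TRUE, species = sp_node, root_len = remaining))
  }
  kids <- lapply(sp_node$children, function(ch) {
    fam_enter_edge(ch$node, ch$length, dup_rate, loss_rate)
  })
  kids <- Filter(Negate(is.null), kids)
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) {
    kids[[1]]$root_len <- kids[[1]]$root_len + remaining
    return(kids[[1]])
  }
  list(leaf = FALSE, children = kids, root_len = remaining, event = "S")
}

# phylo -> nested list with named leaves and branch lengths
phylo_to_nested <- function(tr) {
  ntip <- length(tr$tip.label)
  build <- function(node) {
    kid_rows <- which(tr$edge[, 1] == node)
    children <- lapply(kid_rows, function(r) {
      child <- tr$edge[r, 2]
      list(node = if (child <= ntip) tr$tip.label[child] else build(child),
           length = tr$edge.length[r])
    })
    list(children = children)
  }
  build(ntip + 1L)
}

fam_to_newick <- function(node, counters_env, family_id) {
  if (isTRUE(node$leaf)) {
    sp <- node$species
    counters_env[[sp]] <- (if (is.null(counters_env[[sp]])) 0L else counters_env[[sp]]) + 1L
    lab <- sprintf("%s_f%02d_%d", sp, family_id, counters_env[[sp]])
    return(sprintf("%s:%g", lab, node$root_len))
  }
  inner <- vapply(node$children, fam_to_newick, character(1),
                  counters_env = counters_env, family_id = family_id)
  sprintf("(%s)%s:%g", paste(inner, collapse = ","), node$event, node$root_len)
}

#' Simulate a gene family along the species tree
#'
#' A single ancestral gene enters the root edge and evolves by duplication
#' (at most one per lineage per branch, at a uniform position) and loss;
#' lineages split at every speciation. The true gene tree carries
#' duplication/speciation node labels, leaf names are species-tagged
#' (`Gma_f01_1`), path-length distances are additive on the true tree, and
#' a protein alignment is evolved along it by Poisson site substitution.
#' Families extinct in all species are redrawn (error after 100 attempts).
#'
#' @param config A `sim_config`.
#' @param family_id Integer family index (also seeds the family's RNG
#'   stream).
#' @return List with `tree` (`phylo`, node labels `"D"`/`"S"`),
#'   `distances` (path-length matrix), `alignment` (named character
#'   vector), and `truth` (list `n_duplications`, `events`).
#' @export
simulate_family <- function(config, family_id = 1L) {
  set.seed(sub_seed(config, 505L + family_id))
  sp_tree <- config$species_tree
  nested <- phylo_to_nested(sp_tree)
  root_edge <- if (!is.null(sp_tree$root.edge)) sp_tree$root.edge else 0.05
  for (attempt in seq_len(100L)) {
    fam <- fam_enter_edge(nested, root_edge, config$family_dup_rate,
                          config$family_loss_rate)
    if (!is.null(fam)) break
    fam <- NULL
  }
  if (is.null(fam)) stop("family extinct in all species after 100 attempts")
  counters <- new.env()
  nwk <- fam_to_newick(fam, counters, family_id)
  if (isTRUE(fam$leaf)) {
    # single surviving gene: no tree to build
    lab <- sub(":.*$", "", nwk)
    return(list(tree = NULL, distances = NULL,
                alignment = stats::setNames(random_protein(config$family_seq_len), lab),
                truth = list(n_duplications = 0L, events = character())))
  }
  tree <- ape::read.tree(text = paste0(nwk, ";"))
  dmat <- ape::cophenetic.phylo(tree)
  aln <- evolve_alignment(tree, config$family_seq_len)
  list(
    tree = tree,
    distances = dmat,
    alignment = aln,
    truth = list(
      n_duplications = sum(tree$node.label == "D"),
      events = tree$node.label
    )
  )
}

random_protein <- function(len) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# evolve sequences down a phylo by per-site substitution with prob
# 1 - exp(-branch length)
evolve_alignment <- function(tree, len) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample(aa, len, replace = TRUE)
  # edges of a phylo read top-down in edge order
  for (r in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[r, 1]
    child <- tree$edge[r, 2]
    p_sub <- 1 - exp(-tree$edge.length[r])
    s <- seqs[[parent]]
    hit <- stats::runif(len) < p_sub
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(cur) sample(setdiff(aa, cur), 1L),
                       character(1))
    }
    seqs[[child]] <- s
  }
  stats::setNames(
    vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
           character(1)),
    tree$tip.label
  )
}

#' Miniature GO ontology for synthetic annotation
#'
#' A fixed, hand-built DAG: biological_process root, a metabolic-process
#' layer, eight slim terms (six "processes of interest" for the candidate
#' pipeline plus two decoys) and leaf terms beneath them, including two
#' diamond motifs (a leaf with two slim ancestors). Built as OBO text and
#' parsed with [parse_obo()], so generated ontologies round-trip through
#' the reader by construction.
#'
#' @return List with `ontology` (an `ontology`), `obo_lines` (the OBO
#'   text), and `interest_terms` (the six interest slim ids).
#' @export
simulate_ontology <- function() {
  term <- function(id, name, isa = character(), slim = FALSE) {
    c("[Term]", paste0("id: ", id), paste0("name: ", name),
      "namespace: biological_process",
      if (slim) "subset: goslim_plant",
      paste0("is_a: ", isa, " ! ", name), "")
  }
  lines <- c(
    "format-version: 1.2", "",
    term("GO:0008150", "biological_process", slim = TRUE),
    term("GO:0008152", "metabolic process", "GO:0008150", slim = TRUE),
    term("GO:0005975", "carbohydrate metabolic process", "GO:0008152", slim = TRUE),
    term("GO:0006629", "lipid metabolic process", "GO:0008152", slim = TRUE),
    term("GO:0009056", "catabolic process", "GO:0008152", slim = TRUE),
    term("GO:0019538", "protein metabolic process", "GO:0008152", slim = TRUE),
    term("GO:0006810", "transport", "GO:0008150", slim = TRUE),
    term("GO:0007165", "signal transduction", "GO:0008150", slim = TRUE),
    term("GO:0032502", "developmental process", "GO:0008150", slim = TRUE),
    term("GO:0006950", "response to stress", "GO:0008150", slim = TRUE),
    term("GO:0008610", "lipid biosynthetic process", "GO:0006629"),
    term("GO:0006633", "fatty acid biosynthetic process", "GO:0008610"),
    term("GO:0019432", "triglyceride biosynthetic process", "GO:0008610"),
    term("GO:0016042", "lipid catabolic process",
         c("GO:0006629", "GO:0009056")),
    term("GO:0005982", "starch metabolic process", "GO:0005975"),
    term("GO:0005983", "starch catabolic process",
         c("GO:0005982", "GO:0009056")),
    term("GO:0008643", "carbohydrate transport", "GO:0006810"),
    term("GO:0015748", "organophosphate ester transport", "GO:0006810"),
    term("GO:0009755", "hormone-mediated signaling pathway", "GO:0007165"),
    term("GO:0006508", "proteolysis", "GO:0019538"),
    term("GO:0048316", "seed development", "GO:0032502"),
    term("GO:0009409", "response to cold", "GO:0006950")
  )
  list(
    ontology = parse_obo(lines),
    obo_lines = lines,
    interest_terms = c("GO:0005975", "GO:0006629", "GO:0006810",
                       "GO:0007165", "GO:0009056", "GO:0019538")
  )
}

#' Generate the full synthetic study with planted truth
#'
#' Weaves the per-module generators into one coherent dataset over the
#' focal species: an OG table whose focal-species genes form the expression
#' universe; gene roles (pathway members, core enzymes, TFs, seed-specific
#' TFs, planted regulators) with cluster assignments that place pathway
#' machinery and regulators in the oil-window clusters; count tables whose
#' planted DEGs include the regulators and seed TFs; promoters for the core
#' genes; gene families; and a miniature GO annotation.
#'
#' @param config A `sim_config`.
#' @return A list with elements `ogs`, `og_truth`, `genes` (metadata data
#'   frame), `expression`, `counts`, `lib_sizes`, `promoters`, `families`,
#'   `ontology`, `annotations`, `interest_terms`, `seed_tf_list`, and
#'   `truth` (all planted labels combined).
#' @export
simulate_study <- function(config = sim_config()) {
  og <- simulate_og_table(config)
  focal <- config$panel$focal_species
  focal_pool <- sort(unique(og$ogs$gene_id[og$ogs$species == focal]))

  set.seed(sub_seed(config, 707L))
  n <- config$n_genes_expr
  if (length(focal_pool) >= n) {
    genes <- sort(sample(focal_pool, n))
  } else {
    extra <- sprintf("%sU%05d", focal, seq_len(n - length(focal_pool)))
    genes <- sort(c(focal_pool, extra))
  }

  # gene roles
  pathway <- sort(sample(genes, config$n_pathway))
  core <- sort(sample(pathway, config$n_core))
  tfs <- sort(sample(setdiff(genes, pathway), config$n_tf))
  seed_tfs <- sort(sample(tfs, config$n_seed_tf))
  regulators <- sort(sample(setdiff(genes, c(pathway, tfs)),
                            config$n_regulators))

  # cluster assignment: window clusters are 3-5 (peaks at stages 4-6)
  arch <- config$archetype_table
  peak_stage <- apply(arch, 1, which.max)
  window_idx <- which(colnames(arch) %in% oil_window_stages())
  window_clusters <- which(peak_stage %in% window_idx)
  labels <- stats::setNames(
    sample.int(nrow(arch), length(genes), replace = TRUE), genes)
  put_in <- function(ids, clusters, prob_in = 1) {
    pick <- ids[stats::runif(length(ids)) < prob_in]
    labels[pick] <<- sample(clusters, length(pick), replace = TRUE)
  }
  put_in(pathway, window_clusters, 0.75)
  put_in(core, window_clusters, 0.90)
  put_in(regulators, window_clusters, 1)
  put_in(seed_tfs, window_clusters, 1)

  expr <- simulate_expression(config, gene_ids = genes,
                              labels = unname(labels[genes]))

  # count tables: role genes first, then fill
  role_genes <- sort(unique(c(pathway, tfs, regulators)))
  fill <- setdiff(genes, role_genes)
  de_universe <- sort(c(role_genes,
                        fill[seq_len(max(0, config$n_de_genes - length(role_genes)))]))
  n_planted <- round(config$de_fraction * length(de_universe))
  forced <- sort(unique(c(regulators, seed_tfs, sample(core, ceiling(config$n_core / 2)))))
  forced <- intersect(forced, de_universe)
  extra_de <- sort(sample(setdiff(de_universe, forced),
                          max(0, n_planted - length(forced))))
  de_genes <- sort(c(forced, extra_de))
  de_direction <- stats::setNames(rep("down", length(de_genes)), de_genes)
  de_direction[forced] <- "up" # candidates are up-regulated in high oil
  counts <- simulate_counts_de(config, gene_ids = de_universe,
                               de_genes = de_genes,
                               de_direction = de_direction)

  # promoters: core genes first, fill with other pathway genes then others
  prom_genes <- c(core, setdiff(pathway, core), setdiff(genes, pathway))
  prom_genes <- prom_genes[seq_len(min(config$n_promoters, length(prom_genes)))]
  promoters <- simulate_promoters(config, gene_ids = prom_genes)

  families <- lapply(seq_len(config$n_families), function(k) {
    simulate_family(config, family_id = k)
  })

  onto <- simulate_ontology()
  set.seed(sub_seed(config, 808L))
  lipid_leaves <- c("GO:0006633", "GO:0019432", "GO:0008610", "GO:0016042")
  interest_leaves <- c("GO:0005982", "GO:0005983", "GO:0008643",
                       "GO:0015748", "GO:0009755", "GO:0006508")
  decoy_leaves <- c("GO:0048316", "GO:0009409")
  ann_term <- character(length(genes))
  names(ann_term) <- genes
  in_window <- names(labels)[labels %in% window_clusters]
  for (g in genes) {
    ann_term[g] <- if (g %in% pathway) {
      sample(lipid_leaves, 1)
    } else if (g %in% in_window && stats::runif(1) < 0.30) {
      sample(interest_leaves, 1)
    } else {
      sample(c(interest_leaves, decoy_leaves), 1,
             prob = c(rep(0.4 / 6, 6), 0.3, 0.3))
    }
  }
  annotations <- data.frame(gene_id = genes, term_id = unname(ann_term),
                            stringsAsFactors = FALSE)

  set.seed(sub_seed(config, 909L))
  lengths_bp <- round(exp(stats::runif(length(genes), log(300), log(10000))))
  genes_df <- data.frame(
    gene_id = genes,
    species = focal,
    length_bp = lengths_bp,
    is_pathway = genes %in% pathway,
    is_core = genes %in% core,
    is_tf = genes %in% tfs,
    is_seed_tf = genes %in% seed_tfs,
    is_regulator = genes %in% regulators,
    cluster_truth = unname(labels[genes]),
    stringsAsFactors = FALSE
  )

  list(
    ogs = og$ogs,
    og_truth = og$truth,
    genes = genes_df,
    expression = expr$expression,
    counts = counts$counts,
    lib_sizes = counts$lib_sizes,
    promoters = promoters$promoters,
    families = families,
    ontology = onto$ontology,
    obo_lines = onto$obo_lines,
    annotations = annotations,
    interest_terms = onto$interest_terms,
    seed_tf_list = seed_tfs,
    truth = list(
      og_class_by_id = og$truth$og_class_by_id,
      cluster_label_by_gene = expr$truth$cluster_label_by_gene,
      pathway_member_flags = stats::setNames(genes %in% pathway, genes),
      regulator_flags = stats::setNames(genes %in% regulators, genes),
      de_gene_flags = counts$truth$de_gene_flags,
      de_direction = counts$truth$de_direction,
      motif_positions_by_promoter = promoters$truth$motif_positions_by_promoter,
      duplication_nodes_by_family = lapply(families, function(f) f$truth$n_duplications)
    )
  )
}
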