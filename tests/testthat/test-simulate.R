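test_that("config validation catches bad parameter vectors", {
  expect_error(sim_config(composition_probs = c(shared = 1)), "classes")
  bad <- c(shared = 0.5, dicot_specific = 0.5, grass_specific = 0.5,
           dicot_partial = 0, grass_partial = 0, other = 0)
  expect_error(sim_config(composition_probs = bad), "summing to 1")
  expect_error(sim_config(sigma_gene = -1), "SDs")
  expect_error(sim_config(fold_change = 0), "fold_change")
  expect_error(sim_config(promoter_length = 10), "promoter_length")
  expect_error(sim_config(n_clusters = 5), "archetype_table")
})

test_that("OG species compositions are consistent with their truth class", {
  cfg <- sim_config(seed = 50, n_ogs = 400)
  sim <- simulate_og_table(cfg)
  panel <- cfg$panel
  cls <- sim$truth$og_class_by_id
  sp_by_og <- split(sim$ogs$species, sim$ogs$og_id)
  gene_by_og <- split(sim$ogs$gene_id, sim$ogs$og_id)
  for (og in names(sp_by_og)) {
    if (cls[[og]] == "other") {
      # singleton recipe: one species, one gene
      expect_length(unique(sp_by_og[[og]]), 1)
      expect_length(gene_by_og[[og]], 1)
    } else {
      expect_equal(truth_class(unique(sp_by_og[[og]]), panel), cls[[og]],
                   info = og)
    }
  }
  expect_false(anyDuplicated(sim$ogs$gene_id) > 0)
  # n_ogs = 0: empty table and truth
  empty <- simulate_og_table(sim_config(n_ogs = 0))
  expect_equal(nrow(empty$ogs), 0)
  expect_length(empty$truth$og_class_by_id, 0)
})

test_that("observed class frequencies sit inside exact binomial bounds", {
  cfg <- sim_config(seed = 1, n_ogs = 500)
  sim <- simulate_og_table(cfg)
  obs <- table(factor(sim$truth$og_class_by_id,
                      levels = names(cfg$composition_probs)))
  for (cl in names(cfg$composition_probs)) {
    p <- cfg$composition_probs[[cl]]
    lo <- qbinom(0.005, 500, p)
    hi <- qbinom(0.995, 500, p)
    expect_gte(obs[[cl]], lo)
    expect_lte(obs[[cl]], hi)
  }
})

test_that("class marginals converge to the configured probabilities", {
  cfg <- sim_config(seed = 51, n_ogs = 5000)
  sim <- simulate_og_table(cfg)
  obs <- table(factor(sim$truth$og_class_by_id,
                      levels = names(cfg$composition_probs)))
  gof <- chisq.test(obs, p = cfg$composition_probs)
  expect_gt(gof$p.value, 0.001)
})

test_that("zero-noise expression equals the archetypes, two replicates each", {
  cfg <- sim_config(seed = 52, n_genes_expr = 40, sigma_gene = 0,
                    sigma_rep = 0, sigma_offset = 0)
  sim <- simulate_expression(cfg)
  prof <- stage_profiles(sim$expression, log2p1 = FALSE)
  arch <- 2^cfg$archetype_table
  for (g in rownames(prof)) {
    lab <- sim$truth$cluster_label_by_gene[[g]]
    expect_equal(unname(prof[g, ]), unname(arch[lab, ]), tolerance = 1e-9)
  }
  meta <- sim$expression$sample_meta
  expect_equal(unname(table(meta$stage)), rep(2L, 7), ignore_attr = TRUE)
})

test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(seed = 53, n_ogs = 100, n_genes_expr = 50,
                    n_de_genes = 40, n_pathway = 10, n_core = 5, n_tf = 8,
                    n_seed_tf = 2, n_regulators = 3, n_promoters = 5,
                    n_families = 2)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$ogs, b$ogs)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$counts, b$counts)
  expect_identical(a$promoters, b$promoters)
  expect_identical(lapply(a$families, `[[`, "alignment"),
                   lapply(b$families, `[[`, "alignment"))
  expect_identical(a$truth, b$truth)
})

test_that("count tables cover 3 accessions x 4 stages near the target depth", {
  cfg <- sim_config(seed = 54, n_de_genes = 300, lib_size = 5e4)
  sim <- simulate_counts_de(cfg)
  expect_setequal(names(sim$counts), c("HD5", "LO1", "LO2"))
  expect_equal(colnames(sim$counts$HD5), c("15DAF", "25DAF", "35DAF", "55DAF"))
  expect_true(all(abs(sim$lib_sizes / 5e4 - 1) < 0.05))
})

test_that("promoters carry the planted motifs at the recorded positions", {
  cfg <- sim_config(seed = 55, n_promoters = 8, promoter_length = 500,
                    planted_motifs_per_promoter = 2)
  sim <- simulate_promoters(cfg)
  expect_true(all(nchar(sim$promoters) == 500))
  for (g in names(sim$promoters)) {
    for (s in sim$truth$motif_positions_by_promoter[[g]]) {
      site <- substr(sim$promoters[[g]], s + 1, s + 14)
      expect_match(site, "^C.T.G.{7}CG$")
    }
  }
  expect_error(simulate_promoters(
    sim_config(promoter_length = 20, planted_motifs_per_promoter = 4)),
    "overlap")
})

test_that("families are congruent with the species tree when rates are zero", {
  cfg <- sim_config(seed = 56, family_dup_rate = 0, family_loss_rate = 0)
  fam <- simulate_family(cfg, family_id = 1)
  expect_equal(fam$truth$n_duplications, 0)
  expect_true(all(fam$tree$node.label == "S"))
  sp <- leaf_species(fam$tree$tip.label)
  expect_setequal(sp, cfg$panel$species)
  expect_equal(length(fam$tree$tip.label), 7) # one gene per species
  # NJ on the emitted additive distances recovers the planted topology
  tr <- neighbor_joining(fam$distances)
  d2 <- ape::cophenetic.phylo(tr)[rownames(fam$distances),
                                  colnames(fam$distances)]
  expect_lt(max(abs(d2 - fam$distances)), 1e-9)
})

test_that("generated files round-trip through the package readers", {
  cfg <- sim_config(seed = 57, n_ogs = 60, n_genes_expr = 30, n_de_genes = 20,
                    n_pathway = 8, n_core = 4, n_tf = 6, n_seed_tf = 2,
                    n_regulators = 2, n_promoters = 4, n_families = 1)
  st <- simulate_study(cfg)
  # groups dialect
  gp <- tempfile()
  write_groups(st$ogs, gp)
  back <- read_groups(gp)
  expect_setequal(back$gene_id, st$ogs$gene_id)
  expect_equal(length(unique(back$og_id)), length(unique(st$ogs$og_id)))
  # FASTA
  fp <- tempfile(fileext = ".fa")
  write_fasta(st$promoters, fp)
  expect_equal(read_fasta(fp), st$promoters)
  # OBO
  op <- tempfile(fileext = ".obo")
  writeLines(st$obo_lines, op)
  ont <- parse_obo(op)
  expect_equal(ont$terms, st$ontology$terms)
  # newick
  np <- tempfile(fileext = ".nwk")
  write_newick(st$families[[1]]$tree, np)
  expect_equal(sort(read_newick(np)$tip.label),
               sort(st$families[[1]]$tree$tip.label))
})
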