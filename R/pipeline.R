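#' Default GO "processes of interest" for the candidate filter
#'
#' Carbohydrate metabolic process, lipid metabolic process, transport,
#' signal transduction, catabolic process and protein metabolic process —
#' the biological processes plausibly feeding carbon into seed lipid
#' synthesis.
#'
#' @return Character vector of GO ids.
#' @export
default_interest_terms <- function() {
  c("GO:0005975", "GO:0006629", "GO:0006810",
    "GO:0007165", "GO:0009056", "GO:0019538")
}

#' Run the candidate-gene pipeline on a synthetic study
#'
#' Chains the full inference: lineage classification of the OG table,
#' expressed-gene filtering and MCL expression clustering, selection of the
#' clusters peaking in the oil-accumulation window, GO interest filtering,
#' PLC candidate prediction against the pathway genes, up-regulation
#' screens of the core enzymes, TF co-expression screens, Fisher-exact
#' differential expression between the high-oil and each low-oil accession,
#' and the validating intersections. Every resulting gene set is recorded
#' in a candidate ledger with its provenance (rule and thresholds).
#'
#' @param config A `sim_config` describing the synthetic study.
#' @param study Optionally a pre-generated [simulate_study()] result (so a
#'   study can be shared across runs); default generates from `config`.
#' @param min_rpkm Expressed-gene threshold (default 1).
#' @param cor_threshold Expression-graph |r| threshold (default 0.7).
#' @param plc_p,plc_min_partners PLC thresholds (default 1e-4, 2).
#' @param tf_permissive_p,tf_permissive_partners Known-TF screen thresholds
#'   (default 0.05, 11).
#' @param de_alpha DE significance level (default 0.01).
#' @param cluster_selection `"peak"` (clusters whose mean profile peaks in
#'   the window; default) or an integer vector of cluster indices.
#' @return An object of class `candidate_ledger`: list with `sets` (named
#'   list of sorted gene-id vectors), `provenance` (named list of one-line
#'   rule descriptions), plus `clustering`, `de`, `report_tables` and
#'   `config` components for audit.
#' @export
run_pipeline <- function(config = sim_config(), study = NULL,
                         min_rpkm = 1, cor_threshold = 0.7,
                         plc_p = 1e-4, plc_min_partners = 2,
                         tf_permissive_p = 0.05, tf_permissive_partners = 11,
                         de_alpha = 0.01,
                         cluster_selection = "peak") {
  if (is.null(study)) study <- simulate_study(config)
  genes <- study$genes

  # --- lineage-specific genes of the focal species
  og_class <- classify_og_table(study$ogs, config$panel)
  ds <- lineage_specific_genes(study$ogs, config$panel, "dicot_specific")
  dicot_specific <- sort(intersect(ds[[config$panel$focal_species]],
                                   genes$gene_id))
  pathway <- sort(genes$gene_id[genes$is_pathway])
  core <- sort(genes$gene_id[genes$is_core])
  tfs <- sort(genes$gene_id[genes$is_tf])

  # --- expression: filter, profiles, clustering
  expressed <- expressed_filter(study$expression, min_rpkm = min_rpkm)
  prof <- stage_profiles(study$expression, log2p1 = TRUE)
  cl <- cluster_expression(prof[expressed, , drop = FALSE],
                           threshold = cor_threshold)
  window <- oil_window_stages()
  if (identical(cluster_selection, "peak")) {
    peaks <- colnames(cl$profiles)[apply(cl$profiles, 1, which.max)]
    sel_clusters <- which(peaks %in% window)
  } else {
    sel_clusters <- as.integer(cluster_selection)
  }
  clusters_3_5 <- sort(unlist(cl$clusters$clusters[sel_clusters]))

  # --- GO filter on the selected clusters (pathway members set aside)
  candidates_raw <- setdiff(clusters_3_5, pathway)
  closure <- propagate_annotations(study$annotations, study$ontology)
  interest_genes <- unique(closure$gene_id[closure$term_id %in%
                                             study$interest_terms])
  go_filtered <- sort(intersect(candidates_raw, interest_genes))

  # --- PLC candidate prediction
  plc <- plc_candidates(prof, go_filtered, pathway,
                        p_thresh = plc_p, min_partners = plc_min_partners)
  plc_pass <- sort(plc$gene[plc$passes])
  plc_dicot <- sort(intersect(plc_pass, dicot_specific))

  # --- up-regulation screens of the core enzymes
  up1 <- upregulated(prof[core, , drop = FALSE], window, fold = 1)
  up2 <- upregulated(prof[core, , drop = FALSE], window, fold = 2)

  # --- TF screens
  tf_stringent <- tf_screen(prof, tfs, core, p_thresh = plc_p,
                            min_partners = plc_min_partners)
  tf_plc <- sort(tf_stringent$gene[tf_stringent$passes])
  tf_prof <- prof[intersect(tf_plc, rownames(prof)), , drop = FALSE]
  tf_up <- names(which(upregulated(tf_prof, window, fold = 2)))
  tf_seed <- sort(intersect(tf_up, study$seed_tf_list))

  # --- differential expression between high-oil and the two low-oil
  degs1 <- call_degs(study$counts$HD5, study$counts$LO1,
                     lib_a = study$lib_sizes["HD5", ],
                     lib_b = study$lib_sizes["LO1", ], alpha = de_alpha)
  degs2 <- call_degs(study$counts$HD5, study$counts$LO2,
                     lib_a = study$lib_sizes["HD5", ],
                     lib_b = study$lib_sizes["LO2", ], alpha = de_alpha)
  common <- common_degs(degs1, degs2)

  sets <- list(
    dicot_specific = dicot_specific,
    pathway_orthologs = pathway,
    pathway_dicot_specific = sort(intersect(pathway, dicot_specific)),
    clusters_3_5 = clusters_3_5,
    go_filtered = go_filtered,
    plc_candidates = plc_dicot,
    core_upregulated_1x = sort(names(which(up1))),
    core_upregulated_2x = sort(names(which(up2))),
    tf_plc = tf_plc,
    tf_dicot_specific = sort(intersect(tf_plc, dicot_specific)),
    tf_upregulated = sort(tf_up),
    tf_seed_specific = tf_seed,
    degs_pair1 = degs1$degs,
    degs_pair2 = degs2$degs,
    degs_common = common$common,
    validated_candidates = sort(intersect(plc_dicot, common$common)),
    validated_tfs = sort(intersect(tf_plc, common$common))
  )
  provenance <- list(
    dicot_specific = "focal-species genes in OGs with all dicots present and no grass gene",
    pathway_orthologs = "acyl-lipid pathway membership transferred by orthology (simulated flags)",
    pathway_dicot_specific = "pathway_orthologs intersect dicot_specific",
    clusters_3_5 = sprintf("MCL clusters (|r|>%g graph) whose mean profile peaks in stages %s",
                           cor_threshold, paste(window, collapse = "/")),
    go_filtered = "clusters_3_5 minus pathway, annotated to an interest GO process (closure)",
    plc_candidates = sprintf("dicot-specific genes with >=%d pathway partners at p<%g",
                             plc_min_partners, plc_p),
    core_upregulated_1x = "core genes with window max >= 1x overall stage mean",
    core_upregulated_2x = "core genes with window max >= 2x overall stage mean",
    tf_plc = sprintf("TFs with >=%d core partners at p<%g", plc_min_partners, plc_p),
    tf_dicot_specific = "tf_plc intersect dicot_specific",
    tf_upregulated = "tf_plc with window max >= 2x overall stage mean",
    tf_seed_specific = "tf_upregulated intersect seed-specific TF list",
    degs_pair1 = sprintf("Fisher exact p<%g in >=1 stage, HD5 vs LO1", de_alpha),
    degs_pair2 = sprintf("Fisher exact p<%g in >=1 stage, HD5 vs LO2", de_alpha),
    degs_common = "degs_pair1 intersect degs_pair2",
    validated_candidates = "plc_candidates intersect degs_common",
    validated_tfs = "tf_plc intersect degs_common"
  )
  structure(
    list(
      sets = sets,
      provenance = provenance,
      og_class = og_class,
      expressed = sort(expressed),
      clustering = cl,
      selected_clusters = sel_clusters,
      plc = plc,
      tf_table = tf_stringent,
      de = list(pair1 = degs1, pair2 = degs2),
      config_seed = config$seed,
      thresholds = list(min_rpkm = min_rpkm, cor_threshold = cor_threshold,
                        plc_p = plc_p, plc_min_partners = plc_min_partners,
                        tf_permissive_p = tf_permissive_p,
                        tf_permissive_partners = tf_permissive_partners,
                        de_alpha = de_alpha)
    ),
    class = "candidate_ledger"
  )
}

#' @export
print.candidate_ledger <- function(x, ...) {
  cat("candidate_ledger (seed ", x$config_seed, "):\n", sep = "")
  for (nm in names(x$sets)) {
    cat(sprintf("  %-24s %5d genes\n", nm, length(x$sets[[nm]])))
  }
  invisible(x)
}

#' Serialise a candidate ledger to JSON
#'
#' Gene sets are written sorted, with provenance and thresholds, so two
#' runs with the same configuration produce byte-identical files.
#'
#' @param ledger A `candidate_ledger`.
#' @param path Output path.
#' @return The path, invisibly; with `path = NULL` the JSON string.
#' @export
write_ledger_json <- function(ledger, path = NULL) {
  payload <- list(
    seed = ledger$config_seed,
    thresholds = ledger$thresholds,
    sets = lapply(ledger$sets, as.character),
    provenance = ledger$provenance,
    set_sizes = lapply(ledger$sets, length)
  )
  json <- jsonlite::toJSON(payload, pretty = TRUE, auto_unbox = TRUE,
                           digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Percentage in the reporting convention
#'
#' `format_pct(1534, 29095)` prints `"5.27%"` — two decimals of the
#' percentage of `k` within `n`.
#'
#' @param k,n Numerator and denominator counts.
#' @return Character string.
#' @export
format_pct <- function(k, n) sprintf("%.2f%%", 100 * k / n)

#' Human-readable pipeline report
#'
#' Per-set counts with percentages against their natural universe, the
#' thresholds in force, and set-algebra audit lines showing that every
#' reported intersection is contained in its operands.
#'
#' @param ledger A `candidate_ledger`.
#' @return Character vector of report lines (also printed invisibly by
#'   `cat` when `print = TRUE`).
#' @param print Print the report to the console (default `FALSE`).
#' @export
make_report <- function(ledger, print = FALSE) {
  s <- ledger$sets
  n_of <- function(nm) length(s[[nm]])
  lines <- c(
    sprintf("candidate-gene pipeline report (seed %s)", ledger$config_seed),
    sprintf("thresholds: %s",
            paste(names(ledger$thresholds), unlist(ledger$thresholds),
                  sep = "=", collapse = ", ")),
    ""
  )
  universe <- list(
    pathway_dicot_specific = "pathway_orthologs",
    go_filtered = "clusters_3_5",
    plc_candidates = "go_filtered",
    core_upregulated_1x = NULL, core_upregulated_2x = NULL,
    tf_dicot_specific = "tf_plc", tf_upregulated = "tf_plc",
    tf_seed_specific = "tf_upregulated",
    degs_common = "degs_pair1",
    validated_candidates = "plc_candidates",
    validated_tfs = "tf_plc"
  )
  for (nm in names(s)) {
    k <- n_of(nm)
    u <- universe[[nm]]
    lines <- c(lines, if (!is.null(u) && n_of(u) > 0) {
      sprintf("%-24s %5d (%s of %s)", nm, k, format_pct(k, n_of(u)), u)
    } else {
      sprintf("%-24s %5d", nm, k)
    })
  }
  audits <- c(
    all(s$pathway_dicot_specific %in% s$pathway_orthologs),
    all(s$pathway_dicot_specific %in% s$dicot_specific),
    all(s$go_filtered %in% s$clusters_3_5),
    all(s$plc_candidates %in% s$dicot_specific),
    all(s$degs_common %in% s$degs_pair1),
    all(s$degs_common %in% s$degs_pair2),
    all(s$validated_candidates %in% s$plc_candidates),
    all(s$validated_candidates %in% s$degs_common),
    all(s$validated_tfs %in% s$tf_plc),
    all(s$tf_seed_specific %in% s$tf_upregulated)
  )
  lines <- c(lines, "",
             sprintf("set-algebra audit: %d/%d containments hold",
                     sum(audits), length(audits)))
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
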