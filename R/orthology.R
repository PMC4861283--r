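#' Species panel for lineage classification
#'
#' A species panel maps short species codes to lineages (dicot or grass) and
#' names the focal species whose genes the downstream pipeline analyses.
#'
#' @param species Character vector of species codes.
#' @param lineage Character vector, same length, each `"dicot"` or `"grass"`.
#' @param focal_species Code of the focal species (default first dicot).
#' @return An object of class `species_panel`.
#' @export
species_panel <- function(species, lineage, focal_species = NULL) {
  stopifnot(length(species) == length(lineage))
  if (!all(lineage %in% c("dicot", "grass"))) {
    stop("lineage must be 'dicot' or 'grass'")
  }
  if (anyDuplicated(species)) stop("duplicate species codes")
  if (!any(lineage == "dicot") || !any(lineage == "grass")) {
    stop("panel needs at least one species per lineage")
  }
  if (is.null(focal_species)) focal_species <- species[lineage == "dicot"][1]
  if (!focal_species %in% species) stop("focal_species not in panel")
  structure(
    list(species = species,
         lineage_of = stats::setNames(lineage, species),
         focal_species = focal_species),
    class = "species_panel"
  )
}

#' Default 7-species panel: four high-oil dicots, three low-oil grasses
#'
#' Codes: Gma (soybean), Gra (cotton D genome), Rco (castor bean),
#' Ath (Arabidopsis); Sbi (sorghum), Sit (foxtail millet), Osa (rice).
#' Soybean is the focal species.
#'
#' @return A `species_panel`.
#' @export
default_species_panel <- function() {
  species_panel(
    species = c("Gma", "Gra", "Rco", "Ath", "Sbi", "Sit", "Osa"),
    lineage = c(rep("dicot", 4), rep("grass", 3)),
    focal_species = "Gma"
  )
}

#' Read / write an ortholog-group table in the groups dialect
#'
#' One OG per line: `OG0001: Gma|GmaG00001 Ath|AthG00002 ...`. The in-memory
#' representation is a long data frame with columns og_id, species, gene_id.
#'
#' @param path File path.
#' @return For `read_groups`, a data frame (og_id, species, gene_id).
#' @export
read_groups <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ":", fixed = TRUE)
  og_id <- trimws(vapply(parts, `[`, character(1), 1))
  members <- strsplit(trimws(vapply(parts, `[`, character(1), 2)), "[ \t]+")
  n <- lengths(members)
  memb <- unlist(members)
  sp_gene <- strsplit(memb, "|", fixed = TRUE)
  data.frame(
    og_id = rep(og_id, n),
    species = vapply(sp_gene, `[`, character(1), 1),
    gene_id = vapply(sp_gene, `[`, character(1), 2),
    stringsAsFactors = FALSE
  )
}

#' @param ogs OG data frame (og_id, species, gene_id).
#' @rdname read_groups
#' @export
write_groups <- function(ogs, path) {
  tok <- paste0(ogs$species, "|", ogs$gene_id)
  by_og <- split(tok, ogs$og_id)
  by_og <- by_og[order(names(by_og))]
  writeLines(paste0(names(by_og), ": ", vapply(by_og, paste, character(1),
                                               collapse = " ")), path)
  invisible(path)
}

#' Keep the longest protein isoform per gene
#'
#' For genes with multiple transcript records, only the record with the
#' maximal sequence length is retained; ties are broken by the
#' lexicographically smallest transcript id.
#'
#' @param records Data frame with columns gene_id, transcript_id, sequence
#'   (or a `length` column in place of sequence).
#' @return The input rows reduced to one per gene.
#' @export
select_longest_isoform <- function(records) {
  stopifnot(all(c("gene_id", "transcript_id") %in% names(records)))
  if (nrow(records) == 0L) {
    warning("empty isoform table")
    return(records)
  }
  len <- if ("length" %in% names(records)) records$length else nchar(records$sequence)
  ord <- order(records$gene_id, -len, records$transcript_id)
  records <- records[ord, , drop = FALSE]
  records[!duplicated(records$gene_id), , drop = FALSE]
}

#' Classify an ortholog group by its lineage-specificity
#'
#' The dicot-specific rule: an OG is dicot-specific when every dicot species
#' of the panel is represented and no grass gene is present; grass-specific
#' is the symmetric rule. OGs with genes in both lineages are `shared`.
#' Single-lineage OGs missing at least one species of their lineage are
#' `dicot_partial` / `grass_partial`; anything else (e.g. one-species OGs in
#' a one-species lineage) is `other`. Classification depends only on the set
#' of species present, never on member order or gene multiplicity.
#'
#' @param species_present Character vector of species codes present in the
#'   OG (repetitions allowed).
#' @param panel A `species_panel`.
#' @return One of `"dicot_specific"`, `"grass_specific"`, `"shared"`,
#'   `"dicot_partial"`, `"grass_partial"`, `"other"`.
#' @export
classify_og <- function(species_present, panel) {
  sp <- unique(as.character(species_present))
  if (length(sp) == 0L) stop("empty ortholog group")
  unknown <- setdiff(sp, panel$species)
  if (length(unknown)) stop("species not in panel: ", paste(unknown, collapse = ", "))
  lin <- panel$lineage_of[sp]
  dic <- panel$species[panel$lineage_of == "dicot"]
  gra <- panel$species[panel$lineage_of == "grass"]
  has_d <- any(lin == "dicot")
  has_g <- any(lin == "grass")
  if (has_d && has_g) return("shared")
  if (has_d) {
    if (all(dic %in% sp)) return("dicot_specific")
    return("dicot_partial")
  }
  if (all(gra %in% sp)) return("grass_specific")
  "grass_partial"
}

#' Classify every OG in a table
#'
#' @param ogs OG data frame (og_id, species, gene_id).
#' @param panel A `species_panel`.
#' @return Named character vector: class per og_id (sorted by og_id).
#' @export
classify_og_table <- function(ogs, panel) {
  sp_by_og <- split(ogs$species, ogs$og_id)
  vapply(sp_by_og, classify_og, character(1), panel = panel)
}

#' Per-species gene lists for a lineage-specificity class
#'
#' @param ogs OG data frame (og_id, species, gene_id).
#' @param panel A `species_panel`.
#' @param target_class A classification label, e.g. `"dicot_specific"`.
#' @return Named list: for each species of the panel, the sorted vector of
#'   its genes in OGs of the target class.
#' @export
lineage_specific_genes <- function(ogs, panel, target_class = "dicot_specific") {
  cls <- classify_og_table(ogs, panel)
  sel <- ogs[ogs$og_id %in% names(cls)[cls == target_class], , drop = FALSE]
  out <- lapply(panel$species, function(sp) sort(unique(sel$gene_id[sel$species == sp])))
  stats::setNames(out, panel$species)
}

#' Build ortholog groups from a similarity graph via MCL
#'
#' Each MCL cluster of size >= 2 becomes an OG; singleton clusters and
#' isolated proteins are reported separately, not as OGs. Gene identifiers
#' must be prefixed `species|gene` or carry species in a metadata table.
#'
#' @param graph Symmetric non-negative similarity graph (matrix, sparse
#'   matrix, or 3-column edge data frame) over `species|gene` node ids.
#' @param panel A `species_panel`.
#' @param inflation,... Passed to [mcl()].
#' @return List with `ogs` (og_id, species, gene_id data frame) and
#'   `singletons` (character vector of node ids outside any OG).
#' @export
build_ogs <- function(graph, panel, inflation = 1.5, ...) {
  adj <- as_adjacency(graph)
  if (nrow(adj) == 0L) {
    return(list(ogs = data.frame(og_id = character(), species = character(),
                                 gene_id = character()),
                singletons = character()))
  }
  cs <- mcl(adj, inflation = inflation, ...)
  sizes <- lengths(cs$clusters)
  ogc <- cs$clusters[sizes >= 2]
  singles <- c(unlist(cs$clusters[sizes < 2]), cs$unclustered)
  if (length(ogc) == 0L) {
    return(list(ogs = data.frame(og_id = character(), species = character(),
                                 gene_id = character()),
                singletons = sort(singles)))
  }
  og_id <- sprintf("OG%04d", seq_along(ogc))
  memb <- unlist(ogc)
  sp_gene <- strsplit(memb, "|", fixed = TRUE)
  species <- vapply(sp_gene, `[`, character(1), 1)
  gene <- vapply(sp_gene, function(x) paste(x[-1], collapse = "|"), character(1))
  unknown <- setdiff(unique(species), panel$species)
  if (length(unknown)) stop("species not in panel: ", paste(unknown, collapse = ", "))
  list(
    ogs = data.frame(og_id = rep(og_id, lengths(ogc)), species = species,
                     gene_id = gene, stringsAsFactors = FALSE),
    singletons = sort(singles)
  )
}
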