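#' AW-box consensus (WRI1 binding site)
#'
#' The 14-bp AW-box CNTNG(N)7CG: five fixed positions (C, T, G, C, G)
#' interleaved with unconstrained positions.
#'
#' @return The IUPAC consensus string.
#' @export
awbox_pattern <- function() "CNTNGNNNNNNNCG"

# IUPAC code -> base set. Pattern N matches any base including an ambiguous
# N in the subject; every other code matches only its real bases, so a
# subject N can never satisfy a fixed position.
iupac_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGTN]")
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(map))
  if (length(bad)) stop("unsupported pattern symbols: ", paste(unique(bad), collapse = ", "))
  paste(map[chars], collapse = "")
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(seq, ""), function(x) paste(rev(x), collapse = ""),
                character(1)))
}

#' Scan a promoter sequence for AW-boxes
#'
#' Reports every (possibly overlapping) match of the motif on the forward
#' strand, and of its reverse complement when `both_strands` is set. Starts
#' are 0-based on the forward strand; an ambiguous N in the sequence never
#' matches a fixed pattern position.
#'
#' @param sequence A nucleotide string over A, C, G, T, N.
#' @param both_strands Also scan the reverse strand (default `FALSE`: the
#'   AW-box is a promoter-strand element).
#' @param pattern IUPAC consensus (default [awbox_pattern()]).
#' @return Data frame (start, strand, site), sorted by start; `site` is the
#'   forward-strand sequence at the hit.
#' @examples
#' scan_awbox("CATAGAAAAAAACG") # one hit at start 0
#' @export
scan_awbox <- function(sequence, both_strands = FALSE,
                       pattern = awbox_pattern()) {
  stopifnot(length(sequence) == 1L)
  seq <- toupper(sequence)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("non-nucleotide characters in sequence: ", paste(bad, collapse = ", "))
  }
  width <- nchar(pattern)
  rx <- sprintf("(?=%s)", iupac_regex(pattern))
  find_starts <- function(s) {
    m <- gregexpr(rx, s, perl = TRUE)[[1]]
    if (m[1] == -1) integer() else as.integer(m)
  }
  fwd <- find_starts(seq)
  hits <- data.frame(
    start = fwd - 1L,
    strand = rep("+", length(fwd)),
    site = if (length(fwd)) substring(seq, fwd, fwd + width - 1L) else character(),
    stringsAsFactors = FALSE
  )
  if (both_strands) {
    rc <- revcomp(seq)
    rev_hits <- find_starts(rc)
    L <- nchar(seq)
    if (length(rev_hits)) {
      start_fwd <- L - (rev_hits - 1L) - width # 0-based on forward strand
      hits <- rbind(hits, data.frame(
        start = start_fwd,
        strand = "-",
        site = substring(seq, start_fwd + 1L, start_fwd + width),
        stringsAsFactors = FALSE
      ))
    }
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Count AW-boxes per gene over a promoter set
#'
#' @param promoters Named character vector of promoter sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file whose headers are
#'   gene ids. Duplicate gene ids are an error.
#' @param both_strands Strand policy passed to [scan_awbox()].
#' @param pattern IUPAC consensus (default [awbox_pattern()]).
#' @return Data frame (gene_id, n_awbox) including zero-count genes, in
#'   input order, with the per-gene hit tables as attribute `"hits"`.
#' @export
count_awbox_per_gene <- function(promoters, both_strands = FALSE,
                                 pattern = awbox_pattern()) {
  if (is.character(promoters) && length(promoters) == 1L &&
      file.exists(promoters) && is.null(names(promoters))) {
    promoters <- read_fasta(promoters)
  }
  if (inherits(promoters, "XStringSet")) {
    promoters <- stats::setNames(as.character(promoters), names(promoters))
  }
  if (length(promoters) == 0L) {
    return(data.frame(gene_id = character(), n_awbox = integer()))
  }
  if (is.null(names(promoters)) || anyDuplicated(names(promoters))) {
    stop("promoters must have unique gene ids")
  }
  hits <- lapply(promoters, scan_awbox, both_strands = both_strands,
                 pattern = pattern)
  out <- data.frame(
    gene_id = names(promoters),
    n_awbox = vapply(hits, nrow, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "hits") <- hits
  out
}

#' Read / write FASTA as a named character vector
#'
#' Thin wrappers over Biostrings for plain sequence sets.
#'
#' @param path FASTA file path.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @param seqs Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}
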