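test_that("protein distances are definitional with pairwise deletion", {
  aln <- c(a = "MKVLITAGHE", b = "MKVLITAGHE")
  d <- protein_distance(aln, model = "p")
  expect_equal(d["a", "b"], 0)
  aln2 <- c(a = "AAAAAAAAAA", b = "AACCAAAAAA") # 2 mismatches of 10
  expect_equal(protein_distance(aln2, "p")["a", "b"], 0.2)
  expect_equal(protein_distance(aln2, "poisson")["a", "b"], -log(0.8))
  # gaps removed pairwise
  aln3 <- c(a = "AA--AAAAAA", b = "AACCAAAAAA") # 8 comparable, 0 mismatch
  expect_equal(protein_distance(aln3, "p")["a", "b"], 0)
  expect_error(protein_distance(c(a = "----", b = "AAAA")), "comparable")
  expect_error(protein_distance(c(a = "AAA", b = "AAAA")), "aligned")
})

test_that("the hand-built additive 4-taxon matrix is reconstructed exactly", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  # split AB|CD with internal edge 1 and leaf edges 1,2,3,4
  expect_lt(max(abs(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]] - d)),
            1e-12)
  bp <- ape::prop.part(tr)
  pair_ab <- any(vapply(bp, function(x) {
    setequal(tr$tip.label[x], c("A", "B")) ||
      setequal(tr$tip.label[x], c("C", "D"))
  }, logical(1)))
  expect_true(pair_ab)
  edge_len <- stats::setNames(tr$edge.length,
                              c(tr$tip.label, rep(NA, tr$Nnode))[tr$edge[, 2]])
  expect_equal(unname(sort(edge_len[c("A", "B", "C", "D")])), c(1, 2, 3, 4))
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal, 1)
})

test_that("three taxa resolve to the unique star with exact edges", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(tr)[c("x", "y", "z"), c("x", "y", "z")],
               d, tolerance = 1e-12)
  expect_error(neighbor_joining(d[1:2, 1:2]), ">= 3")
})

test_that("random additive matrices are reconstructed to 1e-9 and order-invariant", {
  set.seed(40)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(tr0)
    tr <- neighbor_joining(d)
    d2 <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_lt(max(abs(d2 - d)), 1e-9)
    # taxon input order does not change the reconstructed metric
    perm <- sample(n)
    tr_p <- neighbor_joining(d[perm, perm])
    d3 <- ape::cophenetic.phylo(tr_p)[rownames(d), colnames(d)]
    expect_lt(max(abs(d3 - d)), 1e-9)
  }
})

test_that("species-overlap duplication labeling matches planted truth", {
  # hand case: ((gma_1, ath_1), (gma_2, ath_2)) root is a duplication
  tr <- read_newick(text = "((gma_1:1,ath_1:1):1,(gma_2:1,ath_2:1):1);")
  out <- label_duplications(tr)
  expect_equal(out$n_duplications, 1)
  root_event <- out$events$event[out$events$node ==
                                   length(out$tree$tip.label) + 1]
  expect_equal(root_event, "D")
  # congruent with the species tree: zero duplications
  tr2 <- read_newick(text = "((gma_1:1,ath_1:1):1,(osa_1:1,sbi_1:1):1);")
  expect_equal(label_duplications(tr2)$n_duplications, 0)
  expect_error(label_duplications(
    read_newick(text = "((gma_1:1,ath1:1):1,(osa_1:1,sbi_1:1):1);")),
    NA) # 'ath1' still yields a tag ('ath1'); no error
  # simulated families at zero loss: labels match the generator's truth
  cfg <- sim_config(seed = 41, family_dup_rate = 0.6, family_loss_rate = 0)
  for (k in 1:5) {
    fam <- simulate_family(cfg, family_id = k)
    if (is.null(fam$tree) || length(fam$tree$tip.label) < 3) next
    bare <- fam$tree
    true_events <- bare$node.label
    bare$node.label <- NULL
    out <- label_duplications(bare)
    expect_equal(out$tree$node.label, true_events, info = paste("family", k))
    expect_equal(out$n_duplications, fam$truth$n_duplications)
  }
})

test_that("newick io round-trips topology, lengths and labels", {
  tr <- read_newick(text = "(A:1,B:2):0;")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 2))
  set.seed(42)
  big <- ape::rtree(50)
  big$node.label <- as.character(seq_len(big$Nnode))
  tmp <- tempfile(fileext = ".nwk")
  write_newick(big, tmp)
  back <- read_newick(tmp)
  expect_equal(as.numeric(suppressWarnings(ape::dist.topo(back, big))), 0)
  expect_equal(back$node.label, big$node.label)
  d1 <- ape::cophenetic.phylo(big)
  expect_equal(ape::cophenetic.phylo(back)[rownames(d1), colnames(d1)], d1,
               tolerance = 1e-9)
  expect_error(read_newick(text = "(((A:1;"))
})

test_that("bootstrap supports are percentages and saturate on clean signal", {
  set.seed(43)
  # 4 taxa, two tight clades separated by a long internal branch
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  anc <- sample(aa, 120, replace = TRUE)
  mut <- function(s, k) {
    idx <- sample(length(s), k)
    s[idx] <- vapply(s[idx], function(c) sample(setdiff(aa, c), 1), "")
    s
  }
  other <- mut(anc, 60)
  aln <- c(
    A1 = paste(mut(anc, 2), collapse = ""),
    A2 = paste(mut(anc, 2), collapse = ""),
    B1 = paste(mut(other, 2), collapse = ""),
    B2 = paste(mut(other, 2), collapse = "")
  )
  tr <- bootstrap_support(aln, n_reps = 100, seed = 7)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_gte(max(sup, na.rm = TRUE), 95)
  # n_reps = 1 can only give 0 or 100
  tr1 <- bootstrap_support(aln, n_reps = 1, seed = 8)
  sup1 <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 100)))
  # determinism given the seed
  tr2 <- bootstrap_support(aln, n_reps = 25, seed = 9)
  tr3 <- bootstrap_support(aln, n_reps = 25, seed = 9)
  expect_equal(tr2$node.label, tr3$node.label)
})
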