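test_that("rpkm is definitional, linear, and scale-invariant", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_error(rpkm(1, 0, 1e6), "gene_length")
  expect_error(rpkm(1, 100, 0), "library_size")
  # algebraic identity: sum(rpkm * length) = 1e9 when counts sum to library
  set.seed(1)
  counts <- rpois(50, 100)
  len <- sample(300:5000, 50)
  lib <- sum(counts)
  expect_equal(sum(rpkm(counts, len, lib) * len), 1e9)
  # invariance under joint scaling
  expect_equal(rpkm(counts, len, lib), rpkm(counts * 3, len, lib * 3))
})

test_that("expressed_filter honours the both-replicates rule", {
  v <- rbind(
    zero = rep(0, 6),
    one_rep = c(5, 0, 0, 0, 0, 0),   # rep1 stage1 only
    both = c(5, 0, 0, 5, 0, 0),      # both reps stage1
    late = c(0, 0, 2, 0, 0, 2)       # both reps stage3
  )
  em <- make_em(v)
  expect_setequal(expressed_filter(em, 1, TRUE), c("both", "late"))
  expect_setequal(expressed_filter(em, 1, FALSE), c("one_rep", "both", "late"))
})

test_that("up-regulation windows use the overall mean and are monotone in fold", {
  prof <- matrix(c(1, 1, 1, 4, 1, 1, 1), 1,
                 dimnames = list("g1", paste0("s", 1:7)))
  expect_true(upregulated(prof, "s4", fold = 2)[["g1"]]) # 4 >= 2 * 10/7
  flat <- matrix(rep(2, 7), 1, dimnames = list("g1", paste0("s", 1:7)))
  expect_false(upregulated(flat, "s4", fold = 2)[["g1"]])
  expect_true(upregulated(flat, "s4", fold = 1)[["g1"]]) # >= comparison
  expect_error(upregulated(prof, character()), "empty")
  # monotone: fold=2 set is a subset of fold=1 set on random profiles
  set.seed(2)
  rp <- matrix(rexp(700), 100, dimnames = list(sprintf("g%03d", 1:100),
                                               paste0("s", 1:7)))
  w <- c("s4", "s5", "s6")
  up1 <- upregulated(rp, w, 1)
  up2 <- upregulated(rp, w, 2)
  expect_true(all(names(which(up2)) %in% names(which(up1))))
})

test_that("correlation graph applies the strict absolute-value rule", {
  prof <- rbind(
    a = 1:7,
    b = 2 * (1:7) + 1,          # proportional: r = 1
    c = -(1:7) * 0.9 + 10,      # anti-correlated: r = -1
    d = c(5, 1, 4, 2, 6, 1, 7)  # unrelated
  )
  colnames(prof) <- paste0("s", 1:7)
  g <- correlation_graph(prof, 0.7)
  expect_equal(g["a", "b"], 1)
  expect_equal(g["a", "c"], 1) # |r| rule keeps anti-correlation
  expect_equal(g["a", "d"], 0)
  # threshold 1 with strict inequality leaves no edges
  g1 <- correlation_graph(prof, 1)
  expect_equal(sum(g1), 0)
  # constant profiles are excluded with a warning
  prof2 <- rbind(prof, e = rep(3, 7))
  expect_warning(correlation_graph(prof2, 0.7), "constant")
  # Pearson invariance under positive affine transform
  prof3 <- prof
  prof3["d", ] <- prof["d", ] * 4 + 2
  expect_equal(as.matrix(correlation_graph(prof3, 0.7)),
               as.matrix(correlation_graph(prof, 0.7)))
})

test_that("expression clustering recovers planted archetypes exactly at zero noise", {
  cfg <- sim_config(seed = 3, n_genes_expr = 160, sigma_gene = 0,
                    sigma_rep = 0, sigma_offset = 0)
  sim <- simulate_expression(cfg)
  prof <- stage_profiles(sim$expression, log2p1 = TRUE)
  cl <- cluster_expression(prof)
  truth <- sim$truth$cluster_label_by_gene
  common <- names(cl$labels)
  expect_equal(mclust::adjustedRandIndex(cl$labels[common], truth[common]), 1)
  expect_length(cl$clusters$unclustered, 0)
  # per-cluster mean profiles are emitted, one row per cluster
  expect_equal(nrow(cl$profiles), length(cl$clusters$clusters))
})

test_that("sample clustering matches a brute-force average-linkage oracle", {
  set.seed(4)
  v <- matrix(rexp(100 * 5, 1 / 50), 100, 5,
              dimnames = list(NULL, paste0("smp", 1:5)))
  hc <- sample_hclust(v)
  d <- as.matrix(1 - cor(log2(v + 1)))
  oracle <- naive_average_linkage(d)
  expect_equal(hc$height, oracle$heights, tolerance = 1e-12)
  # reconstruct merged member sets from hc$merge and compare step by step
  sets <- list()
  for (k in seq_len(nrow(hc$merge))) {
    grab <- function(idx) {
      if (idx < 0) hc$labels[-idx] else sets[[idx]]
    }
    sets[[k]] <- sort(c(grab(hc$merge[k, 1]), grab(hc$merge[k, 2])))
    expect_equal(sets[[k]], oracle$merges[[k]])
  }
})

test_that("identical samples merge at height zero", {
  v <- cbind(a = c(1, 5, 2, 8), b = c(1, 5, 2, 8), c = c(9, 1, 4, 2))
  hc <- sample_hclust(v, log2p1 = FALSE)
  expect_equal(min(hc$height), 0)
  expect_error(sample_hclust(cbind(a = rep(1, 4), b = c(1, 2, 3, 4)),
                             log2p1 = FALSE), "constant")
  # newick serialisation is produced
  expect_match(hclust_newick(hc), "^\\(.*\\);$")
})

test_that("accessions separate before stages when the accession effect dominates", {
  set.seed(5)
  n <- 200
  base <- rexp(n, 1 / 50)
  acc_eff <- list(A = rnorm(n, 0, 1.5), B = rnorm(n, 0, 1.5))
  cols <- list()
  for (acc in c("A", "B")) {
    for (stg in 1:3) {
      cols[[paste0(acc, stg)]] <-
        base * 2^(acc_eff[[acc]] + rnorm(n, 0, 0.1) + 0.05 * stg)
    }
  }
  v <- do.call(cbind, cols)
  hc <- sample_hclust(v)
  top <- stats::cutree(hc, k = 2)
  expect_equal(length(unique(top[c("A1", "A2", "A3")])), 1)
  expect_equal(length(unique(top[c("B1", "B2", "B3")])), 1)
  expect_false(top[["A1"]] == top[["B1"]])
})

test_that("expression matrices round-trip through the TSV pair", {
  cfg <- sim_config(seed = 6, n_genes_expr = 20)
  em <- simulate_expression(cfg)$expression
  vp <- tempfile(fileext = ".tsv")
  mp <- tempfile(fileext = ".tsv")
  write_expression(em, vp, mp)
  back <- read_expression(vp, mp)
  expect_equal(back$values, em$values, tolerance = 1e-8)
  expect_equal(back$sample_meta, em$sample_meta)
})
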