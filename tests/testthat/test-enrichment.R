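chain_obo <- c(
  "[Term]", "id: a", "name: root", "namespace: bp", "",
  "[Term]", "id: b", "name: mid", "namespace: bp", "is_a: a ! root", "",
  "[Term]", "id: c", "name: leaf", "namespace: bp", "is_a: b ! mid", ""
)

diamond_obo <- c(
  "[Term]", "id: a", "name: root", "namespace: bp", "subset: goslim_plant", "",
  "[Term]", "id: b", "name: left", "namespace: bp", "subset: goslim_plant",
  "is_a: a", "",
  "[Term]", "id: c", "name: right", "namespace: bp", "subset: goslim_plant",
  "is_a: a", "",
  "[Term]", "id: d", "name: bottom", "namespace: bp", "is_a: b", "is_a: c", ""
)

test_that("parse_obo builds chains and diamonds, skips obsolete, flags cycles", {
  ont <- parse_obo(chain_obo)
  expect_equal(sort(term_ancestors(ont, "c")), c("a", "b"))
  expect_equal(term_ancestors(ont, "a"), character())
  # empty input gives an empty ontology
  expect_equal(nrow(parse_obo(character())$terms), 0)
  # diamond ancestors are deduplicated
  ont2 <- parse_obo(diamond_obo)
  expect_equal(sort(term_ancestors(ont2, "d")), c("a", "b", "c"))
  # obsolete terms skipped with a warning
  obs <- c(chain_obo, "[Term]", "id: z", "name: gone", "is_obsolete: true", "")
  expect_warning(parse_obo(obs), "obsolete")
  # cycles are an error naming the cycle
  cyc <- c("[Term]", "id: a", "is_a: b", "", "[Term]", "id: b", "is_a: a", "")
  expect_error(parse_obo(cyc), "cycle")
})

test_that("annotation propagation follows the true-path rule and is idempotent", {
  ont <- parse_obo(chain_obo)
  ann <- data.frame(gene_id = c("g1", "g2"), term_id = c("c", "a"))
  closure <- propagate_annotations(ann, ont)
  expect_setequal(closure$term_id[closure$gene_id == "g1"], c("a", "b", "c"))
  expect_equal(closure$term_id[closure$gene_id == "g2"], "a")
  expect_equal(propagate_annotations(closure, ont), closure)
  expect_warning(propagate_annotations(
    data.frame(gene_id = "g", term_id = "nope"), ont), "unknown")
})

test_that("hypergeometric enrichment matches direct enumeration", {
  # N=20, K=5, n=5, k=4: upper tail = 76/15504
  ont <- parse_obo(chain_obo)
  universe <- sprintf("g%02d", 1:20)
  ann <- data.frame(gene_id = universe[1:5], term_id = "c")
  study <- universe[c(1:4, 20)] # 4 of the 5 annotated genes
  res <- hypergeom_enrich(study, universe, ann, ont, p_thresh = 1)
  expect_equal(res$p[res$term_id == "c"], 76 / 15504)
  expect_equal(res$k[res$term_id == "c"], 4)
  # direct enumeration oracle
  p_hand <- (choose(5, 4) * choose(15, 1) + choose(5, 5) * choose(15, 0)) /
    choose(20, 5)
  expect_equal(res$p[res$term_id == "c"], p_hand)
  # k = 0 gives p = 1, never below any threshold < 1
  res0 <- hypergeom_enrich(universe[6:10], universe, ann, ont, p_thresh = 1.1)
  expect_equal(res0$p[res0$term_id == "c"], 1)
  expect_equal(nrow(hypergeom_enrich(universe[6:10], universe, ann, ont,
                                     p_thresh = 0.01)), 0)
  # study = universe: nothing can be enriched
  resU <- hypergeom_enrich(universe, universe, ann, ont, p_thresh = 1.1)
  expect_true(all(resU$p == 1))
  expect_error(hypergeom_enrich(c(universe, "gX"), universe, ann, ont),
               "subset")
})

test_that("enrichment p agrees with a Monte-Carlo permutation estimate", {
  ont <- parse_obo(chain_obo)
  universe <- sprintf("g%02d", 1:20)
  ann <- data.frame(gene_id = universe[1:5], term_id = "c")
  study <- universe[c(1:4, 20)]
  res <- hypergeom_enrich(study, universe, ann, ont, p_thresh = 1)
  p_exact <- res$p[res$term_id == "c"]
  set.seed(14)
  nperm <- 1e4
  hits <- replicate(nperm, sum(sample(universe, 5) %in% universe[1:5]) >= 4)
  p_mc <- mean(hits)
  se <- sqrt(p_exact * (1 - p_exact) / nperm)
  expect_lt(abs(p_mc - p_exact), 3 * se)
})

test_that("slim summarisation maps to minimal slim ancestors", {
  ont <- parse_obo(diamond_obo)
  # d has two slim parents, neither ancestral to the other: mapped to both
  out <- goslim_summarize("d", ont)
  expect_setequal(out$slim_id, c("b", "c"))
  # a slim term maps to itself only
  expect_equal(goslim_summarize("b", ont)$slim_id, "b")
  # a term whose parent is slim maps to that slim only (not to the root)
  chain_slim <- c(
    "[Term]", "id: a", "name: root", "namespace: bp", "subset: goslim_plant", "",
    "[Term]", "id: b", "name: mid", "namespace: bp", "subset: goslim_plant",
    "is_a: a", "",
    "[Term]", "id: c", "name: leaf", "namespace: bp", "is_a: b", ""
  )
  ont2 <- parse_obo(chain_slim)
  expect_equal(goslim_summarize("c", ont2)$slim_id, "b")
  # no slim ancestor: namespace root bucket
  ont3 <- parse_obo(c(chain_obo, "[Term]", "id: s", "name: s",
                      "namespace: bp", "subset: goslim_plant", ""))
  expect_equal(goslim_summarize("c", ont3)$slim_id, "root:bp")
})

test_that("results are invariant to gene and term input order", {
  ont <- parse_obo(diamond_obo)
  universe <- sprintf("g%02d", 1:30)
  set.seed(15)
  ann <- data.frame(gene_id = sample(universe, 25, replace = TRUE),
                    term_id = sample(c("b", "c", "d"), 25, replace = TRUE))
  study <- universe[1:8]
  r1 <- hypergeom_enrich(study, universe, ann, ont, p_thresh = 1.1)
  r2 <- hypergeom_enrich(rev(study), rev(universe), ann[sample(25), ], ont,
                         p_thresh = 1.1)
  expect_equal(r1, r2)
})
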