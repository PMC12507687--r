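test_that("extant graphs encode contig adjacencies and orientation classes", {
  fx <- toy3()
  # orientation classes follow the strand pairs in contig order
  for (case in list(c("+", "+", "head_to_tail"), c("-", "-", "head_to_tail"),
                    c("+", "-", "head_to_head"), c("-", "+", "tail_to_tail"))) {
    gg <- mk_genome("S1", list(c(paste0("a1", case[1]), paste0("b1", case[2]))))
    E <- build_extant_graph(gg, fx$lin)
    expect_equal(infer_orientation(E), case[3])
  }
  # 5-gene contig: 4 edges, all degrees <= 2; no edges across contigs
  g5 <- mk_genome("S2", list(c("a2+", "b2+", "c2+"), c("x2+", "y2+")))
  lin5 <- suppressMessages(build_gene_lineage(fx$forest, fx$tree,
    list(S1 = fx$genomes$S1, S2 = g5, S3 = fx$genomes$S3)))
  E5 <- build_extant_graph(g5, lin5)
  expect_equal(nrow(E5), 3L)
  deg <- table(c(E5$g1, E5$g2))
  expect_true(all(deg <= 2))
})

test_that("bottom-up propagation matches the hand-simulated worked example", {
  fx <- toy3()
  syn <- run_core(fx$tree, fx$genomes, fx$lin, linearized = FALSE)
  a12 <- match("A12", fx$tree$labels); r <- match("R", fx$tree$labels)
  lab <- function(v) {
    E <- syn$edges[[v]]
    f <- function(u) sub("@.*", "", syn$lin$label[u])
    stats::setNames(E$weight, paste0(pmin(f(E$g1), f(E$g2)), "-", pmax(f(E$g1), f(E$g2))))
  }
  wA <- lab(a12)
  expect_setequal(names(wA), c("A-B", "B-C"))
  expect_equal(unname(wA[c("A-B", "B-C")]), c(2L, 2L))
  wR <- lab(r)
  expect_setequal(names(wR), c("A-B", "B-C", "A-C"))
  expect_equal(unname(wR["A-C"]), 1L)
  expect_equal(unname(wR["A-B"]), 2L)
  # supporting children: everything at R has single-child support
  expect_true(all(syn$edges[[r]]$nsupp == 1L))
  expect_true(all(syn$edges[[a12]]$nsupp == 2L))
})

test_that("gain bridging connects the flanks' parents with one weight-1 edge", {
  # S1: a1 - x1 - b1 with x1 species-specific; S2: a2 - b2
  tree <- read_species_tree("((S1,S2)A12,S3)R;")
  genomes <- list(S1 = mk_genome("S1", list(c("a1+", "x1+", "b1+"))),
                  S2 = mk_genome("S2", list(c("a2+", "b2+"))),
                  S3 = mk_genome("S3", list(c("a3+", "b3+"))))
  ox <- mk_orthoxml(
    list(S1 = c("a1", "b1", "x1"), S2 = c("a2", "b2"), S3 = c("a3", "b3")),
    paste0('<orthologGroup id="A"><property name="TaxRange" value="R"/>',
           '<geneRef id="a1"/><geneRef id="a2"/><geneRef id="a3"/></orthologGroup>',
           '<orthologGroup id="B"><property name="TaxRange" value="R"/>',
           '<geneRef id="b1"/><geneRef id="b2"/><geneRef id="b3"/></orthologGroup>'))
  lin <- build_gene_lineage(read_orthoxml(ox, tree), tree, genomes)
  syn <- run_core(tree, genomes, lin, linearized = FALSE)
  a12 <- match("A12", tree$labels)
  E <- syn$edges[[a12]]
  expect_equal(nrow(E), 1L)
  expect_equal(E$weight, 2L)   # bridged (1) + observed (1)
  expect_equal(E$nbridge, 1L)
  expect_equal(E$nsupp, 2L)
  expect_equal(infer_orientation(E), "head_to_tail")
  # a run at a contig end produces no bridge: S1: x1 - a1 (x1 unparented end)
  genomes2 <- genomes
  genomes2$S1 <- mk_genome("S1", list(c("x1+", "a1+"), c("b1+")))
  lin2 <- build_gene_lineage(read_orthoxml(ox, tree), tree, genomes2)
  syn2 <- run_core(tree, genomes2, lin2, linearized = FALSE)
  expect_equal(syn2$edges[[a12]]$nbridge, 0L)
})

test_that("duplicated child edges merge into one parental edge, weights summed", {
  # tandem copies in S1: p1a - q1 and q1 - p1b, both map to pair (P, Q) at A12
  tree <- read_species_tree("((S1,S2)A12,S3)R;")
  genomes <- list(S1 = mk_genome("S1", list(c("p1a+", "q1+", "p1b-"))),
                  S2 = mk_genome("S2", list(c("p2+", "q2+"))),
                  S3 = mk_genome("S3", list("z3+")))
  ox <- mk_orthoxml(
    list(S1 = c("p1a", "p1b", "q1"), S2 = c("p2", "q2"), S3 = "z3"),
    paste0('<orthologGroup id="P"><property name="TaxRange" value="A12"/>',
           '<paralogGroup><geneRef id="p1a"/><geneRef id="p1b"/></paralogGroup>',
           '<geneRef id="p2"/></orthologGroup>',
           '<orthologGroup id="Q"><property name="TaxRange" value="A12"/>',
           '<geneRef id="q1"/><geneRef id="q2"/></orthologGroup>'))
  lin <- build_gene_lineage(read_orthoxml(ox, tree), tree, genomes)
  syn <- run_core(tree, genomes, lin, linearized = FALSE)
  a12 <- match("A12", tree$labels)
  E <- syn$edges[[a12]]
  expect_equal(nrow(E), 1L)      # one merged P - Q edge
  expect_equal(E$weight, 3L)     # two S1 child edges + one S2 edge
  expect_true(E$dupsup)
  expect_equal(E$nsupp, 2L)
})

test_that("top-down filtering implements the parsimony rule with emergence", {
  fx <- toy3()
  syn <- run_core(fx$tree, fx$genomes, fx$lin, linearized = FALSE)
  r <- match("R", fx$tree$labels); a12 <- match("A12", fx$tree$labels)
  expect_true(all(!syn$retained[[r]]))          # single-child support everywhere
  expect_true(all(syn$retained[[a12]]))         # supported by S1 and S2
  expect_true(all(syn$emergence[[a12]] == a12))
  # extant edges: inherited ones date to A12, S3-specific to S3
  s1 <- match("S1", fx$tree$labels); s3 <- match("S3", fx$tree$labels)
  expect_true(all(syn$emergence[[s1]] == a12))
  expect_equal(syn$emergence[[s3]], s3)
})

test_that("adjacency observed in every leaf is retained everywhere, one leaf nowhere", {
  tree <- read_species_tree("(((S1,S2)A,S3)B,S4)R;")
  mk <- function(order_by_sp) lapply(order_by_sp, function(x) mk_genome(x$sp, x$ctg))
  genomes <- stats::setNames(lapply(1:4, function(i)
    mk_genome(paste0("S", i), list(c(sprintf("a%d+", i), sprintf("b%d+", i))))),
    paste0("S", 1:4))
  ox <- mk_orthoxml(
    list(S1 = c("a1", "b1"), S2 = c("a2", "b2"), S3 = c("a3", "b3"),
         S4 = c("a4", "b4")),
    paste0('<orthologGroup id="A"><property name="TaxRange" value="R"/>',
           paste(sprintf('<geneRef id="a%d"/>', 1:4), collapse = ""), '</orthologGroup>',
           '<orthologGroup id="B"><property name="TaxRange" value="R"/>',
           paste(sprintf('<geneRef id="b%d"/>', 1:4), collapse = ""), '</orthologGroup>'))
  lin <- build_gene_lineage(read_orthoxml(ox, tree), tree, genomes)
  syn <- run_core(tree, genomes, lin, linearized = FALSE)
  for (v in which(!tree$is_leaf)) expect_true(all(syn$retained[[v]]))
  expect_true(all(syn$emergence[[tree$root]] == tree$root))
  # same adjacency in S1 only: never retained ancestrally
  genomes2 <- genomes
  for (i in 2:4) genomes2[[i]] <- mk_genome(paste0("S", i),
    list(sprintf("a%d+", i), sprintf("b%d+", i)))
  lin2 <- build_gene_lineage(read_orthoxml(ox, tree), tree, genomes2)
  syn2 <- run_core(tree, genomes2, lin2, linearized = FALSE)
  for (v in which(!tree$is_leaf)) expect_true(all(!syn2$retained[[v]]))
  s1 <- match("S1", tree$labels)
  expect_equal(syn2$emergence[[s1]], s1)
})

test_that("filtering is invariant to reordering of clades in the newick", {
  g <- list(S1 = mk_genome("S1", list(c("a1+", "b1+", "c1+"))),
            S2 = mk_genome("S2", list(c("a2+", "b2+", "c2+"))),
            S3 = mk_genome("S3", list(c("a3+", "c3+"))))
  mk_syn <- function(nwk) {
    tree <- read_species_tree(nwk)
    ox <- mk_orthoxml(
      list(S1 = c("a1", "b1", "c1"), S2 = c("a2", "b2", "c2"), S3 = c("a3", "c3")),
      paste0('<orthologGroup id="A"><property name="TaxRange" value="R"/>',
             '<geneRef id="a1"/><geneRef id="a2"/><geneRef id="a3"/></orthologGroup>',
             '<orthologGroup id="B"><property name="TaxRange" value="R"/>',
             '<geneRef id="b1"/><geneRef id="b2"/></orthologGroup>',
             '<orthologGroup id="C"><property name="TaxRange" value="R"/>',
             '<geneRef id="c1"/><geneRef id="c2"/><geneRef id="c3"/></orthologGroup>'))
    lin <- build_gene_lineage(read_orthoxml(ox, tree), tree, g)
    run_core(tree, g, lin, linearized = FALSE)
  }
  s1 <- mk_syn("((S1,S2)A12,S3)R;")
  s2 <- mk_syn("(S3,(S2,S1)A12)R;")
  expect_identical(edge_pairs(s1, "A12"), edge_pairs(s2, "A12"))
  expect_identical(edge_pairs(s1, "R"), edge_pairs(s2, "R"))
})

test_that("linearization keeps the two best-supported neighbours", {
  # star: g with neighbours p (w5), q (w3), r (w1), all otherwise isolated
  E <- data.table::data.table(id = 1:3, g1 = c(1L, 1L, 1L), g2 = c(2L, 3L, 4L),
                              weight = c(5L, 3L, 1L), ht = c(5L, 3L, 1L),
                              hh = 0L, tt = 0L, nsupp = 2L, dupsup = FALSE,
                              nbridge = 0L)
  res <- linearize_graph(E)
  expect_equal(res$keep, c(TRUE, TRUE, FALSE))
  expect_equal(nrow(res$contigs), 3L)  # path q - g - p
  # already-linear input is unchanged (idempotence)
  E2 <- data.table::data.table(id = 1:2, g1 = c(1L, 2L), g2 = c(2L, 3L),
                               weight = c(2L, 7L), ht = 0L, hh = 0L, tt = 0L,
                               nsupp = 2L, dupsup = FALSE, nbridge = 0L)
  res2 <- linearize_graph(E2)
  expect_true(all(res2$keep))
  expect_equal(res2$contigs$uid, 1:3)
  # triangle weights 3, 2, 1: minimum-weight edge removed, one 3-gene contig
  E3 <- data.table::data.table(id = 1:3, g1 = c(1L, 2L, 1L), g2 = c(2L, 3L, 3L),
                               weight = c(3L, 2L, 1L), ht = 0L, hh = 0L, tt = 0L,
                               nsupp = 2L, dupsup = FALSE, nbridge = 0L)
  res3 <- linearize_graph(E3)
  expect_equal(res3$keep, c(TRUE, TRUE, FALSE))
  expect_equal(sort(unique(res3$contigs$uid)), 1:3)
  # exhaustive check of the triangle: removing the w1 edge maximizes kept weight
  # among all single-edge removals that linearize the graph
  for (drop in 1:3) {
    keep <- setdiff(1:3, drop)
    deg <- table(c(E3$g1[keep], E3$g2[keep]))
    expect_true(all(deg <= 2))  # any single removal linearizes a triangle
  }
  expect_equal(which(!res3$keep), which.min(E3$weight))
})

test_that("linear path weight decides among neighbours through chains", {
  # conflict at g(1): neighbour p(2) continues p - x (w10); neighbour q(3)
  # continues q - y (w1); neighbour r(4) isolated but direct w4.
  # path weights: via p = 2 + 10 = 12, via q = 3 + 1 = 4, via r = 4.
  # tie (q vs r) broken by larger direct edge weight -> r kept.
  E <- data.table::data.table(
    id = 1:5,
    g1 = c(1L, 1L, 1L, 2L, 3L),
    g2 = c(2L, 3L, 4L, 5L, 6L),
    weight = c(2L, 3L, 4L, 10L, 1L),
    ht = 0L, hh = 0L, tt = 0L, nsupp = 2L, dupsup = FALSE, nbridge = 0L)
  res <- linearize_graph(E)
  # q's chain q - y survives as its own contig; only the g - q edge is cut
  expect_equal(res$keep, c(TRUE, FALSE, TRUE, TRUE, TRUE))
})

test_that("orientation majority, ties and contig strand assignment", {
  expect_equal(infer_orientation(data.frame(ht = 5L, hh = 1L, tt = 0L)), "head_to_tail")
  expect_equal(infer_orientation(data.frame(ht = 0L, hh = 2L, tt = 2L)), "unknown")
  expect_equal(infer_orientation(data.frame(ht = 0L, hh = 0L, tt = 0L)), "unknown")
  # head_to_head flips strand: a(+) b(-) pattern
  E <- data.table::data.table(id = 1:2, g1 = c(1L, 2L), g2 = c(2L, 3L),
                              weight = 1L, ht = c(0L, 0L), hh = c(3L, 0L),
                              tt = c(0L, 3L), nsupp = 2L, dupsup = FALSE,
                              nbridge = 0L)
  res <- linearize_graph(E)
  expect_equal(res$contigs$strand, c("+", "-", "+"))
})

test_that("edge weights equal their recounted support closure", {
  p <- sim_params(n_leaves = 12, root_genes = 60, root_contigs = 3, seed = 21,
                  preset = "harsh")
  out <- sim_pipeline(p)
  syn <- out$res$syn
  rc <- recount_weights(syn)
  for (v in seq_along(syn$edges)) {
    E <- syn$edges[[v]]
    if (is.null(E) || !nrow(E)) next
    expect_identical(rc[[v]], E$weight)
  }
  # with no gene gains there is no bridging: closure is purely extant edges
  p0 <- sim_params(n_leaves = 10, root_genes = 50, root_contigs = 2, seed = 22,
                   rates = list(gain = 0, loss = 0.002, dup_tandem = 0.001,
                                dup_dispersed = 5e-04, inversion = 0.004,
                                translocation = 0.001))
  out0 <- sim_pipeline(p0)
  expect_true(all(vapply(seq_along(out0$res$syn$edges), function(v) {
    E <- out0$res$syn$edges[[v]]
    is.null(E) || !nrow(E) || all(E$nbridge == 0L)
  }, TRUE)))
})
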