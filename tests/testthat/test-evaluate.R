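test_that("gene mapping maximizes shared extant descendants", {
  dtb <- function(...) data.table::data.table(...)
  # identical descendant sets: identity mapping
  inf <- dtb(ext_key = c("a", "b", "c", "d"), anc = c(1L, 1L, 2L, 2L))
  tru <- dtb(ext_key = c("a", "b", "c", "d"), anc = c(10L, 10L, 20L, 20L))
  mp <- map_ancestral_genes(inf, tru)
  expect_equal(mp[order(inf)]$true, c(10L, 20L))
  expect_equal(mp$overlap, c(2L, 2L))
  # 5-vs-2 overlap: mapped to the larger
  inf2 <- dtb(ext_key = paste0("e", 1:7), anc = 1L)
  tru2 <- dtb(ext_key = paste0("e", 1:7), anc = c(rep(10L, 5), rep(20L, 2)))
  mp2 <- map_ancestral_genes(inf2, tru2)
  expect_equal(mp2$true[mp2$inf == 1L], 10L)
  # zero overlap stays unmapped
  mp3 <- map_ancestral_genes(dtb(ext_key = "x", anc = 1L),
                             dtb(ext_key = "y", anc = 9L))
  expect_equal(nrow(mp3), 0L)
  # independently coded naive greedy oracle on random instances
  set.seed(41)
  for (i in 1:30) {
    nx <- sample(5:30, 1)
    inf_r <- dtb(ext_key = paste0("k", 1:nx), anc = sample.int(5, nx, TRUE))
    tru_r <- dtb(ext_key = paste0("k", 1:nx), anc = sample.int(5, nx, TRUE) + 100L)
    got <- map_ancestral_genes(inf_r, tru_r)
    # oracle: repeated argmax over the overlap matrix
    ov <- table(inf_r$anc[match(tru_r$ext_key, inf_r$ext_key)], tru_r$anc)
    ov <- as.matrix(ov)
    pairs <- list()
    while (any(ov > 0)) {
      best <- which(ov == max(ov), arr.ind = TRUE)
      best <- best[order(as.integer(rownames(ov)[best[, 1]]),
                         as.integer(colnames(ov)[best[, 2]])), , drop = FALSE][1, ]
      pairs[[length(pairs) + 1L]] <- c(as.integer(rownames(ov)[best[1]]),
                                       as.integer(colnames(ov)[best[2]]),
                                       ov[best[1], best[2]])
      ov[best[1], ] <- 0L; ov[, best[2]] <- 0L
    }
    oracle <- do.call(rbind, pairs)
    got <- got[order(inf)]
    oracle <- oracle[order(oracle[, 1]), , drop = FALSE]
    expect_equal(got$inf, oracle[, 1])
    expect_equal(got$true, oracle[, 2])
    expect_equal(got$overlap, oracle[, 3])
  }
})

test_that("precision/recall formulas and boundary conventions", {
  dtb <- function(...) data.table::data.table(...)
  mp <- dtb(inf = 1:4, true = 11:14, overlap = 5L)
  # TP 9 FP 1 FN 3 analogue: construct 3 inferred edges, 1 false, 2 missed
  inf <- dtb(g1 = c(1L, 1L, 2L), g2 = c(2L, 3L, 4L))
  tru <- dtb(g1 = c(11L, 11L, 12L, 13L), g2 = c(12L, 13L, 13L, 14L))
  pr <- precision_recall(inf, tru, mp)
  expect_equal(pr$TP, 2L)   # (11,12) and (11,13) recovered
  expect_equal(pr$FP, 1L)   # (12,14) is not a true adjacency
  expect_equal(pr$FN, 2L)
  expect_equal(pr$precision, 100 * 2 / 3)
  expect_equal(pr$recall, 50)
  # arithmetic identity of the formulas
  pr2 <- precision_recall(dtb(g1 = rep(1L, 0), g2 = integer(0)), tru, mp)
  expect_true(is.na(pr2$precision))  # empty inference: undefined precision
  expect_equal(pr2$recall, 0)
  # against a naive set-comparison oracle on 100 random instances
  set.seed(51)
  for (i in 1:100) {
    ni <- sample(0:12, 1); nt <- sample(1:12, 1)
    genes <- 1:8
    mpx <- dtb(inf = genes, true = genes + 100L, overlap = 1L)
    mk <- function(n) {
      if (n == 0) return(dtb(g1 = integer(0), g2 = integer(0)))
      a <- sample(genes, n, TRUE); b <- sample(genes, n, TRUE)
      unique(dtb(g1 = pmin(a, b), g2 = pmax(a, b))[a != b])
    }
    infx <- mk(ni); trux <- mk(nt)[, .(g1 = g1 + 100L, g2 = g2 + 100L)]
    got <- precision_recall(infx, trux, mpx)
    # naive: string sets and loops
    tset <- paste(trux$g1, trux$g2)
    tp <- 0L
    for (j in seq_len(nrow(infx))) {
      key <- paste(infx$g1[j] + 100L, infx$g2[j] + 100L)
      if (key %in% tset) tp <- tp + 1L
    }
    expect_equal(got$TP, tp)
    expect_equal(got$FP, nrow(infx) - tp)
    expect_equal(got$FN, length(tset) - tp)
    if (nrow(infx)) expect_equal(got$precision, 100 * tp / nrow(infx))
    if (length(tset)) expect_equal(got$recall, 100 * tp / length(tset))
  }
})

test_that("harmonic mean follows the closed form and conventions", {
  expect_equal(harmonic_mean(c(50, 50, 50)), 50)
  expect_equal(harmonic_mean(c(100, 50)), 66.667, tolerance = 1e-4)
  set.seed(6)
  x <- stats::runif(9, 10, 100)
  expect_equal(harmonic_mean(x), harmonic_mean(sample(x)))
  expect_warning(z <- harmonic_mean(c(10, 0, 50)), "zero")
  expect_equal(z, 0)
  expect_message(harmonic_mean(c(NA, 50)), "dropping")
})

test_that("mapping and scoring are invariant to inferred uid relabeling", {
  p <- sim_params(n_leaves = 10, root_genes = 50, root_contigs = 3, seed = 23,
                  preset = "low_rearrangement")
  out <- sim_pipeline(p)
  ev1 <- evaluate_reconstruction(out$res$syn, out$truth)
  # relabel: shift all uids by a constant offset in a deep copy
  syn2 <- out$res$syn
  off <- 10000L
  syn2$edges <- lapply(syn2$edges, function(E) {
    if (is.null(E)) return(E)
    E <- data.table::copy(E); E[, `:=`(g1 = g1 + off, g2 = g2 + off)]; E
  })
  syn2$contigs <- lapply(syn2$contigs, function(ct) {
    if (is.null(ct)) return(ct)
    ct <- data.table::copy(ct); ct[, uid := uid + off]; ct
  })
  lin2 <- syn2$lin
  n <- length(lin2$node)
  pad <- function(x, fill) c(rep(fill, off), x)
  lin2 <- structure(list(
    node = pad(lin2$node, 1L), family = pad(lin2$family, 1L),
    parent = pad(ifelse(is.na(lin2$parent), NA_integer_, lin2$parent + off), NA_integer_),
    via_dup = pad(lin2$via_dup, FALSE), label = pad(lin2$label, ""),
    is_extant = pad(lin2$is_extant, FALSE),
    families = lin2$families,
    ext_uid = lin2$ext_uid + off, tree = lin2$tree), class = "lineage_forest")
  syn2$lin <- lin2
  ev2 <- evaluate_reconstruction(syn2, out$truth)
  expect_equal(ev1$per_level$precision, ev2$per_level$precision)
  expect_equal(ev1$per_level$recall, ev2$per_level$recall)
})

test_that("masked projection requires unique descendants on both sides", {
  # S3 masked: singleton contigs; ancestor edges project onto single-copy pairs
  tree <- read_species_tree("((S1,S2)A12,(S3,S4)A34)R;")
  genomes <- list(
    S1 = mk_genome("S1", list(c("a1+", "b1+"))),
    S2 = mk_genome("S2", list(c("a2+", "b2+"))),
    S3 = mk_genome("S3", list("a3+", "b3+")),   # masked: each gene a singleton
    S4 = mk_genome("S4", list(c("a4+", "b4+"))))
  ox <- mk_orthoxml(
    list(S1 = c("a1", "b1"), S2 = c("a2", "b2"), S3 = c("a3", "b3"),
         S4 = c("a4", "b4")),
    paste0('<orthologGroup id="A"><property name="TaxRange" value="R"/>',
           paste(sprintf('<geneRef id="a%d"/>', 1:4), collapse = ""), '</orthologGroup>',
           '<orthologGroup id="B"><property name="TaxRange" value="R"/>',
           paste(sprintf('<geneRef id="b%d"/>', 1:4), collapse = ""), '</orthologGroup>'))
  lin <- build_gene_lineage(read_orthoxml(ox, tree), tree, genomes)
  syn <- run_core(tree, genomes, lin)
  pred <- project_to_masked(syn, "S3")
  expect_equal(nrow(pred), 1L)
  expect_setequal(unlist(pred[1, ]), c("a3", "b3"))

  # whole-genome duplication on the masked branch: paralogues block projection
  genomes2 <- genomes
  genomes2$S3 <- mk_genome("S3", list("a3a+", "a3b+", "b3a+", "b3b+"))
  fam <- function(f) paste0(
    '<orthologGroup id="', toupper(f), '"><property name="TaxRange" value="R"/>',
    '<geneRef id="', f, '1"/><geneRef id="', f, '2"/>',
    '<orthologGroup><property name="TaxRange" value="A34"/>',
    '<geneRef id="', f, '4"/>',
    '<paralogGroup><geneRef id="', f, '3a"/><geneRef id="', f, '3b"/></paralogGroup>',
    '</orthologGroup></orthologGroup>')
  ox2 <- mk_orthoxml(
    list(S1 = c("a1", "b1"), S2 = c("a2", "b2"),
         S3 = c("a3a", "a3b", "b3a", "b3b"), S4 = c("a4", "b4")),
    paste0(fam("a"), fam("b")))
  lin2 <- build_gene_lineage(read_orthoxml(ox2, tree), tree, genomes2)
  syn2 <- run_core(tree, genomes2, lin2)
  expect_equal(nrow(project_to_masked(syn2, "S3")), 0L)
})
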