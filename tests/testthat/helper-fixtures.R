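# Fixture builders shared across the suite. Everything is generated in code;
# no data files ship with the package.

# gene table in read_gff() output format from a compact contig spec,
# e.g. mk_genome("S1", list(c("a1+", "b1-", "c1+"), c("d1+")))
mk_genome <- function(species, contigs) {
  rows <- list()
  for (k in seq_along(contigs)) {
    gs <- contigs[[k]]
    ids <- sub("[+-]$", "", gs)
    str <- substring(gs, nchar(gs))
    rows[[k]] <- data.frame(
      gene_id = ids, species = species, contig = paste0("c", k),
      start = 1000L * seq_along(gs) + 1L, end = 1000L * seq_along(gs) + 500L,
      strand = str, rank = seq_along(gs) - 1L, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

gff_text <- function(genome) {
  paste(c("##gff-version 3",
          sprintf("%s\tt\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  genome$contig, genome$start, genome$end, genome$strand,
                  genome$gene_id)),
        collapse = "\n")
}

# OrthoXML from declarations (list species -> gene ids) and a groups string
# written with gene ids (translated to numeric refs here)
mk_orthoxml <- function(decl, groups_xml) {
  ids <- unlist(decl, use.names = FALSE)
  num <- seq_along(ids)
  sp_blocks <- vapply(names(decl), function(sp) {
    g <- decl[[sp]]
    paste0(sprintf('<species name="%s"><database name="d" version="1"><genes>', sp),
           paste(sprintf('<gene id="%d" protId="%s"/>', num[match(g, ids)], g),
                 collapse = ""),
           '</genes></database></species>')
  }, "")
  for (i in seq_along(ids)) {
    groups_xml <- gsub(sprintf('geneRef id="%s"', ids[i]),
                       sprintf('geneRef id="%d"', num[i]), groups_xml, fixed = TRUE)
  }
  paste0('<?xml version="1.0"?><orthoXML xmlns="http://orthoXML.org/2011/" ',
         'version="0.3" origin="t" originVersion="1">',
         paste(sp_blocks, collapse = ""),
         '<groups>', groups_xml, '</groups></orthoXML>')
}

# the worked 3-species example: families A, B, C rooted at R, B lost in S3
toy3 <- function() {
  tree <- read_species_tree("((S1,S2)A12,S3)R;")
  genomes <- list(
    S1 = mk_genome("S1", list(c("a1+", "b1+", "c1+"))),
    S2 = mk_genome("S2", list(c("a2+", "b2+", "c2+"))),
    S3 = mk_genome("S3", list(c("a3+", "c3+"))))
  ox <- mk_orthoxml(
    list(S1 = c("a1", "b1", "c1"), S2 = c("a2", "b2", "c2"),
         S3 = c("a3", "c3")),
    paste0(
      '<orthologGroup id="A"><property name="TaxRange" value="R"/>',
      '<geneRef id="a1"/><geneRef id="a2"/><geneRef id="a3"/></orthologGroup>',
      '<orthologGroup id="B"><property name="TaxRange" value="R"/>',
      '<geneRef id="b1"/><geneRef id="b2"/></orthologGroup>',
      '<orthologGroup id="C"><property name="TaxRange" value="R"/>',
      '<geneRef id="c1"/><geneRef id="c2"/><geneRef id="c3"/></orthologGroup>'))
  forest <- read_orthoxml(ox, tree)
  lin <- build_gene_lineage(forest, tree, genomes)
  list(tree = tree, genomes = genomes, forest = forest, lin = lin)
}

# run propagation + filtering (+ optional linearization) on in-memory inputs
run_core <- function(tree, genomes, lin, linearized = TRUE, ...) {
  extant <- stats::setNames(
    lapply(names(genomes), function(sp) build_extant_graph(genomes[[sp]], lin)),
    names(genomes))
  syn <- propagate_bottom_up(tree, lin, extant)
  syn <- filter_top_down(syn, ...)
  if (linearized) syn <- linearize(syn, genomes)
  syn
}

# label pairs of edges at a node, optionally only retained ones
edge_pairs <- function(syn, node, retained_only = TRUE) {
  v <- match(node, syn$tree$labels)
  E <- syn$edges[[v]]
  if (is.null(E) || !nrow(E)) return(character(0))
  sel <- if (retained_only && !syn$tree$is_leaf[v]) syn$retained[[v]] else rep(TRUE, nrow(E))
  l1 <- syn$lin$label[E$g1[sel]]; l2 <- syn$lin$label[E$g2[sel]]
  fam1 <- syn$lin$families[syn$lin$family[E$g1[sel]]]
  fam2 <- syn$lin$families[syn$lin$family[E$g2[sel]]]
  sort(paste(pmin(fam1, fam2), pmax(fam1, fam2), sep = "--"))
}

# simulate, write truth to disk, run the file-based pipeline, evaluate
sim_pipeline <- function(params, out = tempfile(), infer_args = list()) {
  truth <- simulate_evolution(params)
  write_truth(truth, out)
  gd <- file.path(out, "gff"); dir.create(gd, showWarnings = FALSE)
  for (sp in truth$tree$labels[truth$tree$is_leaf]) {
    file.copy(file.path(out, paste0(sp, ".gff3")), file.path(gd, paste0(sp, ".gff3")),
              overwrite = TRUE)
  }
  cfg <- do.call(run_config, c(list(
    tree = file.path(out, "tree.nwk"), hogs = file.path(out, "hogs.orthoxml"),
    gff_dir = gd, out_dir = file.path(out, "out")), infer_args))
  res <- suppressMessages(run_infer(cfg))
  list(truth = truth, res = res, dir = out)
}
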