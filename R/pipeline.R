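#' Configuration for an inference run
#'
#' @param tree path to the rooted newick species tree.
#' @param hogs path to the OrthoXML file.
#' @param gff_dir directory holding one `<leaf label>.gff3` (or `.gff`) per
#'   species.
#' @param out_dir output directory.
#' @param age_table optional two-column TSV (node label, age in Ma).
#' @param feature_type,id_attr GFF3 selection (see [read_gff()]).
#' @param min_weight,min_completeness optional edge pre-filters (see
#'   [filter_top_down()]).
#' @param date whether to write the per-edge dating table and
#'   phylostratigraphy.
#' @return an object of class `run_config`.
#' @export
run_config <- function(tree, hogs, gff_dir, out_dir,
                       age_table = NULL, feature_type = "gene", id_attr = "ID",
                       min_weight = 0, min_completeness = 0, date = TRUE) {
  stopifnot(min_weight >= 0, min_completeness >= 0)
  structure(list(tree = tree, hogs = hogs, gff_dir = gff_dir,
                 out_dir = out_dir, age_table = age_table,
                 feature_type = feature_type, id_attr = id_attr,
                 min_weight = min_weight, min_completeness = min_completeness,
                 date = date),
            class = "run_config")
}

#' Run the full inference pipeline
#'
#' Reads the species tree, per-species GFF3s and OrthoXML HOGs,
#' cross-checks the species sets, builds the gene-lineage forest,
#' propagates adjacencies bottom-up, filters them top-down by parsimony,
#' linearizes every ancestral graph and (optionally) dates all adjacencies.
#' Per-node adjacency and contig TSVs, summary tables and a run manifest
#' are written under `config$out_dir`. The pipeline involves no random
#' numbers: identical inputs and configuration give identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `tree`, `lin`, `syn`, `genomes` and
#'   the paths written.
#' @export
run_infer <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tree <- read_species_tree(config$tree)
  leaves <- tree$labels[tree$is_leaf]

  gff_files <- list.files(config$gff_dir, pattern = "\\.gff3?$", full.names = TRUE)
  gff_sp <- sub("\\.gff3?$", "", basename(gff_files))
  miss_gff <- setdiff(leaves, gff_sp)
  extra_gff <- setdiff(gff_sp, leaves)
  if (length(miss_gff) || length(extra_gff)) {
    stop_input(sprintf("species mismatch between tree and GFF directory; missing GFF: [%s]; GFF without tree leaf: [%s]",
                       paste(miss_gff, collapse = ", "),
                       paste(extra_gff, collapse = ", ")))
  }
  genomes <- stats::setNames(
    lapply(seq_along(gff_files), function(i)
      read_gff(gff_files[i], gff_sp[i], config$feature_type, config$id_attr)),
    gff_sp)[leaves]

  forest <- read_orthoxml(config$hogs, tree)
  lin <- build_gene_lineage(forest, tree, genomes)

  extant <- stats::setNames(
    lapply(leaves, function(sp) build_extant_graph(genomes[[sp]], lin)), leaves)
  syn <- propagate_bottom_up(tree, lin, extant)
  syn <- filter_top_down(syn, min_weight = config$min_weight,
                         min_completeness = config$min_completeness)
  syn <- linearize(syn, genomes)
  check_linear(syn)
  check_emergence(syn)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (v in tree$preorder) {
    if (tree$is_leaf[v]) next
    paths <- c(paths, write_ancestral_genome(v, syn, config$out_dir))
  }
  if (isTRUE(config$date)) {
    ages <- NULL
    if (!is.null(config$age_table)) {
      ages <- utils::read.delim(config$age_table, header = FALSE,
                                col.names = c("node", "age"))
    }
    dt <- date_edges(syn, ages = ages)
    p <- file.path(config$out_dir, "edge_ages.tsv")
    data.table::fwrite(dt, p, sep = "\t")
    ps <- phylostratigraphy(syn)
    p2 <- file.path(config$out_dir, "phylostratigraphy.tsv")
    data.table::fwrite(ps, p2, sep = "\t")
    paths <- c(paths, p, p2)
  }
  cfg_rec <- unclass(config)[setdiff(names(config), "out_dir")]
  for (f in c("tree", "hogs", "gff_dir", "age_table")) {
    if (!is.null(cfg_rec[[f]])) cfg_rec[[f]] <- basename(cfg_rec[[f]])
  }
  sums <- tools::md5sum(c(config$tree, config$hogs, gff_files))
  names(sums) <- basename(names(sums))  # content-addressed, not path-addressed
  manifest <- list(
    package = "ancora",
    version = as.character(utils::packageVersion("ancora")),
    config = cfg_rec,
    inputs = as.list(sums),
    counts = list(
      species = length(leaves),
      genes_extant = sum(lin$is_extant),
      genes_ancestral = sum(!lin$is_extant),
      edges_total = sum(vapply(syn$edges, function(e) if (is.null(e)) 0L else nrow(e), 0L)),
      edges_retained = sum(vapply(which(!tree$is_leaf), function(v)
        sum(syn$retained[[v]]), 0L))
    )
  )
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  paths <- c(paths, mp)
  invisible(list(tree = tree, lin = lin, syn = syn, genomes = genomes,
                 paths = paths))
}

#' Write one ancestral genome (adjacencies + contigs) as TSV
#'
#' Two files per node: `<label>.adjacencies.tsv` with columns `gene1`,
#' `gene2`, `weight`, `orientation_class`, `lca_label`, `contig_id` (one
#' row per linearized adjacency, in contig order) and `<label>.contigs.tsv`
#' with columns `contig_id`, `size`, `genes` (ordered, oriented gene list).
#'
#' @param node internal node index or label.
#' @param syn a linearized `synteny_set`.
#' @param out_dir output directory.
#' @return the two file paths.
#' @export
write_ancestral_genome <- function(node, syn, out_dir) {
  tree <- syn$tree; lin <- syn$lin
  if (is.character(node)) node <- node_of(tree, node)
  lab <- tree$labels[node]
  safe <- gsub("[^A-Za-z0-9._-]", "_", lab)
  ctg <- syn$contigs[[node]]
  E <- syn$edges[[node]]
  adj_rows <- list()
  if (!is.null(ctg) && nrow(ctg)) {
    key_of <- function(x, y) paste(pmin(x, y), pmax(x, y))
    ekey <- key_of(E$g1, E$g2)
    n <- nrow(ctg)
    i <- which(ctg$contig_id[-n] == ctg$contig_id[-1L])
    eid <- match(key_of(ctg$uid[i], ctg$uid[i + 1L]), ekey)
    adj_rows <- data.table::data.table(
      gene1 = lin$label[ctg$uid[i]],
      gene2 = lin$label[ctg$uid[i + 1L]],
      weight = E$weight[eid],
      orientation_class = infer_orientation(E[eid]),
      lca_label = tree$labels[syn$emergence[[node]][eid]],
      contig_id = ctg$contig_id[i])
  } else {
    adj_rows <- data.table::data.table(
      gene1 = character(0), gene2 = character(0), weight = integer(0),
      orientation_class = character(0), lca_label = character(0),
      contig_id = integer(0))
  }
  p1 <- file.path(out_dir, paste0(safe, ".adjacencies.tsv"))
  data.table::fwrite(adj_rows, p1, sep = "\t")

  ctg_rows <- if (!is.null(ctg) && nrow(ctg)) {
    ctg[, .(size = .N,
            genes = paste(sprintf("%s(%s)", lin$label[uid],
                                  ifelse(strand == "unknown", "?", strand)),
                          collapse = ",")),
        by = contig_id]
  } else {
    data.table::data.table(contig_id = integer(0), size = integer(0),
                           genes = character(0))
  }
  p2 <- file.path(out_dir, paste0(safe, ".contigs.tsv"))
  data.table::fwrite(ctg_rows, p2, sep = "\t")
  c(p1, p2)
}
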