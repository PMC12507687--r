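#' Read hierarchical orthologous groups from OrthoXML
#'
#' Parses an OrthoXML document into a forest of nested group records against
#' a species tree. Group taxonomic levels are taken from a `TaxRange`
#' property when present, otherwise implied as the MRCA of the member
#' species. Children of a `paralogGroup` are marked as arising through a
#' duplication below the enclosing group's level. Genes declared in the
#' header but referenced by no group are returned as singleton
#' species-specific families.
#'
#' The parser is namespace-agnostic and reads the whole document in a single
#' pass (element names, depths and attributes are extracted in bulk; nesting
#' is rebuilt from document order), which keeps it fast on files with
#' hundreds of thousands of group elements.
#'
#' @param path path to an OrthoXML file, or a string containing the XML
#'   (detected by a leading `<`).
#' @param tree a `species_tree` covering all species declared in the file.
#' @return An object of class `hog_forest` with elements `og` (data.frame of
#'   ortholog groups: `level`, `parent`, `via_dup`, `fam`, `label`),
#'   `generef` (extant members: `og`, `via_dup`, `gene_id`, `species`),
#'   `singletons` (data.frame `gene_id`, `species`), `families` (labels of
#'   family roots) and `tree`.
#' @export
read_orthoxml <- function(path, tree) {
  doc <- xml2::read_xml(path)  # xml2 accepts a path or literal XML text
  all <- xml2::xml_find_all(doc, "//*")
  nm <- xml2::xml_name(all)
  pth <- xml2::xml_path(all)
  depth <- nchar(pth) - nchar(gsub("/", "", pth, fixed = TRUE))
  n <- length(all)
  a_name <- xml2::xml_attr(all, "name")
  a_id <- xml2::xml_attr(all, "id")
  a_prot <- xml2::xml_attr(all, "protId")
  a_value <- xml2::xml_attr(all, "value")

  is_og <- nm == "orthologGroup"
  is_pg <- nm == "paralogGroup"
  is_grp <- is_og | is_pg
  is_gr <- nm == "geneRef"
  is_spc <- nm == "species"
  is_gene <- nm == "gene"
  is_prop <- nm == "property"

  # rebuild nesting: document order is preorder, so the parent of element i
  # is the most recent element one level shallower
  parent <- integer(n)
  spc_anc <- integer(n)
  grp_anc <- integer(n)
  last_at <- integer(max(depth) + 1L)
  for (i in seq_len(n)) {
    d <- depth[i]
    p <- if (d > 1L) last_at[d - 1L] else 0L
    parent[i] <- p
    spc_anc[i] <- if (is_spc[i]) i else if (p > 0L) spc_anc[p] else 0L
    grp_anc[i] <- if (p > 0L) { if (is_grp[p]) p else grp_anc[p] } else 0L
    last_at[d] <- i
  }

  # gene declarations
  gi <- which(is_gene)
  if (!length(gi)) stop_input("OrthoXML: no gene declarations")
  decl <- data.frame(
    xml_id = a_id[gi],
    gene_id = ifelse(is.na(a_prot[gi]), a_id[gi], a_prot[gi]),
    species = a_name[spc_anc[gi]],
    stringsAsFactors = FALSE
  )
  sp_unknown <- setdiff(unique(decl$species), tree$labels[tree$is_leaf])
  if (length(sp_unknown)) {
    stop_input(paste0("OrthoXML species not in the species tree: ",
                      paste(sp_unknown, collapse = ", ")))
  }
  if (anyDuplicated(decl$xml_id)) {
    stop_input("OrthoXML: duplicated gene declaration ids")
  }

  # TaxRange properties attach to their enclosing group
  tax <- rep(NA_character_, n)
  pi <- which(is_prop & !is.na(a_name) & a_name == "TaxRange")
  if (length(pi)) tax[parent[pi]] <- a_value[pi]

  # ortholog groups: effective parent OG (skipping paralogGroups) + dup flag
  og_i <- which(is_og)
  n_og <- length(og_i)
  og_ord <- integer(n); og_ord[og_i] <- seq_len(n_og)
  climb_og <- function(el) {
    a <- grp_anc[el]; dup <- FALSE
    while (a > 0L && is_pg[a]) { dup <- TRUE; a <- grp_anc[a] }
    list(og = if (a > 0L) og_ord[a] else NA_integer_, dup = dup)
  }
  og_parent <- rep(NA_integer_, n_og)
  og_dup <- logical(n_og)
  for (k in seq_len(n_og)) {
    cl <- climb_og(og_i[k])
    og_parent[k] <- cl$og; og_dup[k] <- cl$dup
  }

  # gene references
  gr_i <- which(is_gr)
  gr_og <- rep(NA_integer_, length(gr_i))
  gr_dup <- logical(length(gr_i))
  for (k in seq_along(gr_i)) {
    cl <- climb_og(gr_i[k])
    gr_og[k] <- cl$og; gr_dup[k] <- cl$dup
  }
  if (anyNA(gr_og)) stop_input("OrthoXML: geneRef outside any orthologGroup")
  hit <- match(a_id[gr_i], decl$xml_id)
  if (anyNA(hit)) {
    stop_input(paste0("OrthoXML: geneRef to undeclared gene id(s): ",
                      paste(utils::head(a_id[gr_i][is.na(hit)], 5L), collapse = ", ")))
  }
  generef <- data.frame(
    og = gr_og, via_dup = gr_dup,
    gene_id = decl$gene_id[hit], species = decl$species[hit],
    stringsAsFactors = FALSE
  )
  key <- paste(generef$species, generef$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_input("OrthoXML: a gene is referenced by more than one group")
  }

  # levels: explicit TaxRange, else MRCA of member species (computed
  # bottom-up only for the groups that need it; document order guarantees
  # children come after parents)
  leaf_node <- match(generef$species, tree$labels)
  og_tax <- tax[og_i]
  og_level <- rep(NA_integer_, n_og)
  expl <- !is.na(og_tax)
  if (any(expl)) og_level[expl] <- node_of(tree, og_tax[expl])
  if (!all(expl)) {
    mrca_acc <- rep(NA_integer_, n_og)
    comb <- function(cur, v) {
      if (is.na(cur)) return(v)
      a <- cur
      while (!is_ancestor_or_self(tree, a, v)) a <- tree$parent[a]
      a
    }
    for (k in seq_along(gr_i)) {
      o <- gr_og[k]
      mrca_acc[o] <- comb(mrca_acc[o], leaf_node[k])
    }
    for (k in rev(seq_len(n_og))) {
      p <- og_parent[k]
      if (!is.na(p) && !is.na(mrca_acc[k])) mrca_acc[p] <- comb(mrca_acc[p], mrca_acc[k])
    }
    og_level[!expl] <- mrca_acc[!expl]
  }
  if (anyNA(og_level)) stop_input("OrthoXML: empty orthologGroup (no members)")

  # structural validation (all vectorized)
  if (any(tree$is_leaf[og_level])) {
    stop_input("OrthoXML: group level is a leaf; group levels must be internal nodes")
  }
  bad <- !is_ancestor_or_self(tree, og_level[gr_og], leaf_node)
  if (any(bad)) {
    stop_input(paste0("OrthoXML: group contains species outside its level's clade: ",
                      paste(utils::head(generef$gene_id[bad], 5L), collapse = ", ")))
  }
  hasp <- which(!is.na(og_parent))
  if (length(hasp)) {
    plev <- og_level[og_parent[hasp]]; clev <- og_level[hasp]
    if (any(plev == clev)) {
      stop_input("OrthoXML: nested group repeats its parent's level (same-level duplication is not supported)")
    }
    okn <- is_ancestor_or_self(tree, plev, clev)
    if (!all(okn)) {
      k <- hasp[which(!okn)[1L]]
      stop_input(sprintf("OrthoXML: group level '%s' is not a descendant of its parent group's level '%s'",
                         tree$labels[og_level[k]], tree$labels[og_level[og_parent[k]]]))
    }
  }

  # family (root group) assignment, in document order so parents come first
  og_fam <- integer(n_og)
  for (k in seq_len(n_og)) {
    og_fam[k] <- if (is.na(og_parent[k])) k else og_fam[og_parent[k]]
  }
  roots <- which(is.na(og_parent))
  fam_label <- ifelse(is.na(a_id[og_i[roots]]),
                      paste0("HOG_", seq_along(roots)), a_id[og_i[roots]])
  if (anyDuplicated(fam_label)) fam_label <- make.unique(fam_label, sep = "_r")

  singles <- decl[!paste(decl$species, decl$gene_id, sep = "\r") %in% key,
                  c("gene_id", "species")]
  rownames(singles) <- NULL

  structure(list(
    og = data.frame(level = og_level, parent = og_parent, via_dup = og_dup,
                    fam = match(og_fam, roots), stringsAsFactors = FALSE),
    generef = generef,
    singletons = singles,
    families = fam_label,
    tree = tree
  ), class = "hog_forest")
}

#' @export
print.hog_forest <- function(x, ...) {
  cat(sprintf("<hog_forest> %d families, %d groups, %d extant members, %d singletons\n",
              length(x$families), nrow(x$og), nrow(x$generef), nrow(x$singletons)))
  invisible(x)
}

#' Write a gene-lineage forest as OrthoXML
#'
#' Serializes a lineage forest (for example the simulator's ground truth) as
#' OrthoXML readable by [read_orthoxml()]. Only what ideal orthology
#' inference could observe is written: lineages without extant descendants
#' are pruned, runs of single-child ancestral genes are collapsed (the
#' reader re-materializes the intermediate levels), and duplications are
#' wrapped in `paralogGroup` elements only when at least two copies survive.
#' Family root levels are always written explicitly as `TaxRange`
#' properties, so a family known to be older than its first surviving
#' branching keeps its true root level.
#'
#' @param lin a `lineage_forest`.
#' @param path output path.
#' @param origin value of the `origin` attribute.
#' @return `path`, invisibly.
#' @export
write_orthoxml <- function(lin, path, origin = "ancora") {
  tree <- lin$tree
  M <- length(lin$node)
  kids <- lineage_children(lin)
  has_ext <- lin$is_extant
  for (u in rev(seq_len(M))) {
    p <- lin$parent[u]
    if (!is.na(p) && has_ext[u]) has_ext[p] <- TRUE
  }

  # line accumulator: a frame-local list filled by index stays in place
  parts <- vector("list", 4096L); np <- 0L
  add <- function(s) {  # only called with small/vector chunks, outside hot loop
    np <<- np + 1L
    if (np > length(parts)) length(parts) <<- 2L * np
    parts[[np]] <<- s
  }

  add(c('<?xml version="1.0" encoding="UTF-8"?>',
        sprintf('<orthoXML xmlns="http://orthoXML.org/2011/" version="0.3" origin="%s" originVersion="%s">',
                origin, as.character(utils::packageVersion("ancora")))))

  # species / gene declarations
  ext <- which(lin$is_extant)
  xml_gid <- integer(M)
  ctr <- 0L
  for (leaf in which(tree$is_leaf)) {
    gs <- ext[lin$node[ext] == leaf]
    if (!length(gs)) next
    gs <- gs[order(lin$label[gs], method = "radix")]
    add(sprintf('<species name="%s" NCBITaxId="0"><database name="%s" version="1"><genes>',
                xml_escape(tree$labels[leaf]), origin))
    xml_gid[gs] <- ctr + seq_along(gs)
    ctr <- ctr + length(gs)
    add(sprintf('<gene id="%d" protId="%s"/>', xml_gid[gs], xml_escape(lin$label[gs])))
    add('</genes></database></species>')
  }
  add('<groups>')

  # group section: explicit-stack DFS emitting one line per element into a
  # preallocated frame-local vector (closure-based accumulators would copy
  # the buffer on every append)
  next_emission <- function(u) {
    # collapse chains of single-child ancestral genes
    repeat {
      if (lin$is_extant[u]) return(u)
      ks <- kids[[u]]; ks <- ks[has_ext[ks]]
      if (length(ks) != 1L) return(u)
      u <- ks
    }
  }
  roots <- which(is.na(lin$parent) & has_ext)
  roots <- roots[order(lin$family[roots], roots)]
  roots <- roots[!lin$is_extant[roots]]  # extant singletons: declared only

  lines <- character(2L * M + 16L); ln <- 0L
  su <- integer(256L); slit <- character(256L); sp <- 0L  # DFS stack
  open_tag <- function(u, idattr) {
    sprintf('<orthologGroup%s>',
            if (is.na(idattr)) "" else sprintf(' id="%s"', xml_escape(idattr)))
  }
  for (r in rev(roots)) {
    sp <- sp + 1L; su[sp] <- r; slit[sp] <- lin$families[lin$family[r]]
  }
  while (sp > 0L) {
    u <- su[sp]; lit <- slit[sp]; sp <- sp - 1L
    if (u == 0L) {  # literal line
      ln <- ln + 1L
      if (ln > length(lines)) lines <- c(lines, character(length(lines)))
      lines[ln] <- lit
      next
    }
    if (lin$is_extant[u]) {
      ln <- ln + 1L
      if (ln > length(lines)) lines <- c(lines, character(length(lines)))
      lines[ln] <- sprintf('<geneRef id="%d"/>', xml_gid[u])
      next
    }
    ln <- ln + 2L
    while (ln > length(lines)) lines <- c(lines, character(length(lines)))
    lines[ln - 1L] <- open_tag(u, if (lit == "") NA_character_ else lit)
    lines[ln] <- sprintf('<property name="TaxRange" value="%s"/>',
                         xml_escape(tree$labels[lin$node[u]]))
    ks <- kids[[u]]; ks <- ks[has_ext[ks]]
    ks <- ks[order(lin$node[ks], ks)]
    # build the child action sequence, then push it reversed (LIFO)
    acts_u <- integer(0); acts_l <- character(0)
    run_start <- 1L
    nn <- lin$node[ks]
    for (i in seq_along(ks)) {
      if (i < length(ks) && nn[i + 1L] == nn[i]) next
      run <- ks[run_start:i]
      run_start <- i + 1L
      if (length(run) >= 2L) {
        acts_u <- c(acts_u, 0L, vapply(run, next_emission, 0L), 0L)
        acts_l <- c(acts_l, '<paralogGroup>', character(length(run)), '</paralogGroup>')
      } else {
        acts_u <- c(acts_u, next_emission(run))
        acts_l <- c(acts_l, "")
      }
    }
    acts_u <- c(acts_u, 0L); acts_l <- c(acts_l, '</orthologGroup>')
    for (i in rev(seq_along(acts_u))) {
      sp <- sp + 1L
      while (sp > length(su)) { su <- c(su, integer(length(su)))
                                slit <- c(slit, character(length(slit))) }
      su[sp] <- acts_u[i]; slit[sp] <- acts_l[i]
    }
  }
  add(lines[seq_len(ln)])
  add(c('</groups>', '</orthoXML>'))
  writeLines(unlist(parts[seq_len(np)]), path, useBytes = TRUE)
  invisible(path)
}

#' @keywords internal
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}
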