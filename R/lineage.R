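#' Build the gene-lineage forest from a HOG forest
#'
#' Converts nested orthologous groups into per-node ancestral gene sets with
#' explicit child-to-parent gene links. A family is materialized at every
#' species-tree node on the path between a group's level and each nested
#' subgroup or extant member, so lineage links never skip tree nodes; clades
#' with no members receive no gene (the HOG implies loss there). Links
#' created under a `paralogGroup` are flagged as arising through
#' duplication on their first (oldest) segment.
#'
#' @param forest a `hog_forest` from [read_orthoxml()].
#' @param tree the `species_tree` the forest was resolved against.
#' @param genomes optional named list (by species) of gene tables from
#'   [read_gff()]. Genes present in a genome but absent from the forest are
#'   added as singleton species-specific families; genes in the forest but
#'   missing from the genome are kept in the lineage (they simply carry no
#'   coordinates, hence no adjacencies) and counted in a message.
#' @return An object of class `lineage_forest`: parallel vectors `node`,
#'   `family`, `parent`, `via_dup`, `label`, `is_extant` indexed by gene
#'   uid (1..M, parents always have smaller uid than their children), plus
#'   `families` (family labels), `ext_uid` (named uid lookup keyed by
#'   `species\rgene_id`), and `tree`.
#' @export
build_gene_lineage <- function(forest, tree, genomes = NULL) {
  og <- forest$og
  gr <- forest$generef
  n_og <- nrow(og)

  leaf_idx <- match(gr$species, tree$labels)
  bad <- !is_ancestor_or_self(tree, og$level[gr$og], leaf_idx)
  if (any(bad)) {
    stop_input(paste0("OrthoXML members outside their group's clade: ",
                      paste(utils::head(gr$gene_id[bad], 5L), collapse = ", ")))
  }

  singles <- forest$singletons
  if (!is.null(genomes)) {
    known <- c(paste(gr$species, gr$gene_id, sep = "\r"),
               paste(singles$species, singles$gene_id, sep = "\r"))
    extra <- do.call(rbind, lapply(names(genomes), function(sp) {
      gdf <- genomes[[sp]]
      miss <- !paste(sp, gdf$gene_id, sep = "\r") %in% known
      if (!any(miss)) return(NULL)
      data.frame(gene_id = gdf$gene_id[miss], species = sp,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(extra) && nrow(extra)) {
      message(sprintf("%d gene(s) present in GFF but absent from OrthoXML: added as singleton families",
                      nrow(extra)))
      singles <- rbind(singles, extra)
    }
    gkeys <- unlist(lapply(names(genomes), function(sp)
      paste(sp, genomes[[sp]]$gene_id, sep = "\r")))
    nocoord <- sum(!paste(gr$species, gr$gene_id, sep = "\r") %in% gkeys)
    if (nocoord > 0L) {
      message(sprintf("%d OrthoXML gene(s) have no GFF coordinates: kept in lineages, excluded from synteny",
                      nocoord))
    }
  }
  n_sg <- nrow(singles)

  families <- c(forest$families,
                if (n_sg) paste0("SG:", singles$species, ":", singles$gene_id))

  # gene store: fixed-size chunk buffers flushed into a list, so that each
  # per-gene write only ever copies one small chunk (writing scalars into a
  # long environment-held vector would copy it wholesale on every call)
  CH <- 1024L
  st <- new.env(parent = emptyenv())
  st$chunks <- list(); st$nc <- 0L
  st$bnode <- integer(CH); st$bfam <- integer(CH); st$bpar <- integer(CH)
  st$bdup <- logical(CH); st$blab <- character(CH)
  st$bi <- 0L; st$n <- 0L
  flush_chunk <- function() {
    if (st$bi == 0L) return(invisible())
    i <- seq_len(st$bi)
    st$nc <- st$nc + 1L
    st$chunks[[st$nc]] <- list(node = st$bnode[i], fam = st$bfam[i],
                               par = st$bpar[i], dup = st$bdup[i],
                               lab = st$blab[i])
    st$bi <- 0L
    invisible()
  }
  new_gene <- function(node_, fam_, parent_, dup_, label_ = NA_character_) {
    if (st$bi == CH) flush_chunk()
    st$bi <- st$bi + 1L
    st$bnode[st$bi] <- node_; st$bfam[st$bi] <- fam_
    st$bpar[st$bi] <- parent_; st$bdup[st$bi] <- dup_
    st$blab[st$bi] <- label_
    st$n <- st$n + 1L
    st$n
  }

  # child items per group: sub-groups first, then extant members, both in
  # document order (stable, hence deterministic uids)
  sub_of <- vector("list", n_og)
  spl <- split(seq_len(n_og), og$parent[seq_len(n_og)])
  sub_of[as.integer(names(spl))] <- spl
  gr_of <- vector("list", n_og)
  spl <- split(seq_len(nrow(gr)), gr$og)
  gr_of[as.integer(names(spl))] <- spl

  # which child of L lies on the path down to x
  child_under <- function(L, x) {
    while (!identical(tree$parent[x], L)) x <- tree$parent[x]
    x
  }

  # Materialization by routing: a parent gene at node L distributes its
  # member items (sub-groups / extant members) over the children of L that
  # their levels fall under; each such child node holds one shared gene
  # unless a duplication separates lineages. An item whose level equals the
  # child node "claims" that gene (extra same-level claimants become
  # parallel lineages); items routed deeper create intermediate genes.
  # Items flagged via_dup are independent lineages by definition.
  route <- function(parent_uid, L, tg, kind, ref, dup, fam) {
    dups <- which(dup)
    for (j in dups) chain_item(parent_uid, L, tg[j], kind[j], ref[j], TRUE, fam)
    rest <- which(!dup)
    if (!length(rest)) return(invisible())
    cc <- vapply(tg[rest], function(x) child_under(L, x), 0L)
    for (cn in unique(cc)) {
      sel <- rest[cc == cn]
      claim <- sel[tg[sel] == cn]
      deeper <- sel[tg[sel] != cn]
      if (length(claim)) {
        j <- claim[1L]
        settle_item(parent_uid, tg[j], kind[j], ref[j], FALSE, fam, deeper,
                    tg, kind, ref)
        for (j2 in claim[-1L]) {
          settle_item(parent_uid, tg[j2], kind[j2], ref[j2], FALSE, fam,
                      integer(0), tg, kind, ref)
        }
      } else {
        g <- new_gene(cn, fam, parent_uid, FALSE)
        route(g, cn, tg[deeper], kind[deeper], ref[deeper], dup[deeper], fam)
      }
    }
    invisible()
  }
  # create the gene an item stands for (at its own level) and expand it
  settle_item <- function(parent_uid, at, kind_j, ref_j, dup_j, fam,
                          extra_idx, tg, kind, ref) {
    if (kind_j == 0L) {  # extant member
      new_gene(at, fam, parent_uid, dup_j, ref_label[ref_j])
      return(invisible())
    }
    g <- new_gene(at, fam, parent_uid, dup_j)
    k <- ref_j
    ctg <- c(og$level[sub_of[[k]]], ref_leaf[gr_of[[k]]], tg[extra_idx])
    ckind <- c(rep(1L, length(sub_of[[k]])), rep(0L, length(gr_of[[k]])),
               kind[extra_idx])
    cref <- c(sub_of[[k]], gr_of[[k]], ref[extra_idx])
    cdup <- c(og$via_dup[sub_of[[k]]], gr$via_dup[gr_of[[k]]],
              rep(FALSE, length(extra_idx)))
    if (length(ctg)) route(g, at, ctg, ckind, cref, cdup, fam)
    invisible()
  }
  # a via_dup item: its lineage is its own; materialize the chain from L
  # (exclusive) to its level, duplication stamped on the first link
  chain_item <- function(parent_uid, L, at, kind_j, ref_j, dup_j, fam) {
    path <- tree_path_down(tree, L, at)
    p <- parent_uid; first <- TRUE
    for (v in path[-length(path)]) {
      p <- new_gene(v, fam, p, first && dup_j)
      first <- FALSE
    }
    settle_item(p, at, kind_j, ref_j, first && dup_j, fam, integer(0),
                integer(0), integer(0), integer(0))
  }

  ref_label <- gr$gene_id
  ref_leaf <- leaf_idx
  roots <- which(is.na(og$parent))
  for (r in roots) {
    settle_item(NA_integer_, og$level[r], 1L, r, FALSE, og$fam[r],
                integer(0), integer(0), integer(0), integer(0))
  }
  if (n_sg) {
    sg_leaf <- match(singles$species, tree$labels)
    for (j in seq_len(n_sg)) {
      new_gene(sg_leaf[j], length(forest$families) + j, NA_integer_, FALSE,
               singles$gene_id[j])
    }
  }

  flush_chunk()
  M <- st$n
  node <- unlist(lapply(st$chunks, `[[`, "node"), use.names = FALSE)
  family <- unlist(lapply(st$chunks, `[[`, "fam"), use.names = FALSE)
  parent <- unlist(lapply(st$chunks, `[[`, "par"), use.names = FALSE)
  via_dup <- unlist(lapply(st$chunks, `[[`, "dup"), use.names = FALSE)
  label <- unlist(lapply(st$chunks, `[[`, "lab"), use.names = FALSE)
  is_extant <- tree$is_leaf[node]
  anc <- which(is.na(label) | label == "")
  k_in <- stats::ave(seq_len(M), family, node, FUN = seq_along)
  label[anc] <- paste0(families[family[anc]], "@", tree$labels[node[anc]],
                       ".", k_in[anc])

  ext_uid <- which(is_extant)
  ext_key <- paste(tree$labels[node[ext_uid]], label[ext_uid], sep = "\r")
  if (anyDuplicated(ext_key)) {
    stop_input("duplicate extant gene identifiers within a species")
  }
  names(ext_uid) <- ext_key

  structure(list(
    node = node, family = family, parent = parent, via_dup = via_dup,
    label = label, is_extant = is_extant,
    families = families, ext_uid = ext_uid, tree = tree
  ), class = "lineage_forest")
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat(sprintf("<lineage_forest> %d genes (%d extant) in %d families over %d tree nodes\n",
              length(x$node), sum(x$is_extant), length(x$families),
              length(x$tree$labels)))
  invisible(x)
}

#' Children lists of a lineage forest
#' @keywords internal
lineage_children <- function(lin) {
  M <- length(lin$node)
  kids <- vector("list", M)
  idx <- which(!is.na(lin$parent))
  if (length(idx)) {
    spl <- split(idx, lin$parent[idx])
    kids[as.integer(names(spl))] <- spl
  }
  kids
}

#' Gene uids present at a tree node
#' @param lin a `lineage_forest`
#' @param node node index or label
#' @return integer vector of gene uids
#' @export
genes_at_node <- function(lin, node) {
  if (is.character(node)) node <- node_of(lin$tree, node)
  which(lin$node == node)
}

#' HOG completeness score of ancestral genes
#'
#' Fraction of the species in a gene's clade that retain at least one extant
#' descendant of the gene, in `[0, 1]`. Low values flag dubious ancestral
#' genes implying many losses. Extant genes get `NA`.
#'
#' @param lin a `lineage_forest`.
#' @return numeric vector indexed by gene uid.
#' @export
completeness_score <- function(lin) {
  M <- length(lin$node)
  dt <- data.table::data.table(u = which(lin$is_extant))
  dt[, sp := lin$node[u]]
  acc <- vector("list", 32L); ai <- 0L
  dt[, u := lin$parent[u]]
  dt <- unique(dt[!is.na(u)])
  while (nrow(dt)) {
    ai <- ai + 1L; acc[[ai]] <- data.table::copy(dt)
    dt[, u := lin$parent[u]]
    dt <- unique(dt[!is.na(u)])
    if (ai == length(acc)) acc <- c(acc, vector("list", length(acc)))
  }
  counts <- integer(M)
  if (ai > 0L) {
    pairs <- unique(data.table::rbindlist(acc[seq_len(ai)]))
    tb <- pairs[, .N, by = u]
    counts[tb$u] <- tb$N
  }
  cs <- clade_sizes(lin$tree)
  out <- counts / cs[lin$node]
  out[lin$is_extant] <- NA_real_
  out
}

#' Extant descendants of a gene
#'
#' All extant genes reachable from `uid` by child links, optionally
#' restricted to one species. A species not under the gene's level simply
#' yields an empty result.
#'
#' @param lin a `lineage_forest`.
#' @param uid gene uid.
#' @param species optional species label.
#' @param kids precomputed [lineage_children()] (for repeated calls).
#' @return integer vector of extant gene uids.
#' @export
descendant_genes <- function(lin, uid, species = NULL, kids = lineage_children(lin)) {
  out <- integer(0)
  stack <- uid
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (lin$is_extant[v] && v != uid) out <- c(out, v)
    ch <- kids[[v]]
    if (length(ch)) stack <- c(stack, ch)
  }
  if (!is.null(species)) {
    leaf <- node_of(lin$tree, species)
    out <- out[lin$node[out] == leaf]
  }
  sort(out)
}
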