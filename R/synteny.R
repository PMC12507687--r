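# Synteny graphs: one weighted adjacency graph per species-tree node.
#
# Edge tables are data.tables with columns
#   id      edge id within the node (dense, sorted by gene-uid pair)
#   g1, g2  gene uids (g1 < g2)
#   weight  number of propagations from descendant extant genomes
#   ht, hh, tt  orientation tally (head-to-tail / head-to-head / tail-to-tail)
#   nsupp   number of distinct child subtrees supporting the edge (NA at leaves)
#   dupsup  TRUE if some single child contributed >= 2 child edges (paralogous
#           adjacency copies merged here)
#   nbridge number of gain-bridging events merged into this edge at this node
# plus `contig`/`pos` at leaves. Support links between levels live in
# `sup[[v]]` (child node, child edge id, parent edge id at v).

EDGE_COLS <- c("id", "g1", "g2", "weight", "ht", "hh", "tt",
               "nsupp", "dupsup", "nbridge")

empty_edges <- function() {
  data.table::data.table(id = integer(0), g1 = integer(0), g2 = integer(0),
                         weight = integer(0), ht = integer(0), hh = integer(0),
                         tt = integer(0), nsupp = integer(0),
                         dupsup = logical(0), nbridge = integer(0))
}

#' Build the observed synteny graph of one extant genome
#'
#' Adds one weight-1 edge between rank-consecutive genes of each contig.
#' The orientation class of an edge follows the two strands read in
#' left-to-right contig order: same strand is head-to-tail, `+ -` is
#' head-to-head (the genes' 3' ends abut), `- +` is tail-to-tail. These
#' classes do not depend on which way the contig is read.
#'
#' @param genes gene table from [read_gff()] for one species.
#' @param lin a `lineage_forest` containing these genes.
#' @return edge data.table (see package source for the column contract).
#' @export
build_extant_graph <- function(genes, lin) {
  sp <- genes$species[1L]
  uid <- unname(lin$ext_uid[paste(sp, genes$gene_id, sep = "\r")])
  if (anyNA(uid)) {
    stop_input(sprintf("%s: %d gene(s) missing from the lineage forest",
                       sp, sum(is.na(uid))))
  }
  o <- order(genes$contig, genes$rank, method = "radix")
  genes <- genes[o, , drop = FALSE]; uid <- uid[o]
  n <- nrow(genes)
  if (n < 2L) return(empty_edges())
  i <- which(genes$contig[-n] == genes$contig[-1L])
  if (!length(i)) return(empty_edges())
  u1 <- uid[i]; u2 <- uid[i + 1L]
  s1 <- genes$strand[i]; s2 <- genes$strand[i + 1L]
  cls <- orient_class(s1, s2)
  E <- data.table::data.table(
    g1 = pmin(u1, u2), g2 = pmax(u1, u2), weight = 1L,
    ht = as.integer(cls == "head_to_tail"),
    hh = as.integer(cls == "head_to_head"),
    tt = as.integer(cls == "tail_to_tail"),
    nsupp = NA_integer_, dupsup = FALSE, nbridge = 0L,
    contig = genes$contig[i], pos = genes$rank[i]
  )
  data.table::setorder(E, g1, g2)
  E[, id := seq_len(.N)]
  data.table::setcolorder(E, EDGE_COLS)
  E[]
}

#' @keywords internal
orient_class <- function(s1, s2) {
  out <- rep("unknown", length(s1))
  out[s1 == "+" & s2 == "+"] <- "head_to_tail"
  out[s1 == "-" & s2 == "-"] <- "head_to_tail"
  out[s1 == "+" & s2 == "-"] <- "head_to_head"
  out[s1 == "-" & s2 == "+"] <- "tail_to_tail"
  out
}

#' Propagate extant adjacencies bottom-up along gene lineages
#'
#' Post-order traversal of the species tree. For every edge (x, y) of a
#' child graph whose endpoints both have parent genes, the edge is lifted to
#' the parental pair, summing weights and orientation tallies; child edges
#' collapsing onto a single parent gene (duplicates merging at the point of
#' duplication) vanish; several child edges mapping to the same parental
#' pair merge into one edge. A maximal run of parentless genes (a gene gain)
#' flanked by two parented genes is bridged by a single weight-1 edge
#' between the flanks' parents, so the gain is modelled as an insertion
#' between two older genes. Every propagated child edge records its
#' propagated form for the later top-down phase.
#'
#' @param tree a `species_tree`.
#' @param lin a `lineage_forest`.
#' @param extant_graphs named list (species label -> edge table from
#'   [build_extant_graph()]).
#' @return an object of class `synteny_set` with per-node edge tables,
#'   support links and phase `"propagated"`.
#' @export
propagate_bottom_up <- function(tree, lin, extant_graphs) {
  n_node <- length(tree$labels)
  edges <- vector("list", n_node)
  sup <- vector("list", n_node)
  for (leaf in which(tree$is_leaf)) {
    lab <- tree$labels[leaf]
    edges[[leaf]] <- if (!is.null(extant_graphs[[lab]])) extant_graphs[[lab]] else empty_edges()
  }
  par_of <- lin$parent

  for (v in tree$postorder) {
    if (tree$is_leaf[v]) next
    acc <- list(); ai <- 0L
    sup_acc <- list()
    for (cc in tree$children[[v]]) {
      E <- edges[[cc]]
      if (is.null(E) || nrow(E) == 0L) next
      p1 <- par_of[E$g1]; p2 <- par_of[E$g2]
      direct <- !is.na(p1) & !is.na(p2) & p1 != p2
      if (any(direct)) {
        ai <- ai + 1L
        acc[[ai]] <- data.table::data.table(
          child = cc, cedge = E$id[direct],
          g1 = pmin(p1[direct], p2[direct]), g2 = pmax(p1[direct], p2[direct]),
          weight = E$weight[direct],
          ht = E$ht[direct], hh = E$hh[direct], tt = E$tt[direct],
          nbridge = 0L, is_direct = TRUE
        )
      }
      br <- bridge_gains(E, par_of)
      if (!is.null(br) && nrow(br)) {
        ai <- ai + 1L
        br[, `:=`(child = cc, cedge = NA_integer_, is_direct = FALSE)]
        acc[[ai]] <- br
      }
    }
    if (ai == 0L) { edges[[v]] <- empty_edges(); next }
    rows <- data.table::rbindlist(acc, use.names = TRUE)
    # per-child aggregation first, to detect paralogous edge copies merging
    byc <- rows[, .(weight = sum(weight), ht = sum(ht), hh = sum(hh),
                    tt = sum(tt), nbridge = sum(nbridge),
                    ndirect = sum(is_direct)), by = .(child, g1, g2)]
    agg <- byc[, .(weight = sum(weight), ht = sum(ht), hh = sum(hh),
                   tt = sum(tt), nbridge = sum(nbridge),
                   nsupp = .N, dupsup = any(ndirect >= 2L)), by = .(g1, g2)]
    data.table::setorder(agg, g1, g2)
    agg[, id := seq_len(.N)]
    data.table::setcolorder(agg, EDGE_COLS)
    edges[[v]] <- agg
    dsup <- rows[is_direct == TRUE, .(child, cedge, g1, g2)]
    dsup[, pedge := agg[dsup, id, on = c("g1", "g2")]]
    sup[[v]] <- dsup[, .(child, cedge, pedge)]
    data.table::setorder(sup[[v]], child, cedge)
  }

  structure(list(tree = tree, lin = lin, edges = edges, sup = sup,
                 phase = "propagated"), class = "synteny_set")
}

#' @export
print.synteny_set <- function(x, ...) {
  ne <- sum(vapply(x$edges, function(e) if (is.null(e)) 0L else nrow(e), 0L))
  cat(sprintf("<synteny_set> phase '%s', %d edges over %d tree nodes\n",
              x$phase, ne, length(x$tree$labels)))
  invisible(x)
}

# Bridge maximal runs of parentless genes in a child graph. A connected
# component of parentless genes adjacent to exactly two distinct parented
# genes yields one weight-1 edge between the parents of those flanks; runs
# at contig ends (one flank) yield nothing. The orientation contribution is
# derived by walking the run when it forms a simple path.
#' @keywords internal
bridge_gains <- function(E, par_of) {
  gl <- unique(c(E$g1, E$g2))
  pl <- gl[is.na(par_of[gl])]
  if (!length(pl)) return(NULL)
  plset <- match(c(E$g1, E$g2), pl)  # 2n vector: component membership helper
  n <- nrow(E)
  in1 <- !is.na(plset[seq_len(n)]); in2 <- !is.na(plset[n + seq_len(n)])
  # union-find over parentless genes, joined by edges internal to the set
  uf <- seq_along(pl)
  find <- function(i) { while (uf[i] != i) { uf[i] <<- uf[uf[i]]; i <- uf[i] }; i }
  both <- which(in1 & in2)
  for (k in both) {
    a <- find(plset[k]); b <- find(plset[n + k])
    if (a != b) uf[a] <- b
  }
  comp <- vapply(seq_along(pl), find, 0L)
  # boundary edges: exactly one endpoint parentless
  bidx <- which(xor(in1, in2))
  if (!length(bidx)) return(NULL)
  bcomp <- comp[ifelse(in1[bidx], plset[bidx], plset[n + bidx])]
  bout <- ifelse(in1[bidx], E$g2[bidx], E$g1[bidx])  # the parented flank
  out <- list(); oi <- 0L
  for (cid in unique(bcomp)) {
    sel <- bidx[bcomp == cid]
    flank <- unique(bout[bcomp == cid])
    if (length(flank) != 2L) next
    pu <- par_of[flank[1L]]; pw <- par_of[flank[2L]]
    if (is.na(pu) || is.na(pw) || pu == pw) next
    members <- pl[comp == cid]
    tl <- bridge_orientation(E, members, flank)
    oi <- oi + 1L
    out[[oi]] <- data.table::data.table(
      g1 = min(pu, pw), g2 = max(pu, pw), weight = 1L,
      ht = tl[1L], hh = tl[2L], tt = tl[3L], nbridge = 1L
    )
  }
  if (!oi) return(NULL)
  data.table::rbindlist(out)
}

# Orientation tally (ht, hh, tt) of a bridged edge, from walking the run of
# parentless genes between the two flanks when it forms a simple path.
# Per-edge majority classes constrain strands along the walk: head-to-tail
# preserves the strand, head-to-head requires + then -, tail-to-tail
# requires - then +. If no class pins the strands, any all-head-to-tail walk
# means the flanks share a strand, which is itself head-to-tail.
#' @keywords internal
bridge_orientation <- function(E, members, flank) {
  zero <- c(0L, 0L, 0L)
  keep <- (E$g1 %in% members | E$g1 %in% flank) &
          (E$g2 %in% members | E$g2 %in% flank)
  S <- E[keep]
  nodes <- c(flank, members)
  if (nrow(S) != length(members) + 1L) return(zero)
  deg <- tabulate(match(c(S$g1, S$g2), nodes), length(nodes))
  if (any(deg[1:2] != 1L) || any(deg[-(1:2)] != 2L)) return(zero)
  # walk from flank[1] to flank[2]
  cls <- character(nrow(S))
  for (k in seq_len(nrow(S))) cls[k] <- infer_orientation(S[k])
  path_cls <- character(0)
  cur <- flank[1L]; prev_e <- 0L
  for (step in seq_len(nrow(S))) {
    cand <- which((S$g1 == cur | S$g2 == cur) & seq_len(nrow(S)) != prev_e)
    if (length(cand) != 1L) return(zero)
    path_cls <- c(path_cls, cls[cand])
    cur <- if (S$g1[cand] == cur) S$g2[cand] else S$g1[cand]
    prev_e <- cand
    if (cur == flank[2L]) break
  }
  if (cur != flank[2L]) return(zero)
  out_cls <- walk_path_class(path_cls)
  c(as.integer(out_cls == "head_to_tail"),
    as.integer(out_cls == "head_to_head"),
    as.integer(out_cls == "tail_to_tail"))
}

#' @keywords internal
walk_path_class <- function(classes) {
  if (any(classes == "unknown")) return("unknown")
  ok_first <- c("+", "-")
  res <- character(0)
  for (s0 in ok_first) {
    s <- s0; ok <- TRUE
    for (cl in classes) {
      s <- switch(cl,
        head_to_tail = s,
        head_to_head = if (s == "+") "-" else NA,
        tail_to_tail = if (s == "-") "+" else NA)
      if (is.na(s)) { ok <- FALSE; break }
    }
    if (ok) {
      res <- c(res, orient_class(s0, s))
    }
  }
  res <- unique(res)
  if (length(res) == 1L) res else "unknown"
}

#' Remove adjacencies not supported by parsimony (top-down phase)
#'
#' Pre-order traversal from the root. At the root an edge is retained only
#' if at least two distinct child subtrees support it; elsewhere an edge is
#' retained if at least two children support it or its propagated form was
#' retained at the parent. Edge weights play no role in removal. Every
#' retained edge lineage is stamped with its emergence: the root-most node
#' at which it is retained. Extant adjacencies inherit the emergence of
#' their parent edge when that was retained, and otherwise emerge at the
#' leaf itself.
#'
#' Optional pre-filters (both off by default) drop candidate ancestral edges
#' below a weight threshold or incident to ancestral genes below a HOG
#' completeness threshold before the parsimony rule is applied.
#'
#' @param syn a `synteny_set` with phase `"propagated"`.
#' @param min_weight drop ancestral edges with weight below this.
#' @param min_completeness drop ancestral edges incident to genes with
#'   completeness score below this.
#' @return the `synteny_set` with `retained`, `emergence`, `parent_edge`
#'   per-node vectors and phase `"filtered"`.
#' @export
filter_top_down <- function(syn, min_weight = 0, min_completeness = 0) {
  stopifnot(inherits(syn, "synteny_set"))
  tree <- syn$tree
  n_node <- length(tree$labels)
  comp <- if (min_completeness > 0) completeness_score(syn$lin) else NULL
  retained <- vector("list", n_node)
  emergence <- vector("list", n_node)
  parent_edge <- vector("list", n_node)

  for (v in tree$preorder) {
    E <- syn$edges[[v]]
    ne <- if (is.null(E)) 0L else nrow(E)
    p <- tree$parent[v]
    pe <- rep(NA_integer_, ne)
    if (ne && !is.na(p) && !is.null(syn$sup[[p]])) {
      s <- syn$sup[[p]][child == v]
      pe[s$cedge] <- s$pedge
    }
    parent_edge[[v]] <- pe
    if (ne == 0L) {
      retained[[v]] <- logical(0); emergence[[v]] <- integer(0); next
    }
    if (tree$is_leaf[v]) {
      retained[[v]] <- rep(TRUE, ne)
      em <- rep(v, ne)
      if (!is.na(p)) {
        pr <- !is.na(pe) & retained[[p]][ifelse(is.na(pe), 1L, pe)]
        em[pr] <- emergence[[p]][pe[pr]]
      }
      emergence[[v]] <- em
      next
    }
    elig <- rep(TRUE, ne)
    if (min_weight > 0) elig <- elig & E$weight >= min_weight
    if (!is.null(comp)) {
      elig <- elig & comp[E$g1] >= min_completeness & comp[E$g2] >= min_completeness
    }
    if (is.na(p)) {
      ret <- elig & E$nsupp >= 2L
      em <- ifelse(ret, v, NA_integer_)
    } else {
      pr <- !is.na(pe) & retained[[p]][ifelse(is.na(pe), 1L, pe)]
      ret <- elig & (E$nsupp >= 2L | pr)
      em <- rep(NA_integer_, ne)
      em[ret & pr] <- emergence[[p]][pe[ret & pr]]
      em[ret & !pr] <- v
    }
    retained[[v]] <- ret
    emergence[[v]] <- em
  }
  syn$retained <- retained
  syn$emergence <- emergence
  syn$parent_edge <- parent_edge
  syn$phase <- "filtered"
  syn
}
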