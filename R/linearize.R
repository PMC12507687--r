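#' Majority orientation class of edges
#'
#' Returns the majority class of each edge's orientation tally; ties and
#' empty tallies give `"unknown"`.
#'
#' @param edges edge table (or subset of rows) with columns `ht`, `hh`, `tt`.
#' @return character vector of classes.
#' @export
infer_orientation <- function(edges) {
  m <- cbind(edges$ht, edges$hh, edges$tt)
  cls <- c("head_to_tail", "head_to_head", "tail_to_tail")
  apply(m, 1L, function(r) {
    mx <- max(r)
    if (mx == 0L || sum(r == mx) > 1L) "unknown" else cls[which.max(r)]
  })
}

#' Linearize one filtered synteny graph into contigs
#'
#' Flags conflicting genes (more than two neighbours) and removes edges
#' until every gene has at most two. Conflicting genes are processed in
#' decreasing order of their maximum incident edge weight (ties: total
#' incident weight, then gene uid); for each, the two neighbours with
#' maximal linear path weight are kept (the sum of edge weights along the
#' path through the neighbour up to the first gene whose degree differs
#' from two; ties broken by direct edge weight, then neighbour uid) and
#' edges to all other neighbours are removed. Any residual cycle is broken
#' at its minimum-weight edge. Contigs of length >= 2 are emitted with
#' per-gene strands derived from edge orientation classes, the left end of
#' each contig anchored to `+`.
#'
#' @param E data.table of retained edges at one node (columns `g1`, `g2`,
#'   `weight`, `ht`, `hh`, `tt`).
#' @return list with `keep` (logical over rows of `E`) and `contigs`
#'   (data.table `contig_id`, `pos`, `uid`, `strand`).
#' @export
linearize_graph <- function(E) {
  ne <- nrow(E)
  empty_ctg <- data.table::data.table(contig_id = integer(0), pos = integer(0),
                                      uid = integer(0), strand = character(0))
  if (ne == 0L) return(list(keep = logical(0), contigs = empty_ctg))
  genes <- sort(unique(c(E$g1, E$g2)))
  ng <- length(genes)
  a <- match(E$g1, genes); b <- match(E$g2, genes)
  adj <- vector("list", ng)           # incident edge indices per gene
  for (k in seq_len(ne)) {
    adj[[a[k]]] <- c(adj[[a[k]]], k)
    adj[[b[k]]] <- c(adj[[b[k]]], k)
  }
  alive <- rep(TRUE, ne)
  deg <- tabulate(c(a, b), ng)
  other <- function(e, g) if (a[e] == g) b[e] else a[e]

  drop_edge <- function(e) {
    alive[e] <<- FALSE
    deg[a[e]] <<- deg[a[e]] - 1L
    deg[b[e]] <<- deg[b[e]] - 1L
  }

  # linear path weight through neighbour reached by edge e0 from gene g
  path_weight <- function(g, e0) {
    w <- E$weight[e0]
    prev_e <- e0
    cur <- other(e0, g)
    steps <- 0L
    while (deg[cur] == 2L && steps <= ng) {
      es <- adj[[cur]]; es <- es[alive[es] & es != prev_e]
      if (length(es) != 1L) break
      nxt <- other(es, cur)
      w <- w + E$weight[es]
      prev_e <- es
      cur <- nxt
      if (cur == g) break  # came around a cycle
      steps <- steps + 1L
    }
    w
  }

  repeat {
    confl <- which(deg > 2L)
    if (!length(confl)) break
    maxw <- vapply(confl, function(g) max(E$weight[adj[[g]][alive[adj[[g]]]]]), 0L)
    totw <- vapply(confl, function(g) sum(E$weight[adj[[g]][alive[adj[[g]]]]]), 0L)
    ord <- confl[order(-maxw, -totw, genes[confl])]
    progressed <- FALSE
    for (g in ord) {
      es <- adj[[g]]; es <- es[alive[es]]
      if (length(es) <= 2L) next
      pw <- vapply(es, function(e) path_weight(g, e), 0)
      nb <- vapply(es, function(e) genes[other(e, g)], 0L)
      keep2 <- es[order(-pw, -E$weight[es], nb)][1:2]
      for (e in setdiff(es, keep2)) drop_edge(e)
      progressed <- TRUE
    }
    if (!progressed) break
  }

  # break residual cycles at their minimum-weight edge
  visited <- rep(FALSE, ng)
  for (s in seq_len(ng)) {
    if (visited[s] || deg[s] == 0L) next
    comp <- integer(0); stack <- s; visited[s] <- TRUE
    while (length(stack)) {
      gcur <- stack[length(stack)]; stack <- stack[-length(stack)]
      comp <- c(comp, gcur)
      for (e in adj[[gcur]]) {
        if (!alive[e]) next
        o <- other(e, gcur)
        if (!visited[o]) { visited[o] <- TRUE; stack <- c(stack, o) }
      }
    }
    if (all(deg[comp] == 2L)) {  # a simple cycle
      ces <- unique(unlist(adj[comp]))
      ces <- ces[alive[ces]]
      pick <- ces[order(E$weight[ces], E$g1[ces], E$g2[ces])][1L]
      drop_edge(pick)
    }
  }

  # trace contigs from degree-1 endpoints, smaller uid end first
  ctg <- list(); ci <- 0L
  used <- rep(FALSE, ng)
  ends <- which(deg == 1L)
  ends <- ends[order(genes[ends])]
  for (s in ends) {
    if (used[s]) next
    path_g <- s; path_e <- integer(0)
    used[s] <- TRUE
    cur <- s; prev_e <- 0L
    repeat {
      es <- adj[[cur]]; es <- es[alive[es] & es != prev_e]
      if (!length(es)) break
      e <- es[1L]
      nxt <- other(e, cur)
      path_g <- c(path_g, nxt); path_e <- c(path_e, e)
      used[nxt] <- TRUE
      prev_e <- e; cur <- nxt
    }
    if (length(path_g) < 2L) next
    ci <- ci + 1L
    cls <- infer_orientation(E[path_e])
    strand <- character(length(path_g))
    strand[1L] <- "+"; eff <- "+"
    for (k in seq_along(path_e)) {
      nxt <- switch(cls[k],
        head_to_tail = eff,
        head_to_head = if (eff == "+") "-" else NA_character_,
        tail_to_tail = if (eff == "-") "+" else NA_character_,
        NA_character_)
      if (is.na(nxt)) {           # orientation signal broken: re-anchor
        strand[k + 1L] <- "unknown"; eff <- "+"
      } else {
        strand[k + 1L] <- nxt; eff <- nxt
      }
    }
    ctg[[ci]] <- data.table::data.table(
      contig_id = ci, pos = seq_along(path_g),
      uid = genes[path_g], strand = strand)
  }
  keep <- alive
  contigs <- if (ci) data.table::rbindlist(ctg) else empty_ctg
  # structural guarantee: max degree 2 and acyclic
  stopifnot(all(deg <= 2L))
  n_alive <- sum(alive)
  n_in_paths <- if (ci) sum(vapply(ctg, nrow, 0L) - 1L) else 0L
  stopifnot(n_alive == n_in_paths)  # no residual cycles survive
  list(keep = keep, contigs = contigs)
}

#' Linearize every ancestral graph of a filtered synteny set
#'
#' Applies [linearize_graph()] to the retained edges of each internal node,
#' independently of every other node. Leaves keep their observed contigs.
#'
#' @param syn a `synteny_set` with phase `"filtered"`.
#' @param genomes named list of gene tables (from [read_gff()]) used to emit
#'   the extant contigs at the leaves; optional.
#' @return the `synteny_set` with per-node `kept` (logical over edges) and
#'   `contigs`, phase `"linearized"`.
#' @export
linearize <- function(syn, genomes = NULL) {
  stopifnot(inherits(syn, "synteny_set"), syn$phase == "filtered")
  tree <- syn$tree
  n_node <- length(tree$labels)
  kept <- vector("list", n_node)
  contigs <- vector("list", n_node)
  for (v in tree$preorder) {
    E <- syn$edges[[v]]
    ne <- if (is.null(E)) 0L else nrow(E)
    if (tree$is_leaf[v]) {
      kept[[v]] <- rep(TRUE, ne)
      lab <- tree$labels[v]
      if (!is.null(genomes) && !is.null(genomes[[lab]])) {
        gdf <- genomes[[lab]]
        o <- order(gdf$contig, gdf$rank, method = "radix")
        gdf <- gdf[o, , drop = FALSE]
        uid <- unname(syn$lin$ext_uid[paste(lab, gdf$gene_id, sep = "\r")])
        cid <- match(gdf$contig, unique(gdf$contig))
        contigs[[v]] <- data.table::data.table(
          contig_id = cid, pos = gdf$rank + 1L, uid = uid, strand = gdf$strand)
      }
      next
    }
    if (ne == 0L) {
      kept[[v]] <- logical(0)
      contigs[[v]] <- data.table::data.table(contig_id = integer(0), pos = integer(0),
                                             uid = integer(0), strand = character(0))
      next
    }
    ret <- which(syn$retained[[v]])
    res <- linearize_graph(syn$edges[[v]][ret])
    kp <- rep(FALSE, ne)
    kp[ret[res$keep]] <- TRUE
    kept[[v]] <- kp
    contigs[[v]] <- res$contigs
  }
  syn$kept <- kept
  syn$contigs <- contigs
  syn$phase <- "linearized"
  syn
}

#' Adjacencies implied by contigs
#' @keywords internal
contig_pairs <- function(ctg) {
  if (is.null(ctg) || nrow(ctg) < 2L) {
    return(data.table::data.table(g1 = integer(0), g2 = integer(0)))
  }
  n <- nrow(ctg)
  i <- which(ctg$contig_id[-n] == ctg$contig_id[-1L])
  data.table::data.table(g1 = pmin(ctg$uid[i], ctg$uid[i + 1L]),
                         g2 = pmax(ctg$uid[i], ctg$uid[i + 1L]))
}
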