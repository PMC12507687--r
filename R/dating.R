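#' Date adjacencies to their clade of emergence
#'
#' Collects every retained ancestral adjacency and every extant adjacency
#' with its emergence node: the root-most node of the species tree at which
#' the adjacency lineage survives the parsimony filter (the leaf itself for
#' species-specific adjacencies).
#'
#' @param syn a `synteny_set` with phase `"filtered"` or `"linearized"`.
#' @param ages optional named numeric vector of node ages (see
#'   [ages_from_table()]); when given, an `age_ma` column is added.
#' @return data.table with columns `node` (where the edge lives), `edge`
#'   (edge id there), `gene1`, `gene2` (labels), `weight`, `emergence`
#'   (node label) and optionally `age_ma`.
#' @export
date_edges <- function(syn, ages = NULL) {
  stopifnot(inherits(syn, "synteny_set"),
            syn$phase %in% c("filtered", "linearized"))
  tree <- syn$tree; lin <- syn$lin
  out <- list(); oi <- 0L
  for (v in tree$preorder) {
    E <- syn$edges[[v]]
    if (is.null(E) || nrow(E) == 0L) next
    sel <- if (tree$is_leaf[v]) rep(TRUE, nrow(E)) else syn$retained[[v]]
    if (!any(sel)) next
    oi <- oi + 1L
    out[[oi]] <- data.table::data.table(
      node = tree$labels[v], edge = E$id[sel],
      gene1 = lin$label[E$g1[sel]], gene2 = lin$label[E$g2[sel]],
      weight = E$weight[sel],
      emergence = tree$labels[syn$emergence[[v]][sel]])
  }
  res <- if (oi) data.table::rbindlist(out) else {
    data.table::data.table(node = character(0), edge = integer(0),
                           gene1 = character(0), gene2 = character(0),
                           weight = integer(0), emergence = character(0))
  }
  if (!is.null(ages)) {
    full <- ages_from_table(tree, ages)
    res[, age_ma := full[match(emergence, tree$labels)]]
  }
  res[]
}

#' Resolve node ages from a partial age table
#'
#' Leaves are attributed age 0. Internal nodes present in the table keep
#' their age. Any remaining node is assigned the average of the age of its
#' most recent ancestor with age information and the maximum age among its
#' children with age information, applied iteratively from root to leaves
#' until all nodes are resolved.
#'
#' @param tree a `species_tree`.
#' @param ages named numeric vector (names are internal node labels, values
#'   ages in millions of years) or a two-column data.frame (label, age).
#' @return numeric vector of ages indexed by tree node.
#' @export
ages_from_table <- function(tree, ages) {
  if (is.data.frame(ages)) {
    ages <- stats::setNames(as.numeric(ages[[2L]]), as.character(ages[[1L]]))
  }
  if (any(is.na(ages) | ages < 0)) stop_input("age table: ages must be non-negative numbers")
  unknown <- setdiff(names(ages), tree$labels)
  if (length(unknown)) {
    stop_input(paste0("age table refers to unknown node label(s): ",
                      paste(unknown, collapse = ", ")))
  }
  age <- rep(NA_real_, length(tree$labels))
  age[match(names(ages), tree$labels)] <- unname(ages)
  # consistency: a node must not be older than its nearest aged ancestor
  for (v in tree$preorder) {
    if (is.na(age[v])) next
    p <- tree$parent[v]
    while (!is.na(p) && is.na(age[p])) p <- tree$parent[p]
    if (!is.na(p) && age[v] > age[p]) {
      stop_input(sprintf("age table: node '%s' (%g Ma) is older than its ancestor '%s' (%g Ma)",
                         tree$labels[v], age[v], tree$labels[p], age[p]))
    }
  }
  age[tree$is_leaf] <- 0
  repeat {
    changed <- FALSE
    for (v in tree$preorder) {
      if (!is.na(age[v])) next
      anc <- tree$parent[v]
      while (!is.na(anc) && is.na(age[anc])) anc <- tree$parent[anc]
      if (is.na(anc)) next
      ch_ages <- age[tree$children[[v]]]
      ch_ages <- ch_ages[!is.na(ch_ages)]
      if (!length(ch_ages)) next
      age[v] <- (age[anc] + max(ch_ages)) / 2
      changed <- TRUE
    }
    if (!changed) break
  }
  if (anyNA(age)) {
    stop_input(paste0("no aged node on the path to the root for: ",
                      paste(tree$labels[is.na(age)], collapse = ", ")))
  }
  age
}

#' Per-node phylostratigraphy of adjacency events
#'
#' For every tree node, counts adjacencies gained (emergence at the node),
#' retained (also retained at the parent), lost (a retained parent edge
#' both of whose endpoint genes have surviving lineages at the node, with
#' no corresponding edge retained at the node) and duplicated (edges merged
#' from two or more child edges within a single child level). Requiring
#' both endpoint lineages to survive isolates rearrangement-driven loss
#' from gene loss.
#'
#' @param syn a `synteny_set` with phase `"filtered"` or `"linearized"`.
#' @return data.table with columns `node`, `gained`, `retained`, `lost`,
#'   `duplicated`.
#' @export
phylostratigraphy <- function(syn) {
  stopifnot(inherits(syn, "synteny_set"),
            syn$phase %in% c("filtered", "linearized"))
  tree <- syn$tree; lin <- syn$lin
  kids <- lineage_children(lin)
  out <- data.table::data.table(
    node = tree$labels[tree$preorder],
    gained = 0L, retained = 0L, lost = 0L, duplicated = 0L)
  for (k in seq_along(tree$preorder)) {
    v <- tree$preorder[k]
    E <- syn$edges[[v]]
    ne <- if (is.null(E)) 0L else nrow(E)
    p <- tree$parent[v]
    if (ne) {
      sel <- if (tree$is_leaf[v]) rep(TRUE, ne) else syn$retained[[v]]
      em <- syn$emergence[[v]]
      out$gained[k] <- sum(sel & em == v, na.rm = TRUE)
      if (!is.na(p)) {
        pe <- syn$parent_edge[[v]]
        pr <- !is.na(pe) & syn$retained[[p]][ifelse(is.na(pe), 1L, pe)]
        out$retained[k] <- sum(sel & pr, na.rm = TRUE)
      }
      if (!tree$is_leaf[v]) {
        out$duplicated[k] <- sum(sel & E$dupsup, na.rm = TRUE)
      }
    }
    # losses: check each retained parent edge against this node
    if (!is.na(p) && !is.null(syn$edges[[p]]) && nrow(syn$edges[[p]])) {
      P <- syn$edges[[p]][syn$retained[[p]]]
      if (nrow(P)) {
        here <- if (ne) {
          sel <- if (tree$is_leaf[v]) rep(TRUE, ne) else syn$retained[[v]]
          paste(E$g1[sel], E$g2[sel])
        } else character(0)
        nlost <- 0L
        for (j in seq_len(nrow(P))) {
          c1 <- kids[[P$g1[j]]]; c1 <- c1[lin$node[c1] == v]
          c2 <- kids[[P$g2[j]]]; c2 <- c2[lin$node[c2] == v]
          if (!length(c1) || !length(c2)) next
          pairs <- expand.grid(x = c1, y = c2)
          key <- paste(pmin(pairs$x, pairs$y), pmax(pairs$x, pairs$y))
          if (!any(key %in% here)) nlost <- nlost + 1L
        }
        out$lost[k] <- nlost
      }
    }
  }
  out[]
}

#' Find clusters of qualifying adjacencies along a contig
#'
#' Scans an ordered contig for maximal runs of qualifying adjacencies in
#' which consecutive qualifying adjacencies are separated by fewer than
#' `gap_lt` genes, and keeps runs with more than `size_gt` qualifying
#' adjacencies. Defaults follow the histone-cluster definition: more than
#' four adjacencies, fewer than ten genes between them.
#'
#' @param qualifies logical vector over the contig's adjacencies (adjacency
#'   `i` joins genes `i` and `i + 1`).
#' @param size_gt minimum cluster size, exclusive (default 4).
#' @param gap_lt maximum number of intervening genes, exclusive (default 10).
#' @return data.table with columns `first_adj`, `last_adj`, `size` (one row
#'   per cluster).
#' @export
find_adjacency_clusters <- function(qualifies, size_gt = 4L, gap_lt = 10L) {
  idx <- which(qualifies)
  empty <- data.table::data.table(first_adj = integer(0), last_adj = integer(0),
                                  size = integer(0))
  if (!length(idx)) return(empty)
  # genes strictly between adjacency i and j (i < j) number j - i - 1
  brk <- c(TRUE, diff(idx) - 1L >= gap_lt)
  grp <- cumsum(brk)
  res <- data.table::data.table(idx = idx, grp = grp)[
    , .(first_adj = min(idx), last_adj = max(idx), size = .N), by = grp][
      size > size_gt, .(first_adj, last_adj, size)]
  if (nrow(res) == 0L) empty else res[]
}
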