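#' Read a rooted species tree from newick
#'
#' Parses a newick string (or file) into an indexed, rooted species tree.
#' Internal nodes without a label receive a deterministic synthetic label of
#' the form `Nk`, where `k` is the node's preorder position, so repeated runs
#' on the same newick always yield the same labels. Multifurcations are
#' preserved. A root with exactly three children is rejected as the
#' conventional encoding of an unrooted tree; binary roots and explicit
#' multifurcating roots (4+ children) are accepted.
#'
#' @param newick Newick text, or path to a file containing it.
#' @return An object of class `species_tree`: a list with elements
#'   `labels` (character, one per node), `parent` (integer, `NA` at root),
#'   `children` (list of integer vectors), `is_leaf` (logical), `root`
#'   (integer index), `n_tip`, `preorder`, `postorder` (integer node
#'   orderings), `depth` (integer, root = 0), `edge_length` (numeric per
#'   node, length of the branch above, `NA` if absent) and `lo`/`hi`
#'   (contiguous leaf-order intervals used for O(1) ancestor queries).
#' @export
read_species_tree <- function(newick) {
  txt <- newick
  if (length(txt) == 1L && !grepl("[(;]", txt) && file.exists(txt)) {
    txt <- paste(readLines(txt, warn = FALSE), collapse = "")
  }
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop_input("species tree: not valid newick")
  }
  if (ape::Ntip(phy) < 2L) stop_input("species tree must have at least 2 leaves")
  species_tree_from_phylo(phy)
}

#' @keywords internal
species_tree_from_phylo <- function(phy) {
  n_tip <- ape::Ntip(phy)
  n_node <- n_tip + phy$Nnode
  parent <- rep(NA_integer_, n_node)
  children <- vector("list", n_node)
  for (i in seq_len(n_node)) children[[i]] <- integer(0)
  # edge rows are in newick appearance order; keep that child order
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; c <- phy$edge[i, 2L]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  root <- which(is.na(parent))
  if (length(root) != 1L) stop_input("species tree must have exactly one root")
  if (length(children[[root]]) == 3L) {
    stop_input(paste0("species tree root has 3 children: this is the usual ",
                      "encoding of an unrooted tree; please provide a rooted tree"))
  }

  labels <- character(n_node)
  labels[seq_len(n_tip)] <- phy$tip.label
  if (!is.null(phy$node.label)) labels[(n_tip + 1L):n_node] <- phy$node.label
  edge_length <- rep(NA_real_, n_node)
  if (!is.null(phy$edge.length)) edge_length[phy$edge[, 2L]] <- phy$edge.length

  # iterative preorder (children in stored order)
  pre <- integer(n_node); k <- 0L
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; pre[k] <- v
    kids <- children[[v]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  prepos <- integer(n_node); prepos[pre] <- seq_len(n_node)

  # deterministic synthetic labels for unlabeled internal nodes
  unlab <- which(is.na(labels) | labels == "")
  if (length(unlab)) labels[unlab] <- paste0("N", prepos[unlab])
  if (anyDuplicated(labels)) {
    stop_input(paste0("duplicate node labels in species tree: ",
                      paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }

  depth <- integer(n_node)
  for (v in pre) if (!is.na(parent[v])) depth[v] <- depth[parent[v]] + 1L

  # contiguous leaf intervals in preorder-leaf order, for fast ancestry tests
  leaf_pos <- integer(n_node); lp <- 0L
  for (v in pre) if (v <= n_tip) { lp <- lp + 1L; leaf_pos[v] <- lp }
  lo <- rep(.Machine$integer.max, n_node); hi <- rep(0L, n_node)
  for (v in rev(pre)) {
    if (v <= n_tip) { lo[v] <- leaf_pos[v]; hi[v] <- leaf_pos[v] }
    if (!is.na(parent[v])) {
      p <- parent[v]
      lo[p] <- min(lo[p], lo[v]); hi[p] <- max(hi[p], hi[v])
    }
  }

  structure(list(
    labels = labels, parent = parent, children = children,
    is_leaf = seq_len(n_node) <= n_tip, root = root, n_tip = n_tip,
    preorder = pre, postorder = rev(pre), depth = depth,
    edge_length = edge_length,
    lo = lo, hi = hi
  ), class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("<species_tree> %d leaves, %d internal nodes, root '%s'\n",
              x$n_tip, length(x$labels) - x$n_tip, x$labels[x$root]))
  invisible(x)
}

#' Node index for a label
#' @keywords internal
node_of <- function(tree, label) {
  i <- match(label, tree$labels)
  if (anyNA(i)) {
    stop_input(paste0("unknown species-tree node label(s): ",
                      paste(label[is.na(i)], collapse = ", ")))
  }
  i
}

#' Is `a` an ancestor of (or equal to) `b`? Vectorized over b.
#' @keywords internal
is_ancestor_or_self <- function(tree, a, b) {
  tree$lo[b] >= tree$lo[a] & tree$hi[b] <= tree$hi[a]
}

#' MRCA of a set of nodes
#' @keywords internal
tree_mrca <- function(tree, nodes) {
  nodes <- unique(nodes)
  v <- nodes[1L]
  for (w in nodes[-1L]) {
    while (!is_ancestor_or_self(tree, v, w)) v <- tree$parent[v]
  }
  # v is now an ancestor of w's seen so far but earlier nodes may escape it
  repeat {
    if (all(is_ancestor_or_self(tree, v, nodes))) return(v)
    v <- tree$parent[v]
  }
}

#' Nodes on the path from ancestor `a` (exclusive) down to `d` (inclusive)
#' @keywords internal
tree_path_down <- function(tree, a, d) {
  out <- integer(0)
  v <- d
  while (!is.na(v) && v != a) { out <- c(out, v); v <- tree$parent[v] }
  if (is.na(v)) stop("tree_path_down: 'a' is not an ancestor of 'd'")
  rev(out)
}

#' Leaves under a node
#' @keywords internal
leaves_under <- function(tree, v) {
  tips <- which(tree$is_leaf)
  tips[tree$lo[tips] >= tree$lo[v] & tree$hi[tips] <= tree$hi[v]]
}

#' Number of leaf species in the clade of each node
#' @keywords internal
clade_sizes <- function(tree) {
  tree$hi - tree$lo + 1L
}

#' Serialize a species tree back to newick
#' @param tree a `species_tree`
#' @return newick string (with node labels and branch lengths when present)
#' @export
write_species_tree <- function(tree) {
  rec <- function(v) {
    lab <- tree$labels[v]
    bl <- if (is.na(tree$edge_length[v])) "" else sprintf(":%g", tree$edge_length[v])
    if (tree$is_leaf[v]) return(paste0(lab, bl))
    paste0("(", paste(vapply(tree$children[[v]], rec, ""), collapse = ","),
           ")", lab, bl)
  }
  paste0(rec(tree$root), ";")
}

#' @keywords internal
stop_input <- function(msg) {
  stop(structure(class = c("ancora_input_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
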