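# Structural invariants. These are cheap enough to assert on every run and
# are exercised directly by the test suite.

#' Recount edge weights from their support closure
#'
#' Independent recomputation of every edge weight: the weight of an extant
#' edge is 1; the weight of an ancestral edge is the number of gain-bridging
#' events merged into it plus the recounted weights of all child edges that
#' propagated into it. When no gains occurred this equals the number of
#' extant observed adjacencies in the edge's transitive support closure.
#'
#' @param syn a `synteny_set`.
#' @return list (per node) of recounted weights, aligned with edge ids.
#' @export
recount_weights <- function(syn) {
  tree <- syn$tree
  out <- vector("list", length(tree$labels))
  for (v in tree$postorder) {
    E <- syn$edges[[v]]
    ne <- if (is.null(E)) 0L else nrow(E)
    if (ne == 0L) { out[[v]] <- integer(0); next }
    if (tree$is_leaf[v]) { out[[v]] <- rep(1L, ne); next }
    w <- E$nbridge
    s <- syn$sup[[v]]
    if (!is.null(s) && nrow(s)) {
      contrib <- s[, .(add = sum(out[[child[1L]]][cedge])), by = .(child, pedge)][
        , .(add = sum(add)), by = pedge]
      w[contrib$pedge] <- w[contrib$pedge] + contrib$add
    }
    out[[v]] <- w
  }
  out
}

#' Check that every linearized graph is a disjoint union of simple paths
#' @param syn a linearized `synteny_set`
#' @return TRUE (errors otherwise)
#' @export
check_linear <- function(syn) {
  stopifnot(syn$phase == "linearized")
  for (v in which(!syn$tree$is_leaf)) {
    E <- syn$edges[[v]]
    if (is.null(E) || !nrow(E)) next
    K <- E[syn$kept[[v]]]
    if (!nrow(K)) next
    genes <- unique(c(K$g1, K$g2))
    deg <- tabulate(match(c(K$g1, K$g2), genes), length(genes))
    if (any(deg > 2L)) stop("linearized graph has a gene with degree > 2")
    # paths have exactly one more gene than edges in every component
    if (nrow(K) != length(genes) - n_components(K, genes)) {
      stop("linearized graph contains a cycle")
    }
  }
  TRUE
}

#' @keywords internal
n_components <- function(E, genes) {
  n <- length(genes)
  uf <- seq_len(n)
  find <- function(i) { while (uf[i] != i) { uf[i] <<- uf[uf[i]]; i <- uf[i] }; i }
  a <- match(E$g1, genes); b <- match(E$g2, genes)
  for (k in seq_len(nrow(E))) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) uf[ra] <- rb
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

#' Check emergence stamps against exhibiting species
#'
#' Every dated extant adjacency's emergence node must be an ancestor (or
#' the leaf itself) of the species exhibiting it, and every retained
#' ancestral edge's emergence must be an ancestor-or-self of its node.
#'
#' @param syn a filtered or linearized `synteny_set`
#' @return TRUE (errors otherwise)
#' @export
check_emergence <- function(syn) {
  tree <- syn$tree
  for (v in seq_along(tree$labels)) {
    E <- syn$edges[[v]]
    if (is.null(E) || !nrow(E)) next
    sel <- if (tree$is_leaf[v]) rep(TRUE, nrow(E)) else syn$retained[[v]]
    em <- syn$emergence[[v]][sel]
    if (!length(em)) next
    if (!all(is_ancestor_or_self(tree, em, rep(v, length(em))))) {
      stop("emergence node is not an ancestor of the edge's node")
    }
  }
  TRUE
}
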