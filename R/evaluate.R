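#' Table of ancestral genes above every extant gene
#'
#' One row per (extant gene, ancestral gene on its lineage chain), built by
#' climbing parent links. Used to compare two reconstructions through their
#' shared extant gene universe.
#'
#' @param lin a `lineage_forest`.
#' @return data.table with columns `ext_key` (`species\rgene_id`), `anc`
#'   (ancestral gene uid) and `node` (the ancestor's tree node).
#' @export
descendant_table <- function(lin) {
  ext <- which(lin$is_extant)
  key <- paste(lin$tree$labels[lin$node[ext]], lin$label[ext], sep = "\r")
  acc <- list(); ai <- 0L
  cur <- lin$parent[ext]
  k <- key
  while (any(!is.na(cur))) {
    keep <- !is.na(cur)
    cur <- cur[keep]; k <- k[keep]
    ai <- ai + 1L
    acc[[ai]] <- data.table::data.table(ext_key = k, anc = cur,
                                        node = lin$node[cur])
    cur <- lin$parent[cur]
  }
  if (!ai) return(data.table::data.table(ext_key = character(0),
                                         anc = integer(0), node = integer(0)))
  data.table::rbindlist(acc)
}

#' Map inferred ancestral genes to true ancestral genes at one level
#'
#' Greedy maximum-overlap assignment: candidate (inferred, true) pairs are
#' ranked by the number of descendant extant genes they share (ties broken
#' by the two uids) and assigned injectively, largest overlaps first.
#' Genes sharing no descendants stay unmapped.
#'
#' @param inf_dt,true_dt subsets of [descendant_table()] rows for one level
#'   (columns `ext_key`, `anc`).
#' @return data.table with columns `inf`, `true`, `overlap`.
#' @export
map_ancestral_genes <- function(inf_dt, true_dt) {
  m <- merge(inf_dt[, .(ext_key, inf = anc)], true_dt[, .(ext_key, true = anc)],
             by = "ext_key", allow.cartesian = TRUE)
  if (nrow(m) == 0L) {
    return(data.table::data.table(inf = integer(0), true = integer(0),
                                  overlap = integer(0)))
  }
  ov <- m[, .(overlap = .N), by = .(inf, true)]
  data.table::setorder(ov, -overlap, inf, true)
  inf_taken <- new.env(parent = emptyenv())
  true_taken <- new.env(parent = emptyenv())
  keep <- logical(nrow(ov))
  for (i in seq_len(nrow(ov))) {
    ki <- as.character(ov$inf[i]); kt <- as.character(ov$true[i])
    if (is.null(inf_taken[[ki]]) && is.null(true_taken[[kt]])) {
      keep[i] <- TRUE
      inf_taken[[ki]] <- TRUE; true_taken[[kt]] <- TRUE
    }
  }
  ov[keep]
}

#' Precision and recall of inferred adjacencies at one level
#'
#' An inferred edge is a true positive when both endpoints map to true
#' genes and the mapped pair is a true adjacency; otherwise a false
#' positive. False negatives are true adjacencies not recovered. Scores
#' follow `precision = 100 TP / (TP + FP)` and
#' `recall = 100 TP / (TP + FN)`; an undefined ratio (empty denominator)
#' is reported as `NA`.
#'
#' @param inf_pairs data.table `g1`, `g2` of inferred adjacencies (uids in
#'   the inferred lineage).
#' @param true_pairs data.table `g1`, `g2` of true adjacencies (uids in the
#'   true lineage).
#' @param mapping result of [map_ancestral_genes()].
#' @return one-row data.table `TP`, `FP`, `FN`, `precision`, `recall`.
#' @export
precision_recall <- function(inf_pairs, true_pairs, mapping) {
  map <- rep(NA_integer_, max(c(1L, inf_pairs$g1, inf_pairs$g2, mapping$inf)))
  map[mapping$inf] <- mapping$true
  true_key <- paste(pmin(true_pairs$g1, true_pairs$g2),
                    pmax(true_pairs$g1, true_pairs$g2))
  ni <- nrow(inf_pairs)
  if (ni) {
    m1 <- map[inf_pairs$g1]; m2 <- map[inf_pairs$g2]
    ok <- !is.na(m1) & !is.na(m2)
    hit_key <- paste(pmin(m1, m2), pmax(m1, m2))
    tp_edges <- ok & hit_key %in% true_key
    TP <- sum(tp_edges)
  } else TP <- 0L
  FP <- ni - TP
  FN <- length(unique(true_key)) - (if (ni) length(unique(hit_key[tp_edges])) else 0L)
  data.table::data.table(
    TP = TP, FP = FP, FN = FN,
    precision = if (ni) 100 * TP / (TP + FP) else NA_real_,
    recall = if (length(true_key)) 100 * TP / (TP + FN) else NA_real_)
}

#' Harmonic mean of percentages
#'
#' `NA` values are dropped (with a message when any are); a zero anywhere
#' makes the harmonic mean 0 (with a warning).
#'
#' @param values numeric vector of percentages.
#' @return the harmonic mean `n / sum(1/v)`.
#' @export
harmonic_mean <- function(values) {
  nna <- sum(is.na(values))
  if (nna) message(sprintf("harmonic_mean: dropping %d undefined value(s)", nna))
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  if (any(values == 0)) {
    warning("harmonic_mean: zero value present; harmonic mean is 0")
    return(0)
  }
  length(values) / sum(1 / values)
}

#' Evaluate a reconstruction against simulation truth
#'
#' Maps inferred to true ancestral genes per level (maximal shared extant
#' descendants) and scores inferred adjacencies at every internal node of
#' the species tree. Tree nodes are matched by label between the inferred
#' and true lineages.
#'
#' @param syn a linearized `synteny_set` (the inference result).
#' @param truth a `simulation_truth`.
#' @param step which inferred edge set to score: final `"linearized"`
#'   contig adjacencies (default), `"filtered"` retained edges, or all
#'   `"propagated"` candidates.
#' @return list with `per_level` (data.table: `node`, `TP`, `FP`, `FN`,
#'   `precision`, `recall`) and `hm_precision`, `hm_recall` (harmonic means
#'   over levels where the score is defined).
#' @export
evaluate_reconstruction <- function(syn, truth,
                                    step = c("linearized", "filtered", "propagated")) {
  step <- match.arg(step)
  tree <- syn$tree
  tlin <- as_lineage_forest(truth)
  inf_desc <- descendant_table(syn$lin)
  true_desc <- descendant_table(tlin)
  data.table::setkey(inf_desc, node)
  data.table::setkey(true_desc, node)

  res <- list(); ri <- 0L
  for (v in tree$preorder) {
    if (tree$is_leaf[v]) next
    tv <- match(tree$labels[v], truth$tree$labels)
    if (is.na(tv)) next
    g <- truth$orders[[tv]]
    tp_list <- lapply(g, function(ct) {
      u <- tlin$uid_of_inst[ct$inst]
      n <- length(u)
      if (n < 2L) NULL else data.table::data.table(g1 = u[-n], g2 = u[-1L])
    })
    true_pairs <- data.table::rbindlist(tp_list[!vapply(tp_list, is.null, TRUE)])
    if (is.null(true_pairs) || nrow(true_pairs) == 0L) {
      true_pairs <- data.table::data.table(g1 = integer(0), g2 = integer(0))
    }
    inf_pairs <- switch(step,
      linearized = contig_pairs(syn$contigs[[v]]),
      filtered = {
        E <- syn$edges[[v]]
        if (is.null(E) || !nrow(E)) data.table::data.table(g1 = integer(0), g2 = integer(0))
        else E[syn$retained[[v]], .(g1, g2)]
      },
      propagated = {
        E <- syn$edges[[v]]
        if (is.null(E) || !nrow(E)) data.table::data.table(g1 = integer(0), g2 = integer(0))
        else E[, .(g1, g2)]
      })
    mp <- map_ancestral_genes(inf_desc[.(v), .(ext_key, anc), nomatch = NULL],
                              true_desc[.(tv), .(ext_key, anc), nomatch = NULL])
    pr <- precision_recall(inf_pairs, true_pairs, mp)
    ri <- ri + 1L
    res[[ri]] <- data.table::data.table(node = tree$labels[v], pr)
  }
  per_level <- data.table::rbindlist(res)
  list(per_level = per_level,
       hm_precision = suppressMessages(harmonic_mean(per_level$precision)),
       hm_recall = suppressMessages(harmonic_mean(per_level$recall)))
}

#' Project ancestral adjacencies into a masked extant genome
#'
#' For every adjacency retained at the direct ancestor of the masked
#' species, the corresponding extant gene pair is predicted if and only if
#' both ancestral endpoints have exactly one descendant gene in the masked
#' species (no descending paralogues, which would leave the copies
#' unphased).
#'
#' @param syn a filtered or linearized `synteny_set`.
#' @param species masked species label.
#' @return data.table `gene1`, `gene2` of predicted extant gene ids.
#' @export
project_to_masked <- function(syn, species) {
  tree <- syn$tree; lin <- syn$lin
  leaf <- node_of(tree, species)
  anc <- tree$parent[leaf]
  E <- syn$edges[[anc]]
  if (is.null(E) || !nrow(E)) {
    return(data.table::data.table(gene1 = character(0), gene2 = character(0)))
  }
  E <- E[syn$retained[[anc]]]
  if (!nrow(E)) {
    return(data.table::data.table(gene1 = character(0), gene2 = character(0)))
  }
  kids <- lineage_children(lin)
  desc1 <- function(u) {
    d <- descendant_genes(lin, u, species = species, kids = kids)
    if (length(d) == 1L) d else NA_integer_
  }
  d1 <- vapply(E$g1, desc1, 0L)
  d2 <- vapply(E$g2, desc1, 0L)
  ok <- !is.na(d1) & !is.na(d2)
  data.table::data.table(gene1 = lin$label[d1[ok]], gene2 = lin$label[d2[ok]])
}
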