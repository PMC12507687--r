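#' Simulation parameters
#'
#' Event rates are per gene and per unit branch length; event counts on a
#' branch are Poisson with mean `rate * genome size at branch start *
#' branch length`. Two presets bundle the rate choices used throughout the
#' package's benchmarks: `"low_rearrangement"` emulates a benign regime in
#' which orthology is easy and rearrangements are rare (a handful of events
#' per branch at 1,000 genes), and `"harsh"` a regime with an order of
#' magnitude more rearrangement.
#'
#' @param n_leaves number of extant genomes.
#' @param root_genes number of genes in the root genome.
#' @param root_contigs number of root chromosomes/contigs.
#' @param rates named list with elements `gain`, `loss`, `dup_tandem`,
#'   `dup_dispersed`, `inversion`, `translocation`.
#' @param inv_len_mean mean length (genes) of inverted or translocated
#'   segments; lengths are `1 + Geometric`.
#' @param branch_mean mean of the exponential branch lengths of the
#'   generated Yule tree.
#' @param seed integer seed fixing the entire simulation output.
#' @param preset `NULL`, `"low_rearrangement"` or `"harsh"`; a preset
#'   overrides `rates`.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_leaves = 20L, root_genes = 200L, root_contigs = 5L,
                       rates = list(gain = 0.001, loss = 0.001,
                                    dup_tandem = 0.0005, dup_dispersed = 0.0002,
                                    inversion = 0.002, translocation = 0.0005),
                       inv_len_mean = 3, branch_mean = 1, seed = 1L,
                       preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("low_rearrangement", "harsh"))
    rates <- switch(preset,
      low_rearrangement = list(gain = 0.001, loss = 0.001,
                               dup_tandem = 0.0005, dup_dispersed = 0.0002,
                               inversion = 0.002, translocation = 0.0005),
      harsh = list(gain = 0.005, loss = 0.005,
                   dup_tandem = 0.002, dup_dispersed = 0.001,
                   inversion = 0.02, translocation = 0.005))
  }
  need <- c("gain", "loss", "dup_tandem", "dup_dispersed", "inversion",
            "translocation")
  stopifnot(all(need %in% names(rates)),
            all(unlist(rates[need]) >= 0), n_leaves >= 2L, root_genes >= 1L,
            root_contigs >= 1L, inv_len_mean >= 1, branch_mean > 0)
  structure(list(n_leaves = as.integer(n_leaves),
                 root_genes = as.integer(root_genes),
                 root_contigs = as.integer(root_contigs),
                 rates = rates[need], inv_len_mean = inv_len_mean,
                 branch_mean = branch_mean, seed = as.integer(seed)),
            class = "sim_params")
}

# Yule topology: split uniformly chosen leaves until n are present;
# exponential branch lengths; leaves labelled S1.. and internal nodes A1..
# in preorder. Uses the current RNG stream.
#' @keywords internal
yule_newick <- function(n_leaves, branch_mean) {
  children <- list(integer(0))
  nn <- 1L
  add_child <- function(p) {
    nn <<- nn + 1L
    children[[p]] <<- c(children[[p]], nn)
    children[[nn]] <<- integer(0)
    nn
  }
  leaves <- c(add_child(1L), add_child(1L))
  while (length(leaves) < n_leaves) {
    i <- sample.int(length(leaves), 1L)
    v <- leaves[i]
    leaves <- c(leaves[-i], add_child(v), add_child(v))
  }
  bl <- stats::rexp(nn, rate = 1 / branch_mean)
  lc <- 0L; ic <- 0L
  rec <- function(v, is_root) {
    if (!length(children[[v]])) {
      lc <<- lc + 1L
      return(sprintf("S%d:%.6f", lc, bl[v]))
    }
    ic <<- ic + 1L
    lab <- sprintf("A%d", ic)
    kids <- paste(vapply(children[[v]], rec, "", is_root = FALSE), collapse = ",")
    if (is_root) sprintf("(%s)%s", kids, lab) else sprintf("(%s)%s:%.6f", kids, lab, bl[v])
  }
  paste0(rec(1L, TRUE), ";")
}

#' Simulate genome evolution along a species tree
#'
#' Generates a seeded Yule tree (or uses a supplied one), gives the root a
#' random genome, and evolves it along every branch with Poisson numbers of
#' gene gains, losses, tandem and dispersed duplications, inversions and
#' translocations. Inversions reverse a contiguous segment and flip its
#' strands; translocations move a segment to a uniformly chosen position
#' (possibly on another contig). Every node's true gene order, the full
#' gene-lineage forest and an event log sufficient to replay the simulation
#' are recorded.
#'
#' @param params a [sim_params()] object.
#' @param tree optional `species_tree` to use instead of a generated one.
#' @return an object of class `simulation_truth` with elements `tree`,
#'   `orders` (per node: list of contigs, each with `inst` and `strand`),
#'   `inst` (instance table: `fam`, `parent`, `dup`, `node`), `events`
#'   (replayable log) and `params`.
#' @export
simulate_evolution <- function(params, tree = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  if (is.null(tree)) {
    tree <- read_species_tree(yule_newick(params$n_leaves, params$branch_mean))
  }
  st <- new.env(parent = emptyenv())
  st$fam <- integer(1024L); st$parent <- integer(1024L)
  st$dup <- logical(1024L); st$node <- integer(1024L)
  st$n <- 0L
  st$next_fam <- 0L
  new_insts <- function(k, fam, parent, dup, node) {
    while (st$n + k > length(st$fam)) {
      st$fam <- c(st$fam, integer(length(st$fam)))
      st$parent <- c(st$parent, integer(length(st$parent)))
      st$dup <- c(st$dup, logical(length(st$dup)))
      st$node <- c(st$node, integer(length(st$node)))
    }
    ids <- st$n + seq_len(k)
    st$fam[ids] <- fam; st$parent[ids] <- parent
    st$dup[ids] <- dup; st$node[ids] <- node
    st$n <- st$n + k
    ids
  }

  # root genome: families 1..G over root_contigs contigs, random strands
  G <- params$root_genes
  st$next_fam <- G
  root_ids <- new_insts(G, seq_len(G), NA_integer_, FALSE, tree$root)
  cuts <- sort(sample.int(G - 1L, min(params$root_contigs, G) - 1L))
  bounds <- c(0L, cuts, G)
  genome0 <- lapply(seq_len(length(bounds) - 1L), function(i) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    list(inst = root_ids[idx],
         strand = sample(c("+", "-"), length(idx), replace = TRUE))
  })

  orders <- vector("list", length(tree$labels))
  orders[[tree$root]] <- genome0
  ev_log <- list(); ei <- 0L
  types <- names(params$rates)

  for (v in tree$preorder) {
    p <- tree$parent[v]
    if (is.na(p)) next
    g <- orders[[p]]
    # inherit: one fresh instance per gene, linked to its parent instance
    g <- lapply(g, function(ct) {
      ids <- new_insts(length(ct$inst), st$fam[ct$inst], ct$inst, FALSE, v)
      list(inst = ids, strand = ct$strand)
    })
    n0 <- sum(vapply(g, function(ct) length(ct$inst), 0L))
    bl <- tree$edge_length[v]
    if (is.na(bl)) bl <- params$branch_mean
    counts <- vapply(types, function(tp)
      stats::rpois(1L, params$rates[[tp]] * n0 * bl), 0L)
    evs <- rep(types, counts)
    if (length(evs) > 1L) evs <- sample(evs)
    for (tp in evs) {
      ev <- draw_event(tp, g, params, st, new_insts, v)
      if (is.null(ev)) next
      ei <- ei + 1L
      ev$node <- v
      ev_log[[ei]] <- ev
      g <- apply_event(g, ev)
      if (!length(g)) {
        stop(sprintf("simulated genome on the branch to '%s' lost all genes; lower the loss rate",
                     tree$labels[v]))
      }
    }
    orders[[v]] <- g
  }

  events <- if (ei) data.table::rbindlist(ev_log, fill = TRUE) else
    data.table::data.table(type = character(0), node = integer(0))
  structure(list(
    tree = tree,
    orders = orders,
    inst = data.frame(fam = st$fam[seq_len(st$n)], parent = st$parent[seq_len(st$n)],
                      dup = st$dup[seq_len(st$n)], node = st$node[seq_len(st$n)]),
    events = events, params = params
  ), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> %d leaves, %d gene instances, %d events\n",
              x$tree$n_tip, nrow(x$inst), nrow(x$events)))
  invisible(x)
}

# Draw one event of the given type against the current genome; returns a
# replayable record (positions refer to the genome state at draw time) or
# NULL when the event is impossible (e.g. inversion on a 1-gene genome).
#' @keywords internal
draw_event <- function(tp, g, params, st, new_insts, v) {
  sizes <- vapply(g, function(ct) length(ct$inst), 0L)
  N <- sum(sizes)
  pick_gene <- function() {
    j <- sample.int(N, 1L)
    k <- findInterval(j - 1L, cumsum(c(0L, sizes)), rightmost.closed = FALSE)
    list(ctg = k, pos = j - c(0L, cumsum(sizes))[k])
  }
  pick_slot <- function() {
    k <- sample.int(length(g), 1L, prob = sizes + 1L)
    list(ctg = k, pos = sample.int(sizes[k] + 1L, 1L) - 1L)  # insert after pos
  }
  seg_len <- function() 1L + stats::rgeom(1L, 1 / params$inv_len_mean)
  switch(tp,
    gain = {
      st$next_fam <- st$next_fam + 1L
      id <- new_insts(1L, st$next_fam, NA_integer_, FALSE, v)
      sl <- pick_slot()
      data.table::data.table(type = "gain", c1 = sl$ctg, p1 = sl$pos,
                             inst = id, strand = sample(c("+", "-"), 1L))
    },
    loss = {
      pg <- pick_gene()
      data.table::data.table(type = "loss", c1 = pg$ctg, p1 = pg$pos)
    },
    dup_tandem = ,
    dup_dispersed = {
      pg <- pick_gene()
      src <- g[[pg$ctg]]$inst[pg$pos]
      if (is.na(st$parent[src])) {
        # copy of a gene gained on this same branch: treat as a new family
        st$next_fam <- st$next_fam + 1L
        id <- new_insts(1L, st$next_fam, NA_integer_, FALSE, v)
      } else {
        id <- new_insts(1L, st$fam[src], st$parent[src], TRUE, v)
        st$dup[src] <- TRUE
      }
      sl <- if (tp == "dup_tandem") list(ctg = pg$ctg, pos = pg$pos) else pick_slot()
      data.table::data.table(type = tp, c1 = pg$ctg, p1 = pg$pos,
                             c2 = sl$ctg, p2 = sl$pos, inst = id)
    },
    inversion = {
      k <- sample.int(length(g), 1L, prob = sizes)
      if (sizes[k] < 2L) return(NULL)
      s <- sample.int(sizes[k], 1L)
      len <- min(seg_len(), sizes[k] - s + 1L)
      if (len < 1L) return(NULL)
      data.table::data.table(type = "inversion", c1 = k, p1 = s, len = len)
    },
    translocation = {
      k <- sample.int(length(g), 1L, prob = sizes)
      s <- sample.int(sizes[k], 1L)
      len <- min(seg_len(), sizes[k] - s + 1L)
      rem <- sizes; rem[k] <- rem[k] - len
      if (sum(rem) == 0L) return(NULL)
      k2 <- sample.int(length(g), 1L, prob = rem + ifelse(seq_along(g) == k, 0, 1))
      pos2 <- sample.int(rem[k2] + 1L, 1L) - 1L
      data.table::data.table(type = "translocation", c1 = k, p1 = s, len = len,
                             c2 = k2, p2 = pos2)
    })
}

# Apply one event record to a genome (list of contigs).
#' @keywords internal
apply_event <- function(g, ev) {
  ins <- function(vec, pos, val) append(vec, val, after = pos)
  switch(ev$type,
    gain = {
      ct <- g[[ev$c1]]
      ct$inst <- ins(ct$inst, ev$p1, ev$inst)
      ct$strand <- ins(ct$strand, ev$p1, ev$strand)
      g[[ev$c1]] <- ct
    },
    loss = {
      ct <- g[[ev$c1]]
      ct$inst <- ct$inst[-ev$p1]; ct$strand <- ct$strand[-ev$p1]
      g[[ev$c1]] <- ct
      if (!length(ct$inst)) g[[ev$c1]] <- NULL
    },
    dup_tandem = ,
    dup_dispersed = {
      src <- g[[ev$c1]]
      strand <- src$strand[ev$p1]
      ct <- g[[ev$c2]]
      ct$inst <- ins(ct$inst, ev$p2, ev$inst)
      ct$strand <- ins(ct$strand, ev$p2, strand)
      g[[ev$c2]] <- ct
    },
    inversion = {
      ct <- g[[ev$c1]]
      idx <- ev$p1:(ev$p1 + ev$len - 1L)
      ct$inst[idx] <- rev(ct$inst[idx])
      ct$strand[idx] <- chartr("+-", "-+", rev(ct$strand[idx]))
      g[[ev$c1]] <- ct
    },
    translocation = {
      ct <- g[[ev$c1]]
      idx <- ev$p1:(ev$p1 + ev$len - 1L)
      seg_i <- ct$inst[idx]; seg_s <- ct$strand[idx]
      ct$inst <- ct$inst[-idx]; ct$strand <- ct$strand[-idx]
      g[[ev$c1]] <- ct
      dropped <- FALSE
      if (!length(ct$inst)) { g[[ev$c1]] <- NULL; dropped <- TRUE }
      k2 <- ev$c2
      if (dropped && k2 > ev$c1) k2 <- k2 - 1L
      ct2 <- g[[k2]]
      ct2$inst <- ins(ct2$inst, ev$p2, seg_i)
      ct2$strand <- ins(ct2$strand, ev$p2, seg_s)
      g[[k2]] <- ct2
    })
  g
}

#' Replay the event log of a simulation
#'
#' Re-derives every node's gene order from the root order and the recorded
#' events alone, as a consistency oracle for the stored orders.
#'
#' @param truth a `simulation_truth`.
#' @return per-node orders in the same format as `truth$orders`.
#' @export
replay_events <- function(truth) {
  tree <- truth$tree
  inherit_ids <- truth$inst
  orders <- vector("list", length(tree$labels))
  orders[[tree$root]] <- truth$orders[[tree$root]]
  # reconstruct the inherited instance ids: for node v, the fresh copies of
  # the parent's genes are exactly the non-event instances at v, which map
  # 1:1 onto parent instances via `parent`
  child_of <- split(seq_len(nrow(inherit_ids)), inherit_ids$parent)
  for (v in tree$preorder) {
    p <- tree$parent[v]
    if (is.na(p)) next
    g <- orders[[p]]
    g <- lapply(g, function(ct) {
      ids <- vapply(ct$inst, function(i) {
        cand <- child_of[[as.character(i)]]
        cand <- cand[inherit_ids$node[cand] == v & !inherit_ids$dup[cand]]
        if (length(cand) == 1L) cand else {
          # the original copy of a duplicated lineage: the smallest id at v
          cand2 <- child_of[[as.character(i)]]
          cand2 <- cand2[inherit_ids$node[cand2] == v]
          min(cand2)
        }
      }, 0L)
      list(inst = ids, strand = ct$strand)
    })
    evs <- truth$events[node == v]
    if (nrow(evs)) {
      for (j in seq_len(nrow(evs))) g <- apply_event(g, as.list(evs[j]))
    }
    orders[[v]] <- g
  }
  orders
}

#' Ground-truth lineage forest of a simulation
#'
#' Exposes the simulated gene instances as a `lineage_forest`, directly
#' comparable to the forest rebuilt by [read_orthoxml()] +
#' [build_gene_lineage()] from the files written by [write_truth()].
#'
#' @param truth a `simulation_truth`.
#' @return a `lineage_forest`.
#' @export
as_lineage_forest <- function(truth) {
  tree <- truth$tree
  it <- truth$inst
  M <- nrow(it)
  # instances created and lost within one branch never appear in any node's
  # genome snapshot: they are not genes of any reconstructed level
  present <- logical(M)
  for (v in seq_along(truth$orders)) {
    g <- truth$orders[[v]]
    if (!is.null(g)) present[unlist(lapply(g, `[[`, "inst"))] <- TRUE
  }
  keep <- which(present)
  remap <- integer(M); remap[keep] <- seq_along(keep)
  parent <- it$parent[keep]
  if (any(!is.na(parent) & !present[ifelse(is.na(parent), 1L, parent)])) {
    stop("internal error: surviving lineage with transient parent")
  }
  parent <- ifelse(is.na(parent), NA_integer_, remap[parent])
  label <- paste0("g", keep)
  node <- it$node[keep]
  is_extant <- tree$is_leaf[node]
  ext <- which(is_extant)
  ext_uid <- ext
  names(ext_uid) <- paste(tree$labels[node[ext]], label[ext], sep = "\r")
  structure(list(
    node = node, family = it$fam[keep],
    parent = parent, via_dup = it$dup[keep],
    label = label, is_extant = is_extant,
    families = paste0("F", seq_len(max(it$fam))),
    ext_uid = ext_uid, tree = tree,
    uid_of_inst = remap  # original instance id -> uid (0 if transient)
  ), class = "lineage_forest")
}

#' Write simulation ground truth as analysis inputs
#'
#' Emits the newick tree, one GFF3 per leaf genome (gene at rank i placed at
#' `[1000 i + 1, 1000 i + 500]`), the ground-truth HOGs as OrthoXML, and
#' TSVs of the true adjacencies and contigs at every node.
#'
#' @param truth a `simulation_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- truth$tree
  writeLines(write_species_tree(tree), file.path(dir, "tree.nwk"))
  for (leaf in which(tree$is_leaf)) {
    lab <- tree$labels[leaf]
    g <- truth$orders[[leaf]]
    rows <- lapply(seq_along(g), function(k) {
      data.frame(gene_id = paste0("g", g[[k]]$inst),
                 contig = sprintf("%s_ctg%d", lab, k),
                 strand = g[[k]]$strand,
                 rank = seq_along(g[[k]]$inst) - 1L,
                 stringsAsFactors = FALSE)
    })
    write_gff(do.call(rbind, rows), file.path(dir, paste0(lab, ".gff3")))
  }
  write_orthoxml(as_lineage_forest(truth), file.path(dir, "hogs.orthoxml"),
                 origin = "ancora-sim")
  adj <- list(); ctg <- list(); ai <- 0L
  for (v in tree$preorder) {
    g <- truth$orders[[v]]
    for (k in seq_along(g)) {
      n <- length(g[[k]]$inst)
      ai <- ai + 1L
      ctg[[ai]] <- data.table::data.table(
        node = tree$labels[v], contig = k, pos = seq_len(n),
        gene = paste0("g", g[[k]]$inst), strand = g[[k]]$strand)
      if (n >= 2L) {
        adj[[ai]] <- data.table::data.table(
          node = tree$labels[v],
          gene1 = paste0("g", g[[k]]$inst[-n]),
          gene2 = paste0("g", g[[k]]$inst[-1L]))
      }
    }
  }
  data.table::fwrite(data.table::rbindlist(adj[!vapply(adj, is.null, TRUE)]),
                     file.path(dir, "true_adjacencies.tsv"), sep = "\t")
  data.table::fwrite(data.table::rbindlist(ctg),
                     file.path(dir, "true_contigs.tsv"), sep = "\t")
  invisible(dir)
}
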