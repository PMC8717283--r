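## Gene-tree / species-tree reconciliation and repertoire trajectories.
## The LCA (last-common-ancestor) mapping gives the duplication/loss-minimal
## embedding of a gene tree into a species tree; per-branch events are then
## summed over families and propagated into ancestral repertoire counts.

#' Read a Newick tree with validation
#'
#' @param text Newick string, or `file` a path.
#' @param file optional path to a Newick file.
#' @return ape `phylo`; attribute `binary` flags whether the tree is fully
#'   binary (non-binary trees are accepted and flagged).
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- tryCatch(
    suppressWarnings(
      if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    .stopf("malformed Newick input")
  if (anyDuplicated(tr$tip.label))
    .stopf("duplicate leaf labels: %s",
           paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  # fully binary as a rooted tree: a trifurcating root is flagged
  attr(tr, "binary") <- ape::is.binary(tr) && ape::is.rooted(tr)
  attr(tr, "rooted") <- ape::is.rooted(tr)
  tr
}

#' Write a tree as Newick
#' @param tree ape `phylo`.
#' @param file optional path; if omitted the string is returned.
#' @return Newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = file); invisible(ape::write.tree(tree)) }
}

#' Neighbor-joining tree from a distance table
#'
#' Standard neighbor joining (the fallback when no externally built
#' maximum-likelihood gene tree is supplied). Taxa are processed in label
#' order, so ties break deterministically.
#'
#' @param d symmetric non-negative distance matrix (or `dist`).
#' @return unrooted ape `phylo`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  stopifnot(isSymmetric(unname(d)), all(d >= 0))
  ord <- order(rownames(d))
  d <- d[ord, ord]
  ape::nj(stats::as.dist(d))
}

## ---- species-tree scaffolding --------------------------------------------

# internal indexed form of a rooted binary species tree
.sp_index <- function(sp) {
  sp <- .as_species_tree(sp)
  ntip <- length(sp$tip.label)
  n <- ntip + sp$Nnode
  parent <- integer(n); parent[ntip + 1L] <- 0L
  kids <- vector("list", n)
  for (e in seq_len(nrow(sp$edge))) {
    p <- sp$edge[e, 1L]; c_ <- sp$edge[e, 2L]
    parent[c_] <- p
    kids[[p]] <- c(kids[[p]], c_)
  }
  root <- ntip + 1L
  depth <- integer(n); depth[root] <- 0L
  ord <- root
  stack <- root
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    for (k in kids[[v]]) {
      depth[k] <- depth[v] + 1L
      ord <- c(ord, k)
      stack <- c(stack, k)
    }
  }
  list(tree = sp, ntip = ntip, root = root, parent = parent, kids = kids,
       depth = depth, preorder = ord,
       labels = vapply(seq_len(n), function(v) .node_label(sp, v), character(1)))
}

.sp_lca <- function(idx, a, b) {
  while (a != b) {
    if (idx$depth[a] < idx$depth[b]) b <- idx$parent[b] else a <- idx$parent[a]
  }
  a
}

# path from ancestor a down to descendant d (inclusive)
.sp_path <- function(idx, a, d) {
  p <- d
  while (d != a) { d <- idx$parent[d]; p <- c(d, p) }
  p
}

#' Default species extraction from gene-tree leaf labels
#'
#' Gene leaves are labelled `Species_gene`; the species is everything before
#' the final underscore.
#' @param labels character vector of gene leaf labels.
#' @return character vector of species labels.
#' @export
species_of <- function(labels) sub("_[^_]+$", "", labels)

#' LCA reconciliation of a rooted gene tree with a rooted species tree
#'
#' Computes the last-common-ancestor mapping of every gene-tree node onto the
#' species tree. A gene node is a `DUPLICATION` when its mapping equals the
#' mapping of at least one child; losses are counted along the species-tree
#' path below each gene edge (one fewer for speciation nodes) and charged to
#' the species branch on which the gene lineage disappeared. Duplications are
#' charged to the species branch above their mapped node. The resulting
#' duplication and loss counts are simultaneously minimal over all
#' reconciliations of the two trees.
#'
#' @param gene_tree rooted binary ape `phylo` (or Newick string).
#' @param species_tree rooted binary ape `phylo` (or Newick string).
#' @param leaf_species optional named character vector mapping gene leaf
#'   labels to species; defaults to [species_of()] on the leaf labels.
#' @return object of class `reconciliation`: list with `D`, `L`, per-node
#'   `events` data frame, `dup_per_branch` and `loss_per_branch` (named by
#'   the species-tree label of the branch's child node), and `root_map`
#'   (species-tree label the gene root maps to).
#' @export
lca_reconcile <- function(gene_tree, species_tree, leaf_species = NULL) {
  if (is.character(gene_tree)) gene_tree <- read_newick(gene_tree)
  idx <- .sp_index(species_tree)
  if (!ape::is.binary(gene_tree) || !ape::is.rooted(gene_tree))
    .stopf("gene tree must be rooted and binary")
  gt <- gene_tree
  gntip <- length(gt$tip.label)
  gn <- gntip + gt$Nnode
  if (is.null(leaf_species))
    leaf_species <- stats::setNames(species_of(gt$tip.label), gt$tip.label)
  sp_tip <- match(leaf_species[gt$tip.label], idx$tree$tip.label)
  if (anyNA(sp_tip))
    .stopf("gene leaves map to unknown species: %s",
           paste(gt$tip.label[is.na(sp_tip)], collapse = ", "))
  gkids <- vector("list", gn)
  for (e in seq_len(nrow(gt$edge)))
    gkids[[gt$edge[e, 1L]]] <- c(gkids[[gt$edge[e, 1L]]], gt$edge[e, 2L])
  # postorder mapping: sweep until every internal node is resolved
  M <- integer(gn); M[seq_len(gntip)] <- sp_tip
  todo <- setdiff(seq_len(gn), seq_len(gntip))
  while (length(todo)) {
    for (v in todo) {
      ch <- gkids[[v]]
      if (all(M[ch] > 0L)) M[v] <- .sp_lca(idx, M[ch[1L]], M[ch[2L]])
    }
    todo <- todo[M[todo] == 0L]
  }
  nlab <- idx$labels
  dup_b <- stats::setNames(numeric(length(nlab)), nlab)
  loss_b <- stats::setNames(numeric(length(nlab)), nlab)
  events <- data.frame(node = seq_len(gn),
                       event = rep("LEAF", gn), map = nlab[M],
                       stringsAsFactors = FALSE)
  internal <- setdiff(seq_len(gn), seq_len(gntip))
  for (v in internal) {
    ch <- gkids[[v]]
    is_dup <- M[v] == M[ch[1L]] || M[v] == M[ch[2L]]
    events$event[v] <- if (is_dup) "DUPLICATION" else "SPECIATION"
    if (is_dup) dup_b[nlab[M[v]]] <- dup_b[nlab[M[v]]] + 1
    for (c_ in ch) {
      path <- .sp_path(idx, M[v], M[c_])
      k <- length(path) - 1L
      if (is_dup) {
        # lineage present at M[v] itself: losses possible at every node on
        # the path except the terminal one
        loss_at <- path[seq_len(k)]
      } else {
        if (k >= 2L) loss_at <- path[2:k] else loss_at <- integer(0)
      }
      for (s in loss_at) {
        nxt <- path[which(path == s) + 1L]
        sib <- setdiff(idx$kids[[s]], nxt)
        loss_b[nlab[sib]] <- loss_b[nlab[sib]] + 1
      }
    }
  }
  structure(list(
    gene_tree = gt, species_tree = idx$tree,
    D = sum(events$event == "DUPLICATION"), L = sum(loss_b),
    events = events, dup_per_branch = dup_b, loss_per_branch = loss_b,
    root_map = nlab[M[gntip + 1L]]
  ), class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("Reconciliation: %d duplications, %d losses (gene root maps to %s)\n",
              x$D, as.integer(x$L), x$root_map))
  invisible(x)
}

## ---- rooting --------------------------------------------------------------

# all rooted versions of an unrooted binary tree: one per branch
.enumerate_rootings <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  adj <- vector("list", n)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  subnewick <- function(v, from) {
    nb <- setdiff(adj[[v]], from)
    if (!length(nb)) return(tree$tip.label[v])
    sprintf("(%s)", paste(vapply(nb, subnewick, character(1), from = v),
                          collapse = ","))
  }
  lapply(seq_len(nrow(tree$edge)), function(e) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    read_newick(sprintf("(%s,%s);", subnewick(a, b), subnewick(b, a)))
  })
}

#' Root an unrooted gene tree by minimising duplication + loss
#'
#' Evaluates every branch of the gene tree as a root position, reconciles
#' each rooted version against the species tree, and returns the rooting with
#' the smallest duplication + loss total (ties broken by duplications, then
#' losses, then branch enumeration order).
#'
#' @param gene_tree unrooted binary ape `phylo` (or Newick string).
#' @param species_tree rooted binary species tree.
#' @param leaf_species as in [lca_reconcile()].
#' @return the winning `reconciliation` object (its `gene_tree` element is
#'   the chosen rooted tree).
#' @export
root_by_dl <- function(gene_tree, species_tree, leaf_species = NULL) {
  if (is.character(gene_tree)) gene_tree <- read_newick(gene_tree)
  if (length(gene_tree$tip.label) == 2L)
    return(lca_reconcile(gene_tree, species_tree, leaf_species))
  tree <- if (ape::is.rooted(gene_tree)) ape::unroot(gene_tree) else gene_tree
  rootings <- .enumerate_rootings(tree)
  recs <- lapply(rootings, lca_reconcile, species_tree = species_tree,
                 leaf_species = leaf_species)
  key <- vapply(recs, function(r) c(r$D + r$L, r$D, r$L), numeric(3))
  best <- order(key[1L, ], key[2L, ], key[3L, ])[1L]
  recs[[best]]
}

## ---- trajectories ---------------------------------------------------------

#' Propagate ancestral repertoire counts along a species tree
#'
#' Given per-branch gains and losses (branches named by their child node
#' label), computes the count at every node from the root count so that on
#' every branch `child = parent + gains - losses`.
#'
#' @param species_tree rooted binary species tree.
#' @param root_count repertoire size at the root.
#' @param gains,losses named numeric vectors (species node label -> events on
#'   the branch above that node); missing names count as 0.
#' @return data frame of class `trajectory`: node label, `count`, `gain`,
#'   `loss`, with the bookkeeping identity asserted on every branch.
#' @export
propagate_counts <- function(species_tree, root_count, gains = numeric(0),
                             losses = numeric(0)) {
  idx <- .sp_index(species_tree)
  n <- length(idx$labels)
  cnt <- stats::setNames(numeric(n), idx$labels)
  g <- stats::setNames(numeric(n), idx$labels)
  l <- stats::setNames(numeric(n), idx$labels)
  g[names(gains)[names(gains) %in% idx$labels]] <-
    gains[names(gains) %in% idx$labels]
  l[names(losses)[names(losses) %in% idx$labels]] <-
    losses[names(losses) %in% idx$labels]
  cnt[idx$labels[idx$root]] <- root_count + g[idx$labels[idx$root]] -
    l[idx$labels[idx$root]]
  for (v in idx$preorder[-1L]) {
    lab <- idx$labels[v]; par <- idx$labels[idx$parent[v]]
    cnt[lab] <- cnt[par] + g[lab] - l[lab]
    stopifnot(cnt[lab] == cnt[par] + g[lab] - l[lab])
  }
  out <- data.frame(node = idx$labels, count = unname(cnt),
                    gain = unname(g), loss = unname(l),
                    is_leaf = seq_len(n) <= idx$ntip,
                    stringsAsFactors = FALSE)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Repertoire trajectory from a set of reconciliations
#'
#' Sums per-branch duplications and losses over a family set, adds one
#' origination gain on the branch above a family's gene-root mapping when the
#' family does not reach the species root, and propagates ancestral counts
#' from the root. When observed per-species counts are supplied, leaf counts
#' are checked against them and a mismatch errors, naming the branch.
#'
#' @param recs a `reconciliation` or list of them, all on the same species
#'   tree.
#' @param species_tree the common rooted species tree.
#' @param observed_counts optional named vector of observed per-species gene
#'   counts.
#' @return a `trajectory` data frame (see [propagate_counts()]).
#' @export
ancestral_trajectory <- function(recs, species_tree, observed_counts = NULL) {
  if (inherits(recs, "reconciliation")) recs <- list(recs)
  idx <- .sp_index(species_tree)
  root_lab <- idx$labels[idx$root]
  gains <- stats::setNames(numeric(length(idx$labels)), idx$labels)
  losses <- gains
  root_count <- 0
  for (r in recs) {
    gains <- gains + r$dup_per_branch[names(gains)]
    losses <- losses + r$loss_per_branch[names(losses)]
    if (r$root_map == root_lab) root_count <- root_count + 1
    else gains[r$root_map] <- gains[r$root_map] + 1
  }
  traj <- propagate_counts(species_tree, root_count, gains, losses)
  if (!is.null(observed_counts)) {
    leaf <- traj[traj$is_leaf, , drop = FALSE]
    obs <- observed_counts[leaf$node]
    bad <- which(!is.na(obs) & obs != leaf$count)
    if (length(bad))
      .stopf("trajectory count mismatch on branch to %s: propagated %d, observed %d",
             leaf$node[bad[1L]], leaf$count[bad[1L]], obs[bad[1L]])
  }
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Repertoire trajectory over %d nodes (root count %d)\n",
              nrow(x), as.integer(x$count[!x$is_leaf][1L] -
                                    x$gain[!x$is_leaf][1L] +
                                    x$loss[!x$is_leaf][1L])))
  print.data.frame(x)
  invisible(x)
}
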