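#  Duplication-loss reconciliation of a rooted binary gene tree against a
#  rooted binary species tree by LCA mapping (parsimony, unit costs).
#
#  A gene-tree node is a duplication iff it maps to the same species node
#  as at least one of its children.  Losses are counted per gene-tree edge
#  (u, v) from the species-tree path length d between the mapped nodes:
#  d - 1 losses when u is a speciation, d when u is a duplication; each
#  loss is attributed to the off-path child of the species node where the
#  copy disappeared.

# children[[node]] and parent[node] lookup tables from a phylo edge matrix
.tree_index <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  parent <- rep(NA_integer_, n_nodes)
  children <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    c_ <- tree$edge[i, 2L]
    parent[c_] <- p
    children[[p]] <- c(children[[p]], c_)
  }
  root <- which(is.na(parent) & vapply(children, length, 0L) > 0L)
  depth <- rep(NA_integer_, n_nodes)
  depth[root] <- 0L
  ord <- root
  while (length(ord) > 0L) {
    nxt <- unlist(children[ord])
    depth[nxt] <- depth[parent[nxt]] + 1L
    ord <- nxt
  }
  list(parent = parent, children = children, root = root, depth = depth,
       n_tips = ape::Ntip(tree))
}

.check_rooted_binary <- function(tree, what) {
  if (!inherits(tree, "phylo")) stop(what, " must be an ape phylo tree")
  if (ape::Ntip(tree) < 2L) stop(what, " must have at least 2 leaves")
  if (!ape::is.rooted(tree)) stop(what, " must be rooted")
  if (!ape::is.binary(tree)) stop(what, " must be binary (no polytomies)")
  invisible(tree)
}

.lca2 <- function(a, b, idx) {
  while (a != b) {
    if (idx$depth[a] >= idx$depth[b]) a <- idx$parent[a] else b <- idx$parent[b]
  }
  a
}

# Human-readable label for a species-tree node: tip label, node label if
# present, else the sorted descendant tips joined by '|'.
.species_node_labels <- function(tree, idx) {
  n_nodes <- length(idx$parent)
  labels <- character(n_nodes)
  labels[seq_len(idx$n_tips)] <- tree$tip.label
  for (v in order(idx$depth, decreasing = TRUE)) {
    if (v <= idx$n_tips) next
    nl <- if (!is.null(tree$node.label)) tree$node.label[v - idx$n_tips] else ""
    if (!is.null(nl) && !is.na(nl) && nzchar(nl)) {
      labels[v] <- nl
    } else {
      kids <- labels[idx$children[[v]]]
      tips <- sort(unlist(strsplit(kids, "|", fixed = TRUE)))
      labels[v] <- paste(tips, collapse = "|")
    }
  }
  labels
}

#' LCA map of a gene tree onto a species tree
#'
#' Maps every gene-tree node to the last common ancestor (in the species
#' tree) of the species its descendant leaves belong to.
#'
#' @param gene_tree,species_tree Rooted binary `ape::phylo` trees.
#' @param leaf_species_map Named character vector mapping every gene-tree
#'   leaf name to a species-tree leaf name (see [read_species_map()]).
#' @return Integer vector over gene-tree node indices (tips first, ape
#'   convention) giving the mapped species-tree node index.
#' @export
lca_map <- function(gene_tree, species_tree, leaf_species_map) {
  .check_rooted_binary(gene_tree, "gene tree")
  .check_rooted_binary(species_tree, "species tree")
  unmapped <- setdiff(gene_tree$tip.label, names(leaf_species_map))
  if (length(unmapped) > 0L)
    stop("gene-tree leaf (leaves) missing from species map: ",
         paste(unmapped, collapse = ", "))
  sp <- leaf_species_map[gene_tree$tip.label]
  unknown <- setdiff(sp, species_tree$tip.label)
  if (length(unknown) > 0L)
    stop("species not in species tree: ", paste(unknown, collapse = ", "))

  gidx <- .tree_index(gene_tree)
  sidx <- .tree_index(species_tree)
  mapping <- rep(NA_integer_, length(gidx$parent))
  mapping[seq_len(gidx$n_tips)] <- match(sp, species_tree$tip.label)
  for (v in order(gidx$depth, decreasing = TRUE)) {
    if (v <= gidx$n_tips) next
    kids <- gidx$children[[v]]
    mapping[v] <- .lca2(mapping[kids[1L]], mapping[kids[2L]], sidx)
  }
  mapping
}

#' Duplication and loss counts from gene-tree/species-tree reconciliation
#'
#' Parsimony LCA reconciliation with unit duplication and loss costs.
#' Duplications and losses are reported per species-tree node and as
#' totals.  A gene tree congruent with the species tree, one gene per
#' species, yields zero duplications and zero losses.
#'
#' @inheritParams lca_map
#' @return Object of class `reconciliation`: a list with `per_node` (data
#'   frame: `node_label`, `duplications`, `losses`), `total_duplications`,
#'   `total_losses`, and `mapping` (the [lca_map()] vector).
#' @examples
#' st <- ape::read.tree(text = "(A,B);")
#' gt <- ape::read.tree(text = "((a1,b1),(a2,b2));")
#' map <- c(a1 = "A", b1 = "B", a2 = "A", b2 = "B")
#' count_duplications_losses(gt, st, map)
#' @export
count_duplications_losses <- function(gene_tree, species_tree,
                                      leaf_species_map) {
  mapping <- lca_map(gene_tree, species_tree, leaf_species_map)
  gidx <- .tree_index(gene_tree)
  sidx <- .tree_index(species_tree)
  n_sp_nodes <- length(sidx$parent)
  dup <- loss <- rep(0L, n_sp_nodes)

  is_dup <- rep(FALSE, length(gidx$parent))
  for (v in seq_along(gidx$parent)) {
    if (v <= gidx$n_tips) next
    kids <- gidx$children[[v]]
    if (any(mapping[kids] == mapping[v])) {
      is_dup[v] <- TRUE
      dup[mapping[v]] <- dup[mapping[v]] + 1L
    }
  }
  # losses along each gene-tree edge: walk the species path from the
  # child's mapping up to (exclusive) the parent's mapping; every step off
  # the path drops a copy in the sibling subtree.  At a duplication parent
  # the copy also had to survive at the parent's own mapping, adding the
  # step at the top of the path.
  for (v in seq_along(gidx$parent)) {
    p <- gidx$parent[v]
    if (is.na(p)) next
    top <- mapping[p]
    cur <- mapping[v]
    path <- integer(0)
    while (cur != top) {
      path <- c(path, cur)
      cur <- sidx$parent[cur]
    }
    # path = species nodes the surviving copy passed through, child-first.
    # The copy lost a sibling at every node it entered below the top; a
    # speciation parent's own split is covered by the other gene-tree edge,
    # so its first step (the last path element) is not a loss there.
    skipped <- if (is_dup[p]) path else path[-length(path)]
    for (w in skipped) {
      sib <- setdiff(sidx$children[[sidx$parent[w]]], w)
      loss[sib] <- loss[sib] + 1L
    }
  }

  labels <- .species_node_labels(species_tree, sidx)
  per_node <- data.frame(node_label = labels,
                         duplications = dup, losses = loss,
                         stringsAsFactors = FALSE)
  structure(list(per_node = per_node,
                 total_duplications = sum(dup),
                 total_losses = sum(loss),
                 mapping = mapping),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("Reconciliation: %d duplication(s), %d loss(es)\n",
              x$total_duplications, x$total_losses))
  nz <- x$per_node[x$per_node$duplications > 0 | x$per_node$losses > 0, ]
  if (nrow(nz) > 0L) print(nz, row.names = FALSE)
  invisible(x)
}
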