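# Shared fixtures: a hand-built toy genome for the classifier, species
# trees with labelled internal nodes, and an event sampler restricted to
# scenarios that parsimony reconciliation can recover exactly
# (duplications on internal/root branches; losses at leaves that are
# neither mutual siblings nor, when emptied, children of the root).

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# six genes on two chromosomes; ranks chr1: g1..g4 = 0..3, chr2: g5,g6
toy_loci <- function() {
  assign_gene_ranks(data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(0L, 2000L, 4000L, 9000L, 0L, 2000L),
    end = c(1000L, 3000L, 5000L, 10000L, 1000L, 3000L),
    strand = "+", stringsAsFactors = FALSE))
}

recon_species_trees <- list(
  ape::read.tree(text = "((A,B)P,(C,D)Q)R;"),
  ape::read.tree(text = "(((A,B)P,C)Q,D)R;"))

# identifiable duplication/loss scenario on one of the fixture trees
sample_safe_events <- function(tree) {
  internal <- tree$node.label
  tips <- tree$tip.label
  idx <- ksdater:::.tree_index(tree)
  root_child_tips <- tips[match(idx$children[[idx$root]][
    idx$children[[idx$root]] <= length(tips)], seq_along(tips))]
  sibling_of <- vapply(tips, function(t) {
    v <- match(t, tips)
    sib <- setdiff(idx$children[[idx$parent[v]]], v)
    if (sib <= length(tips)) tips[sib] else NA_character_
  }, "")

  n_dup <- sample(0:2, 1L)
  dups <- if (n_dup > 0L) sample(internal, n_dup, replace = TRUE) else character(0)
  # leaves covered by a duplication get an extra copy per covering dup
  copies <- setNames(rep(1L, length(tips)), tips)
  clades <- ape::prop.part(tree)  # tip sets per internal node, node order
  for (d in dups) {
    desc <- tips[clades[[match(d, internal)]]]
    copies[desc] <- copies[desc] + 1L
  }

  n_loss_max <- if (n_dup > 0L) 1L else 2L
  n_loss <- sample(0:n_loss_max, 1L)
  losses <- character(0)
  for (i in seq_len(n_loss)) {
    cand <- setdiff(tips, losses)
    ok <- vapply(cand, function(t) {
      if (copies[[t]] >= 2L) return(TRUE)          # stays alive
      if (t %in% root_child_tips) return(FALSE)    # emptying root child
      sib <- sibling_of[[t]]
      !(isTRUE(sib %in% losses) && copies[[sib]] <= 1L)
    }, TRUE)
    # also forbid future sibling conflicts: drop candidates whose sibling
    # is already an emptying loss
    cand <- cand[ok]
    if (length(cand) == 0L) break
    pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
    losses <- c(losses, pick)
    copies[[pick]] <- copies[[pick]] - 1L
  }
  # recheck: no two emptied siblings
  emptied <- names(copies)[copies == 0L]
  if (any(sibling_of[emptied] %in% emptied)) {
    drop <- emptied[1L]
    losses <- setdiff(losses, drop)
    copies[[drop]] <- copies[[drop]] + 1L
  }
  data.frame(branch = c(dups, losses),
             type = rep(c("duplication", "loss"),
                        c(length(dups), length(losses))),
             stringsAsFactors = FALSE)
}
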