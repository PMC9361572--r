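#  Simulators with exact ground truth for the three pipeline stages:
#  codon-pair divergence to a target Ks at a chosen dN/dS, genomes with
#  planted tandem/proximal/collinear/dispersed structure, and gene trees
#  grown from a species tree by known duplication/loss events.
#
#  All generators are pure functions of their arguments including `seed`.

#' Simulate an aligned codon pair diverged to a target Ks
#'
#' Draws a random ancestor of sense codons (uniform over the 61 sense
#' codons) and evolves two independent lineages by repeated single-
#' nucleotide mutation: proposal sites and alternative bases uniform,
#' proposals creating stop codons rejected, nonsynonymous proposals
#' accepted with probability `omega`, synonymous proposals always.  Each
#' lineage mutates until its count of accepted synonymous events per
#' NG86-counted synonymous site of the ancestor reaches `target_ks / 2`, so
#' the realized event counts are exact ground truth (the NG86 estimate on
#' the pair differs by multiple-hit effects only).
#'
#' @param n_codons Number of codons (`>= 1`).
#' @param target_ks Target synonymous substitutions per synonymous site for
#'   the pair (`>= 0`).
#' @param omega Target dN/dS acceptance ratio (`>= 0`).
#' @param seed Integer seed; same seed, same output.
#' @param pair_id Identifier for the generated pair.
#' @return List with elements `pair` (a `codon_pair`, see
#'   [preprocess_pair()]) and `truth`: ancestor sequence, ancestor
#'   synonymous sites `S_anc`, and per-lineage accepted synonymous /
#'   nonsynonymous event counts.
#' @export
simulate_codon_pair <- function(n_codons, target_ks, omega, seed,
                                pair_id = "sim_pair") {
  if (n_codons < 1L) stop("n_codons must be >= 1")
  if (target_ks < 0) stop("target_ks must be >= 0")
  if (omega < 0) stop("omega must be >= 0")
  env <- .ng86_tables()
  sense <- env$sense_codons
  code <- .genetic_code()
  withr::with_seed(as.integer(seed), {
    ancestor <- sample(sense, n_codons, replace = TRUE)
    S_anc <- sum(env$site_table[ancestor, "s"])
    needed_syn <- target_ks / 2 * S_anc

    evolve <- function(codons) {
      syn <- 0L
      nonsyn <- 0L
      while (syn < needed_syn) {
        site <- sample.int(3L * n_codons, 1L)
        ci <- (site - 1L) %/% 3L + 1L
        pos <- (site - 1L) %% 3L + 1L
        nt <- strsplit(codons[ci], "")[[1]]
        nt[pos] <- sample(setdiff(.BASES, nt[pos]), 1L)
        cand <- paste(nt, collapse = "")
        if (code[[cand]] == "*") next
        if (code[[cand]] == code[[codons[ci]]]) {
          codons[ci] <- cand
          syn <- syn + 1L
        } else if (runif(1) < omega) {
          codons[ci] <- cand
          nonsyn <- nonsyn + 1L
        }
      }
      list(codons = codons, syn = syn, nonsyn = nonsyn)
    }
    la <- evolve(ancestor)
    lb <- evolve(ancestor)
    pair <- preprocess_pair(paste(la$codons, collapse = ""),
                            paste(lb$codons, collapse = ""), pair_id)
    list(pair = pair,
         truth = list(ancestor = paste(ancestor, collapse = ""),
                      S_anc = S_anc, needed_syn_per_lineage = needed_syn,
                      syn_a = la$syn, nonsyn_a = la$nonsyn,
                      syn_b = lb$syn, nonsyn_b = lb$nonsyn))
  })
}

# sample a run of `len` consecutive free ranks on some chromosome; marks
# them used.  `free` is a list of logical vectors, one per chromosome.
.take_run <- function(free, len, chroms = names(free)) {
  starts <- list()
  for (ch in chroms) {
    f <- free[[ch]]
    n <- length(f)
    if (n < len) next
    ok <- which(vapply(seq_len(n - len + 1L),
                       function(s) all(f[s:(s + len - 1L)]), TRUE))
    if (length(ok) > 0L) starts[[ch]] <- ok
  }
  if (length(starts) == 0L)
    stop("planted features exceed genome capacity")
  ch <- if (length(starts) == 1L) names(starts) else sample(names(starts), 1L)
  s <- if (length(starts[[ch]]) == 1L) starts[[ch]] else sample(starts[[ch]], 1L)
  free[[ch]][s:(s + len - 1L)] <- FALSE
  list(free = free, chrom = ch, start_rank = s - 1L)
}

#' Simulate a genome with planted duplication structure
#'
#' Lays out genes with unique ranks on chromosomes and plants features in
#' disjoint rank slots: tandem arrays (runs of adjacent homologs), proximal
#' pairs (same-chromosome homologs 2..`proximal_window` ranks apart),
#' collinear blocks (rank-preserving homolog runs across two chromosomes,
#' recorded as collinear pairs) and optional dispersed pairs
#' (cross-chromosome homologs without collinearity).  Every planted feature
#' is recorded in the returned truth labels, so [classify_genes()] can be
#' validated exactly.
#'
#' @param n_chromosomes,genes_per_chromosome Genome dimensions.
#' @param n_tandem_arrays Number of tandem arrays of `tandem_array_size`
#'   adjacent genes.
#' @param tandem_array_size Genes per tandem array (`>= 2`).
#' @param n_proximal_pairs Number of proximal pairs.
#' @param n_collinear_blocks,block_length Collinear blocks and their length
#'   in gene pairs (`block_length >= 1`).
#' @param n_dispersed_pairs Cross-chromosome homolog pairs without
#'   collinearity.
#' @param proximal_window Maximum proximal rank distance (also the
#'   classifier window to use on this genome).
#' @param seed Integer seed.
#' @return List with `loci` (ranked locus data frame, internal 0-based
#'   half-open coordinates), `homolog_pairs`, `collinear_pairs` (pair data
#'   frames) and `truth` (named character vector of duplication-type labels
#'   over all genes).
#' @export
simulate_genome <- function(n_chromosomes = 3L, genes_per_chromosome = 30L,
                            n_tandem_arrays = 1L, tandem_array_size = 2L,
                            n_proximal_pairs = 1L, n_collinear_blocks = 1L,
                            block_length = 3L, n_dispersed_pairs = 0L,
                            proximal_window = 10L, seed = 1L) {
  stopifnot(n_chromosomes >= 1L, genes_per_chromosome >= 1L,
            n_tandem_arrays >= 0L, tandem_array_size >= 2L,
            n_proximal_pairs >= 0L, n_collinear_blocks >= 0L,
            block_length >= 1L, n_dispersed_pairs >= 0L,
            proximal_window >= 2L)
  if (n_collinear_blocks > 0L && n_chromosomes < 2L)
    stop("collinear blocks need at least two chromosomes")
  withr::with_seed(as.integer(seed), {
    chroms <- sprintf("chr%d", seq_len(n_chromosomes))
    gene_id <- function(ch, rank) sprintf("%s_g%03d", ch, rank)
    loci <- do.call(rbind, lapply(chroms, function(ch) {
      rank <- seq_len(genes_per_chromosome) - 1L
      data.frame(gene_id = gene_id(ch, rank), chrom = ch,
                 start = rank * 2000L, end = rank * 2000L + 1000L,
                 strand = sample(c("+", "-"), genes_per_chromosome,
                                 replace = TRUE),
                 rank = rank, stringsAsFactors = FALSE)
    }))
    free <- setNames(lapply(chroms,
                            function(ch) rep(TRUE, genes_per_chromosome)),
                     chroms)
    truth <- setNames(rep("singleton", nrow(loci)), loci$gene_id)
    hom_a <- hom_b <- col_a <- col_b <- character(0)

    for (i in seq_len(n_collinear_blocks)) {
      t1 <- .take_run(free, block_length)
      free <- t1$free
      t2 <- .take_run(free, block_length, setdiff(chroms, t1$chrom))
      free <- t2$free
      for (k in seq_len(block_length) - 1L) {
        ga <- gene_id(t1$chrom, t1$start_rank + k)
        gb <- gene_id(t2$chrom, t2$start_rank + k)
        col_a <- c(col_a, ga)
        col_b <- c(col_b, gb)
        hom_a <- c(hom_a, ga)
        hom_b <- c(hom_b, gb)
        truth[c(ga, gb)] <- "wgd_segmental"
      }
    }
    for (i in seq_len(n_tandem_arrays)) {
      t1 <- .take_run(free, tandem_array_size)
      free <- t1$free
      ids <- gene_id(t1$chrom, t1$start_rank + seq_len(tandem_array_size) - 1L)
      hom_a <- c(hom_a, ids[-length(ids)])
      hom_b <- c(hom_b, ids[-1L])
      truth[ids] <- "tandem"
    }
    for (i in seq_len(n_proximal_pairs)) {
      d <- sample(2:proximal_window, 1L)
      t1 <- .take_run(free, d + 1L)
      free <- t1$free
      # only the two endpoint genes are part of the pair; interior slots
      # are released for other features
      ga <- gene_id(t1$chrom, t1$start_rank)
      gb <- gene_id(t1$chrom, t1$start_rank + d)
      if (d > 1L)
        free[[t1$chrom]][(t1$start_rank + 2L):(t1$start_rank + d)] <- TRUE
      hom_a <- c(hom_a, ga)
      hom_b <- c(hom_b, gb)
      truth[c(ga, gb)] <- "proximal"
    }
    for (i in seq_len(n_dispersed_pairs)) {
      t1 <- .take_run(free, 1L)
      free <- t1$free
      t2 <- .take_run(free, 1L, setdiff(chroms, t1$chrom))
      free <- t2$free
      ga <- gene_id(t1$chrom, t1$start_rank)
      gb <- gene_id(t2$chrom, t2$start_rank)
      hom_a <- c(hom_a, ga)
      hom_b <- c(hom_b, gb)
      truth[c(ga, gb)] <- "dispersed"
    }
    list(loci = loci,
         homolog_pairs = if (length(hom_a) > 0L)
           gene_pair_list(hom_a, hom_b, "homolog")
         else gene_pair_list(character(0), character(0), "homolog"),
         collinear_pairs = if (length(col_a) > 0L)
           gene_pair_list(col_a, col_b, "collinear")
         else gene_pair_list(character(0), character(0), "collinear"),
         truth = truth)
  })
}

# Branch labels for a species tree: tip labels for terminal branches,
# node labels for internal ones (auto-filled N1..Nk when absent, root
# included).
.branch_labels <- function(tree) {
  n_tip <- ape::Ntip(tree)
  nl <- tree$node.label
  if (is.null(nl) || any(is.na(nl)) || any(!nzchar(nl)))
    nl <- sprintf("N%d", seq_len(tree$Nnode))
  tree$node.label <- nl
  tree
}

#' Simulate a gene tree from a species tree with known events
#'
#' Grows a gene tree top-down along the species tree.  Events are placed on
#' species-tree branches (identified by the label of the branch's child
#' node; internal nodes without labels are auto-labelled `N1..Nk`, root
#' first in ape node order).  A duplication splits one gene lineage present
#' on that branch into two; a loss removes one.  Random choices (which
#' lineage) are governed by `seed`.
#'
#' Truth counts are the events that remain identifiable in the realized
#' tree: duplications whose node survives with both daughter lineages, and
#' applied losses.  Scenarios where events mask each other (a duplication
#' cancelled by a same-branch loss, or a whole clade erased by several
#' losses) are legal input but not recoverable by parsimony reconciliation.
#'
#' @param species_tree Rooted binary `ape::phylo` tree.
#' @param events Data frame with columns `branch` (branch label) and `type`
#'   (`"duplication"` or `"loss"`), applied in row order within each branch.
#' @param seed Integer seed.
#' @return List with `gene_tree` (`ape::phylo`), `leaf_species_map` (named
#'   character vector), `species_tree` (with node labels filled in) and
#'   `truth` (list: `duplications`, `losses`).
#' @export
simulate_gene_tree <- function(species_tree, events, seed = 1L) {
  .check_rooted_binary(species_tree, "species tree")
  species_tree <- .branch_labels(species_tree)
  if (is.null(events) || nrow(events) == 0L)
    events <- data.frame(branch = character(0), type = character(0))
  if (!all(events$type %in% c("duplication", "loss")))
    stop("event types must be 'duplication' or 'loss'")
  idx <- .tree_index(species_tree)
  n_tip <- idx$n_tips
  node_label <- c(species_tree$tip.label, species_tree$node.label)
  bad <- setdiff(events$branch, node_label)
  if (length(bad) > 0L)
    stop("event branch(es) not in species tree: ", paste(bad, collapse = ", "))

  counter <- new.env(parent = emptyenv())
  leaf2sp <- new.env(parent = emptyenv())
  truth <- new.env(parent = emptyenv())
  truth$losses <- 0L

  withr::with_seed(as.integer(seed), {
    # Within-branch structures: nested lists of placeholders ("live" slots)
    # and dup nodes created on this branch.  branch_sim() returns, for each
    # entering lineage, a newick substring or NA if extinct below.
    new_leaf <- function(species) {
      k <- (get0(species, envir = counter, ifnotfound = 0L)) + 1L
      assign(species, k, envir = counter)
      nm <- sprintf("%s_%d", species, k)
      assign(nm, species, envir = leaf2sp)
      nm
    }

    branch_sim <- function(v, k_entering) {
      if (k_entering == 0L) return(character(0))
      # each struct: a nested list; leaf nodes are placeholder ids
      next_ph <- 1L
      make_ph <- function() {
        id <- sprintf("ph%d", next_ph)
        next_ph <<- next_ph + 1L
        id
      }
      structs <- lapply(seq_len(k_entering), function(i) make_ph())

      collect_ph <- function(s) {
        if (is.character(s)) return(s)
        c(collect_ph(s$left), collect_ph(s$right))
      }
      replace_ph <- function(s, target, value) {
        if (is.character(s)) return(if (identical(s, target)) value else s)
        s$left <- replace_ph(s$left, target, value)
        s$right <- replace_ph(s$right, target, value)
        s
      }
      drop_ph <- function(s, target) {  # returns NULL when emptied
        if (is.character(s)) return(if (identical(s, target)) NULL else s)
        s$left <- drop_ph(s$left, target)
        s$right <- drop_ph(s$right, target)
        if (is.null(s$left) && is.null(s$right)) return(NULL)
        if (is.null(s$left)) return(s$right)
        if (is.null(s$right)) return(s$left)
        s
      }

      ev <- events[events$branch == node_label[v], , drop = FALSE]
      for (i in seq_len(nrow(ev))) {
        live <- unlist(lapply(structs, function(s)
          if (is.null(s)) character(0) else collect_ph(s)))
        if (ev$type[i] == "duplication") {
          if (length(live) == 0L) stop("duplication on an extinct branch")
          target <- if (length(live) == 1L) live else sample(live, 1L)
          node <- list(left = make_ph(), right = make_ph(), dup = TRUE)
          structs <- lapply(structs, function(s)
            if (is.null(s)) NULL else replace_ph(s, target, node))
        } else {
          if (length(live) == 0L) stop("loss on an extinct branch")
          target <- if (length(live) == 1L) live else sample(live, 1L)
          structs <- lapply(structs, function(s)
            if (is.null(s)) NULL else drop_ph(s, target))
          truth$losses <- truth$losses + 1L
        }
      }

      live <- unlist(lapply(structs, function(s)
        if (is.null(s)) character(0) else collect_ph(s)))
      m <- length(live)
      expansion <- setNames(rep(NA_character_, m), live)
      if (m > 0L) {
        if (v <= n_tip) {
          expansion[] <- vapply(live, function(p)
            new_leaf(species_tree$tip.label[v]), "")
        } else {
          kids <- idx$children[[v]]
          left <- branch_sim(kids[1L], m)
          right <- branch_sim(kids[2L], m)
          for (i in seq_len(m)) {
            l <- left[i]
            r <- right[i]
            expansion[i] <- if (!is.na(l) && !is.na(r)) {
              sprintf("(%s,%s)", l, r)
            } else if (!is.na(l)) {
              l
            } else if (!is.na(r)) {
              r
            } else {
              NA_character_
            }
          }
        }
      }

      render <- function(s) {
        if (is.null(s)) return(NA_character_)
        if (is.character(s)) return(expansion[[s]])
        l <- render(s$left)
        r <- render(s$right)
        if (!is.na(l) && !is.na(r)) {
          truth$duplications <- (get0("duplications", envir = truth,
                                      ifnotfound = 0L)) + 1L
          sprintf("(%s,%s)", l, r)
        } else if (!is.na(l)) {
          l
        } else if (!is.na(r)) {
          r
        } else {
          NA_character_
        }
      }
      vapply(structs, render, "")
    }

    truth$duplications <- 0L
    res <- branch_sim(idx$root, 1L)
    if (is.na(res))
      stop("loss events emptied the gene tree")
    if (!grepl("\\(", res))
      stop("gene tree collapsed to a single leaf; reduce loss events")
    gene_tree <- ape::read.tree(text = paste0(res, ";"))
    leaf_map <- setNames(vapply(gene_tree$tip.label,
                                function(nm) get(nm, envir = leaf2sp), ""),
                         gene_tree$tip.label)
    list(gene_tree = gene_tree,
         leaf_species_map = leaf_map,
         species_tree = species_tree,
         truth = list(duplications = truth$duplications,
                      losses = truth$losses))
  })
}
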