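test_that("LCA mapping sends each gene node to the ancestor of its species", {
  st <- ape::read.tree(text = "(A,B);")
  gt <- ape::read.tree(text = "(a1,b1);")
  map <- lca_map(gt, st, c(a1 = "A", b1 = "B"))
  expect_equal(map[3], 3L)  # gene root -> species root
  expect_equal(map[1:2], match(c("A", "B"), st$tip.label))

  # congruent gene tree: every internal node maps to its counterpart
  st2 <- ape::read.tree(text = "((A,B),C);")
  gt2 <- ape::read.tree(text = "((a,b),c);")
  m2 <- lca_map(gt2, st2, c(a = "A", b = "B", c = "C"))
  expect_equal(m2, c(1L, 2L, 3L, 4L, 5L))

  expect_error(lca_map(gt, st, c(a1 = "A")), "b1")
  expect_error(lca_map(gt, st, c(a1 = "A", b1 = "Z")), "Z")
  poly <- ape::read.tree(text = "(a1,b1,c1);")
  expect_error(lca_map(poly, st, c(a1 = "A", b1 = "B", c1 = "A")),
               "binary|rooted")
})

test_that("duplication and loss counts match hand reconciliations", {
  st <- ape::read.tree(text = "(A,B);")

  # one ancestral duplication, fully retained: 1 duplication, 0 losses
  gt <- ape::read.tree(text = "((a1,b1),(a2,b2));")
  r <- count_duplications_losses(gt, st, c(a1 = "A", b1 = "B",
                                           a2 = "A", b2 = "B"))
  expect_equal(r$total_duplications, 1L)
  expect_equal(r$total_losses, 0L)
  expect_equal(r$per_node$duplications[r$per_node$node_label == "A|B"], 1L)

  # species-specific duplication in A
  gt2 <- ape::read.tree(text = "((a1,a2),b1);")
  r2 <- count_duplications_losses(gt2, st, c(a1 = "A", a2 = "A", b1 = "B"))
  expect_equal(r2$total_duplications, 1L)
  expect_equal(r2$total_losses, 0L)
  expect_equal(r2$per_node$duplications[r2$per_node$node_label == "A"], 1L)

  # congruent one-copy tree: zero duplications, zero losses
  st3 <- ape::read.tree(text = "((A,B),C);")
  gt3 <- ape::read.tree(text = "((a,b),c);")
  r3 <- count_duplications_losses(gt3, st3, c(a = "A", b = "B", c = "C"))
  expect_equal(r3$total_duplications, 0L)
  expect_equal(r3$total_losses, 0L)
})

test_that("losses are counted and placed by the path-length rule", {
  st <- ape::read.tree(text = "((A,B),C);")
  # single-copy family missing in A: one loss on the A branch
  r <- count_duplications_losses(ape::read.tree(text = "(b,c);"), st,
                                 c(b = "B", c = "C"))
  expect_equal(r$total_duplications, 0L)
  expect_equal(r$total_losses, 1L)
  expect_equal(r$per_node$losses[r$per_node$node_label == "A"], 1L)

  # duplication at the root, second copy lost in A
  gt <- ape::read.tree(text = "(((a1,b1),c1),(b2,c2));")
  r2 <- count_duplications_losses(gt, st,
                                  c(a1 = "A", b1 = "B", c1 = "C",
                                    b2 = "B", c2 = "C"))
  expect_equal(r2$total_duplications, 1L)
  expect_equal(r2$total_losses, 1L)
  expect_equal(r2$per_node$losses[r2$per_node$node_label == "A"], 1L)
})

test_that("counts are invariant under gene relabelling", {
  st <- ape::read.tree(text = "((A,B),C);")
  gt <- ape::read.tree(text = "(((x1,y1),z1),(y2,z2));")
  map <- c(x1 = "A", y1 = "B", z1 = "C", y2 = "B", z2 = "C")
  r <- count_duplications_losses(gt, st, map)
  gt2 <- gt
  gt2$tip.label <- paste0("q_", gt$tip.label)
  r2 <- count_duplications_losses(gt2, st, setNames(map, paste0("q_", names(map))))
  expect_equal(r$per_node, r2$per_node)
  expect_equal(r$total_duplications, r2$total_duplications)
  expect_equal(r$total_losses, r2$total_losses)
})
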