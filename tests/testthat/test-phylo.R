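test_that("hamming matrix counts differing columns with the gap rule", {
  aln <- structure(list(
    reference = "R",
    matrix = rbind(R = c("M", "K", "V"),
                   A = c("M", "R", "V"),
                   B = c("M", "-", "V"),
                   C = c("M", "-", "V")),
    ref_pos = 1:3, labels = as.character(1:3)),
    class = "protein_alignment")
  d <- hamming_matrix(aln)
  expect_identical(d["R", "A"], 1L)
  expect_identical(d["R", "B"], 1L)   # gap vs residue differs
  expect_identical(d["B", "C"], 0L)   # gap vs gap does not
  expect_true(all(diag(d) == 0L))
  expect_identical(d, t(d))
  d2 <- hamming_matrix(aln, exclude = "C")
  expect_false("C" %in% rownames(d2))
})

test_that("NJ solves the 4-taxon additive example exactly", {
  d <- matrix(c(0, 2, 4, 6,
                2, 0, 4, 6,
                4, 4, 0, 4,
                6, 6, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tree <- neighbor_joining(d)
  # additivity: every pairwise path distance is reproduced
  expect_equal(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)], d,
               tolerance = 1e-12, ignore_attr = TRUE)
  # topology: A and B are siblings
  expect_true(ape::is.monophyletic(ape::root(tree, "D"), c("A", "B")))
  # leaf branch lengths A:1, B:1, C:1, D:3
  leaf_edge <- function(t, tip) {
    t$edge.length[t$edge[, 2] == which(t$tip.label == tip)]
  }
  expect_equal(leaf_edge(tree, "A"), 1)
  expect_equal(leaf_edge(tree, "B"), 1)
  expect_equal(leaf_edge(tree, "C"), 1)
  expect_equal(leaf_edge(tree, "D"), 3)
})

test_that("3 taxa give the closed-form star resolution", {
  d <- matrix(c(0, 3, 5,
                3, 0, 6,
                5, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(d)
  leaf_edge <- function(t, tip) {
    t$edge.length[t$edge[, 2] == which(t$tip.label == tip)]
  }
  expect_equal(leaf_edge(tree, "A"), (3 + 5 - 6) / 2)
  expect_equal(leaf_edge(tree, "B"), (3 + 6 - 5) / 2)
  expect_equal(leaf_edge(tree, "C"), (5 + 6 - 3) / 2)
})

test_that("all-zero distances give all-zero branch lengths", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tree <- neighbor_joining(d)
  expect_true(all(tree$edge.length == 0))
})

test_that("NJ agrees with the reference implementation on random matrices", {
  for (seed in 1:10) {
    d <- random_additive_matrix(sample(4:8, 1), seed)
    mine <- neighbor_joining(d)
    oracle <- ape::nj(d)
    expect_equal(ape::cophenetic.phylo(mine)[rownames(d), rownames(d)],
                 ape::cophenetic.phylo(oracle)[rownames(d), rownames(d)],
                 tolerance = 1e-9, ignore_attr = TRUE,
                 label = paste("NJ path distances, seed", seed))
    expect_true(ape::all.equal.phylo(ape::unroot(mine), ape::unroot(oracle),
                                     use.edge.length = FALSE),
                label = paste("NJ topology, seed", seed))
  }
})

test_that("midpoint rooting equalizes the two deepest leaves", {
  for (seed in 11:20) {
    d <- random_additive_matrix(sample(4:8, 1), seed)
    rooted <- midpoint_root(neighbor_joining(d))
    expect_true(ape::is.rooted(rooted))
    n_tip <- length(rooted$tip.label)
    depths <- ape::dist.nodes(rooted)[seq_len(n_tip), n_tip + 1L]
    two_deepest <- sort(depths, decreasing = TRUE)[1:2]
    expect_lt(abs(two_deepest[[1]] - two_deepest[[2]]), 1e-9)
    # deepest leaf depth equals half the tree diameter
    expect_equal(max(depths), max(d[rooted$tip.label, rooted$tip.label]) / 2,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("midpoint rooting matches the phangorn oracle topologically", {
  skip_if_not_installed("phangorn")
  for (seed in 21:25) {
    d <- random_additive_matrix(6, seed)
    tree <- neighbor_joining(d)
    mine <- midpoint_root(tree)
    oracle <- phangorn::midpoint(tree)
    expect_equal(
      ape::cophenetic.phylo(mine)[rownames(d), rownames(d)],
      ape::cophenetic.phylo(oracle)[rownames(d), rownames(d)],
      tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("two-leaf midpoint splits the single edge in half", {
  tree <- ape::read.tree(text = "(A:1,B:3);")
  rooted <- midpoint_root(tree)
  depths <- ape::dist.nodes(rooted)[1:2, 3]
  expect_equal(unname(depths), c(2, 2))
})

test_that("square-root transform changes lengths only", {
  d <- random_additive_matrix(6, 33)
  tree <- midpoint_root(neighbor_joining(d))
  sq <- sqrt_branch_transform(tree)
  expect_equal(sq$edge.length, sqrt(tree$edge.length))
  expect_identical(sq$edge, tree$edge)
  expect_identical(sq$tip.label, tree$tip.label)
  expect_true(attr(sq, "sqrt_transformed"))
  # monotone: ordering of branch lengths preserved
  expect_identical(order(sq$edge.length), order(tree$edge.length))
})

test_that("newick serialization round-trips byte-stably", {
  for (seed in 41:45) {
    d <- random_additive_matrix(6, seed)
    tree <- midpoint_root(neighbor_joining(d))
    s1 <- write_newick(tree)
    s2 <- write_newick(read_newick(s1))
    expect_identical(s2, s1)
  }
  # file round trip with MICA-style labels
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("MICA*008", "MICA*002#", "MICA*107N"),
                              c("MICA*008", "MICA*002#", "MICA*107N")))
  tree <- neighbor_joining(d)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  back <- read_newick(path)
  expect_setequal(back$tip.label, rownames(d))
})

test_that("degenerate inputs are handled with warnings", {
  d <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_warning(tree <- neighbor_joining(d), "fewer than 3")
  expect_equal(sum(tree$edge.length), 4)
  d0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(midpoint_root(neighbor_joining(d0)), "arbitrarily")
})
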