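test_that("Newick parsing and writing round-trip topology, lengths and labels", {
  t1 <- parseNewick("(A:1,B:1);")
  expect_identical(treeLeafLabels(t1), c("A", "B"))
  expect_equal(sum(t1@phylo$edge.length), 2)
  t2 <- parseNewick("((A:0.1,B:0.2)n1:0.3,C:0.4);")
  expect_true("n1" %in% treeNodeLabels(t2))
  # unlabeled nodes are auto-labeled deterministically in preorder
  expect_identical(treeRootLabel(t2), "node1")
  # round trip of a random 10-leaf tree
  set.seed(7)
  t3 <- randomTree(10, labels = paste0("t", 1:10))
  t4 <- parseNewick(writeNewick(t3))
  expect_equal(t4@phylo$edge, t3@phylo$edge)
  expect_equal(t4@phylo$edge.length, t3@phylo$edge.length, tolerance = 1e-8)
  expect_identical(t4@phylo$tip.label, t3@phylo$tip.label)
  expect_identical(t4@phylo$node.label, t3@phylo$node.label)
  expect_error(parseNewick("((A:1,B:1;"), "malformed Newick")
})

test_that("node iterators are deterministic preorder and subtrees are closed", {
  tr <- tree4()
  expect_identical(treeNodeLabels(tr),
                   c("root", "n1", "A", "B", "n2", "C", "D"))
  expect_identical(treeBranchLabels(tr), c("n1", "A", "B", "n2", "C", "D"))
  expect_setequal(subtreeNodeLabels(tr, "n2"), c("n2", "C", "D"))
  expect_identical(subtreeNodeLabels(tr, "A"), "A")
  expect_setequal(subtreeNodeLabels(tr, "root"), treeNodeLabels(tr))
})

test_that("neighbor-joining recovers an additive tree and handles 2 and 3 taxa", {
  # distances generated from a known 4-taxon tree: ((A,B),(C,D)) with
  # pendant 0.1/0.2/0.3/0.4 and internal 0.25
  bl <- c(A = 0.1, B = 0.2, C = 0.3, D = 0.4)
  d <- matrix(0, 4, 4, dimnames = list(names(bl), names(bl)))
  d["A", "B"] <- d["B", "A"] <- bl["A"] + bl["B"]
  d["C", "D"] <- d["D", "C"] <- bl["C"] + bl["D"]
  for (x in c("A", "B")) for (y in c("C", "D"))
    d[x, y] <- d[y, x] <- bl[x] + bl[y] + 0.25
  tr <- neighborJoining(d)
  # topology: A and B form a cherry
  phy <- tr@phylo
  mrcaAB <- ape::getMRCA(phy, c("A", "B"))
  expect_false(mrcaAB == ape::getMRCA(phy, c("A", "C")))
  # branch lengths recovered (pendant edges)
  for (leaf in names(bl)) {
    i <- match(leaf, phy$tip.label)
    e <- which(phy$edge[, 2] == i)
    expect_equal(phy$edge.length[e], unname(bl[leaf]), tolerance = 1e-10)
  }
  # path-length additivity
  expect_equal(ape::cophenetic.phylo(phy)["A", "D"], d["A", "D"],
               tolerance = 1e-10)
  # 2 taxa: the distance splits evenly across an arbitrary root
  t2 <- neighborJoining(matrix(c(0, 1, 1, 0), 2,
                               dimnames = list(c("X", "Y"), c("X", "Y"))))
  expect_equal(t2@phylo$edge.length, c(0.5, 0.5))
  # ultrametric 3 taxa: hand-computed join
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighborJoining(d3)
  cp <- ape::cophenetic.phylo(t3@phylo)
  expect_equal(cp[c("A", "B", "C"), c("A", "B", "C")], d3,
               tolerance = 1e-10)
  expect_error(neighborJoining(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("negative NJ branch lengths are clamped with a warning", {
  d <- matrix(c(0, 0.531, 0.744, 1.146,
                0.531, 0, 1.816, 0.403,
                0.744, 1.816, 0, 1.797,
                1.146, 0.403, 1.797, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_warning(tr <- neighborJoining(d), "clamping")
  expect_true(all(tr@phylo$edge.length >= 0))
})

test_that("JC-corrected distances invert simulated divergence", {
  tr <- parseNewick("(A:0.15,B:0.15);")
  g <- readGrammar(grammarFile("jc69"))
  p <- grammarParams(g); p@rates["u"] <- 1 / 3; grammarParams(g) <- p
  aln <- simulateAlignment(g, tr, length = 4000, seed = 99)
  d <- jcDistances(alignmentRows(aln))
  expect_equal(d["A", "B"], 0.3, tolerance = 0.05)
  expect_equal(diag(d), c(A = 0, B = 0))
})
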