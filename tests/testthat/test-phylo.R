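test_that("K2P distance matches the closed form on counted-mutation toys", {
  # 100 sites: 10 transitions (A<->G), 5 transversions (A<->C)
  s1 <- rep("A", 100)
  s2 <- s1
  s2[1:10] <- "G"
  s2[11:15] <- "C"
  expect_equal(k2p_distance(s1, s2),
               -0.5 * log((1 - 0.25) * sqrt(1 - 0.1)))
  expect_equal(k2p_distance(s2, s1), k2p_distance(s1, s2))
  expect_equal(k2p_distance(s1, s1), 0)
  # string input works too
  expect_equal(k2p_distance(paste(s1, collapse = ""),
                            paste(s2, collapse = "")),
               k2p_distance(s1, s2))
})

test_that("gap and ambiguity sites are excluded pairwise", {
  s1 <- c("A", "A", "-", "G", "T", "N")
  s2 <- c("G", "A", "C", "-", "T", "A")
  # only sites 1, 2, 5 compare: one transition in three sites
  expect_equal(k2p_distance(s1, s2),
               -0.5 * log((1 - 2 / 3) * sqrt(1)))
  expect_error(k2p_distance(c("-", "N"), c("A", "C")), "no comparable")
})

test_that("saturated pairs raise an explicit error", {
  s1 <- rep(c("A", "C"), 50)
  s2 <- rep(c("G", "T"), 50)   # every site a transition: P = 1
  expect_error(k2p_distance(s1, s2), "saturation")
})

test_that("K2P matrix agrees with an independent implementation", {
  tree <- ape::read.tree(text = "((a:0.1,b:0.12):0.05,(c:0.08,d:0.1):0.07);")
  aln <- simulate_alignment(tree, 1500, rate_ratio = 2, seed = 99)
  D <- k2p_matrix(aln)
  expect_true(isSymmetric(unname(D)))
  expect_equal(unname(diag(D)), rep(0, 4))
  D_ape <- as.matrix(ape::dist.dna(as_dnabin(aln), model = "K80"))
  expect_equal(D, D_ape[rownames(D), colnames(D)], tolerance = 1e-12)
})

test_that("K2P estimates are unbiased in the mean at d = 0.1", {
  tree <- ape::read.tree(text = "(a:0.05,b:0.05);")
  ds <- vapply(1:200, function(i) {
    aln <- simulate_alignment(tree, 2000, rate_ratio = 2, seed = 1000 + i)
    k2p_distance(unclass(aln)["a", ], unclass(aln)["b", ])
  }, numeric(1))
  expect_lt(abs(mean(ds) - 0.1), 0.005)
})

test_that("three taxa resolve by the closed three-point formulas", {
  D <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- nj_tree(D)
  pc <- ape::cophenetic.phylo(tree)
  expect_equal(pc["a", "b"], 0.3)
  expect_equal(pc["a", "c"], 0.4)
  expect_equal(pc["b", "c"], 0.5)
  el <- tree$edge.length[match(1:3, tree$edge[, 2])]
  expect_equal(el, c((0.3 + 0.4 - 0.5) / 2,
                     (0.3 + 0.5 - 0.4) / 2,
                     (0.4 + 0.5 - 0.3) / 2))
})

test_that("an additive four-taxon matrix is recovered exactly", {
  # tree ((a:2,b:3):1,c:4,d:5) -> additive distances
  D <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, byrow = TRUE,
              dimnames = list(letters[1:4], letters[1:4]))
  tree <- nj_tree(D)
  # the only correct quartet split is ab|cd
  expect_true("c|d" %in% tree_bipartitions(tree) ||
                "a|b" %in% tree_bipartitions(tree))
  expect_equal(ape::cophenetic.phylo(tree)[letters[1:4], letters[1:4]],
               D)
  # and it matches the reference implementation's topology
  ref <- ape::nj(D)
  expect_true(ape::all.equal.phylo(ape::unroot(tree), ape::unroot(ref),
                                   use.edge.length = FALSE))
  expect_error(nj_tree(matrix(c(0, 1, 1, 0), 2)), "3 taxa")
  Dbad <- D; Dbad[1, 2] <- 99
  expect_error(nj_tree(Dbad), "symmetric")
})

test_that("NJ is invariant to taxon input order up to relabeling", {
  set.seed(5)
  tree0 <- ape::rtree(6)
  aln <- simulate_alignment(tree0, 800, seed = 3)
  D <- k2p_matrix(aln)
  t1 <- nj_tree(D)
  perm <- sample(rownames(D))
  t2 <- nj_tree(D[perm, perm])
  expect_setequal(tree_bipartitions(t1), tree_bipartitions(t2))
  pc1 <- ape::cophenetic.phylo(t1)
  pc2 <- ape::cophenetic.phylo(t2)
  expect_equal(pc2[rownames(pc1), colnames(pc1)], pc1, tolerance = 1e-12)
})

test_that("negative intermediate branch lengths are clamped, deficit moved", {
  # a matrix known to produce a negative NJ branch estimate
  D <- matrix(c(0, 0.1, 0.4, 0.45,
                0.1, 0, 0.43, 0.48,
                0.4, 0.43, 0, 0.05,
                0.45, 0.48, 0.05, 0), 4, byrow = TRUE,
              dimnames = list(letters[1:4], letters[1:4]))
  tree <- nj_tree(D)
  expect_true(all(tree$edge.length >= 0))
})

test_that("bootstrap supports behave at the replicate extremes and are seeded", {
  tree0 <- ape::read.tree(
    text = "((a:0.05,b:0.05):0.3,(c:0.05,d:0.05):0.3);")
  aln <- simulate_alignment(tree0, 600, seed = 21)
  one <- suppressWarnings(bootstrap_support(aln, replicates = 1, seed = 4))
  sup <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
  b1 <- bootstrap_support(aln, replicates = 25, seed = 9)
  b2 <- bootstrap_support(aln, replicates = 25, seed = 9)
  expect_identical(b1$node.label, b2$node.label)
})

test_that("a long internal branch earns near-unanimous support", {
  tree0 <- ape::read.tree(
    text = "((a:0.05,b:0.05):0.4,(c:0.05,d:0.05):0.4);")
  aln <- simulate_alignment(tree0, 1000, seed = 31)
  bs <- bootstrap_support(aln, replicates = 100, seed = 2)
  sup <- suppressWarnings(as.numeric(bs$node.label))
  expect_gte(max(sup, na.rm = TRUE), 95)
})

test_that("simulated two-cluster data separates the clusters in the NJ tree", {
  # two geographic clades plus two distant outgroups
  txt <- paste0("(((sp1:0.02,sp2:0.02):0.02,sp3:0.03):0.15,",
                "((sp4:0.02,sp5:0.03):0.02,(sp6:0.02,sp7:0.02):0.03):0.15,",
                "(out1:0.4,out2:0.45):0.2);")
  tree0 <- ape::read.tree(text = txt)
  aln <- simulate_alignment(tree0, 3000, seed = 8)
  tree <- nj_tree(k2p_matrix(aln))
  splits <- tree_bipartitions(tree)
  cluster1 <- sort(c("sp1", "sp2", "sp3"))
  cluster2 <- sort(c("sp4", "sp5", "sp6", "sp7"))
  has_split <- function(side) {
    all_tips <- sort(tree$tip.label)
    key <- if (all_tips[1] %in% side)
      paste(setdiff(all_tips, side), collapse = "|")
    else paste(side, collapse = "|")
    key %in% splits
  }
  expect_true(has_split(cluster1))
  expect_true(has_split(cluster2))
})

test_that("trees and distance matrices serialize to standard text formats", {
  D <- matrix(c(0, 0.1, 0.2, 0.1, 0, 0.15, 0.2, 0.15, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  path_d <- withr::local_tempfile(fileext = ".dist")
  write_phylip_distance(D, path_d)
  lines <- readLines(path_d)
  expect_match(lines[1], "^\\s+3$")
  expect_length(lines, 4L)
  tree <- nj_tree(D)
  path_t <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path_t)
  back <- ape::read.tree(path_t)
  expect_setequal(back$tip.label, c("a", "b", "c"))
})

test_that("aligned FASTA round-trips through the alignment container", {
  aln <- sequence_alignment(c(t1 = "ACGTAC", t2 = "ACGTTC", t3 = "ACGAAC"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(aln, path)
  back <- read_fasta_alignment(path)
  expect_equal(unclass(back), unclass(aln))
  expect_error(sequence_alignment(c(a = "ACG", b = "ACGT")), "equal length")
  expect_error(sequence_alignment(c("ACG", "ACG")), "named")
})
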