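test_that("concatenation tiles genes in canonical order", {
  genes <- setNames(lapply(1:13, function(i) {
    setNames(replicate(3, random_dna(30)), c("t1", "t2", "t3"))
  }), c("cox1", "nad2", "cox2", "atp8", "atp6", "cox3", "nad3", "nad5",
        "nad4", "nad4L", "nad6", "cytb", "nad1"))
  sm <- concatenate_pcgs(genes)
  expect_equal(nchar(sm$matrix[[1]]), 390L)
  expect_equal(sm$partitions$gene[1:2], c("nad2", "cox1"))
  expect_equal(sm$partitions$end[13], 390L)
  expect_true(all(sm$partitions$start ==
                    c(1L, head(sm$partitions$end, -1) + 1L)))
  # partitions slice back to the exact input alignments
  for (g in names(genes)) {
    expect_equal(extract_partition(sm, g), genes[[g]][sm$taxa])
  }
})

test_that("a single taxon with the published gene sizes spans 11191 columns", {
  aeg <- fixture_record("aegypti")
  pcg <- aeg$features[aeg$features$category == "PCG", ]
  genes <- setNames(lapply(pcg$size, function(n) c(PQ197330 = random_dna(n))),
                    pcg$name)
  sm <- concatenate_pcgs(genes)
  expect_equal(nchar(sm$matrix[[1]]), 11191L)
  expect_equal(nrow(sm$partitions), 13L)
})

test_that("taxon bookkeeping: duplicates error, partial taxa are dropped", {
  g <- list(cox1 = c(a = "ACGTAA", b = "ACGTAA", a = "ACGTAA"))
  expect_error(concatenate_pcgs(g), "duplicated")
  g2 <- list(cox1 = c(a = "ACGTAA", b = "ACGTAA"),
             nad2 = c(a = "ACGTAA"))
  expect_warning(sm <- concatenate_pcgs(g2), "dropped")
  expect_equal(sm$taxa, "a")
})

test_that("neighbor joining reproduces additive distance matrices exactly", {
  # 4-taxon tree ((A:1,B:2):1,(C:3,D:4))
  D4 <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(D4)
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], D4,
               tolerance = 1e-9)
  expect_true(ape::is.binary(tr))
  # internal edge length of the true tree is recovered
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal, 1, tolerance = 1e-9)
  # 3 taxa: unique unrooted tree with closed-form branch lengths
  D3 <- matrix(c(0, 2, 3, 2, 0, 3.4, 3, 3.4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- nj_tree(D3)
  expect_equal(ape::cophenetic.phylo(tr3)[c("x", "y", "z"), c("x", "y", "z")],
               D3, tolerance = 1e-9)
})

test_that("neighbor joining matches the reference implementation topology", {
  set.seed(40)
  for (i in 1:5) {
    tr0 <- ape::rtree(7)
    tr0$edge.length <- runif(nrow(tr0$edge), 0.05, 0.3)
    D <- ape::cophenetic.phylo(tr0)
    noise <- matrix(runif(49, 0, 0.01), 7, 7)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    Dn <- D + noise
    ours <- nj_tree(Dn)
    ref <- ape::nj(Dn)
    expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ on an ultrametric matrix agrees with average-linkage clustering", {
  set.seed(41)
  tr0 <- ape::rcoal(8)
  D <- ape::cophenetic.phylo(tr0)
  ours <- nj_tree(D)
  upgma <- ape::as.phylo(hclust(as.dist(D), method = "average"))
  expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(upgma)), 0,
               ignore_attr = TRUE)
})

test_that("negative branch estimates are clamped with the deficit moved to the sister", {
  # b sits "past" a, so a's branch estimate in the (a,b) join is negative
  D <- matrix(c(0,   0.1, 0.5,  0.5,
                0.1, 0,   0.62, 0.62,
                0.5, 0.62, 0,   0.9,
                0.5, 0.62, 0.9, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  # the joined cherry keeps its pairwise path length despite the clamp
  ph <- ape::cophenetic.phylo(tr)
  expect_equal(ph["a", "b"], 0.1, tolerance = 1e-9)
  tip_a <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")]
  expect_equal(tip_a, 0)
})

test_that("malformed distance input is rejected", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(nj_tree(D), "at least 3")
  D3 <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3)
  expect_error(nj_tree(D3), "NA")
  D3b <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3, 3)
  expect_error(nj_tree(D3b), "negative")
  D3c <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3)
  expect_error(nj_tree(D3c), "symmetric")
})

test_that("NJ recovers the generating topology from simulated supermatrices", {
  set.seed(90)
  hits <- 0L
  for (run in 1:100) {
    tr0 <- ape::rtree(10)
    tr0$edge.length <- runif(nrow(tr0$edge), 0.01, 0.03)
    anc <- random_dna(1500)
    ev <- evolve_sequences(anc, tr0, kappa = 4, seed = 9000 + run)
    D <- k2p_matrix(ev$leaves)
    if (any(is.na(D))) next
    got <- nj_tree(D)
    rf <- ape::dist.topo(ape::unroot(got), ape::unroot(tr0))
    if (rf == 0) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("bootstrap supports are reproducible and bounded", {
  panel <- cached_panel(n_taxa = 4, depth = 0.01)
  sm <- concatenate_pcgs(panel$gene_alignments)
  one <- bootstrap_nj(sm, n_replicates = 1, seed = 5)
  expect_true(all(one$supports %in% c(0, 100)))
  b1 <- bootstrap_nj(sm, n_replicates = 10, seed = 5)
  b2 <- bootstrap_nj(sm, n_replicates = 10, seed = 5)
  expect_identical(b1$supports, b2$supports)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))
  # growing the replicate count extends the stream without reshuffling
  b3 <- bootstrap_nj(sm, n_replicates = 20, seed = 5)
  expect_identical(lapply(b1$replicates, ape::write.tree),
                   lapply(b3$replicates[1:10], ape::write.tree))
  expect_true(all(b3$supports >= 0 & b3$supports <= 100))
})

test_that("a clean two-cherry signal gets full central support", {
  set.seed(70)
  anc <- random_dna(4000)
  ev <- evolve_sequences(
    anc, "((A:0.01,B:0.01):0.1,(C:0.01,D:0.01):0.1);", kappa = 4,
    seed = 71)
  bs <- bootstrap_nj(ev$leaves, n_replicates = 100, seed = 72)
  expect_equal(bs$n_ok, 100L)
  expect_true(is_monophyletic_unrooted(bs$tree, c("A", "B")))
  expect_equal(split_support(bs$replicates, c("A", "B")), 100)
})

test_that("Newick output round-trips isomorphically with supports", {
  set.seed(80)
  for (i in 1:5) {
    tr <- ape::rtree(8)
    tf <- tempfile(fileext = ".nwk")
    write_newick(tr, tf)
    back <- ape::read.tree(tf)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(back$tip.label), sort(tr$tip.label))
  }
  panel <- cached_panel(n_taxa = 4, depth = 0.01)
  bs <- bootstrap_nj(concatenate_pcgs(panel$gene_alignments),
                     n_replicates = 10, seed = 3)
  tf <- tempfile(fileext = ".nwk")
  write_newick(bs$tree, tf)
  back <- ape::read.tree(tf)
  expect_identical(back$node.label, bs$tree$node.label)
})

test_that("supermatrix exports are consistent and re-readable", {
  panel <- cached_panel(n_taxa = 4, depth = 0.01)
  sm <- concatenate_pcgs(panel$gene_alignments)
  expect_equal(nchar(sm$matrix[[1]]), sum(with(sm$partitions, end - start + 1)))
  dir <- tempfile()
  paths <- write_supermatrix(sm, dir)
  expect_equal(read_fasta(paths[["fasta"]]), sm$matrix)
  phy <- readLines(paths[["phylip"]])
  expect_equal(phy[1], sprintf("%d %d", length(sm$taxa),
                               nchar(sm$matrix[[1]])))
  parts <- read.delim(paths[["partitions"]])
  expect_equal(nrow(parts), 13L)
})
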