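test_that("pairwise deletion masks keep only unambiguous shared sites", {
  aln <- epf_alignment(c(x = "AC-T", y = "ACGT"))
  expect_identical(pairwise_mask(aln, "x", "y"), c(1L, 2L, 4L))
  aln2 <- epf_alignment(c(x = "ANGT", y = "ACGT"))
  expect_identical(pairwise_mask(aln2, 1L, 2L), c(1L, 3L, 4L))
  expect_error(pairwise_mask(aln, "x", "x"), "must differ")

  set.seed(13)
  chars <- c("A", "C", "G", "T", "-", "N", "R", "Y")
  a <- sample(chars, 200, replace = TRUE, prob = c(rep(0.22, 4), 0.06,
                                                   0.03, 0.015, 0.015))
  b <- sample(chars, 200, replace = TRUE, prob = c(rep(0.22, 4), 0.06,
                                                   0.03, 0.015, 0.015))
  aln3 <- epf_alignment(rbind(p = a, q = b))
  oracle <- intersect(which(a %in% c("A", "C", "G", "T")),
                      which(b %in% c("A", "C", "G", "T")))
  expect_identical(pairwise_mask(aln3, "p", "q"), oracle)
})

test_that("TN93 distance is zero on identity, symmetric, and collapses
           to Jukes-Cantor on balanced input", {
  aln <- epf_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_equal(tn93_distance(aln, "a", "b"), 0)

  pair <- jc_limit_pair()
  p <- 12 / 120
  jc <- -0.75 * log(1 - 4 * p / 3)
  expect_equal(tn93_distance(pair, "s1", "s2"), jc, tolerance = 1e-6)
  expect_equal(tn93_distance(pair, "s1", "s2", freq_mode = "pair"), jc,
               tolerance = 1e-6)
  expect_equal(tn93_distance(pair, "s1", "s2"),
               tn93_distance(pair, "s2", "s1"))
})

test_that("TN93 matrix agrees with the reference pooled-frequency
           implementation", {
  sim <- generate_alignment(seqsim_spec(n_taxa = 8, aln_length = 400,
                                        gap_rate = 0.03, seed = 21))
  d <- tn93_matrix(sim$alignment)
  bin <- ape::as.DNAbin(tolower(unclass(sim$alignment)))
  ref <- as.matrix(ape::dist.dna(bin, model = "TN93",
                                 pairwise.deletion = TRUE))
  expect_equal(d, ref[rownames(d), colnames(d)], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("TN93 recovers the simulation-true distance at long lengths", {
  tree <- ape::read.tree(text = "(a:0.075,b:0.075);")
  sim <- generate_alignment(seqsim_spec(n_taxa = 2, aln_length = 1e5,
                                        tree = tree, gap_rate = 0,
                                        ambiguity_rate = 0, seed = 31))
  est <- tn93_distance(sim$alignment, "a", "b")
  expect_lt(abs(est - 0.15) / 0.15, 0.02)
})

test_that("saturated pairs are flagged and capped", {
  set.seed(41)
  a <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  b <- chartr("ACGT", "TGCA", a)  # every site a transversion
  aln <- epf_alignment(rbind(s1 = a, s2 = b))
  expect_warning(d <- tn93_distance(aln, "s1", "s2"), "saturated")
  expect_equal(as.numeric(d), 5)
  expect_true(attr(d, "saturated"))
  expect_warning(d2 <- tn93_distance(aln, "s1", "s2",
                                     saturation_ceiling = 2), "saturated")
  expect_equal(as.numeric(d2), 2)
})

test_that("neighbor joining reconstructs additive distances exactly", {
  for (seed in 1:6) {
    n <- 4 + (seed %% 5)
    ad <- random_additive(n, seed = 1000 + seed)
    tr <- nj_tree(ad$d)
    expect_equal(attr(tr, "total_length"), sum(tr$edge.length))
    # path-length oracle: the reconstructed tree's leaf-to-leaf path
    # lengths equal the input matrix
    coph <- cophenetic(tr)
    expect_equal(coph[rownames(ad$d), colnames(ad$d)], ad$d,
                 tolerance = 1e-8)
    expect_equal(phangorn::RF.dist(ape::unroot(tr),
                                   ape::unroot(ad$tree)), 0)
  }
})

test_that("three-taxon trees use the closed-form branch lengths", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  coph <- cophenetic(tr)
  expect_equal(coph["a", "b"], 3)
  expect_equal(coph["a", "c"], 5)
  expect_equal(coph["b", "c"], 6)
  # la = (3 + 5 - 6)/2 = 1; lb = 2; lc = 4
  lens <- sort(tr$edge.length)
  expect_equal(lens, c(1, 2, 4))
  expect_error(nj_tree(matrix(0, 1, 1)), ">= 2")
})

test_that("two taxa yield a single-edge tree", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  tr <- nj_tree(d)
  expect_identical(sort(tr$tip.label), c("a", "b"))
  expect_equal(sum(tr$edge.length), 0.4)
})

test_that("NJ matches UPGMA topology on ultrametric input and the
           reference NJ elsewhere", {
  set.seed(51)
  tr0 <- ape::rcoal(5)
  d <- cophenetic(tr0)
  nj <- nj_tree(d)
  up <- ape::as.phylo(upgma_linkage(d))
  expect_equal(phangorn::RF.dist(ape::unroot(nj), ape::unroot(up)), 0)

  # noisy matrices: same topology as the reference implementation
  for (seed in 1:4) {
    set.seed(seed)
    base <- random_additive(7, seed = 600 + seed)
    noisy <- base$d + matrix(runif(49, 0, 0.02), 7, 7)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    expect_equal(phangorn::RF.dist(ape::unroot(nj_tree(noisy)),
                                   ape::unroot(ape::nj(noisy))), 0)
  }
})

test_that("negative branch-length estimates are clamped to zero", {
  found_negative_ref <- FALSE
  for (seed in 1:20) {
    set.seed(seed)
    n <- 6
    m <- matrix(runif(n * n, 0.05, 1), n, n)
    d <- (m + t(m)) / 2
    diag(d) <- 0
    dimnames(d) <- list(letters[1:n], letters[1:n])
    tr <- nj_tree(d)
    expect_true(all(tr$edge.length >= 0))
    ref <- ape::nj(d)
    if (any(ref$edge.length < 0)) found_negative_ref <- TRUE
  }
  # the battery did exercise the clamping path
  expect_true(found_negative_ref)
})

test_that("bootstrap support is reproducible and saturates on clean
           two-clade signal", {
  sim <- two_clade_alignment(n_per_clade = 3, length = 800,
                             internal = 0.5, tip = 0.03, seed = 61)
  bt1 <- bootstrap_support(sim$alignment, replicates = 50, seed = 99)
  bt2 <- bootstrap_support(sim$alignment, replicates = 50, seed = 99)
  expect_identical(ape::write.tree(bt1), ape::write.tree(bt2))
  expect_gte(clade_support(bt1, c("a1", "a2", "a3")), 99)
  expect_equal(phangorn::RF.dist(ape::unroot(bt1),
                                 ape::unroot(sim$tree)), 0)

  one <- bootstrap_support(sim$alignment, replicates = 1, seed = 7)
  s1 <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
})

test_that("bootstrap support is invariant to taxon order", {
  sim <- two_clade_alignment(n_per_clade = 3, length = 300, seed = 71)
  aln <- sim$alignment
  perm <- epf_alignment(unclass(aln)[c(4, 2, 6, 1, 3, 5), , drop = FALSE])
  b1 <- bootstrap_support(aln, replicates = 30, seed = 3)
  b2 <- bootstrap_support(perm, replicates = 30, seed = 3)
  s1 <- sort(suppressWarnings(as.numeric(b1$node.label)))
  s2 <- sort(suppressWarnings(as.numeric(b2$node.label)))
  expect_identical(s1, s2)
})

test_that("tree annotation embeds metadata and summarizes clades", {
  sim <- two_clade_alignment(n_per_clade = 3, length = 600, seed = 81)
  tree <- nj_tree(tn93_matrix(sim$alignment))
  meta <- data.frame(
    strain_id = tree$tip.label,
    host_order = ifelse(grepl("^a", tree$tip.label), "Lepidoptera",
                        "Coleoptera"),
    host_species = "x", state = "S", source = "cadaver",
    stringsAsFactors = FALSE)
  ann <- annotate_tree(tree, meta, n_clades = 2)
  expect_match(ann$newick, "\\[&host=Lepidoptera")
  expect_identical(sort(unique(ann$table$clade)), c("clade1", "clade2"))
  comp <- ann$composition$host_order
  # planted host-clade structure: each clade is pure
  expect_true(all(apply(comp, 1, function(r) sum(r > 0) == 1)))

  # metadata-free call: plain Newick unchanged
  expect_identical(annotate_tree(tree), ape::write.tree(tree))
  bad_meta <- meta[-1, ]
  expect_error(annotate_tree(tree, bad_meta), meta$strain_id[1])
})
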