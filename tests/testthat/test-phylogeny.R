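test_that("p-distance uses pairwise deletion", {
  msa <- c(a = "AC-D", b = "ACED")
  expect_equal(p_distance(msa, "a", "b"), 0)
  expect_equal(p_distance(c(a = "AAAA", b = "AATT"), 1, 2), 0.5)
  expect_equal(p_distance(c(a = "AAAA", b = "AAAA"), 1, 2), 0)
  # no shared gap-free column
  expect_true(is.na(p_distance(c(a = "AA--", b = "--AA"), 1, 2)))
})

test_that("Poisson correction matches the closed form and its properties", {
  expect_equal(poisson_correct(0), 0)
  expect_lt(abs(poisson_correct(0.1) - 0.105361), 1e-6)
  expect_lt(abs(poisson_correct(0.5) - 0.693147), 1e-6)
  expect_error(poisson_correct(1), "saturated")
  expect_error(poisson_correct(-0.1), "non-negative")

  grid <- seq(0, 0.95, by = 0.05)
  d <- poisson_correct(grid)
  expect_true(all(d >= grid))          # correction never shrinks
  expect_true(all(diff(d) > 0))        # strictly monotone
})

test_that("NJ solves the 3-taxon system and recovers additive trees", {
  D3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D3)
  br <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(br[["A"]], 1)
  expect_equal(br[["B"]], 2)
  expect_equal(br[["C"]], 4)

  D4 <- additive_4taxon()
  tr4 <- nj_tree(D4)
  # topology: AB|CD split present
  expect_true("C|D" %in% tree_splits(tr4)$key)
  # exact recovery: path lengths reproduce the input to 1e-9
  co <- ape::cophenetic.phylo(tr4)[rownames(D4), colnames(D4)]
  expect_lt(max(abs(co - D4)), 1e-9)

  # degenerate all-equal matrix still yields a valid tree, internal 0
  De <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(De) <- 0
  tre <- nj_tree(De)
  internal <- tre$edge[, 2] > length(tre$tip.label)
  expect_equal(unname(tre$edge.length[internal]), 0)
  expect_true(all(tre$edge.length >= 0))

  expect_error(nj_tree(matrix(c(0, 1, 1, 0), 2, 2)), "3 taxa")
  Dn <- D4
  Dn[1, 2] <- Dn[2, 1] <- NA
  expect_error(nj_tree(Dn), "undefined")
})

test_that("NJ agrees with the reference implementation on random additive trees", {
  set.seed(61)
  for (i in 1:8) {
    n <- sample(5:9, 1)
    rt <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
    D <- ape::cophenetic.phylo(rt)
    ord <- sort(rownames(D))
    D <- D[ord, ord]
    mine <- nj_tree(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine),
                                           ape::unroot(ref))), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(mine)[ord, ord] - D)), 1e-8)
  }
})

test_that("distance matrices from identical rows give all-zero NJ trees", {
  msa <- setNames(rep("MKWVTFISLL", 4), paste0("s", 1:4))
  D <- poisson_dist(msa)
  expect_true(all(D == 0))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length == 0))
})

test_that("saturated pairs are flagged undefined and rejected", {
  msa <- c(a = "AAAAAAAAAA", b = "CCCCCCCCCC", c = "AAAAACCCCC")
  D <- poisson_dist(msa)
  expect_true(is.na(D["a", "b"]))
  expect_true(attr(D, "undefined")["a", "b"])
  expect_false(attr(D, "undefined")["a", "c"])
  expect_error(nj_tree(D), "undefined")
})

test_that("bootstrap supports are reproducible and match a resampling oracle", {
  # all informative columns agree: support 100
  msa_uni <- four_taxon_msa(40, 20, 0)
  tr <- bootstrap_support(msa_uni, replicates = 200, seed = 3)
  sp <- tree_splits(tr)
  expect_equal(tr$node.label[sp$node - 4L], "100")

  # determinism under a fixed seed
  t1 <- bootstrap_support(msa_uni, replicates = 100, seed = 11)
  t2 <- bootstrap_support(msa_uni, replicates = 100, seed = 11)
  expect_identical(t1$node.label, t2$node.label)

  # contested split: support within binomial sampling error of the
  # independent column-type resampling oracle
  msa_mix <- four_taxon_msa(60, 14, 6)
  tr <- bootstrap_support(msa_mix, replicates = 600, seed = 5)
  sp <- tree_splits(tr)
  got <- as.numeric(tr$node.label[sp$node[sp$key == "C|D"] - 4L])
  oracle <- bootstrap_oracle(60, 14, 6, replicates = 20000, seed = 8)
  expect_lt(abs(got - oracle), 6)

  # supports lie in [0, 100] and are invariant to row order
  perm <- bootstrap_support(msa_uni[c("C", "A", "D", "B")],
                            replicates = 100, seed = 11)
  keys <- tree_splits(perm)$key
  expect_setequal(keys, tree_splits(t1)$key)
  sup <- as.numeric(t1$node.label[t1$node.label != ""])
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("Newick serialization round-trips topology, lengths and supports", {
  tr <- nj_tree(additive_4taxon())
  tr$node.label <- c("", "87")
  txt <- write_newick(tr)
  back <- read_newick(text = txt)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(back),
                                         ape::unroot(tr))), 0)
  ord <- sort(tr$tip.label)
  expect_lt(max(abs(ape::cophenetic.phylo(back)[ord, ord] -
                    ape::cophenetic.phylo(tr)[ord, ord])), 1e-6)
  expect_true("87" %in% back$node.label)

  # display threshold blanks weak supports without touching topology
  tr$node.label <- c("", "42")
  txt50 <- write_newick(tr, min_support = 50)
  expect_false(grepl("42", txt50))

  # file round-trip
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  expect_s3_class(read_newick(path = path), "phylo")

  expect_error(read_newick(text = "(A,B"), "parse")
})
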