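test_that("global alignment is optimal, symmetric and gap-consistent", {
  id <- global_align("ACD", "ACD")
  expect_equal(id$aligned_a, "ACD")
  expect_equal(id$aligned_b, "ACD")

  gap <- global_align("ACD", "AD")
  expect_equal(nchar(gap$aligned_a), 3L)
  expect_equal(sum(strsplit(gap$aligned_b, "")[[1]] == "-"), 1L)
  # degapping recovers the inputs
  expect_equal(gsub("-", "", gap$aligned_a), "ACD")
  expect_equal(gsub("-", "", gap$aligned_b), "AD")

  # score symmetry under the symmetric substitution table
  s1 <- global_align("MKWVTFISLLF", "MKWTFSLLF")$score
  s2 <- global_align("MKWTFSLLF", "MKWVTFISLLF")$score
  expect_equal(s1, s2)

  expect_error(global_align("", "ACD"), "empty")
})

test_that("percent identity counts gap-free columns of the overlap", {
  expect_equal(percent_identity(global_align("ACDEFG", "ACDEFG")), 100)
  expect_equal(
    percent_identity(list(aligned_a = "AAAA", aligned_b = "AAAT")), 75)
  # long query overhanging a short reference: identity on overlap only
  expect_equal(
    percent_identity(list(aligned_a = "WWAAAAWW", aligned_b = "--AAAA--")),
    100)
  expect_error(
    percent_identity(list(aligned_a = "AA--", aligned_b = "--AA")),
    "no comparable")
  # self-identity is always 100
  set.seed(41)
  for (i in 1:5) {
    p <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "W"),
                      sample(10:40, 1), replace = TRUE), collapse = "")
    expect_equal(percent_identity(global_align(p, p)), 100)
  }
})

# a reference with known anchors for the mapping tests
ref <- paste0("MAFTTQVDKL", "QEELDCCPHG", "RSTNNYYAAK", "LMFAP",
              "W", "GHI", "D", "VVKKLLSSTT")  # 50 aa; W at 36, D at 40
spec <- anchor_spec("REF1", "CLASS_II",
                    data.frame(position = c(36L, 40L),
                               residue = c("W", "D"),
                               role = c("trp171", "asp175")))

test_that("anchor mapping reports residues, GAP and ABSENT correctly", {
  # self-mapping of an internal fragment covering the anchors
  frag <- substr(ref, 21, 50)
  hits <- map_anchors(frag, spec, ref)
  expect_equal(hits$query_residue, c("W", "D"))
  expect_true(all(hits$matches_expected))
  expect_equal(hits$query_index, c(16L, 20L))

  # substitution engineered at the Trp anchor column
  sub <- frag
  substr(sub, 16, 16) <- "F"
  hits <- map_anchors(sub, spec, ref)
  expect_equal(hits$query_residue[hits$role == "trp171"], "F")
  expect_false(hits$matches_expected[hits$role == "trp171"])
  expect_true(hits$matches_expected[hits$role == "asp175"])

  # deletion spanning the anchor: GAP, not a match
  del <- paste0(substr(frag, 1, 13), substr(frag, 19, 30))
  hits <- map_anchors(del, spec, ref)
  expect_equal(hits$query_residue[hits$role == "trp171"], "GAP")
  expect_false(hits$matches_expected[hits$role == "trp171"])

  # partial query ending before the anchors: ABSENT
  early <- substr(ref, 1, 25)
  hits <- map_anchors(early, spec, ref)
  expect_true(all(hits$query_residue == "ABSENT"))
  expect_false(any(hits$matches_expected))

  # anchor positions beyond the reference are rejected
  bad <- anchor_spec("REF1", "CLASS_II",
                     data.frame(position = 99L, residue = "W",
                                role = "trp171"))
  expect_error(map_anchors(frag, bad, ref), "beyond reference")
})

test_that("anchor mapping is invariant to unrelated query flanks", {
  frag <- substr(ref, 21, 50)
  base <- map_anchors(frag, spec, ref)
  padded <- paste0("GGGGG", frag)
  hits <- map_anchors(padded, spec, ref)
  expect_equal(hits$query_residue, base$query_residue)
  expect_equal(hits$matches_expected, base$matches_expected)
})

test_that("progressive MSA reduces to pairwise and preserves sequences", {
  two <- progressive_msa(c(x = "ACDEFG", y = "ACEFG"))
  pw <- global_align("ACDEFG", "ACEFG")
  expect_equal(unname(two["x"]), pw$aligned_a)
  expect_equal(unname(two["y"]), pw$aligned_b)

  # identical records align gap-free
  same <- progressive_msa(c(a = "MKWVTF", b = "MKWVTF", c = "MKWVTF",
                            d = "MKWVTF"))
  expect_true(all(!grepl("-", same)))

  # one internal deletion among three records: exactly one gap column
  three <- progressive_msa(c(a = "MKWVTFISLL", b = "MKWVTFSLL",
                             c = "MKWVTFISLL"))
  expect_equal(length(unique(nchar(three))), 1L)
  cols <- do.call(rbind, strsplit(unname(unclass(three)), ""))
  gap_cols <- sum(apply(cols == "-", 2, any))
  expect_equal(gap_cols, 1L)

  # degapping recovers every input
  set.seed(42)
  seqs <- setNames(vapply(1:5, function(i) {
    paste(sample(c("A", "C", "D", "E", "F", "G", "K", "W"),
                 sample(15:25, 1), replace = TRUE), collapse = "")
  }, character(1)), paste0("s", 1:5))
  msa <- progressive_msa(seqs)
  expect_equal(length(unique(nchar(msa))), 1L)
  expect_identical(gsub("-", "", unclass(msa)), unclass(seqs))

  expect_error(progressive_msa(c(a = "ACD")), "two")
})

test_that("best-reference assignment maximizes identity with stable ties", {
  panel <- c(R1 = "MKWVTFISLLFLFSSAYS", R2 = "MKWVTAISLLALFSSAYS",
             R3 = "GGGGGGGGGGGGGGGGGG")
  hit <- assign_best_reference("MKWVTFISLLFLFSSAYS", panel)
  expect_equal(hit$ref_id, "R1")
  expect_equal(hit$identity, 100)

  # panel of one wins regardless of identity
  hit <- assign_best_reference("MKWVTFISLLFLFSSAYS", panel["R3"])
  expect_equal(hit$ref_id, "R3")

  # exact tie (query equidistant between two refs): lexicographic id
  tied <- c(B = "AAAACD", A = "AAAACD")
  expect_equal(assign_best_reference("AAAACD", tied)$ref_id, "A")

  expect_error(assign_best_reference("ACD", character(0)), "empty")
})

test_that("mutated copies are traced back to their generating reference", {
  sim <- generate_pools(sim_config(seed = 77, n_sites = 1,
                                   pool_size = c(CLASS_II = 8L, UPO = 0L,
                                                 DYP = 0L),
                                   decoys_per_site = 0L,
                                   duplicate_rate = 0))
  panel <- sim$panel$proteins[sim$panel$truth$ref_id[
    sim$panel$truth$family == "CLASS_II"]]
  hits <- 0L
  n <- nrow(sim$pools)
  for (i in seq_len(n)) {
    prot <- translate_dna(sim$pools$seq[i])
    best <- assign_best_reference(gsub("\\*$", "", prot), panel)
    if (best$ref_id == sim$truth$source_ref[i]) hits <- hits + 1L
  }
  expect_gte(hits / n, 0.95)
})
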