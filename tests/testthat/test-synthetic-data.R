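test_that("reference panels implant anchors per plan and respect lengths", {
  cfg <- sim_config(seed = 101)
  panel <- make_reference_panel(cfg)
  tr <- panel$truth

  # class II: intended label must agree with the implanted residues
  c2 <- tr[tr$family == "CLASS_II", ]
  spec <- panel$anchors$CLASS_II
  ref_prot <- panel$proteins[[spec$ref_id]]
  for (i in seq_len(nrow(c2))) {
    prot <- panel$proteins[[c2$ref_id[i]]]
    hits <- map_anchors(gsub("\\*$", "", prot), spec,
                        gsub("\\*$", "", ref_prot))
    expect_equal(hits$matches_expected[hits$role == "trp171"],
                 c2$has_trp171[i])
    expect_equal(hits$matches_expected[hits$role == "asp175"],
                 c2$has_asp175[i])
  }
  # no MnP-like reference may carry the catalytic tryptophan
  expect_true(all(!c2$has_trp171[c2$intended_label == "MNP_LIKE"]))

  # UPO partial-protein lengths follow the group windows
  upo <- tr[tr$family == "UPO", ]
  i1 <- upo$length_aa[upo$intended_label == "GROUP_I_1"]
  ii <- upo$length_aa[upo$intended_label == "GROUP_II"]
  expect_true(all(i1 >= 66 & i1 <= 74))
  expect_true(all(ii >= 80 & ii <= 90))

  # DyP lengths inside the published range
  dyp <- tr[tr$family == "DYP", ]
  expect_true(all(dyp$length_aa >= 128 & dyp$length_aa <= 144))

  # translated protein length equals the recorded length
  for (id in tr$ref_id) {
    expect_equal(nchar(gsub("\\*$", "", panel$proteins[[id]])),
                 tr$length_aa[tr$ref_id == id])
  }
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 202, n_sites = 2,
                    pool_size = c(CLASS_II = 5L, UPO = 5L, DYP = 4L))
  s1 <- generate_pools(cfg)
  s2 <- generate_pools(cfg)
  expect_identical(s1$pools, s2$pools)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$panel$nucleotides, s2$panel$nucleotides)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }

  # a different seed changes the pools
  s3 <- generate_pools(sim_config(seed = 203, n_sites = 2,
                                  pool_size = c(CLASS_II = 5L, UPO = 5L,
                                                DYP = 4L)))
  expect_false(identical(s1$pools$seq, s3$pools$seq))
})

test_that("written simulations round-trip through the file formats", {
  sim <- generate_pools(sim_config(seed = 88, n_sites = 1,
                                   pool_size = c(CLASS_II = 2L, UPO = 2L,
                                                 DYP = 2L),
                                   decoys_per_site = 1L))
  d <- withr::local_tempdir()
  write_simulation(sim, d)

  pool <- read_fasta(file.path(d, "site01.fasta"))
  s1 <- sim$pools[sim$pools$site == "site01", ]
  expect_identical(unname(pool[s1$id]), s1$seq)

  refs <- read_fasta(file.path(d, "references_nt.fasta"))
  expect_identical(unname(refs), unname(sim$panel$nucleotides))

  anchors <- read_anchors_yaml(file.path(d, "anchors.yaml"))
  expect_setequal(vapply(anchors, `[[`, "", "family"), c("CLASS_II", "DYP"))
  got <- anchors$CLASS_II_ANCHORREF$anchors
  want <- sim$panel$anchors$CLASS_II$anchors
  expect_equal(unname(got$position), unname(want$position))
  expect_equal(unname(got$residue), unname(want$residue))
  expect_equal(unname(got$role), unname(want$role))

  truth <- read.delim(file.path(d, "truth.tsv"))
  expect_setequal(truth$id, sim$truth$id)
})

test_that("mutation respects rate, preservation and indel framing", {
  s <- random_nt(300, seed = 71)
  expect_equal(mutate_seq(s, 0, 0)$seq, s)

  # preserved positions survive even at rate 1
  keep <- c(1:10, 150:160)
  m <- mutate_seq(s, 1, 0, preserve = keep, seed = 72)
  sc <- strsplit(s, "")[[1]]
  mc <- strsplit(m$seq, "")[[1]]
  expect_identical(mc[keep], sc[keep])
  expect_true(all(mc[-keep] != sc[-keep]))

  # substitution count concentrates around rate * length
  set.seed(73)
  n_sub <- vapply(1:200, function(i) mutate_seq(s, 0.05, 0)$n_sub,
                  numeric(1))
  expect_lt(abs(mean(n_sub) - 0.05 * 300), 2)

  # codon-unit indels keep the frame length divisible by 3
  s3 <- random_nt(300, seed = 74)
  for (i in 1:20) {
    m <- mutate_seq(s3, 0, 1, indel_unit = 3L)
    expect_equal(nchar(m$seq) %% 3L, 0L)
    expect_equal(m$n_indel, 1L)
  }
})

test_that("pools carry complete truth and decoys never amplify", {
  cfg <- sim_config(seed = 303, n_sites = 2, decoys_per_site = 3L,
                    pool_size = c(CLASS_II = 4L, UPO = 4L, DYP = 3L))
  sim <- generate_pools(cfg)
  # exactly one truth row per emitted record
  expect_setequal(sim$truth$id, sim$pools$id)
  expect_equal(anyDuplicated(sim$truth$id), 0L)

  pairs <- peroxidase_primers()
  decoys <- sim$pools[grepl("DECOY", sim$pools$id), ]
  expect_equal(nrow(decoys), 6L)
  for (i in seq_len(nrow(decoys))) {
    for (p in pairs) {
      expect_equal(nrow(amplify(decoys$seq[i], p)), 0L)
    }
  }

  # injected duplicates encode the same protein as their source
  # (exact copies at the DNA level, or synonymous re-encodings)
  dup <- sim$truth[!is.na(sim$truth$duplicate_of), ]
  expect_gt(nrow(dup), 0)
  for (i in seq_len(nrow(dup))) {
    orig <- sim$pools$seq[sim$pools$id == dup$duplicate_of[i]]
    copy <- sim$pools$seq[sim$pools$id == dup$id[i]]
    expect_identical(translate_dna(orig), translate_dna(copy))
  }
})

test_that("cross-site duplicates surface in shared-sequence detection", {
  # high duplicate rate over two sites guarantees cross-site copies
  cfg <- sim_config(seed = 404, n_sites = 2, duplicate_rate = 0.6,
                    mutation_rate = 0, indel_rate = 0,
                    decoys_per_site = 0L,
                    pool_size = c(CLASS_II = 8L, UPO = 0L, DYP = 0L))
  sim <- generate_pools(cfg)
  # with zero noise, records drawn from the same reference at different
  # sites are exact copies; sharing must be detected
  rep <- dereplicate(data.frame(id = sim$pools$id, seq = sim$pools$seq,
                                site = sim$pools$site), "dna")
  sh <- shared_across_sites(rep)
  expect_gt(nrow(sh), 0)
  expect_true(all(sh$n_sites >= 2))
  expect_true(all(grepl(";", sh$sites)))
})
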