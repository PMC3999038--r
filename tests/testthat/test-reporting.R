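test_that("dereplication merges synonymous codons at the protein level", {
  recs <- data.frame(id = c("r1", "r2", "r3"),
                     seq = c("GCT", "GCT", "GCC"),
                     site = c("s1", "s1", "s2"))
  dna <- dereplicate(recs, "dna")
  expect_equal(dna$n_unique, 2L)
  prot <- dereplicate(recs, "protein")   # all encode Ala
  expect_equal(prot$n_unique, 1L)
  expect_equal(prot$clusters$representative, "r1")
  expect_equal(prot$clusters$sites, "s1;s2")

  # all-distinct input: unique == total
  d2 <- dereplicate(data.frame(id = c("a", "b"),
                               seq = c("ATGGAA", "ATGCAA")), "dna")
  expect_equal(d2$n_unique, d2$total)

  expect_error(dereplicate(data.frame(id = character(0),
                                      seq = character(0))), "nrow")
})

test_that("protein-unique never exceeds DNA-unique on synonymous pools", {
  # generator back-translates through random synonymous codons, so exact
  # protein duplicates usually differ at the DNA level
  sim <- generate_pools(sim_config(seed = 13, n_sites = 2,
                                   pool_size = c(CLASS_II = 8L, UPO = 8L,
                                                 DYP = 6L),
                                   mutation_rate = 0, indel_rate = 0,
                                   duplicate_rate = 0.3,
                                   decoys_per_site = 0L))
  recs <- data.frame(id = sim$pools$id, seq = sim$pools$seq,
                     site = sim$pools$site)
  dd <- dedup_summary(recs)
  expect_lte(dd$unique_protein, dd$unique_dna)
  expect_lte(dd$unique_dna, dd$total)
  # the generator injected synonymous duplicates, so the inequality is
  # strict: distinct codon choices, identical proteins
  expect_lt(dd$unique_protein, dd$unique_dna)
})

test_that("cross-site shared clusters are detected", {
  recs <- data.frame(id = c("beech1", "oak1", "beech2", "spruce1"),
                     seq = c("ATGGAA", "ATGGAA", "ATGCAA", "TTGGAA"),
                     site = c("beech-DE", "oak-FR", "beech-DE", "spruce-DE"))
  rep <- dereplicate(recs, "dna")
  sh <- shared_across_sites(rep)
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$sites, "beech-DE;oak-FR")
  expect_equal(sh$n_sites, 2L)

  # all-singleton input: nothing shared
  solo <- dereplicate(recs[3:4, ], "dna")
  expect_equal(nrow(shared_across_sites(solo)), 0L)

  # three-site cluster reported once with three labels
  tri <- data.frame(id = paste0("t", 1:3), seq = "ATGGAA",
                    site = c("a", "b", "c"))
  sh3 <- shared_across_sites(dereplicate(tri, "dna"))
  expect_equal(nrow(sh3), 1L)
  expect_equal(sh3$n_sites, 3L)
})

test_that("richness tables count unique protein types per cell", {
  calls <- data.frame(
    group = c("DyP", "DyP", "UPO", "MnP short/unclassified"),
    forest_type = c("Beech", "Beech", "Beech", "Oak"),
    protein = c("AAA", "AAA", "CCC", "DDD"))  # DyP duplicate collapses
  rt <- richness_table(calls)
  expect_equal(rt["DyP", "Beech"], 1L)
  expect_equal(rt["UPO", "Beech"], 1L)
  expect_equal(rt["MnP short/unclassified", "Oak"], 1L)
  expect_equal(rt["LiP", "Beech"], 0L)
  expect_equal(sum(rt), 3L)

  expect_error(richness_table(data.frame(group = "Martian",
                                         forest_type = "Beech")),
               "unknown peroxidase group")
})

test_that("activity conversion reproduces the dimensional-analysis example", {
  # 0.036 A/min at eps 36000, 1 cm: 1 uM/min in a 1 mL cuvette holding a
  # 50 uL aliquot of a 100 mL extract from 10 g sample -> 200 mU/g DM
  expect_equal(activity_mU_per_gDM(0.036, 36000, dry_matter_fraction = 1),
               200)
  expect_equal(activity_mU_per_gDM(0, 36000, dry_matter_fraction = 1), 0)

  # linear in slope; inverse in epsilon
  a1 <- activity_mU_per_gDM(0.01, 11590, dry_matter_fraction = 1)
  expect_equal(activity_mU_per_gDM(0.02, 11590, dry_matter_fraction = 1),
               2 * a1)
  expect_equal(activity_mU_per_gDM(0.01, 2 * 11590,
                                   dry_matter_fraction = 1), a1 / 2)

  # moisture correction scales the denominator
  expect_equal(activity_mU_per_gDM(0.036, 36000, dry_matter_fraction = 0.5),
               400)

  expect_error(activity_mU_per_gDM(0.01, -5, dry_matter_fraction = 1),
               "positive")
  expect_warning(activity_mU_per_gDM(0.036, 36000), "fresh weight")
})

test_that("MiP subtraction clamps negative differences with a flag", {
  expect_equal(as.numeric(mip_activity(5, 2)), 3)
  expect_equal(as.numeric(mip_activity(2, 2)), 0)
  clamped <- mip_activity(1, 2)
  expect_equal(as.numeric(clamped), 0)
  expect_true(attr(clamped, "clamped"))
  expect_false(attr(mip_activity(5, 2), "clamped"))
  # vectorized over paired measurements
  v <- mip_activity(c(5, 2, 1), c(2, 2, 2))
  expect_equal(as.numeric(v), c(3, 0, 0))
  expect_equal(attr(v, "clamped"), c(FALSE, FALSE, TRUE))
})

test_that("assay CSVs are converted row-wise", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(slope = c(0.036, 0.072), epsilon = 36000,
                       dry_matter_fraction = 1),
            path, row.names = FALSE)
  df <- read_assay_csv(path)
  expect_equal(df$activity_mU_gDM, c(200, 400))
})
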