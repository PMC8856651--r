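test_that("read_vcf decodes GT calls and decomposes multi-allelic sites", {
  gm <- read_vcf(write_tiny_vcf())
  expect_equal(gm$sample_ids, c("S1", "S2", "S3"))
  # site 1: 0/0, 0/1, 1/1
  expect_equal(unname(gm$calls[1, ]), c(0L, 1L, 2L))
  # site 2 (C -> A,T) decomposes into two records at the same position
  expect_equal(sum(gm$variants$pos == 200), 2)
  # S2 is 1/2: one copy of each alt
  expect_equal(unname(gm$calls[gm$variants$alt == "A" & gm$variants$pos == 200, "S2"]), 1L)
  expect_equal(unname(gm$calls[gm$variants$alt == "T" & gm$variants$pos == 200, "S2"]), 1L)
  expect_equal(unname(gm$calls[gm$variants$alt == "T" & gm$variants$pos == 200, "S3"]), 2L)
})

test_that("generator output round-trips through write_vcf / read_vcf", {
  sim <- simulate_family(family_sim_config(n_background_variants = 50, seed = 11))
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$gm, path)
  back <- read_vcf(path)
  expect_equal(length(back$sample_ids), 23)
  expect_equal(unname(back$calls), unname(sim$gm$calls))
  expect_equal(back$variants$pos, sim$gm$variants$pos)
})

test_that("dominant filter retains the causal fixture variant with no violations", {
  ped <- hgf_pedigree()
  gm <- hgf_genotypes()
  v <- dominant_filter(gm, ped)
  causal <- v[variant_keys(gm) == hgf_causal_key(), ]
  expect_true(causal$segregates)
  expect_equal(nrow(causal$violations[[1]]), 0)
  expect_equal(causal$n_affected_carrier, 12)
  expect_equal(causal$n_unaffected_noncarrier, 11)
  expect_equal(causal$n_missing, 0)
})

test_that("decoys co-segregate in the WES subset but fail on the full family", {
  ped <- hgf_pedigree()
  gm <- hgf_genotypes()
  wes <- subset_samples(gm, hgf_wes_samples())
  expect_equal(sum(dominant_filter(wes, ped)$segregates), 3)
  full <- dominant_filter(gm, ped)
  expect_equal(sum(full$segregates), 1)
  # ATP7B-like decoy fails because affected III-4 lacks the alt allele
  atp <- full[full$gene %in% "ATP7B", ]
  expect_false(atp$segregates)
  expect_true("III-4" %in% atp$violations[[1]]$sample_id)
})

test_that("a single het unaffected member is a listed violation", {
  ped <- hgf_pedigree()
  gm <- hgf_genotypes()
  cdadc <- dominant_filter(gm, ped)
  row <- cdadc[cdadc$gene %in% "CDADC1", ]
  expect_false(row$segregates)
  expect_equal(row$violations[[1]]$sample_id, "III-5")
  expect_match(row$violations[[1]]$reason, "unaffected carries")
})

test_that("hom-alt affected members pass the default filter but not het mode", {
  ped <- hgf_pedigree()
  gm <- hgf_genotypes()
  i <- match(hgf_causal_key(), variant_keys(gm))
  gm$calls[i, "II-2"] <- 2L
  v <- dominant_filter(gm, ped)
  expect_true(v$segregates[i])
  expect_equal(v$n_hom_alt_affected[i], 1)
  vh <- dominant_filter(gm, ped, require_het = TRUE)
  expect_false(vh$segregates[i])
  expect_equal(vh$violations[[i]]$sample_id, "II-2")
  expect_match(vh$violations[[i]]$reason, "not heterozygous")
})

test_that("missing calls are compatible by default, rejected in strict mode", {
  ped <- hgf_pedigree()
  gm <- hgf_genotypes()
  i <- match(hgf_causal_key(), variant_keys(gm))
  gm$calls[i, "II-2"] <- NA
  v <- dominant_filter(gm, ped)
  expect_true(v$segregates[i])
  expect_equal(v$n_missing[i], 1)
  vs <- dominant_filter(gm, ped, strict_missing = TRUE)
  expect_false(vs$segregates[i])
})

test_that("dominant filter is invariant to variant and sample permutation", {
  ped <- hgf_pedigree()
  gm <- hgf_genotypes()
  set.seed(42)
  pv <- sample(nrow(gm$variants))
  ps <- sample(gm$sample_ids)
  gm2 <- genotype_matrix(gm$variants[pv, ], ps, gm$calls[pv, ps])
  v1 <- dominant_filter(gm, ped)
  v2 <- dominant_filter(gm2, ped)
  k1 <- paste(v1$chrom, v1$pos, v1$ref, v1$alt)
  k2 <- paste(v2$chrom, v2$pos, v2$ref, v2$alt)
  expect_equal(v2$segregates[match(k1, k2)], v1$segregates)
})

test_that("passing on a sample superset implies passing on any subset", {
  ped <- hgf_pedigree()
  gm <- hgf_genotypes()
  full <- dominant_filter(gm, ped)
  set.seed(7)
  for (i in 1:5) {
    sub <- subset_samples(gm, sample(gm$sample_ids, 12))
    v <- dominant_filter(sub, ped)
    expect_true(all(v$segregates[full$segregates]))
  }
})

test_that("population absence filter enforces per-panel ceilings", {
  ped <- hgf_pedigree()
  gm <- hgf_genotypes()
  v <- dominant_filter(gm, ped)
  # at max_af = 0 on all panels only frequency-0 / unobserved variants stay
  kept <- population_absence_filter(v, gm, max_af = 0)
  expect_true(hgf_causal_key() %in%
                paste(kept$chrom, kept$pos, kept$ref, kept$alt, sep = ":"))
  expect_false(any(kept$gene %in% c("ATP7B", "SOS1"), na.rm = TRUE))
  # the UTR variant has no frequency entries at all: kept and flagged
  utr <- kept[kept$pos == 39250000, ]
  expect_equal(nrow(utr), 1)
  expect_true(utr$pop_unobserved)
  # a permissive ceiling readmits the low-frequency decoy
  kept2 <- population_absence_filter(v, gm, max_af = 0.001)
  expect_true("ATP7B" %in% kept2$gene)
  expect_error(population_absence_filter(v, gm, require_panels = "nope"),
               "unknown panel")
})

test_that("validation concordance detects flipped calls and re-checks segregation", {
  ped <- hgf_pedigree()
  gm <- hgf_genotypes()
  wes <- subset_samples(gm, hgf_wes_samples())
  ok <- validation_concordance(wes, gm, hgf_causal_key(), ped)
  expect_equal(ok$n_discordant, 0)
  expect_true(ok$full_family_segregates)
  flipped <- gm
  i <- match(hgf_causal_key(), variant_keys(gm))
  flipped$calls[i, "II-2"] <- 0L
  bad <- validation_concordance(wes, flipped, hgf_causal_key(), ped)
  expect_equal(bad$discordant_ids, "II-2")
  expect_false(bad$full_family_segregates)
  expect_error(validation_concordance(wes, gm, "chrX:1:A:T", ped), "absent")
})
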