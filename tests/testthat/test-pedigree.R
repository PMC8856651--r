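test_that("read_ped parses a trio and flags structural problems", {
  ped <- read_ped(write_trio_ped())
  expect_s3_class(ped, "famseg_pedigree")
  expect_equal(nrow(ped$individuals), 3)
  kid <- ped$individuals[ped$individuals$id == "KID", ]
  expect_equal(kid$father_id, "DAD")
  expect_equal(kid$affected, "affected")
  expect_false(is.na(kid$mother_id))

  bad <- tempfile(fileext = ".ped")
  writeLines(c("FAM MOM 0 0 2 1", "FAM KID GHOST MOM 1 2"), bad)
  expect_error(read_ped(bad), "unknown parent")

  malformed <- tempfile(fileext = ".ped")
  writeLines(c("FAM A 0 0 1 1", "FAM B 0 0"), malformed)
  expect_error(read_ped(malformed), "line 2")
})

test_that("pedigree invariants reject bad structures", {
  trio <- read_ped(write_trio_ped())$individuals
  dup <- rbind(trio, trio[1, ])
  expect_error(pedigree(dup), "duplicate")
  swapped <- trio
  swapped[swapped$id == "KID", c("father_id", "mother_id")] <- c("MOM", "DAD")
  expect_error(pedigree(swapped), "sex")
})

test_that("read_ped then write_ped round-trips the canonical dialect", {
  ped <- hgf_pedigree()
  out <- tempfile(fileext = ".ped")
  write_ped(ped, out)
  ped2 <- read_ped(out, sidecar = system.file("extdata", "family_hgf_info.tsv",
                                              package = "famseg"))
  expect_identical(ped2$individuals, ped$individuals)
})

test_that("fixture family has the published composition", {
  ped <- hgf_pedigree()
  ind <- ped$individuals
  expect_equal(nrow(ind), 25)
  expect_equal(sum(ind$genotyped), 23)
  expect_equal(sum(ind$alive), 23)
  expect_equal(sum(ind$affected == "affected"), 13)  # incl. deceased founder
  expect_equal(sum(ind$affected == "affected" & ind$genotyped), 12)
})

test_that("obligate carrier inference matches a brute-force closure oracle", {
  ped <- hgf_pedigree()
  ind <- ped$individuals
  # carrier statuses of the genotyped members (from affection, full
  # penetrance) plus the unaffected founder spouse; the affected founder
  # is left unknown and must be forced by closure
  carriers <- stats::setNames(rep(NA, nrow(ind)), ind$id)
  carriers[ind$genotyped] <- ind$affected[ind$genotyped] == "affected"
  carriers["I-2"] <- FALSE
  got <- obligate_carriers(ped, carriers)
  want <- oracle_obligate(ind, carriers)
  expect_setequal(got, want)
  expect_true("I-1" %in% got)  # affected founder forced carrier
  expect_false("I-2" %in% got)

  # fixed point: re-running with inferred carriers added changes nothing
  carriers[got] <- TRUE
  expect_length(obligate_carriers(ped, carriers), 0)
})

test_that("obligate inference handles forced founders and contradictions", {
  ind <- data.frame(
    id = c("F", "M", "C1", "C2"),
    father_id = c(NA, NA, "F", "F"), mother_id = c(NA, NA, "M", "M"),
    sex = c("male", "female", "male", "female"),
    affected = c("unknown", "unaffected", "affected", "affected"),
    alive = c(FALSE, TRUE, TRUE, TRUE),
    genotyped = c(FALSE, TRUE, TRUE, TRUE), stringsAsFactors = FALSE)
  ped <- pedigree(ind)
  carriers <- c(F = NA, M = FALSE, C1 = TRUE, C2 = TRUE)
  expect_setequal(obligate_carriers(ped, carriers), "F")
  # a stated non-carrier forced to carry is an inconsistency
  expect_error(obligate_carriers(ped, c(F = FALSE, M = FALSE, C1 = TRUE,
                                        C2 = TRUE)),
               "inconsistency")
  # all parents genotyped: nothing to infer
  carriers_full <- c(F = TRUE, M = FALSE, C1 = TRUE, C2 = TRUE)
  expect_length(obligate_carriers(ped, carriers_full), 0)
})

test_that("fixture yields exactly 12 informative meioses, cousin child excluded", {
  ped <- hgf_pedigree()
  carriers <- resolve_carriers(ped)
  ms <- informative_meioses(ped, carriers)
  expect_equal(ms$n_informative, 12)
  expect_equal(round(3.6 / log10(2)), 12)  # count implied by the headline LOD
  # IV-5 has two carrier parents (first-cousin marriage): excluded
  expect_true("IV-5" %in% ms$excluded$child_id)
  expect_match(ms$excluded$reason[ms$excluded$child_id == "IV-5"],
               "both parents carriers")
  # the founder's three children are scored through the obligate carrier
  expect_equal(sort(ms$meioses$child_id[ms$meioses$parent_id == "I-1"]),
               c("II-2", "II-3", "II-8"))
})

test_that("informative meiosis count is monotone in added carrier children", {
  ped <- hgf_pedigree()
  carriers <- resolve_carriers(ped)
  base_n <- informative_meioses(ped, carriers)$n_informative
  ind <- ped$individuals
  extra <- data.frame(id = "IV-6", father_id = "III-2", mother_id = "III-1",
                      sex = "male", affected = "affected", alive = TRUE,
                      genotyped = TRUE, generation = 4,
                      stringsAsFactors = FALSE)
  ped2 <- pedigree(rbind(ind, extra), name = ped$name)
  carriers2 <- c(carriers, "IV-6" = TRUE)
  expect_equal(informative_meioses(ped2, carriers2)$n_informative, base_n + 1)
})

test_that("no carriers means no informative meioses", {
  ped <- read_ped(write_trio_ped())
  carriers <- c(DAD = FALSE, MOM = FALSE, KID = FALSE)
  expect_equal(informative_meioses(ped, carriers)$n_informative, 0)
})
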