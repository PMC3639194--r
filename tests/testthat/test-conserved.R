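test_that("family names normalize to the family label", {
  expect_equal(mirna_family(c("ghr-miR156a", "ath-miR156b-5p", "osa-MIR399",
                              "ghr-miR167")),
               c("miR156", "miR156", "miR399", "miR167"))
})

test_that("assign_families follows the two-tier rule", {
  mir167 <- "TGAAGCTGCCAGCATGATCTA"
  mir399 <- "TGCCAAAGGAGAGTTGCCCTG"
  species <- list(mature = c(`ghr-miR167` = mir167))
  allplant <- list(mature = c(`ath-miR167` = mir167, `ath-miR399` = mir399))

  # exact species-tier match
  a <- assign_families(mir167, species, allplant)
  expect_equal(a$family, "miR167")
  expect_equal(a$tier, 1L)

  # 3 substitutions vs nearest mature with max_mismatch = 2 -> unassigned
  mut3 <- mir167
  substr(mut3, 2, 2) <- "C"; substr(mut3, 10, 10) <- "A"; substr(mut3, 20, 20) <- "C"
  stopifnot(sum(strsplit(mut3, "")[[1]] != strsplit(mir167, "")[[1]]) == 3L)
  expect_true(is.na(assign_families(mut3, species, NULL)$family))

  # absent from species tier, exact in all-plant tier -> tier 2
  b <- assign_families(mir399, species, allplant)
  expect_equal(b$family, "miR399")
  expect_equal(b$tier, 2L)

  # tier-1 assignments do not change when tier-2 references change
  a2 <- assign_families(mir167, species,
                        list(mature = c(`ath-miR9999` = mir167)))
  expect_equal(a2$family, "miR167")
  expect_equal(a2$tier, 1L)

  expect_error(assign_families(mir167, list(mature = character())), "empty mature")
})

test_that("mismatch and end-offset tolerances behave as documented", {
  ref <- "TGAAGCTGCCAGCATGATCTA"
  species <- list(mature = c(`ghr-miR167` = ref))
  # 2 substitutions allowed
  mut2 <- ref
  substr(mut2, 3, 3) <- "T"; substr(mut2, 18, 18) <- "C"
  expect_equal(assign_families(mut2, species)$family, "miR167")
  expect_equal(assign_families(mut2, species)$mismatches, 2)
  # 2-nt 5' offset allowed (tag = reference shifted by two)
  shifted <- paste0("GG", substr(ref, 1, nchar(ref) - 2))
  expect_equal(assign_families(shifted, species)$family, "miR167")
  # 3-nt offset is not
  shifted3 <- paste0("GGG", substr(ref, 1, nchar(ref) - 3))
  expect_true(is.na(assign_families(shifted3, species)$family))
  # containment in a precursor assigns the family
  pre <- list(mature = c(`ghr-miR167` = ref),
              precursor = c(`ghr-MIR9001` = paste0(strrep("G", 30),
                                                   "AACCTTGGAACCTTGGAACCT",
                                                   strrep("C", 30))))
  expect_equal(assign_families("AACCTTGGAACCTTGGAACCT", pre)$family, "miR9001")
})

test_that("ties break lexicographically and output is a function of tags", {
  seqA <- "ACGTACGTACGTACGTACGTA"
  species <- list(mature = c(`ghr-miR200` = seqA, `ghr-miR100` = seqA))
  out <- assign_families(seqA, species)
  expect_equal(out$family, "miR100")
  expect_equal(nrow(out), 1L)
})

test_that("family_abundance computes relative abundance and shares", {
  libs <- data.frame(id = c("W1", "M1"), genotype = c("WT", "GMS"),
                     stage = "meiosis", stringsAsFactors = FALSE)
  f1 <- "TGAAGCTGCCAGCATGATCTA"
  f2 <- "TGCCAAAGGAGAGTTGCCCTG"
  tags <- filter_and_collapse(
    list(W1 = data.frame(sequence = c(f1, f2), count = c(30, 70)),
         M1 = data.frame(sequence = c(f1, f2), count = c(60, 40))),
    library_meta = libs)
  asg <- assign_families(tags, list(mature = c(`ghr-miR167` = f1,
                                               `ghr-miR399` = f2)))
  fam <- family_abundance(asg, tags)
  rel <- fam$relative_abundance
  expect_equal(rel$WT[rel$family == "miR167"], 0.30)
  expect_equal(rel$WT[rel$family == "miR399"], 0.70)
  sh <- fam$share_of_total
  # miR167: WT 30 vs GMS 60 of pooled 90
  expect_equal(sh$WT[sh$family == "miR167"], 1 / 3)
  expect_equal(sh$GMS[sh$family == "miR167"], 2 / 3)

  # family absent from one genotype -> relative abundance 0 there
  tags0 <- filter_and_collapse(
    list(W1 = data.frame(sequence = c(f1, f2), count = c(30, 70)),
         M1 = data.frame(sequence = f2, count = 40)),
    library_meta = libs)
  fam0 <- family_abundance(assign_families(tags0,
                                           list(mature = c(`ghr-miR167` = f1,
                                                           `ghr-miR399` = f2))),
                           tags0)
  rel0 <- fam0$relative_abundance
  expect_equal(rel0$GMS[rel0$family == "miR167"], 0)
})

test_that("unique_mirna_sharing is set arithmetic over the pair union", {
  sets <- list(A = c("a", "b", "c"), B = c("c", "d"), E = character())
  sh <- unique_mirna_sharing(sets, c("A", "B"))
  expect_equal(unname(sh), c(50, 25, 25))
  expect_equal(sum(sh), 100)
  expect_equal(unname(unique_mirna_sharing(list(A = "x", B = "x"),
                                           c("A", "B"))["shared"]), 100)
  expect_equal(unname(unique_mirna_sharing(list(A = "x", B = "y"),
                                           c("A", "B"))["shared"]), 0)
  expect_error(unique_mirna_sharing(list(A = character(), B = character()),
                                    c("A", "B")), "both sets are empty")
  expect_error(unique_mirna_sharing(sets, c("A", "Z")), "unknown library")
})
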