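test_that("sim_config validates the stated world", {
  expect_error(sim_config(length_dist = c(`24` = 0.5, `21` = 0.4)), "sum to 1")
  expect_error(sim_config(length_dist = c(`17` = 0.5, `24` = 0.5)), "18-30")
  bad_de <- data.frame(mirna = "x", library_a = "Mar-F-1",
                       library_b = "Mar-S-1", fold_change = -2)
  expect_error(sim_config(de_spec = bad_de), "fold_change")
  libs <- data.frame(id = c("a", "a"), genotype = "WT", stage = "meiosis")
  expect_error(sim_config(libraries = libs), "distinct")
  expect_error(sim_config(n_conserved_mirnas = 20, n_planted_mirnas = 10),
               "exceed")
})

test_that("plant_hairpin builds a canonical precursor around the mature", {
  set.seed(81)
  for (arm in c("5p", "3p")) {
    mat <- rand_seq(21)
    hp <- plant_hairpin(mat, arm)
    # mature verbatim in the stated arm
    expect_equal(substr(hp$precursor, hp$mature_start, hp$mature_end), mat)
    if (arm == "5p") expect_lt(hp$mature_end, hp$star_start)
    else expect_gt(hp$mature_start, hp$star_end)
    # star is the reverse complement of the mature
    expect_equal(substr(hp$precursor, hp$star_start, hp$star_end), revcomp(mat))
    # terminal loop of at least 3 nt between the arms
    gap <- if (arm == "5p") hp$star_start - hp$mature_end - 1L
           else hp$mature_start - hp$star_end - 1L
    expect_gte(gap, 3L)
    # proxy energy comfortably under the acceptance threshold
    expect_lte(fold_rna(hp$precursor)$energy, -18)
  }
  expect_error(plant_hairpin(rand_seq(17)), "18-26")
  expect_error(plant_hairpin(rand_seq(27)), "18-26")
})

test_that("generate_dataset writes a coherent, reproducible dataset", {
  sim <- shared_sim()
  gt <- sim$gt
  expect_true(all(file.exists(gt$files)))

  # every planted mature is a substring of its precursor, inside its transcript
  txs <- read_fasta(gt$files[["transcripts"]])
  pm <- gt$planted_mirnas
  for (i in seq_len(nrow(pm))) {
    expect_true(grepl(pm$mature[i], pm$precursor[i], fixed = TRUE))
    expect_equal(substr(txs[[pm$transcript[i]]], pm$precursor_start[i],
                        pm$precursor_end[i]), pm$precursor[i])
  }
  # every cleavage position is inside its transcript
  tg <- gt$planted_targets
  expect_true(all(tg$cleavage_position >= 1 &
                    tg$cleavage_position <= nchar(txs[tg$transcript])))

  # determinism: a second run is byte-identical
  dir2 <- file.path(tempdir(), "anthersmallrna-sim2")
  gt2 <- generate_dataset(sim$config, dir2)
  for (k in names(gt$files)) {
    expect_identical(readLines(gt2$files[[k]]), readLines(gt$files[[k]]),
                     info = k)
  }
})

test_that("simulated libraries respect the planted composition", {
  sim <- shared_sim()
  gt <- sim$gt
  cfg <- sim$config
  reads <- lapply(setNames(nm = gt$libraries$id), function(id)
    clean_reads(read_fastq_seqs(gt$files[[id]]), cfg$adapter3))
  tags <- filter_and_collapse(reads, library_meta = gt$libraries)

  # conservation: the pooled count of each planted mature's exact tag equals
  # the number of simulated reads assigned to it
  m <- tag_counts(tags)
  for (i in seq_len(nrow(gt$planted_mirnas))) {
    mat <- gt$planted_mirnas$mature[i]
    got <- if (mat %in% rownames(m)) sum(m[mat, ]) else 0
    expect_equal(got, sum(gt$true_counts[gt$planted_mirnas$name[i], ]))
  }

  # pooled modal length is 24 nt
  expect_equal(modal_length(length_histogram(tags)), 24L)

  # structural fraction within 3 binomial standard deviations
  refs <- lapply(setNames(nm = STRUCTURAL_CLASSES), function(cl)
    read_fasta(file.path(sim$dir, paste0("ncrna_", cl, ".fa"))))
  ann <- classify_structural(tags, refs)
  n_struct <- sum(tag_counts(tags)[ann$annotation$category != "unannotated", ])
  n_tot <- sum(tag_libraries(tags)$total_reads)
  p <- cfg$structural_fraction
  expect_lt(abs(n_struct - n_tot * p), 3 * sqrt(n_tot * p * (1 - p)))
})

test_that("the degradome histogram peaks at each planted cleavage site", {
  sim <- shared_sim()
  gt <- sim$gt
  txs <- read_fasta(gt$files[["transcripts"]])
  sig <- map_degradome(read_small_rna(gt$files[["degradome"]]), txs)
  for (i in seq_len(nrow(gt$planted_targets))) {
    tg <- gt$planted_targets[i, ]
    s <- sig[sig$transcript == tg$transcript, ]
    raw <- tapply(s$raw, s$position, sum)
    expect_equal(as.integer(names(raw)[which.max(raw)]), tg$cleavage_position)
    # unique maximum
    expect_equal(sum(raw == max(raw)), 1L)
  }
})
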