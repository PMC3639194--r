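test_that("fold_rna reproduces hand-computed proxy energies", {
  # perfect 30-bp GC stem with a 4-nt loop: 30 pairs x -3
  stem <- paste0(strrep("G", 30), "AAAA", strrep("C", 30))
  f <- fold_rna(stem)
  expect_equal(f$energy, -90)
  expect_equal(nchar(f$structure), nchar(stem))
  # poly-A folds to nothing
  expect_equal(fold_rna(strrep("A", 60))$energy, 0)
  expect_equal(fold_rna(strrep("A", 60))$structure, strrep(".", 60))
  # RNA alphabet input is converted and folds identically
  expect_equal(fold_rna("GGGGGAAAACCCCCUUUUUAAAA"),
               fold_rna("GGGGGAAAACCCCCTTTTTAAAA"))
})

test_that("fold_rna is deterministic and never reports positive energy", {
  set.seed(51)
  for (i in 1:15) {
    s <- rand_seq(sample(50:120, 1))
    f1 <- fold_rna(s)
    expect_identical(f1, fold_rna(s))
    expect_lte(f1$energy, 0)
    # structure and pairs agree
    expect_equal(sum(f1$pairs > 0), sum(strsplit(f1$structure, "")[[1]] != "."))
  }
})

test_that("fold energy is strand-symmetric on wobble-free alphabets", {
  # with the G:U term the pair-energy model is not reverse-complement
  # symmetric in general (a G:U pair maps to the non-pairing A:C); on
  # alphabets that cannot form wobbles the symmetry is exact
  set.seed(56)
  for (alphabet in list(c("A", "T"), c("G", "C"))) {
    for (i in 1:8) {
      s <- rand_seq(sample(50:100, 1), alphabet = alphabet)
      expect_equal(fold_rna(revcomp(s))$energy, fold_rna(s)$energy)
    }
  }
})

test_that("map_tags reports all exact hits on both strands", {
  tag <- "ACGGTTCAACGGTGCAACGTA"
  tx <- c(t1 = paste0(strrep("C", 100), tag, strrep("G", 80)))
  hits <- map_tags(tag, tx)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 101L)
  expect_equal(hits$strand, "+")
  # tag present on both strands -> two hits
  tx2 <- c(t2 = paste0(strrep("C", 20), tag, strrep("A", 10), revcomp(tag)))
  hits2 <- map_tags(tag, tx2)
  expect_equal(nrow(hits2), 2L)
  expect_setequal(hits2$strand, c("+", "-"))
  # near-miss everywhere -> no hits
  mut <- tag; substr(mut, 11, 11) <- "T"
  expect_equal(nrow(map_tags(mut, tx)), 0L)
})

test_that("extract_windows truncates at bounds and drops short windows", {
  tx <- c(t1 = rand_seq(1000))
  hit <- data.frame(tag = substr(tx, 300, 320), transcript = "t1",
                    strand = "+", start = 300L, end = 320L)
  w <- extract_windows(hit, tx)
  expect_equal(nrow(w), 2L)
  expect_equal(w$tx_start[w$arm_hint == "5p"], 280L)
  expect_equal(w$tx_end[w$arm_hint == "5p"], 540L)
  expect_equal(substr(w$window[1], w$mature_start[1],
                      w$mature_start[1] + 20L), hit$tag)
  # hit near the transcript start: upstream-truncated
  hit2 <- data.frame(tag = substr(tx, 5, 25), transcript = "t1",
                     strand = "+", start = 5L, end = 25L)
  w2 <- extract_windows(hit2, tx)
  expect_true(all(w2$tx_start == 1L))
  # a 40-nt transcript yields nothing
  tx3 <- c(t3 = rand_seq(40))
  hit3 <- data.frame(tag = substr(tx3, 10, 30), transcript = "t3",
                     strand = "+", start = 10L, end = 30L)
  expect_equal(nrow(extract_windows(hit3, tx3)), 0L)
})

test_that("planted hairpins round-trip through evaluate_hairpin", {
  set.seed(52)
  for (i in 1:10) {
    L <- sample(18:26, 1)
    mat <- rand_seq(L)
    arm <- sample(c("5p", "3p"), 1)
    hp <- plant_hairpin(mat, arm)
    ev <- evaluate_hairpin(hairpin_window(hp), mat,
                           hairpin_criteria(min_precursor = 40))
    expect_false(is.null(ev))
    expect_true(ev$accepted)
    expect_equal(ev$arm, arm)
    expect_lte(ev$energy, -18)
  }
})

test_that("stated rejection criteria fire", {
  set.seed(53)
  mat <- rand_seq(21)
  hp <- plant_hairpin(mat, "5p")
  # a 'mature' straddling the terminal loop is rejected for spanning it
  loop_mat <- substr(hp$precursor, hp$mature_end - 8L, hp$mature_end + 12L)
  w <- data.frame(window = hp$precursor, mature_start = hp$mature_end - 8L,
                  tx_start = 1, tx_end = nchar(hp$precursor), arm_hint = "5p")
  ev <- evaluate_hairpin(w, loop_mat, hairpin_criteria(min_precursor = 40))
  expect_false(ev$accepted)
  expect_false(ev$not_spanning_loop && ev$mature_in_one_arm)
  # an unstructured window fails on energy
  flat <- paste0(strrep("A", 30), mat, strrep("A", 30))
  ev2 <- evaluate_hairpin(
    data.frame(window = flat, mature_start = 31, tx_start = 1,
               tx_end = nchar(flat), arm_hint = "5p"), mat)
  expect_false(ev2$accepted)
  expect_false(ev2$energy_ok)
  # short matures are rejected upstream by plant_hairpin
  expect_error(plant_hairpin(rand_seq(17)), "18-26")
})

test_that("acceptance is monotone in the energy threshold", {
  set.seed(54)
  cases <- c(
    lapply(1:6, function(i) { # unstructured windows, mostly rejected
      win <- rand_seq(150)
      ms <- sample(1:129, 1)
      data.frame(window = win, mature_start = ms, tx_start = 1, tx_end = 150,
                 arm_hint = "5p", mat = substr(win, ms, ms + 20))
    }),
    lapply(1:6, function(i) { # planted hairpins, accepted at the default
      mat <- rand_seq(21)
      cbind(hairpin_window(plant_hairpin(mat, "5p")), mat = mat)
    }))
  checked <- 0L
  for (thr in c(-60, -40, -25, -18)) {
    crit_tight <- hairpin_criteria(energy_max = thr, min_precursor = 40)
    crit_loose <- hairpin_criteria(energy_max = thr + 10, min_precursor = 40)
    for (cs in cases) {
      a <- evaluate_hairpin(cs, cs$mat, crit_tight)
      b <- evaluate_hairpin(cs, cs$mat, crit_loose)
      if (!is.null(a) && a$accepted) {
        checked <- checked + 1L
        expect_true(b$accepted)
      }
    }
  }
  expect_gte(checked, 4L) # the property was actually exercised
})

test_that("load_novel_table parses the published table and rejects bad input", {
  tab <- load_novel_table(table2_path())
  rec <- tab[tab$name == "Mar-F-3-m0056", ]
  expect_equal(rec$count, 4369)
  expect_equal(rec$sequence, "UCUUGACCUUGUAAGACCUUU")
  expect_equal(rec$fold_energy, -48.30)
  expect_equal(rec$library, "Mar-F-3")

  tmp <- tempfile(fileext = ".tsv")
  df <- utils::read.delim(table2_path(), colClasses = "character",
                          fileEncoding = "UTF-8")
  dup <- rbind(df, df[1, ])
  utils::write.table(dup, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_novel_table(tmp), "duplicated")

  bad <- df; bad$count[3] <- "many"
  utils::write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_novel_table(tmp), "line 4")
})

test_that("find_novel_mirnas recovers a planted precursor from a transcript", {
  set.seed(55)
  mat <- rand_seq(21)
  hp <- plant_hairpin(mat, "5p")
  tx <- c(tx1 = paste0(rand_seq(150), hp$precursor, rand_seq(150)))
  out <- find_novel_mirnas(mat, tx)
  expect_equal(nrow(out), 1L)
  expect_true(out$accepted)
  # the tag table route applies the read-count floor
  tt <- filter_and_collapse(list(A = rep(mat, 3))) # pooled count 3 < 4
  expect_equal(nrow(find_novel_mirnas(tt, tx)), 0L)
})
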