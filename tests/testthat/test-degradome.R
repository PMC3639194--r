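test_that("score_duplex applies the penalty scheme position by position", {
  set.seed(71)
  m <- rand_seq(21)
  expect_equal(score_duplex(m, revcomp(m))$score, 0)
  expect_true(all(score_duplex(m, revcomp(m))$states == "match"))

  # helper: set the target base facing miRNA position k
  face <- function(m, k, base) {
    v <- rev(strsplit(revcomp(m), "")[[1]])
    v[k] <- base
    paste(rev(v), collapse = "")
  }
  # G:U at position 16 (outside the doubled 2-13 region) -> 0.5
  m16 <- paste0(substr(m, 1, 15), "G", substr(m, 17, 21))
  expect_equal(score_duplex(m16, face(m16, 16, "T"))$score, 0.5)
  # mismatch at position 5 (inside the doubled region) -> 2.0
  non_pairing <- c(A = "C", C = "A", G = "A", T = "C")
  seg5 <- face(m, 5, non_pairing[[substr(m, 5, 5)]])
  expect_equal(score_duplex(m, seg5)$score, 2.0)
  # gaps: one-shorter segment costs the gap penalty at its best placement
  g <- score_duplex(m, substr(revcomp(m), 2, 21))
  expect_equal(g$states[g$gap], "gap")
  expect_error(score_duplex(m, substr(revcomp(m), 3, 21)), "shorter")
  expect_error(score_duplex(rand_seq(17), rand_seq(17)), "18-26")
})

test_that("find_candidate_sites finds a perfect site exactly once", {
  set.seed(72)
  m <- rand_seq(21)
  tx <- c(t1 = paste0(rand_seq(200), revcomp(m), rand_seq(200)))
  sites <- find_candidate_sites(m, tx)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$score, 0)
  expect_equal(sites$start, 201L)
  expect_equal(sites$end, 221L)
  # target position paired to miRNA position 10: end - 9
  expect_equal(sites$pos10, 221L - 9L)
  # miRNA with nothing better than the threshold -> empty
  none <- find_candidate_sites(m, c(t2 = strrep("A", 300)), max_score = 4)
  expect_equal(nrow(none), 0L)
})

test_that("tp10m implements the printed normalization formula", {
  expect_equal(tp10m(5, 1e6), 50)
  expect_equal(tp10m(7, 7), 1e7)
  expect_error(tp10m(5, 100, 100), "denominator")
})

test_that("map_degradome aggregates 5'-end signatures with hit numbers", {
  set.seed(73)
  t1 <- rand_seq(400); t2 <- rand_seq(400); t3 <- rand_seq(400)
  shared <- substr(t1, 77, 96) # 20 nt; also spliced into t2 and t3
  substr(t2, 150, 169) <- shared
  substr(t3, 30, 49) <- shared
  txs <- c(t1 = t1, t2 = t2, t3 = t3)
  reads <- data.frame(sequence = c(shared, substr(t1, 200, 220), rand_seq(19)),
                      count = c(4, 2, 9))
  sig <- map_degradome(reads, txs)
  # 19-nt read never maps; multi-mapper credits full count at each locus
  sh <- sig[sig$raw == 4, ]
  expect_equal(nrow(sh), 3L)
  expect_true(all(sh$hit_number == 3L))
  expect_equal(sort(sh$position), c(30L, 77L, 150L))
  uni <- sig[sig$raw == 2, ]
  expect_equal(uni$transcript, "t1")
  expect_equal(uni$position, 200L)
  expect_equal(uni$hit_number, 1L)
  expect_equal(nrow(sig), 4L)
})

test_that("classify_category ranks the site against the transcript", {
  expect_equal(classify_category(100, c(100, rep(10, 5))), 0L)
  expect_equal(classify_category(100, c(100, 100, 10)), 1L)
  expect_equal(classify_category(50, c(100, 50, 2, 2, 2)), 2L)
  expect_equal(classify_category(2, c(100, 50, 2, 2, 2)), 3L)
  expect_equal(classify_category(1, c(100, 50, 1, 7)), 4L)
  expect_error(classify_category(1, numeric()), "no signatures")
  # categories 0-2 are invariant under uniform scaling of raw counts
  raws <- c(80, 40, 6, 3)
  for (k in c(2, 10)) {
    expect_equal(classify_category(80, raws), classify_category(80 * k, raws * k))
    expect_equal(classify_category(40, raws), classify_category(40 * k, raws * k))
  }
})

test_that("call_cleavage requires 5'-end coincidence with position 10/11", {
  set.seed(74)
  m <- rand_seq(21)
  tx <- c(t1 = paste0(rand_seq(100), revcomp(m), rand_seq(100)),
          t2 = paste0(rand_seq(50), revcomp(m), rand_seq(150)))
  sites <- find_candidate_sites(m, tx)
  expect_equal(nrow(sites), 2L)
  p10_t1 <- sites$pos10[sites$transcript == "t1"]
  # signature exactly at the paired-to-10 position on t1, 3 nt downstream on t2
  p10_t2 <- sites$pos10[sites$transcript == "t2"]
  sig <- data.frame(transcript = c("t1", "t2"),
                    position = c(p10_t1, p10_t2 + 3L),
                    length = 20L, raw = c(40, 40), hit_number = 1L)
  calls <- call_cleavage(sites, sig)
  expect_equal(calls$transcript, "t1")
  expect_equal(calls$cleavage_position, p10_t1)
  expect_equal(calls$category, 0L)
  # both transcripts satisfied -> two calls
  sig2 <- data.frame(transcript = c("t1", "t2"),
                     position = c(p10_t1, p10_t2),
                     length = 20L, raw = c(40, 40), hit_number = 1L)
  expect_equal(nrow(call_cleavage(sites, sig2)), 2L)
  # position 11 coincidence also calls, reporting the canonical position
  sig3 <- data.frame(transcript = "t1", position = p10_t1 - 1L,
                     length = 20L, raw = 7, hit_number = 1L)
  c3 <- call_cleavage(sites, sig3)
  expect_equal(c3$matched_mirna_pos[c3$transcript == "t1"], 11L)
  expect_equal(c3$cleavage_position[c3$transcript == "t1"], p10_t1)
})

test_that("summed TP10M equals the scaled mapped fraction", {
  set.seed(75)
  tx <- c(t1 = rand_seq(500))
  reads <- data.frame(
    sequence = vapply(sample(1:480, 30, TRUE), function(a)
      substr(tx, a, a + sample(19:20, 1)), character(1)),
    count = rpois(30, 5) + 1)
  sig <- map_degradome(reads, tx)
  total <- 1e6; struct <- 1234
  s <- tplot_table("t1", sig, total_genome_match = total, structural = struct)
  expect_equal(sum(s$tp10m), 1e7 * sum(sig$raw) / (total - struct),
               tolerance = 1e-6)
})

test_that("tplot_table flags called positions", {
  sig <- data.frame(transcript = "t1", position = c(10L, 50L),
                    length = 20L, raw = c(3, 40), hit_number = 1L)
  calls <- data.frame(mirna = "m", transcript = "t1", cleavage_position = 50L,
                      matched_mirna_pos = 10L, score = 0, raw = 40,
                      tp10m = 1, category = 0L)
  tp <- tplot_table("t1", sig, calls)
  expect_equal(nrow(tp), 2L)
  expect_equal(tp$called, c(FALSE, TRUE))
  expect_equal(nrow(tplot_table("t2", sig)), 0L)
})
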