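# Shared fixtures and independent oracles used across the suite.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A tiny hand-controlled tag table.
make_tag_table <- function(reads = list(
  libA = c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA", "TTTTGGGGCCCCAAAATTTTGGGG"),
  libB = c("ACGTACGTACGTACGTACGTA"))) {
  filter_and_collapse(reads)
}

# Closed-form Pearson chi-square for a 2x2 table (independent of chisq_2x2).
chisq_closed_form <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Independent brute-force duplex-site oracle: enumerates every window of
# widths L-1, L, L+1 and scores it with vectorized R, entirely apart from the
# C++ scanner. Returns (start, width, score) rows with score <= max_score.
brute_force_sites <- function(mirna, tx, max_score = 4) {
  m <- strsplit(mirna, "")[[1]]
  L <- length(m)
  tchars <- strsplit(tx, "")[[1]]
  n <- length(tchars)
  wt <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  pen_pair <- function(mc, tc) { # vectorized over equal-length vectors
    wc <- (mc == "A" & tc == "T") | (mc == "T" & tc == "A") |
      (mc == "G" & tc == "C") | (mc == "C" & tc == "G")
    gu <- (mc == "G" & tc == "T") | (mc == "T" & tc == "G")
    ifelse(wc, 0, ifelse(gu, 0.5, 1))
  }
  out <- list()
  for (w in (L - 1):(L + 1)) {
    if (w > n) next
    starts <- seq_len(n - w + 1L)
    # reversed windows as a matrix: row = window, col = reversed index k,
    # r[k] = tx[start + w - k]
    R <- sapply(seq_len(w), function(k) tchars[starts + w - k])
    if (length(starts) == 1L) R <- matrix(R, nrow = 1)
    if (w == L) {
      sc <- rowSums(sapply(seq_len(L), function(i)
        pen_pair(m[i], R[, i]) * wt[i]))
    } else if (w == L - 1L) {
      per_g <- sapply(seq_len(L), function(g) {
        s <- rep(wt[g], length(starts)) # gap penalty
        for (i in seq_len(L)[-g]) {
          k <- if (i < g) i else i - 1L
          s <- s + pen_pair(m[i], R[, k]) * wt[i]
        }
        s
      })
      sc <- do.call(pmin, as.data.frame(per_g))
    } else {
      per_g <- sapply(seq_len(w), function(g) {
        s <- rep(ifelse(min(g, L) >= 2 & min(g, L) <= 13, 2, 1), length(starts))
        for (i in seq_len(L)) {
          k <- if (i < g) i else i + 1L
          s <- s + pen_pair(m[i], R[, k]) * wt[i]
        }
        s
      })
      sc <- do.call(pmin, as.data.frame(per_g))
    }
    keep <- sc <= max_score
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(start = starts[keep], width = w,
                                            score = sc[keep])
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), width = integer(), score = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$width), , drop = FALSE]
}

# Build a one-row window data.frame for evaluate_hairpin from plant_hairpin
# output.
hairpin_window <- function(hp) {
  data.frame(window = hp$precursor, mature_start = hp$mature_start,
             tx_start = 1L, tx_end = nchar(hp$precursor),
             arm_hint = hp$arm, stringsAsFactors = FALSE)
}

table2_path <- function() {
  system.file("extdata", "table2_novel_mirnas.tsv", package = "anthersmallrna")
}

# One small shared synthetic dataset per test session (generated lazily).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "anthersmallrna-sim")
      cfg <- sim_config(seed = 101, library_depth = 8000L,
                        n_background_tags = 800L, degradome_depth = 8000L)
      cache <<- list(gt = generate_dataset(cfg, dir), dir = dir, config = cfg)
    }
    cache
  }
})
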