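# Degradome (PARE) target identification: miRNA:target duplex scoring,
# candidate-site scanning, signature mapping, TP10M normalization, cleavage
# calling against signature peaks, peak categories, and t-plot tables.

#' Score a miRNA:target duplex
#'
#' Aligns a miRNA (5' to 3') against a target segment (sense strand, 5' to
#' 3') antiparallel and scores the complementarity in penalty units:
#' Watson-Crick pair 0, G:U wobble 0.5, mismatch 1.0, single-nt gap 1.0, with
#' every penalty doubled at miRNA positions 2-13 (counted from the miRNA 5'
#' end). At most one gap is allowed: a segment one nt shorter than the miRNA
#' leaves one miRNA base opposite a gap, one nt longer bulges one target
#' base; the minimum over gap placements is returned.
#'
#' @param mirna miRNA sequence, 18-26 nt.
#' @param target_segment target segment of length `|mirna|` - 1, `|mirna|`,
#'   or `|mirna|` + 1.
#' @return list: `score`, `states` (per miRNA position: "match", "GU",
#'   "mismatch" or "gap"), `gap` (0 = none, else placement index).
#' @export
score_duplex <- function(mirna, target_segment) {
  m <- strsplit(as_dna(mirna), "")[[1]]
  L <- length(m)
  if (L < 18L || L > 26L) stop("miRNA length must be 18-26 nt")
  t <- strsplit(as_dna(target_segment), "")[[1]]
  M <- length(t)
  if (M < L - 1L) stop("target segment shorter than miRNA - 1")
  if (M > L + 1L) stop("target segment longer than miRNA + 1")
  r <- rev(t) # r[k] faces miRNA position k (antiparallel)
  wt <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  state1 <- function(mc, tc) {
    wc <- (mc == "A" & tc == "T") | (mc == "T" & tc == "A") |
      (mc == "G" & tc == "C") | (mc == "C" & tc == "G")
    gu <- (mc == "G" & tc == "T") | (mc == "T" & tc == "G")
    ifelse(wc, "match", ifelse(gu, "GU", "mismatch"))
  }
  pen <- c(match = 0, GU = 0.5, mismatch = 1, gap = 1)
  if (M == L) {
    st <- state1(m, r)
    return(list(score = sum(pen[st] * wt), states = st, gap = 0L))
  }
  if (M == L - 1L) { # one miRNA base opposite a gap
    best <- NULL
    for (g in seq_len(L)) {
      st <- character(L)
      st[g] <- "gap"
      if (g > 1L) st[1:(g - 1L)] <- state1(m[1:(g - 1L)], r[1:(g - 1L)])
      if (g < L) st[(g + 1L):L] <- state1(m[(g + 1L):L], r[g:(L - 1L)])
      sc <- sum(pen[st] * wt)
      if (is.null(best) || sc < best$score) best <- list(score = sc, states = st, gap = g)
    }
    return(best)
  }
  # M == L + 1: one bulged target base (skipped reversed index g)
  best <- NULL
  for (g in seq_len(M)) {
    st <- character(L)
    lo <- min(g - 1L, L)
    if (lo >= 1L) st[1:lo] <- state1(m[1:lo], r[1:lo])
    if (g <= L) st[g:L] <- state1(m[g:L], r[(g + 1L):(L + 1L)])
    wg <- if (min(g, L) >= 2 && min(g, L) <= 13) 2 else 1
    sc <- sum(pen[st] * wt) + pen["gap"] * wg
    if (is.null(best) || sc < best$score) best <- list(score = unname(sc), states = st, gap = g)
  }
  best
}

# Greedy suppression of overlapping alignments on one transcript: order by
# (score, gapless first, start) and drop any alignment overlapping a kept one
# by more than half the miRNA length.
.suppress_overlaps <- function(df, L) {
  if (nrow(df) < 2L) return(df)
  ord <- order(df$score, df$gap_type != 0L, df$start)
  keep <- logical(nrow(df))
  kept_iv <- NULL
  for (i in ord) {
    s <- df$start[i]; e <- df$end[i]
    if (!is.null(kept_iv)) {
      ov <- pmin(e, kept_iv[, 2]) - pmax(s, kept_iv[, 1]) + 1L
      if (any(ov > L / 2)) next
    }
    keep[i] <- TRUE
    kept_iv <- rbind(kept_iv, c(s, e))
  }
  df[sort(which(keep)), , drop = FALSE]
}

#' Find candidate miRNA target sites on transcripts
#'
#' Exhaustively scans every sense-strand window (ungapped plus single-gap
#' variants) of each transcript, keeping alignments with a duplex score at
#' most `max_score` (see [score_duplex()] for the scheme). Overlapping
#' alignments at one locus are collapsed to the best-scoring one unless
#' `suppress = FALSE`.
#'
#' @param mirna miRNA sequence (18-26 nt).
#' @param transcripts named character vector of transcript sequences.
#' @param max_score maximum duplex score (default 4).
#' @param suppress collapse overlapping alignments (default TRUE).
#' @return data.frame sorted by (score, transcript, position): `mirna`,
#'   `transcript`, `start`, `end`, `score`, `gap_type` (0 none, 1 gapped
#'   miRNA base, 2 bulged target base), `gap_pos`, `pos10`, `pos11` (target
#'   positions paired to miRNA positions 10 and 11; 0 when gapped out).
#' @export
find_candidate_sites <- function(mirna, transcripts, max_score = 4,
                                 suppress = TRUE) {
  mirna <- as_dna(mirna)
  L <- nchar(mirna)
  if (L < 18L || L > 26L) stop("miRNA length must be 18-26 nt")
  transcripts <- as_dna(transcripts)
  if (is.null(names(transcripts))) names(transcripts) <- paste0("tx", seq_along(transcripts))
  out <- lapply(names(transcripts), function(id) {
    df <- .scan_duplex_cpp(mirna, transcripts[[id]], max_score)
    if (nrow(df) == 0L) return(NULL)
    if (suppress) df <- .suppress_overlaps(df, L)
    if (nrow(df) == 0L) return(NULL)
    cbind(data.frame(mirna = mirna, transcript = id, stringsAsFactors = FALSE), df)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(mirna = character(), transcript = character(),
                      start = integer(), end = integer(), width = integer(),
                      score = numeric(), gap_type = integer(),
                      gap_pos = integer(), pos10 = integer(), pos11 = integer(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$score, out$transcript, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map degradome reads to transcripts
#'
#' Keeps reads of 20-21 nt, maps them by exact sense-strand matching, and
#' aggregates 5'-end signatures. Multi-mapping reads credit their full raw
#' count at every locus; the number of transcripts hit by the read is
#' recorded as `hit_number`.
#'
#' @param reads data.frame with `sequence` and `count` (see
#'   [read_small_rna()]) or a character vector of read sequences.
#' @param transcripts named character vector of transcripts.
#' @param read_lengths admissible read lengths (default `c(20, 21)`).
#' @return data.frame of signatures: `transcript`, `position` (1-based
#'   5'-end), `length`, `raw`, `hit_number`.
#' @export
map_degradome <- function(reads, transcripts, read_lengths = c(20L, 21L)) {
  if (!is.data.frame(reads)) reads <- data.frame(sequence = as_dna(reads), count = 1)
  reads$sequence <- as_dna(reads$sequence)
  dt <- data.table::data.table(sequence = reads$sequence, count = reads$count)
  dt <- dt[, list(count = sum(count)), by = "sequence"]
  dt <- dt[nchar(sequence) %in% read_lengths]
  transcripts <- as_dna(transcripts)
  if (is.null(names(transcripts))) names(transcripts) <- paste0("tx", seq_along(transcripts))
  rows <- vector("list", nrow(dt))
  for (i in seq_len(nrow(dt))) {
    sq <- dt$sequence[i]
    hits <- lapply(names(transcripts), function(id) {
      st <- gregexpr(sq, transcripts[[id]], fixed = TRUE)[[1]]
      if (st[1] == -1L) return(NULL)
      data.frame(transcript = id, position = as.integer(st),
                 stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
    if (is.null(hits)) next
    hits$length <- nchar(sq)
    hits$raw <- dt$count[i]
    hits$hit_number <- length(unique(hits$transcript))
    rows[[i]] <- hits
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(transcript = character(), position = integer(),
                      length = integer(), raw = numeric(),
                      hit_number = integer(), stringsAsFactors = FALSE))
  }
  agg <- data.table::as.data.table(out)[, list(raw = sum(raw),
                                               hit_number = max(hit_number)),
                                        by = c("transcript", "position", "length")]
  data.table::setorder(agg, transcript, position, length)
  as.data.frame(agg)
}

#' TP10M normalization
#'
#' Tags per ten million: `raw / (total_genome_match - structural) * 1e7`,
#' where `structural` is the count of reads annotated as
#' t/r/sn/snoRNA among the genome-matched total.
#'
#' @param raw raw signature abundance(s).
#' @param total_genome_match total genome-matched reads.
#' @param structural structural-RNA read count (default 0).
#' @return normalized abundance(s).
#' @export
tp10m <- function(raw, total_genome_match, structural = 0) {
  denom <- total_genome_match - structural
  if (denom <= 0) stop("TP10M denominator not positive (total <= structural)")
  raw / denom * 1e7
}

#' Classify a cleavage-site signature by its rank on the transcript
#'
#' Category 0: the site abundance is the unique maximum over all signature
#' positions of the transcript; 1: equal to a shared maximum; 2: below the
#' maximum but above the median; 3: at or below the median with raw > 1;
#' 4: a singleton read (raw == 1). The median is taken over positions with at
#' least one signature.
#'
#' @param site_raw raw abundance at the candidate site.
#' @param transcript_raws raw abundances of all signature positions on the
#'   transcript (including the site).
#' @return integer category 0-4.
#' @export
classify_category <- function(site_raw, transcript_raws) {
  if (!length(transcript_raws)) stop("transcript has no signatures")
  if (site_raw == 1) return(4L)
  mx <- max(transcript_raws)
  med <- stats::median(transcript_raws)
  if (site_raw >= mx) {
    if (sum(transcript_raws == mx) == 1L) return(0L)
    return(1L)
  }
  if (site_raw > med) return(2L)
  3L
}

#' Call miRNA cleavage events from candidate sites and degradome signatures
#'
#' A candidate duplex site yields a cleavage call when a degradome signature
#' 5' end falls exactly on the target nucleotide paired to miRNA position 10
#' (canonical slicing between positions 10 and 11) or position 11. The
#' canonical paired-to-10 position is reported as the cleavage position (the
#' first nucleotide of the 3' cleavage fragment). Calls are sorted by
#' (category, descending TP10M).
#'
#' @param sites output of [find_candidate_sites()] (rbind-able across
#'   miRNAs).
#' @param signatures output of [map_degradome()].
#' @param total_genome_match,structural TP10M denominator inputs; defaults
#'   to the summed signature raw counts and 0.
#' @return data.frame: `mirna`, `transcript`, `cleavage_position`,
#'   `matched_mirna_pos` (10 or 11), `score`, `raw`, `tp10m`, `category`.
#' @export
call_cleavage <- function(sites, signatures, total_genome_match = NULL,
                          structural = 0) {
  if (is.null(total_genome_match)) total_genome_match <- sum(signatures$raw)
  sig_by_tx <- split(signatures, signatures$transcript)
  # collapse signature lengths: abundance per (transcript, position)
  pos_raw <- lapply(sig_by_tx, function(s) {
    tapply(s$raw, s$position, sum)
  })
  calls <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    tx <- sites$transcript[i]
    pr <- pos_raw[[tx]]
    if (is.null(pr)) next
    hit_pos <- NA_integer_; matched <- NA_integer_
    p10 <- sites$pos10[i]; p11 <- sites$pos11[i]
    if (p10 > 0 && as.character(p10) %in% names(pr)) {
      hit_pos <- p10; matched <- 10L
    } else if (p11 > 0 && as.character(p11) %in% names(pr)) {
      hit_pos <- p11; matched <- 11L
    }
    if (is.na(hit_pos)) next
    raw <- unname(pr[as.character(hit_pos)])
    cleavage <- if (p10 > 0) p10 else hit_pos
    calls[[i]] <- data.frame(
      mirna = sites$mirna[i], transcript = tx, cleavage_position = cleavage,
      matched_mirna_pos = matched, score = sites$score[i], raw = raw,
      tp10m = tp10m(raw, total_genome_match, structural),
      category = classify_category(raw, as.numeric(pr)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(mirna = character(), transcript = character(),
                      cleavage_position = integer(),
                      matched_mirna_pos = integer(), score = numeric(),
                      raw = numeric(), tp10m = numeric(), category = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$category, -out$tp10m, out$transcript,
                   out$cleavage_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-transcript t-plot table
#'
#' The degradome signature abundance of one transcript as a function of
#' position, with cleavage-call positions flagged - the tabular form of a
#' target plot.
#'
#' @param transcript transcript id.
#' @param signatures output of [map_degradome()].
#' @param calls output of [call_cleavage()] (optional).
#' @param total_genome_match,structural TP10M denominator inputs; defaults
#'   to the summed signature raw counts and 0.
#' @return data.frame: `position`, `raw`, `tp10m`, `called` (logical).
#' @export
tplot_table <- function(transcript, signatures, calls = NULL,
                        total_genome_match = NULL, structural = 0) {
  if (is.null(total_genome_match)) total_genome_match <- sum(signatures$raw)
  s <- signatures[signatures$transcript == transcript, , drop = FALSE]
  if (nrow(s) == 0L) {
    return(data.frame(position = integer(), raw = numeric(), tp10m = numeric(),
                      called = logical()))
  }
  raw <- tapply(s$raw, s$position, sum)
  pos <- as.integer(names(raw))
  called <- rep(FALSE, length(pos))
  if (!is.null(calls) && nrow(calls)) {
    cp <- calls$cleavage_position[calls$transcript == transcript]
    called <- pos %in% cp
  }
  out <- data.frame(position = pos, raw = as.numeric(raw),
                    tp10m = tp10m(as.numeric(raw), total_genome_match, structural),
                    called = called)
  out[order(out$position), , drop = FALSE]
}
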