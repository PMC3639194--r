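# Novel miRNA discovery: exact transcript mapping, precursor window
# extraction, secondary-structure folding under a stacking-energy proxy, and
# hairpin/duplex/energy acceptance criteria.

#' Default hairpin acceptance criteria
#'
#' @param energy_max maximal (most positive) allowed fold energy, kcal/mol.
#'   The default -18 is consistent with the weakest fold energies reported
#'   for accepted plant miRNA precursors; configurable.
#' @param max_unpaired_mature maximum unpaired mature bases in the
#'   mature:star duplex (default 4).
#' @param max_bulge maximum asymmetric bulge within the duplex, nt (default 2).
#' @param min_precursor,max_precursor precursor length bounds (50-300 nt).
#' @param min_count read-count floor for calling a novel miRNA (default 4).
#' @return criteria list.
#' @export
hairpin_criteria <- function(energy_max = -18, max_unpaired_mature = 4L,
                             max_bulge = 2L, min_precursor = 50L,
                             max_precursor = 300L, min_count = 4L) {
  list(energy_max = energy_max, max_unpaired_mature = max_unpaired_mature,
       max_bulge = max_bulge, min_precursor = min_precursor,
       max_precursor = max_precursor, min_count = min_count)
}

#' Fold an RNA/DNA sequence under the stacking-energy proxy
#'
#' Maximum-weight pseudoknot-free pairing (weighted Nussinov dynamic
#' program): GC/CG pairs contribute -3, AU/UA -2, GU/UG -1 kcal/mol; hairpin
#' loops enclose at least 3 nt; there are no loop or penalty terms. This is a
#' deliberate proxy, not a thermodynamic model; an external folding backend
#' can be substituted behind the same contract via `backend`.
#'
#' @param sequence a single sequence (DNA or RNA alphabet).
#' @param backend a function `(sequence) -> list(structure=, energy=)`
#'   replacing the built-in proxy, or NULL for the proxy.
#' @return list with `structure` (dot-bracket), `energy` (kcal/mol, <= 0 for
#'   the proxy) and `pairs` (1-based partner index per position, 0 =
#'   unpaired; proxy backend only).
#' @export
fold_rna <- function(sequence, backend = NULL) {
  seq <- as_dna(sequence)
  if (!is.null(backend)) {
    out <- backend(sequence)
    if (is.null(out$pairs)) out$pairs <- .pairs_from_dotbracket(out$structure)
    return(out)
  }
  .fold_proxy_cpp(seq)
}

.pairs_from_dotbracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  pairs <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j; pairs[j] <- i
    }
  }
  pairs
}

#' Map tags to transcripts by exact matching
#'
#' Reports every exact occurrence of each tag on either strand of each
#' transcript, with 1-based inclusive start coordinates on the sense strand.
#'
#' @param tag_sequences character vector of tag sequences.
#' @param transcripts named character vector of transcript sequences.
#' @return data.frame: `tag`, `transcript`, `strand` ("+"/"-"), `start`,
#'   `end`.
#' @export
map_tags <- function(tag_sequences, transcripts) {
  tag_sequences <- as_dna(tag_sequences)
  transcripts <- as_dna(transcripts)
  if (is.null(names(transcripts))) names(transcripts) <- paste0("tx", seq_along(transcripts))
  hits <- vector("list", 2L * length(tag_sequences))
  k <- 0L
  for (i in seq_along(tag_sequences)) {
    tg <- tag_sequences[i]
    for (str in c("+", "-")) {
      probe <- if (str == "+") tg else revcomp(tg)
      for (tx in names(transcripts)) {
        st <- gregexpr(probe, transcripts[[tx]], fixed = TRUE)[[1]]
        if (st[1] == -1L) next
        k <- k + 1L
        hits[[k]] <- data.frame(tag = tg, transcript = tx, strand = str,
                                start = as.integer(st),
                                end = as.integer(st) + nchar(tg) - 1L,
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) {
    return(data.frame(tag = character(), transcript = character(),
                      strand = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Extract candidate precursor windows around a mapped tag
#'
#' Two windows per hit: one with the mature near the window 5' end
#' (`up` nt upstream, `down` nt downstream) and the mirror arrangement.
#' Windows are truncated at transcript bounds; windows shorter than
#' `min_len` nt are dropped. For minus-strand hits the window is reported in
#' the orientation of the mapped tag (reverse complement of the sense
#' strand).
#'
#' @param hit one row of [map_tags()] output (or a list with the same
#'   fields).
#' @param transcripts named character vector of transcripts.
#' @param up,down flank sizes in nt (defaults 20 and 220).
#' @param min_len minimum window length (default 50).
#' @return data.frame: `window` (sequence), `mature_start` (1-based offset of
#'   the tag within the window), `tx_start`, `tx_end`, `arm_hint`.
#' @export
extract_windows <- function(hit, transcripts, up = 20L, down = 220L,
                            min_len = 50L) {
  tx <- as_dna(transcripts[[hit$transcript]])
  n <- nchar(tx)
  L <- hit$end - hit$start + 1L
  mk <- function(a, b) {
    a <- max(1L, a); b <- min(n, b)
    if (b - a + 1L < min_len) return(NULL)
    w <- substr(tx, a, b)
    ms <- hit$start - a + 1L
    if (hit$strand == "-") {
      w <- revcomp(w)
      ms <- b - hit$end + 1L
    }
    data.frame(window = w, mature_start = ms, tx_start = a, tx_end = b,
               stringsAsFactors = FALSE)
  }
  if (hit$strand == "+") {
    w5 <- mk(hit$start - up, hit$end + down)   # mature near 5' end
    w3 <- mk(hit$start - down, hit$end + up)   # mature near 3' end
  } else {
    w5 <- mk(hit$start - down, hit$end + up)
    w3 <- mk(hit$start - up, hit$end + down)
  }
  out <- rbind(if (!is.null(w5)) cbind(w5, arm_hint = "5p"),
               if (!is.null(w3)) cbind(w3, arm_hint = "3p"))
  if (is.null(out)) {
    out <- data.frame(window = character(), mature_start = integer(),
                      tx_start = integer(), tx_end = integer(),
                      arm_hint = character(), stringsAsFactors = FALSE)
  }
  out
}

# Duplex geometry from a folded window: given the fold pair vector and the
# mature interval, derive arm, star interval (2-nt 3' overhang rule) and the
# duplex quality flags.
.duplex_flags <- function(pairs, m1, m2, criteria) {
  n <- length(pairs)
  idx <- m1:m2
  p <- pairs[idx]
  paired <- p > 0L
  flags <- c(mature_in_one_arm = FALSE, not_spanning_loop = FALSE,
             duplex_ok = FALSE)
  arm <- NA_character_
  star <- c(NA_integer_, NA_integer_)
  if (!any(paired)) return(list(flags = flags, arm = arm, star = star))
  partners <- p[paired]
  internal <- partners >= m1 & partners <= m2
  flags["not_spanning_loop"] <- !any(internal)
  if (all(partners > m2)) arm <- "5p" else if (all(partners < m1)) arm <- "3p"
  flags["mature_in_one_arm"] <- !is.na(arm) && !any(internal)
  if (!flags["mature_in_one_arm"]) return(list(flags = flags, arm = arm, star = star))
  L <- m2 - m1 + 1L
  # The mature:star duplex is read off the fold starting from the
  # loop-distal mature end (m1 for a 5p mature, m2 for 3p) and extended pair
  # by pair while the pairing stays nested and each step's bulge asymmetry
  # is within bounds. Pairs beyond the cut - e.g. loop-proximal mature bases
  # folding back into the terminal loop - are not duplex pairs and their
  # mature bases count as unpaired.
  mp <- idx[paired]
  ord <- if (arm == "5p") mp else rev(mp)
  ndup <- 1L
  if (length(ord) > 1L) {
    for (k in 2L:length(ord)) {
      dm <- abs(ord[k] - ord[k - 1L])
      dp <- pairs[ord[k - 1L]] - pairs[ord[k]]
      if (arm == "3p") dp <- -dp
      if (dp <= 0L || abs(dm - dp) > criteria$max_bulge) break
      ndup <- k
    }
  }
  duplex <- ord[seq_len(ndup)]
  n_unpaired <- L - ndup
  flags["duplex_ok"] <- n_unpaired <= criteria$max_unpaired_mature
  pr <- range(pairs[duplex])
  star <- if (arm == "5p") c(pr[1], min(n, pr[2] + 2L)) else
    c(max(1L, pr[1] - 2L), pr[2])
  list(flags = flags, arm = arm, star = star)
}

#' Evaluate candidate precursor windows for one tag
#'
#' Folds each window and applies the acceptance criteria: (a) the mature must
#' lie wholly within one arm without spanning the terminal loop; (b) the
#' mature:star duplex (star defined by the 2-nt 3' overhang of Dicer
#' geometry) must leave at most `max_unpaired_mature` mature bases unpaired
#' with at most `max_bulge` nt of asymmetric bulge; (c) fold energy at most
#' `energy_max`. The best (lowest-energy) accepted window is retained.
#'
#' @param windows output of [extract_windows()] (possibly rbind-ed across
#'   hits).
#' @param tag the mature tag sequence.
#' @param criteria see [hairpin_criteria()].
#' @param backend optional folding backend passed to [fold_rna()].
#' @return a one-row data.frame (hairpin candidate) with the window, its
#'   structure, energy, arm, star coordinates, per-criterion flags and
#'   `accepted`; rejected candidates report the best-energy window. NULL when
#'   no window satisfies the precursor length bounds.
#' @export
evaluate_hairpin <- function(windows, tag, criteria = hairpin_criteria(),
                             backend = NULL) {
  tag <- as_dna(tag)
  if (nrow(windows) == 0L) return(NULL)
  len <- nchar(windows$window)
  windows <- windows[len >= criteria$min_precursor & len <= criteria$max_precursor, ,
                     drop = FALSE]
  if (nrow(windows) == 0L) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(windows))) {
    w <- windows$window[i]
    m1 <- windows$mature_start[i]
    m2 <- m1 + nchar(tag) - 1L
    if (substr(w, m1, m2) != tag) next
    f <- fold_rna(w, backend = backend)
    d <- .duplex_flags(f$pairs, m1, m2, criteria)
    flags <- c(d$flags, energy_ok = f$energy <= criteria$energy_max)
    cand <- data.frame(
      tag = tag, precursor = w, structure = f$structure, energy = f$energy,
      mature_start = m1, mature_end = m2,
      arm = d$arm, star_start = d$star[1], star_end = d$star[2],
      mature_in_one_arm = unname(flags["mature_in_one_arm"]),
      not_spanning_loop = unname(flags["not_spanning_loop"]),
      duplex_ok = unname(flags["duplex_ok"]),
      energy_ok = unname(flags["energy_ok"]),
      accepted = all(flags),
      tx_start = windows$tx_start[i], tx_end = windows$tx_end[i],
      stringsAsFactors = FALSE)
    if (is.null(best)) best <- cand
    else if (cand$accepted && !best$accepted) best <- cand
    else if (cand$accepted == best$accepted && cand$energy < best$energy) best <- cand
  }
  best
}

#' Call novel miRNAs from unannotated tags
#'
#' Maps tags to transcripts, extracts precursor windows, folds and evaluates
#' them, and returns accepted hairpin candidates. Tags whose pooled count is
#' below `criteria$min_count` are not considered.
#'
#' @param tags tag table of unannotated tags (or character vector; then no
#'   count floor applies).
#' @param transcripts named character vector of transcript sequences.
#' @param criteria see [hairpin_criteria()].
#' @param up,down window flanks (see [extract_windows()]).
#' @param backend optional folding backend.
#' @return data.frame of evaluated candidates (one best window per tag),
#'   with an `accepted` column.
#' @export
find_novel_mirnas <- function(tags, transcripts, criteria = hairpin_criteria(),
                              up = 20L, down = 220L, backend = NULL) {
  if (is.data.frame(tags)) {
    pooled <- rowSums(tag_counts(tags))
    seqs <- tags$sequence[pooled >= criteria$min_count]
  } else {
    seqs <- as_dna(tags)
  }
  out <- vector("list", length(seqs))
  if (length(seqs)) {
    hits <- map_tags(seqs, transcripts)
    for (i in seq_along(seqs)) {
      h <- hits[hits$tag == seqs[i], , drop = FALSE]
      if (nrow(h) == 0L) next
      wins <- do.call(rbind, lapply(seq_len(nrow(h)), function(j)
        extract_windows(h[j, ], transcripts, up = up, down = down,
                        min_len = criteria$min_precursor)))
      cand <- evaluate_hairpin(wins, seqs[i], criteria, backend = backend)
      out[[i]] <- cand
    }
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- evaluate_hairpin(
      data.frame(window = paste(rep("A", 60), collapse = ""), mature_start = 1,
                 tx_start = 1, tx_end = 60, arm_hint = "5p",
                 stringsAsFactors = FALSE),
      paste(rep("A", 21), collapse = ""))[0, ]
  }
  rownames(out) <- NULL
  out
}

#' Load a published novel-miRNA table
#'
#' Reads a TSV with columns `name`, `count`, `sequence`, `fold_energy`
#' (RNA alphabet; a leading Unicode minus in the energy column is accepted).
#' The library of each record is inferred from its name prefix
#' (`Mar-F-1-m0001` belongs to `Mar-F-1`). Duplicate names are rejected.
#'
#' @param path TSV path.
#' @return data.frame: `name`, `library`, `count`, `sequence` (RNA),
#'   `fold_energy`.
#' @export
load_novel_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  need <- c("name", "count", "sequence", "fold_energy")
  if (!all(need %in% names(raw))) {
    stop("novel-miRNA table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(raw$name)) {
    stop("duplicated novel-miRNA name(s): ",
         paste(unique(raw$name[duplicated(raw$name)]), collapse = ", "))
  }
  count <- suppressWarnings(as.numeric(raw$count))
  energy <- suppressWarnings(as.numeric(gsub("−", "-", raw$fold_energy)))
  bad <- which(is.na(count) | is.na(energy) |
                 grepl("[^ACGUacgu]", raw$sequence) | !nzchar(raw$name))
  if (length(bad)) {
    stop("malformed novel-miRNA table row(s): line ",
         paste(bad + 1L, collapse = ", "))
  }
  lib <- sub("-m[0-9]+$", "", raw$name)
  if (any(lib == raw$name)) {
    stop("cannot infer library from name(s): ",
         paste(raw$name[lib == raw$name], collapse = ", "))
  }
  data.frame(name = raw$name, library = lib, count = count,
             sequence = toupper(raw$sequence), fold_energy = energy,
             stringsAsFactors = FALSE)
}
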