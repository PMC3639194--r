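#' @useDynLib anthersmallrna, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats chisq.test fisher.test median p.adjust runif setNames
#' @importFrom utils read.delim write.table
NULL

# Sequences are held internally as DNA over ACGTN; RNA input (U) is converted
# on entry and written back as-is on output where the field convention is RNA
# (mature miRNA tables).

#' Convert a nucleotide string to the internal DNA alphabet
#'
#' Uppercases and replaces U with T. Characters outside ACGTN are rejected.
#'
#' @param x character vector of nucleotide sequences (DNA or RNA).
#' @return character vector over ACGTN.
#' @export
as_dna <- function(x) {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(utils::head(which(bad), 3L), collapse = ", "))
  }
  x
}

#' Convert internal DNA representation to RNA (T -> U)
#' @param x character vector over ACGTN.
#' @return character vector with T replaced by U.
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

#' Reverse complement of DNA sequences
#' @param x character vector over ACGTN.
#' @return reverse complements as a character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Deterministic random DNA of given lengths under the current RNG stream.
random_dna <- function(n_lengths, base_probs = c(A = .3, C = .2, G = .2, T = .3)) {
  vapply(n_lengths, function(L) {
    paste(sample(names(base_probs), L, replace = TRUE, prob = base_probs),
          collapse = "")
  }, character(1))
}

#' Dinucleotide-preserving shuffle
#'
#' Shuffles a sequence while preserving its exact dinucleotide composition
#' (Altschul-Erickson style: shuffle the multigraph of base transitions and
#' rebuild by a random Eulerian walk). Used to build decoy precursor windows
#' whose local composition matches real ones.
#'
#' @param x a single sequence (character scalar).
#' @return a shuffled sequence with identical dinucleotide counts.
#' @export
dinuc_shuffle <- function(x, max_tries = 1000L) {
  s <- strsplit(as_dna(x), "")[[1]]
  n <- length(s)
  if (n < 3L) return(paste(s, collapse = ""))
  for (try in seq_len(max_tries)) {
    # successor multilists per base, randomly permuted, then a walk from the
    # original start; a walk that strands edges is rejected and re-drawn
    edges <- lapply(split(s[-1L], s[-n]), sample)
    ptr <- lapply(edges, function(e) 1L)
    out <- character(n)
    out[1L] <- cur <- s[1L]
    ok <- TRUE
    for (i in 2L:n) {
      e <- edges[[cur]]
      k <- ptr[[cur]]
      if (k > length(e)) { ok <- FALSE; break }
      ptr[[cur]] <- k + 1L
      out[i] <- cur <- e[k]
    }
    if (ok) return(paste(out, collapse = ""))
  }
  stop("dinucleotide shuffle failed to find an Eulerian walk")
}

# --- FASTA / FASTQ I/O -------------------------------------------------------

#' Read sequences from FASTA or FASTQ
#'
#' FASTQ records carry count 1 each. For FASTA, a numeric token in the header
#' description (e.g. ">t0001 17") is taken as a read count (collapsed
#' dialect); absent that, count 1.
#'
#' @param path file path (.fa/.fasta/.fq/.fastq).
#' @return data.frame with columns `sequence` (DNA) and `count`.
#' @export
read_small_rna <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  ss <- Biostrings::readBStringSet(path, format = fmt)
  counts <- rep(1, length(ss))
  if (fmt == "fasta") {
    desc <- names(ss)
    tok <- regmatches(desc, regexpr("(?<=\\s)\\d+(\\.\\d+)?$", desc, perl = TRUE))
    has <- grepl("\\s\\d+(\\.\\d+)?$", desc)
    counts[has] <- as.numeric(tok)
  }
  data.frame(sequence = as_dna(as.character(ss)), count = counts,
             stringsAsFactors = FALSE)
}

#' Read a FASTA file into a named character vector of DNA sequences
#' @param path FASTA path.
#' @return named character vector (names = first header token).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path, format = "fasta") # DNA or RNA alphabet
  out <- as_dna(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character vector as FASTA
#' @param x named character vector of sequences.
#' @param path output path.
#' @param rna write in RNA alphabet (T as U)? Default FALSE.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(x, path, rna = FALSE) {
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  seqs <- if (rna) as_rna(x) else x
  con <- file(path, "wb") # fixed \n endings => byte-identical across platforms
  on.exit(close(con))
  writeLines(paste0(">", names(x), "\n", seqs), con)
  invisible(path)
}

# 4-line FASTQ with constant maximal quality (I = Q40); deterministic bytes.
write_fastq <- function(sequences, ids, path) {
  qual <- vapply(nchar(sequences), function(L)
    paste(rep("I", L), collapse = ""), character(1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", sequences, "\n+\n", qual), con)
  invisible(path)
}

read_fastq_seqs <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4L != 0L) stop("malformed FASTQ (line count not multiple of 4): ", path)
  ln[seq(2L, length(ln), by = 4L)]
}

# Stable TSV writer used by all report tables.
write_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
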