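# Read cleanup, the 18-30 nt length window, and tag collapsing.

#' Clean raw small RNA reads
#'
#' Trims the 3' adapter at the first exact occurrence of its prefix (at least
#' 8 nt) and discards reads that carry no insert (pure adapter), reads still
#' containing the 5' adapter, reads whose insert is mostly adenine (poly-A),
#' and reads with ambiguous bases.
#'
#' @param reads character vector of raw read sequences (DNA or RNA).
#' @param adapter3 3' adapter sequence; at least 8 nt. Its first
#'   `adapter_prefix` nt are searched for exactly.
#' @param adapter5 optional 5' adapter; reads containing it anywhere are
#'   discarded (adapter dimer / contaminant).
#' @param adapter_prefix length of the exact-match adapter prefix (default 8).
#' @param polya_frac inserts with at least this fraction of A are discarded
#'   (default 0.8).
#' @return character vector of retained insert sequences.
#' @export
clean_reads <- function(reads, adapter3, adapter5 = NULL,
                        adapter_prefix = 8L, polya_frac = 0.8) {
  if (nchar(adapter3) < 8L) stop("adapter3 must be at least 8 nt")
  reads <- as_dna(reads)
  probe <- substr(as_dna(adapter3), 1L, max(adapter_prefix, 8L))
  hit <- regexpr(probe, reads, fixed = TRUE)
  inserts <- ifelse(hit > 0L, substr(reads, 1L, hit - 1L), reads)
  keep <- nchar(inserts) > 0L                       # no insert tag
  if (!is.null(adapter5) && nzchar(adapter5)) {
    keep <- keep & !grepl(as_dna(adapter5), inserts, fixed = TRUE)
  }
  nA <- nchar(inserts) - nchar(gsub("A", "", inserts, fixed = TRUE))
  keep <- keep & (nA < polya_frac * nchar(inserts)) # poly-A
  keep <- keep & !grepl("N", inserts, fixed = TRUE) # ambiguous bases
  inserts[keep]
}

#' Length-filter reads and collapse them into unique tags
#'
#' Retains reads of 18-30 nt (bounds inclusive and configurable), collapses
#' identical sequences, and tallies per-library counts. The result is a "tag
#' table": a data.frame with columns `sequence`, `length` and one count
#' column per library, plus a `libraries` attribute holding per-library
#' metadata including `total_reads` (retained reads).
#'
#' @param reads_by_library named list; each element is either a character
#'   vector of trimmed read sequences or a data.frame with columns
#'   `sequence` and `count` (collapsed input).
#' @param min_len,max_len inclusive length window (defaults 18 and 30).
#' @param library_meta optional data.frame with columns `id`, `genotype`,
#'   `stage` to merge into the `libraries` attribute.
#' @return tag table (class `tag_table`).
#' @export
filter_and_collapse <- function(reads_by_library, min_len = 18L, max_len = 30L,
                                library_meta = NULL) {
  stopifnot(length(reads_by_library) > 0L, !is.null(names(reads_by_library)))
  lib_ids <- names(reads_by_library)
  pieces <- lapply(lib_ids, function(id) {
    x <- reads_by_library[[id]]
    if (is.data.frame(x)) {
      dt <- data.table::data.table(sequence = as_dna(x$sequence),
                                   count = as.numeric(x$count))
    } else {
      dt <- data.table::data.table(sequence = as_dna(x), count = 1)
    }
    dt[, `:=`(length = nchar(sequence), library = id)]
    dt[length >= min_len & length <= max_len]
  })
  all <- data.table::rbindlist(pieces)
  totals <- setNames(numeric(length(lib_ids)), lib_ids)
  if (nrow(all)) {
    tt <- all[, list(n = sum(count)), by = "library"]
    totals[tt$library] <- tt$n
    coll <- data.table::dcast(all, sequence + length ~ library,
                              value.var = "count", fun.aggregate = sum, fill = 0)
    data.table::setorder(coll, sequence)
  } else {
    coll <- data.table::data.table(sequence = character(), length = integer())
  }
  for (id in setdiff(lib_ids, names(coll))) coll[[id]] <- numeric(nrow(coll))
  out <- as.data.frame(coll[, c("sequence", "length", lib_ids), with = FALSE])
  libs <- data.frame(id = lib_ids, total_reads = as.numeric(totals[lib_ids]),
                     stringsAsFactors = FALSE)
  if (!is.null(library_meta)) {
    libs <- merge(libs, library_meta, by = "id", all.x = TRUE, sort = FALSE)
    libs <- libs[match(lib_ids, libs$id), ]
    rownames(libs) <- NULL
  }
  structure(out, libraries = libs, class = c("tag_table", "data.frame"))
}

#' Library metadata of a tag table
#' @param tags a tag table.
#' @return data.frame of per-library metadata (`id`, `total_reads`, ...).
#' @export
tag_libraries <- function(tags) attr(tags, "libraries")

# Count columns of a tag table, in library order.
tag_counts <- function(tags, libraries = NULL) {
  ids <- tag_libraries(tags)$id
  if (!is.null(libraries)) {
    missing <- setdiff(libraries, ids)
    if (length(missing)) stop("unknown library id(s): ", paste(missing, collapse = ", "))
    ids <- libraries
  }
  m <- as.matrix(as.data.frame(tags)[, ids, drop = FALSE])
  rownames(m) <- tags$sequence
  m
}

#' Tag length histogram
#'
#' Sums tag counts per length over a subset of libraries. Keys are restricted
#' to the retained length window.
#'
#' @param tags a tag table.
#' @param libraries library ids to pool (default: all).
#' @return data.frame with columns `length` and `count` (lengths with zero
#'   count omitted).
#' @export
length_histogram <- function(tags, libraries = NULL) {
  if (nrow(tags) == 0L) {
    return(data.frame(length = integer(), count = numeric()))
  }
  m <- tag_counts(tags, libraries)
  tot <- tapply(rowSums(m), tags$length, sum)
  data.frame(length = as.integer(names(tot)), count = as.numeric(tot))
}

#' Modal tag length of a histogram
#' @param hist output of [length_histogram()].
#' @return the length with the largest pooled count (smallest on ties).
#' @export
modal_length <- function(hist) {
  if (nrow(hist) == 0L) return(NA_integer_)
  hist$length[which.max(hist$count)]
}

#' Write a tag table as TSV (sequence, length, one count column per library)
#' @param tags tag table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tag_table <- function(tags, path) write_tsv(as.data.frame(tags), path)
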