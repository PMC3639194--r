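# Structural ncRNA annotation: partition tags into rRNA/tRNA/snRNA/snoRNA
# versus candidate regulatory small RNAs, and the per-library summary table.

STRUCTURAL_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA")

#' Classify tags against structural ncRNA references
#'
#' A tag is assigned to a class when its sequence, or its reverse complement,
#' is an exact substring of any reference sequence of that class. A tag
#' matching several classes takes the first by precedence (default
#' rRNA > tRNA > snRNA > snoRNA). Unmatched tags are `unannotated`.
#'
#' @param tags a tag table (see [filter_and_collapse()]).
#' @param refs named list of character vectors of reference sequences; names
#'   must be a subset of `c("rRNA","tRNA","snRNA","snoRNA")`.
#' @param precedence class precedence order (first wins).
#' @return a list with `annotation` (data.frame: `sequence`, `category`,
#'   `evidence`) and `summary` (per-class, per-library counts with Table-style
#'   "count(percent%)" formatting).
#' @export
classify_structural <- function(tags, refs,
                                precedence = STRUCTURAL_CLASSES) {
  if (!length(refs) || is.null(names(refs))) {
    stop("refs must be a named list of reference sequence vectors")
  }
  extra <- setdiff(names(refs), STRUCTURAL_CLASSES)
  if (length(extra)) stop("unknown structural class(es): ", paste(extra, collapse = ", "))
  empty <- names(refs)[!vapply(refs, length, integer(1))]
  if (length(empty)) stop("empty reference set for class(es): ", paste(empty, collapse = ", "))
  classes <- intersect(precedence, names(refs))

  category <- rep("unannotated", nrow(tags))
  evidence <- rep(NA_character_, nrow(tags))
  if (nrow(tags)) {
    rc <- revcomp(tags$sequence)
    for (cl in rev(classes)) { # apply lowest precedence first, overwrite later
      seqs <- as_dna(refs[[cl]])
      ref_ids <- names(seqs)
      if (is.null(ref_ids)) ref_ids <- paste0(cl, "_", seq_along(seqs))
      subject <- paste(seqs, collapse = "|") # '|' never occurs in ACGTN
      hit <- vapply(seq_len(nrow(tags)), function(i) {
        grepl(tags$sequence[i], subject, fixed = TRUE) ||
          grepl(rc[i], subject, fixed = TRUE)
      }, logical(1))
      if (any(hit)) {
        ev <- vapply(which(hit), function(i) {
          j <- which(vapply(seqs, function(s)
            grepl(tags$sequence[i], s, fixed = TRUE) ||
              grepl(rc[i], s, fixed = TRUE), logical(1)))[1]
          ref_ids[j]
        }, character(1))
        category[hit] <- cl
        evidence[hit] <- ev
      }
    }
  }
  annotation <- data.frame(sequence = tags$sequence, category = category,
                           evidence = evidence, stringsAsFactors = FALSE)
  list(annotation = annotation,
       summary = structural_summary(tags, annotation, classes))
}

# Per-class x per-library read counts with "count(percent%)" cells plus a
# total-reads row, mirroring the published summary layout.
structural_summary <- function(tags, annotation, classes = STRUCTURAL_CLASSES) {
  libs <- tag_libraries(tags)
  m <- tag_counts(tags)
  out <- data.frame(class = c(classes, "total_reads"), stringsAsFactors = FALSE)
  for (id in libs$id) {
    total <- libs$total_reads[libs$id == id]
    cells <- vapply(classes, function(cl) {
      cnt <- sum(m[annotation$category == cl, id])
      pct <- if (total > 0) 100 * cnt / total else 0
      sprintf("%d(%.2f%%)", as.integer(round(cnt)), pct)
    }, character(1))
    out[[id]] <- c(cells, format(total, scientific = FALSE, trim = TRUE))
  }
  out
}

# Numeric per-class counts per library (used by invariants and TP10M).
structural_counts <- function(tags, annotation, classes = STRUCTURAL_CLASSES) {
  m <- tag_counts(tags)
  sapply(tag_libraries(tags)$id, function(id) {
    vapply(c(classes, "unannotated"), function(cl)
      sum(m[annotation$category == cl, id]), numeric(1))
  })
}
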