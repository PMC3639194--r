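# Conserved miRNA family assignment (two-tier reference rule), family
# abundance profiles, and cross-library unique-miRNA sharing.

#' Normalize a miRBase-style name to its family label
#'
#' Strips the species prefix and any letter/number variant suffix:
#' `ghr-miR156a` and `ath-miR156b-5p` both map to `miR156`.
#'
#' @param x character vector of miRNA names.
#' @return family labels (`miRNNN`); names without a recognizable family
#'   number are returned with only the species prefix stripped.
#' @export
mirna_family <- function(x) {
  fam <- sub("^[A-Za-z]{2,4}-", "", x)
  has <- grepl("(miR|MIR)[0-9]+", fam)
  fam[has] <- sub("^.*?(miR|MIR)([0-9]+).*$", "miR\\2", fam[has])
  fam
}

# Alignment of tag vs mature allowing end offsets of up to `max_offset` nt on
# either side; returns the minimum substitution count over admissible offsets,
# or Inf when no admissible overlap exists.
.tag_vs_mature_mismatches <- function(tag, mature, max_offset = 2L) {
  lt <- nchar(tag); lm <- nchar(mature)
  best <- Inf
  for (s in -max_offset:max_offset) {
    # tag position i sits over mature position i + s
    i1 <- max(1L, 1L - s); i2 <- min(lt, lm - s)
    if (i2 < i1) next
    off5 <- abs(s)                 # 5' end offset
    off3 <- abs((lt + s) - lm)     # 3' end offset
    if (off5 > max_offset || off3 > max_offset) next
    a <- substr(tag, i1, i2)
    b <- substr(mature, i1 + s, i2 + s)
    mm <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (mm < best) best <- mm
  }
  best
}

# Match one tag against one reference tier; returns family + mismatches or NULL.
.match_tier <- function(tag, matures, precursors, max_mismatch, max_offset = 2L) {
  best_fam <- NA_character_; best_mm <- Inf
  if (length(matures)) {
    for (k in seq_along(matures)) {
      mm <- .tag_vs_mature_mismatches(tag, matures[[k]], max_offset)
      if (mm <= max_mismatch) {
        fam <- mirna_family(names(matures)[k])
        if (mm < best_mm || (mm == best_mm && !is.na(best_fam) && fam < best_fam)) {
          best_mm <- mm; best_fam <- fam
        }
      }
    }
  }
  if (is.infinite(best_mm) && length(precursors)) {
    # exact containment in a precursor counts as a family match (0 mismatches)
    for (k in seq_along(precursors)) {
      if (grepl(tag, precursors[[k]], fixed = TRUE)) {
        fam <- mirna_family(names(precursors)[k])
        if (is.na(best_fam) || fam < best_fam) { best_fam <- fam; best_mm <- 0 }
      }
    }
  }
  if (is.na(best_fam)) NULL else list(family = best_fam, mismatches = best_mm)
}

#' Assign tags to conserved miRNA families (two-tier rule)
#'
#' Tier 1 compares every tag against the species-level reference (mature
#' sequences, with precursor containment as a fallback). Only tags left
#' unassigned at tier 1 are compared against the all-plant reference at
#' tier 2. A mature matches when an alignment with at most `max_mismatch`
#' substitutions and at most 2 nt 5'/3' end offset exists; the fewest-mismatch
#' family wins, ties broken lexicographically by family name.
#'
#' @param tags a tag table or character vector of tag sequences.
#' @param species_ref,all_plant_ref named lists with elements `mature` and
#'   optionally `precursor` (named character vectors, miRBase-style names).
#'   `all_plant_ref` may be NULL (single-tier operation).
#' @param max_mismatch maximum substitutions against a mature (default 2).
#' @param max_offset maximum 5'/3' end offset in nt (default 2).
#' @return data.frame: `sequence`, `family` (NA if unassigned), `tier`
#'   (1, 2 or NA), `mismatches`.
#' @export
assign_families <- function(tags, species_ref, all_plant_ref = NULL,
                            max_mismatch = 2L, max_offset = 2L) {
  seqs <- if (is.data.frame(tags)) tags$sequence else as_dna(tags)
  norm_ref <- function(ref, label) {
    if (is.null(ref)) return(NULL)
    mat <- ref$mature; pre <- ref$precursor
    if (is.null(mat) && is.null(pre)) stop("empty reference: ", label)
    if (!is.null(mat) && !length(mat)) stop("empty mature reference: ", label)
    list(mature = if (is.null(mat)) character() else as_dna(mat),
         precursor = if (is.null(pre)) character() else as_dna(pre))
  }
  t1 <- norm_ref(species_ref, "species_ref")
  if (is.null(t1)) stop("species_ref is required")
  t2 <- norm_ref(all_plant_ref, "all_plant_ref")

  fam <- rep(NA_character_, length(seqs))
  tier <- rep(NA_integer_, length(seqs))
  mm <- rep(NA_real_, length(seqs))
  for (i in seq_along(seqs)) {
    hit <- .match_tier(seqs[i], t1$mature, t1$precursor, max_mismatch, max_offset)
    if (!is.null(hit)) {
      fam[i] <- hit$family; tier[i] <- 1L; mm[i] <- hit$mismatches
    } else if (!is.null(t2)) {
      hit <- .match_tier(seqs[i], t2$mature, t2$precursor, max_mismatch, max_offset)
      if (!is.null(hit)) {
        fam[i] <- hit$family; tier[i] <- 2L; mm[i] <- hit$mismatches
      }
    }
  }
  data.frame(sequence = seqs, family = fam, tier = tier, mismatches = mm,
             stringsAsFactors = FALSE)
}

#' Family-level abundance profiles
#'
#' Aggregates per-library counts by family and derives, per genotype, the
#' relative abundance (family reads / all conserved-family reads of that
#' genotype) and the share of the family's pooled WT+mutant total.
#'
#' @param assignments output of [assign_families()].
#' @param tags the tag table the assignments came from.
#' @return list with `counts` (family x library data.frame),
#'   `relative_abundance` and `share_of_total` (family x genotype), and
#'   `member_tags` (list of member sequences per family). Genotype columns
#'   appear only when the tag table carries a `genotype` field.
#' @export
family_abundance <- function(assignments, tags) {
  stopifnot(nrow(assignments) == nrow(tags))
  libs <- tag_libraries(tags)
  m <- tag_counts(tags)
  keep <- !is.na(assignments$family)
  fams <- sort(unique(assignments$family[keep]))
  counts <- matrix(0, nrow = length(fams), ncol = nrow(libs),
                   dimnames = list(fams, libs$id))
  for (f in fams) {
    rows <- which(keep & assignments$family == f)
    counts[f, ] <- colSums(m[rows, , drop = FALSE])
  }
  out <- list(counts = data.frame(family = fams, as.data.frame(counts),
                                  check.names = FALSE, row.names = NULL),
              member_tags = lapply(fams, function(f)
                tags$sequence[keep & assignments$family == f]))
  names(out$member_tags) <- fams
  if (!is.null(libs$genotype) && length(fams)) {
    genos <- unique(libs$genotype)
    gc <- sapply(genos, function(g)
      rowSums(counts[, libs$id[libs$genotype == g], drop = FALSE]))
    if (length(fams) == 1L) gc <- matrix(gc, nrow = 1, dimnames = list(fams, genos))
    rel <- sweep(gc, 2, pmax(colSums(gc), 1e-300), "/")
    rel[, colSums(gc) == 0] <- 0
    share <- gc / pmax(rowSums(gc), 1e-300)
    share[rowSums(gc) == 0, ] <- 0
    out$relative_abundance <- data.frame(family = fams, as.data.frame(rel),
                                         check.names = FALSE, row.names = NULL)
    out$share_of_total <- data.frame(family = fams, as.data.frame(share),
                                     check.names = FALSE, row.names = NULL)
  }
  out
}

#' Unique-miRNA sets per library
#'
#' The distinct miRNA tag sequences present (count >= 1) in each library,
#' restricted to tags annotated as miRNA (conserved or novel).
#'
#' @param tags tag table.
#' @param mirna_sequences character vector of tag sequences annotated as
#'   miRNA (conserved or novel).
#' @return named list of character vectors, one per library.
#' @export
unique_mirna_sets <- function(tags, mirna_sequences) {
  m <- tag_counts(tags)
  rows <- tags$sequence %in% mirna_sequences
  lapply(setNames(nm = colnames(m)), function(id)
    tags$sequence[rows & m[, id] >= 1])
}

#' Pairwise unique-miRNA sharing percentages
#'
#' Percentages of the pair's union that are exclusive to each library and
#' shared between them (a two-set Venn diagram in numbers).
#'
#' @param sets named list of per-library miRNA sequence sets.
#' @param pair character vector of two library ids.
#' @return named numeric vector `exclusiveA`, `exclusiveB`, `shared`
#'   (percentages of the union; they sum to 100).
#' @export
unique_mirna_sharing <- function(sets, pair) {
  stopifnot(length(pair) == 2L)
  if (!all(pair %in% names(sets))) {
    stop("unknown library id(s): ", paste(setdiff(pair, names(sets)), collapse = ", "))
  }
  A <- unique(sets[[pair[1]]]); B <- unique(sets[[pair[2]]])
  u <- union(A, B)
  if (!length(u)) stop("sharing undefined: both sets are empty")
  c(exclusiveA = 100 * length(setdiff(A, B)) / length(u),
    exclusiveB = 100 * length(setdiff(B, A)) / length(u),
    shared = 100 * length(intersect(A, B)) / length(u))
}
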