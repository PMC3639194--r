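# Synthetic data generator: every input the pipeline consumes, with planted
# ground truth, emulating the statistical structure of paired anther small
# RNA libraries (six libraries, 18-30 nt tags with modal length 24, < 5%
# structural ncRNA, genotype-specific differential miRNAs) and a degradome
# with 20-21 nt signatures piling up at positions paired to miRNA
# nucleotide 10.

DEFAULT_LIBRARIES <- data.frame(
  id = c("Mar-F-1", "Mar-F-2", "Mar-F-3", "Mar-S-1", "Mar-S-2", "Mar-S-3"),
  genotype = rep(c("WT", "GMS"), each = 3),
  stage = rep(c("meiosis", "tetrad", "uninucleate"), 2),
  stringsAsFactors = FALSE)

# Tag length probabilities, 18-30 nt, mode at 24 with the 21-24 nt bulk
# dominating (the shape of real anther libraries).
DEFAULT_LENGTH_DIST <- c(`18` = 0.02, `19` = 0.03, `20` = 0.06, `21` = 0.15,
                         `22` = 0.11, `23` = 0.13, `24` = 0.28, `25` = 0.08,
                         `26` = 0.05, `27` = 0.04, `28` = 0.02, `29` = 0.02,
                         `30` = 0.01)

DEFAULT_ADAPTER3 <- "TCGTATGCCGTCTTCTGCTTG" # Illumina small RNA 3' adapter

.default_de_spec <- function() {
  data.frame(
    mirna = c("ghr-miR394", "ghr-miR396", "ghr-miR398", "ghr-miR399",
              "ghr-miR398"),
    library_a = c("Mar-F-1", "Mar-F-1", "Mar-F-2", "Mar-F-2", "Mar-F-3"),
    library_b = c("Mar-S-1", "Mar-S-1", "Mar-S-2", "Mar-S-2", "Mar-S-3"),
    fold_change = c(4, 0.25, 4, 4, 5),
    stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' Defaults encode the stated world the generator emulates; see the methods
#' vignette for the rationale behind each value.
#'
#' @param seed RNG seed (integer).
#' @param n_transcripts number of transcripts.
#' @param transcript_len_range transcript length interval, nt.
#' @param n_planted_mirnas planted miRNAs in total.
#' @param n_conserved_mirnas how many of them carry miRBase-style reference
#'   entries (the rest are discoverable only as novel hairpins).
#' @param libraries data.frame `id`, `genotype`, `stage` (default: the six
#'   Mar-F/S libraries).
#' @param library_depth reads per small RNA library.
#' @param length_dist named probability vector over tag lengths 18-30
#'   (must sum to 1; default mode 24).
#' @param structural_fraction fraction of reads drawn from structural ncRNA
#'   references (default 0.04).
#' @param mirna_fraction fraction of reads drawn from planted miRNAs
#'   (default 0.10).
#' @param de_spec data.frame `mirna`, `library_a`, `library_b`,
#'   `fold_change` (> 0); planted per-library abundance ratios.
#' @param n_planted_targets planted degradome cleavage targets.
#' @param degradome_depth degradome reads.
#' @param degradome_signal_fraction fraction of degradome reads placed at
#'   planted cleavage sites (default 0.3).
#' @param background_noise extra per-position Poisson rate of background
#'   degradome reads on top of the uniform (1 - signal) share (default 0).
#' @param n_background_tags,n_structural_tags distinct tag pool sizes.
#' @param adapter3 3' adapter appended to every simulated read.
#' @param read_length raw read length in cycles (insert + adapter,
#'   truncated).
#' @return validated config (list, class `sim_config`).
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 30L,
                       transcript_len_range = c(600L, 1200L),
                       n_planted_mirnas = 12L,
                       n_conserved_mirnas = 8L,
                       libraries = DEFAULT_LIBRARIES,
                       library_depth = 20000L,
                       length_dist = DEFAULT_LENGTH_DIST,
                       structural_fraction = 0.04,
                       mirna_fraction = 0.10,
                       de_spec = .default_de_spec(),
                       n_planted_targets = 5L,
                       degradome_depth = 20000L,
                       degradome_signal_fraction = 0.3,
                       background_noise = 0,
                       n_background_tags = 2500L,
                       n_structural_tags = 400L,
                       adapter3 = DEFAULT_ADAPTER3,
                       read_length = 42L) {
  if (abs(sum(length_dist) - 1) > 1e-8) {
    stop("length_dist must sum to 1")
  }
  lens <- as.integer(names(length_dist))
  if (any(is.na(lens)) || any(lens < 18L) || any(lens > 30L)) {
    stop("length_dist keys must be lengths within 18-30")
  }
  if (anyDuplicated(libraries$id)) stop("library ids must be distinct")
  if (!is.null(de_spec) && nrow(de_spec)) {
    if (any(de_spec$fold_change <= 0)) stop("fold_change must be > 0")
    bad <- setdiff(c(de_spec$library_a, de_spec$library_b), libraries$id)
    if (length(bad)) stop("de_spec references unknown library: ",
                          paste(bad, collapse = ", "))
  }
  if (structural_fraction < 0 || structural_fraction >= 1) {
    stop("structural_fraction must be in [0, 1)")
  }
  if (n_conserved_mirnas > n_planted_mirnas) {
    stop("n_conserved_mirnas cannot exceed n_planted_mirnas")
  }
  structure(list(
    seed = as.integer(seed), n_transcripts = n_transcripts,
    transcript_len_range = transcript_len_range,
    n_planted_mirnas = n_planted_mirnas,
    n_conserved_mirnas = n_conserved_mirnas,
    libraries = libraries, library_depth = library_depth,
    length_dist = length_dist, structural_fraction = structural_fraction,
    mirna_fraction = mirna_fraction, de_spec = de_spec,
    n_planted_targets = n_planted_targets,
    degradome_depth = degradome_depth,
    degradome_signal_fraction = degradome_signal_fraction,
    background_noise = background_noise,
    n_background_tags = n_background_tags,
    n_structural_tags = n_structural_tags,
    adapter3 = adapter3, read_length = read_length), class = "sim_config")
}

#' Plant a miRNA hairpin precursor around a mature sequence
#'
#' Builds a precursor that folds into a canonical hairpin under the stacking
#' energy proxy: the mature verbatim in the requested arm, a reverse
#' complement star on the other arm with the 2-nt 3' overhang of Dicer
#' geometry, and a terminal loop of 8 nt (the two loop-proximal mature bases
#' stay unpaired, which is the in-hairpin image of the mature 3' overhang).
#'
#' @param mature mature sequence, 18-26 nt (DNA or RNA).
#' @param arm which arm carries the mature: "5p" or "3p".
#' @param seed optional integer; when given, the RNG is seeded locally so the
#'   (currently deterministic) construction is stable by contract.
#' @return list: `precursor`, `mature_start`, `mature_end`, `star_start`,
#'   `star_end`, `arm`.
#' @export
plant_hairpin <- function(mature, arm = c("5p", "3p"), seed = NULL) {
  arm <- match.arg(arm)
  mature <- as_dna(mature)
  L <- nchar(mature)
  if (L < 18L || L > 26L) stop("mature length must be 18-26 nt")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  loop <- "CACACACA"          # C/A only: cannot pair internally
  pad <- "CA"
  # full reverse complement: the planted duplex is the unique energy optimum,
  # so the proxy fold recovers it; the 2-nt pad past the star 3' end (5p) or
  # the unpaired loop bases at it (3p) realize the 2-nt 3' overhang of Dicer
  # geometry
  star <- revcomp(mature)
  if (arm == "5p") {
    precursor <- paste0(mature, loop, star, pad)
    m1 <- 1L
    s1 <- L + nchar(loop) + 1L
  } else {
    precursor <- paste0(pad, star, loop, mature)
    m1 <- nchar(pad) + nchar(star) + nchar(loop) + 1L
    s1 <- nchar(pad) + 1L
  }
  list(precursor = precursor, mature_start = m1, mature_end = m1 + L - 1L,
       star_start = s1, star_end = s1 + nchar(star) - 1L, arm = arm)
}

# Conserved family numbers used for reference naming (the families the field
# reports in anthers).
.CONSERVED_FAMS <- c(156, 166, 167, 172, 394, 396, 398, 399, 482, 827,
                     159, 160, 162, 164, 169, 171)

#' Generate a complete synthetic dataset with planted ground truth
#'
#' Writes, under `dir`: `transcripts.fa`; `ncrna_<class>.fa` for
#' rRNA/tRNA/snRNA/snoRNA; `mature_species.fa` and `mature_allplant.fa`
#' (miRBase-style mature references, RNA alphabet; two conserved miRNAs
#' appear only in the all-plant tier to exercise the two-tier rule);
#' one FASTQ per library (reads = insert + 3' adapter, constant quality);
#' `degradome.fa` (collapsed FASTA, count in header); and a ground-truth
#' manifest (`ground_truth.json` plus TSV tables).
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the ground truth: `planted_mirnas` (data.frame),
#'   `true_counts` (miRNA x library matrix of simulated read counts),
#'   `planted_targets`, `de_spec`, `files` (all written paths), `config`.
#' @export
generate_dataset <- function(config = sim_config(), dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  libs <- config$libraries
  lens <- as.integer(names(config$length_dist))
  pick_len <- function(n) sample(lens, n, replace = TRUE, prob = config$length_dist)

  ## transcripts
  tx_len <- sample(config$transcript_len_range[1]:config$transcript_len_range[2],
                   config$n_transcripts, replace = TRUE)
  transcripts <- random_dna(tx_len)
  names(transcripts) <- sprintf("TC%06d", seq_len(config$n_transcripts))
  occupied <- lapply(transcripts, function(x) NULL) # planted intervals per tx

  .free_slot <- function(tx_id, span) {
    n <- nchar(transcripts[[tx_id]])
    for (try in 1:50) {
      a <- sample(50:(n - span - 50L), 1L)
      iv <- occupied[[tx_id]]
      if (is.null(iv) || all(a > iv[, 2] + 10L | a + span - 1L < iv[, 1] - 10L)) {
        return(a)
      }
    }
    NA_integer_
  }

  ## planted miRNAs: conserved (in reference) + novel
  n <- config$n_planted_mirnas
  nc <- config$n_conserved_mirnas
  mirna_names <- c(paste0("ghr-miR", .CONSERVED_FAMS[seq_len(nc)]),
                   if (n > nc) sprintf("novel-m%03d", seq_len(n - nc)))
  mat_len <- sample(20:22, n, replace = TRUE)
  matures <- random_dna(mat_len)
  while (anyDuplicated(matures)) matures <- random_dna(mat_len)
  names(matures) <- mirna_names
  arms <- rep(c("5p", "3p"), length.out = n)

  planted <- vector("list", n)
  for (i in seq_len(n)) {
    hp <- plant_hairpin(matures[i], arms[i])
    tx_id <- names(transcripts)[(i - 1L) %% config$n_transcripts + 1L]
    plen <- nchar(hp$precursor)
    a <- .free_slot(tx_id, plen)
    if (is.na(a)) stop("could not place precursor ", mirna_names[i])
    substr(transcripts[[tx_id]], a, a + plen - 1L) <- hp$precursor
    occupied[[tx_id]] <- rbind(occupied[[tx_id]], c(a, a + plen - 1L))
    planted[[i]] <- data.frame(
      name = mirna_names[i], mature = matures[i], precursor = hp$precursor,
      transcript = tx_id, precursor_start = a, precursor_end = a + plen - 1L,
      mature_start = a + hp$mature_start - 1L,
      mature_end = a + hp$mature_end - 1L, arm = arms[i],
      conserved = i <= nc, stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, planted)
  rownames(planted) <- NULL

  ## planted degradome targets: splice the reverse complement of the mature
  ## into a transcript other than the precursor's
  nt <- min(config$n_planted_targets, n)
  targets <- vector("list", nt)
  for (i in seq_len(nt)) {
    site <- revcomp(matures[i])
    L <- nchar(site)
    used_tx <- if (i > 1L) vapply(targets[seq_len(i - 1L)],
                                  function(t) t$transcript, character(1))
               else character()
    # one target per transcript: a lone signal peak is the unique maximum
    cand_tx <- setdiff(names(transcripts), c(planted$transcript[i], used_tx))
    repeat {
      tx_id <- sample(cand_tx, 1L)
      a <- .free_slot(tx_id, L)
      if (!is.na(a)) break
    }
    substr(transcripts[[tx_id]], a, a + L - 1L) <- site
    occupied[[tx_id]] <- rbind(occupied[[tx_id]], c(a, a + L - 1L))
    # miRNA position 10 pairs target position (a + L - 10); cleavage = first
    # nucleotide of the 3' fragment
    targets[[i]] <- data.frame(
      mirna = mirna_names[i], transcript = tx_id, site_start = a,
      site_end = a + L - 1L, cleavage_position = a + L - 10L,
      stringsAsFactors = FALSE)
  }
  targets <- do.call(rbind, targets)
  rownames(targets) <- NULL

  ## structural ncRNA references and tag pool
  refs <- list(
    rRNA = setNames(random_dna(rep(600L, 3L)), paste0("rRNA_", 1:3)),
    tRNA = setNames(random_dna(rep(75L, 5L)), paste0("tRNA_", 1:5)),
    snRNA = setNames(random_dna(rep(150L, 3L)), paste0("snRNA_", 1:3)),
    snoRNA = setNames(random_dna(rep(120L, 3L)), paste0("snoRNA_", 1:3)))
  class_w <- c(rRNA = 0.70, tRNA = 0.22, snRNA = 0.05, snoRNA = 0.03)
  draw_substr <- function(pool) {
    len <- pick_len(1L)
    src <- pool[[sample(length(pool), 1L)]]
    a <- sample(nchar(src) - len + 1L, 1L)
    substr(src, a, a + len - 1L)
  }
  struct_tags <- character(config$n_structural_tags)
  for (i in seq_along(struct_tags)) {
    cl <- sample(names(class_w), 1L, prob = class_w)
    struct_tags[i] <- draw_substr(refs[[cl]])
  }
  struct_tags <- setdiff(unique(struct_tags), matures)

  ## background tag pool: substrings of transcripts (siRNA-like), stratified
  ## by length so the pooled background length profile follows length_dist
  ## exactly in expectation (the tag-level abundance noise stays within each
  ## length class)
  bg_len <- rep(lens, pmax(1L, round(config$n_background_tags *
                                       config$length_dist)))
  bg_tags <- character(length(bg_len))
  for (i in seq_along(bg_tags)) {
    src <- transcripts[[sample(length(transcripts), 1L)]]
    a <- sample(nchar(src) - bg_len[i] + 1L, 1L)
    bg_tags[i] <- substr(src, a, a + bg_len[i] - 1L)
  }
  keep_bg <- !duplicated(bg_tags) & !(bg_tags %in% c(matures, struct_tags))
  bg_tags <- bg_tags[keep_bg]
  bg_len <- bg_len[keep_bg]

  ## per-library abundance weights
  base_w <- 10^runif(n, 1, 3) # log-uniform miRNA abundance (assumption)
  if (!is.null(config$de_spec) && nrow(config$de_spec)) {
    # differential miRNAs get a moderate fixed base abundance so that the
    # compositional renormalization of the library leaves the realized
    # count-ratio close to the nominal fold change
    base_w[mirna_names %in% config$de_spec$mirna] <- 10^1.5
  }
  w_mirna <- matrix(rep(base_w, nrow(libs)), ncol = nrow(libs),
                    dimnames = list(mirna_names, libs$id))
  if (!is.null(config$de_spec) && nrow(config$de_spec)) {
    for (k in seq_len(nrow(config$de_spec))) {
      de <- config$de_spec[k, ]
      if (!de$mirna %in% mirna_names) next
      w_mirna[de$mirna, de$library_b] <- w_mirna[de$mirna, de$library_a] *
        de$fold_change
    }
  }
  w_struct <- 10^runif(length(struct_tags), 0, 2)
  w_bg <- 10^runif(length(bg_tags), 0, 2)
  for (l in unique(bg_len)) { # normalize within length class (see above)
    cls <- bg_len == l
    w_bg[cls] <- config$length_dist[[as.character(l)]] * w_bg[cls] / sum(w_bg[cls])
  }
  w_bg <- w_bg / sum(w_bg)

  ## compose libraries and write FASTQ
  true_counts <- matrix(0, nrow = n, ncol = nrow(libs),
                        dimnames = list(mirna_names, libs$id))
  fastq_paths <- character(nrow(libs))
  sf <- config$structural_fraction
  mf <- config$mirna_fraction
  for (j in seq_len(nrow(libs))) {
    id <- libs$id[j]
    w <- c(sf * w_struct / sum(w_struct),
           mf * w_mirna[, id] / sum(w_mirna[, id]),
           (1 - sf - mf) * w_bg / sum(w_bg))
    pool <- c(struct_tags, matures, bg_tags)
    cnt <- as.integer(stats::rmultinom(1L, config$library_depth, w))
    true_counts[, j] <- cnt[length(struct_tags) + seq_len(n)]
    reads <- sample(rep.int(pool, cnt))
    raw <- substr(paste0(reads, config$adapter3, config$adapter3),
                  1L, config$read_length)
    fastq_paths[j] <- file.path(dir, paste0(id, ".fastq"))
    write_fastq(raw, sprintf("%s_%07d", id, seq_along(raw)), fastq_paths[j])
  }

  ## degradome: signal reads start exactly at planted cleavage positions
  dg_records <- list()
  n_signal <- round(config$degradome_signal_fraction * config$degradome_depth)
  if (nt > 0 && n_signal > 0) {
    per <- as.integer(stats::rmultinom(1L, n_signal, rep(1, nt)))
    for (i in seq_len(nt)) {
      if (per[i] == 0L) next
      tx <- transcripts[[targets$transcript[i]]]
      c0 <- targets$cleavage_position[i]
      len20 <- stats::rbinom(1L, per[i], 0.5)
      for (L in c(20L, 21L)) {
        k <- if (L == 20L) len20 else per[i] - len20
        if (k == 0L || c0 + L - 1L > nchar(tx)) next
        dg_records[[length(dg_records) + 1L]] <-
          data.frame(sequence = substr(tx, c0, c0 + L - 1L), count = k,
                     stringsAsFactors = FALSE)
      }
    }
  }
  n_bg <- config$degradome_depth - n_signal
  if (config$background_noise > 0) {
    n_bg <- n_bg + stats::rpois(1L, config$background_noise * sum(nchar(transcripts)))
  }
  if (n_bg > 0) {
    tx_pick <- sample(names(transcripts), n_bg, replace = TRUE,
                      prob = nchar(transcripts))
    Ls <- sample(c(20L, 21L), n_bg, replace = TRUE)
    seqs <- character(n_bg)
    for (i in seq_len(n_bg)) {
      txs <- transcripts[[tx_pick[i]]]
      a <- sample(nchar(txs) - Ls[i] + 1L, 1L)
      seqs[i] <- substr(txs, a, a + Ls[i] - 1L)
    }
    dgb <- data.table::data.table(sequence = seqs)[, list(count = .N), by = "sequence"]
    dg_records[[length(dg_records) + 1L]] <- as.data.frame(dgb)
  }
  dg <- data.table::rbindlist(dg_records)
  dg <- as.data.frame(dg[, list(count = sum(count)), by = "sequence"])
  dg <- dg[order(dg$sequence), , drop = FALSE]
  dg_path <- file.path(dir, "degradome.fa")
  write_fasta(setNames(dg$sequence,
                       sprintf("d%06d %d", seq_len(nrow(dg)), dg$count)),
              dg_path)

  ## references on disk
  tx_path <- file.path(dir, "transcripts.fa")
  write_fasta(transcripts, tx_path)
  ref_paths <- vapply(names(refs), function(cl) {
    p <- file.path(dir, paste0("ncrna_", cl, ".fa"))
    write_fasta(refs[[cl]], p)
    p
  }, character(1))
  # two-tier mature references: the last two conserved miRNAs only appear in
  # the all-plant tier (as if cotton had no miRBase entry for them)
  cons <- planted[planted$conserved, ]
  tier2_only <- utils::tail(seq_len(nrow(cons)), 2L)
  species <- setNames(cons$mature, cons$name)[-tier2_only]
  # the all-plant tier carries every conserved mature under a non-cotton name
  allplant <- setNames(cons$mature, sub("^ghr-", "ath-", cons$name))
  sp_path <- file.path(dir, "mature_species.fa")
  ap_path <- file.path(dir, "mature_allplant.fa")
  write_fasta(species, sp_path, rna = TRUE)
  write_fasta(allplant, ap_path, rna = TRUE)

  ## ground-truth manifest
  gt <- list(planted_mirnas = planted, true_counts = true_counts,
             planted_targets = targets, de_spec = config$de_spec,
             tier2_only = cons$name[tier2_only],
             libraries = libs,
             files = c(transcripts = tx_path, degradome = dg_path,
                       mature_species = sp_path, mature_allplant = ap_path,
                       ref_paths, setNames(fastq_paths, libs$id)),
             config = unclass(config))
  json <- gt
  json$true_counts <- as.data.frame(true_counts)
  jsonlite::write_json(json, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  write_tsv(planted, file.path(dir, "ground_truth_mirnas.tsv"))
  write_tsv(targets, file.path(dir, "ground_truth_targets.tsv"))
  write_tsv(data.frame(mirna = rownames(true_counts), true_counts,
                       check.names = FALSE),
            file.path(dir, "ground_truth_counts.tsv"))
  invisible(gt)
}
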