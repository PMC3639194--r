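# Pipeline orchestration: run every stage from one configuration and emit
# the report bundle (summary, length, sharing, family, DE, degradome and
# novel-miRNA tables plus a manifest of every parameter used).

#' Build a pipeline configuration
#'
#' Paths default to the layout written by [generate_dataset()]. Every
#' parameter is recorded verbatim in the run manifest.
#'
#' @param input_dir directory holding the inputs.
#' @param out_dir directory for the report bundle.
#' @param libraries data.frame `id`, `genotype`, `stage`.
#' @param adapter3 3' adapter to trim.
#' @param pairs list of 2-vectors of library ids to contrast (default: WT vs
#'   mutant at each stage).
#' @param stages character vector of enabled stages, a subset of
#'   `c("preprocess","annotate","conserved","novel","de","degradome")`
#'   (earlier stages are always implied by later ones).
#' @param min_len,max_len tag length window.
#' @param max_mismatch conserved-family mismatch tolerance.
#' @param criteria hairpin criteria, see [hairpin_criteria()].
#' @param alpha,min_abs_log2fc differential-expression thresholds.
#' @param max_score degradome duplex score ceiling.
#' @param seed seed recorded in the manifest (stages are deterministic).
#' @return config list (class `pipeline_config`).
#' @export
pipeline_config <- function(input_dir, out_dir,
                            libraries = DEFAULT_LIBRARIES,
                            adapter3 = DEFAULT_ADAPTER3,
                            pairs = list(c("Mar-F-1", "Mar-S-1"),
                                         c("Mar-F-2", "Mar-S-2"),
                                         c("Mar-F-3", "Mar-S-3")),
                            stages = c("preprocess", "annotate", "conserved",
                                       "novel", "de", "degradome"),
                            min_len = 18L, max_len = 30L, max_mismatch = 2L,
                            criteria = hairpin_criteria(),
                            alpha = 0.01, min_abs_log2fc = 1,
                            max_score = 4, seed = 1L) {
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 libraries = libraries, adapter3 = adapter3, pairs = pairs,
                 stages = stages, min_len = min_len, max_len = max_len,
                 max_mismatch = max_mismatch, criteria = criteria,
                 alpha = alpha, min_abs_log2fc = min_abs_log2fc,
                 max_score = max_score, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path a `.yaml`/`.yml` (requires the yaml package) or `.json` file
#'   whose keys are [pipeline_config()] arguments.
#' @return config list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$libraries)) raw$libraries <- as.data.frame(raw$libraries)
  if (!is.null(raw$criteria)) raw$criteria <- do.call(hairpin_criteria, raw$criteria)
  if (!is.null(raw$pairs)) raw$pairs <- lapply(raw$pairs, unlist)
  do.call(pipeline_config, raw)
}

.stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order against the configured
#' inputs and writes the report bundle: a structural-ncRNA summary table, a
#' tag length histogram, pairwise unique-miRNA sharing, conserved-family
#' abundance tables, one differential-expression table per library pair,
#' degradome cleavage calls with per-target t-plot tables, a novel-miRNA
#' table, and a JSON manifest recording every parameter.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results of each stage and
#'   `files` (paths of the report bundle).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ind <- config$input_dir
  outd <- config$out_dir
  if (!dir.exists(outd)) dir.create(outd, recursive = TRUE)
  libs <- config$libraries
  on <- function(s) s %in% config$stages
  res <- list()
  files <- character()
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  ## preprocess
  tags <- tryCatch({
    reads <- lapply(setNames(nm = libs$id), function(id) {
      p <- file.path(ind, paste0(id, ".fastq"))
      if (!file.exists(p)) stop("missing input FASTQ: ", p)
      clean_reads(read_fastq_seqs(p), config$adapter3)
    })
    tt <- filter_and_collapse(reads, config$min_len, config$max_len,
                              library_meta = libs)
    .stage_msg("preprocess", "%d unique tags, %s reads retained",
               nrow(tt), format(sum(tag_libraries(tt)$total_reads)))
    tt
  }, error = function(e) fail("preprocess", e))
  res$tags <- tags
  hist <- length_histogram(tags)
  files["length_histogram"] <- write_tsv(hist, file.path(outd, "length_histogram.tsv"))

  ## annotate
  ann <- NULL
  if (on("annotate")) {
    ann <- tryCatch({
      refs <- lapply(setNames(nm = STRUCTURAL_CLASSES), function(cl) {
        p <- file.path(ind, paste0("ncrna_", cl, ".fa"))
        if (!file.exists(p)) stop("missing reference FASTA: ", p)
        read_fasta(p)
      })
      classify_structural(tags, refs)
    }, error = function(e) fail("annotate", e))
    res$annotation <- ann
    files["table1_summary"] <- write_tsv(ann$summary,
                                         file.path(outd, "table1_summary.tsv"))
    .stage_msg("annotate", "%d structural tags",
               sum(ann$annotation$category != "unannotated"))
  }

  ## conserved families
  assignments <- NULL
  if (on("conserved")) {
    cons <- tryCatch({
      sp <- read_fasta(file.path(ind, "mature_species.fa"))
      ap_path <- file.path(ind, "mature_allplant.fa")
      ap <- if (file.exists(ap_path)) read_fasta(ap_path) else NULL
      # only non-structural tags are candidate miRNAs
      cand <- if (is.null(ann)) rep(TRUE, nrow(tags)) else
        ann$annotation$category == "unannotated"
      asg <- data.frame(sequence = tags$sequence, family = NA_character_,
                        tier = NA_integer_, mismatches = NA_real_,
                        stringsAsFactors = FALSE)
      sub <- assign_families(tags$sequence[cand], list(mature = sp),
                             if (is.null(ap)) NULL else list(mature = ap),
                             max_mismatch = config$max_mismatch)
      asg[cand, ] <- sub
      asg
    }, error = function(e) fail("conserved", e))
    assignments <- cons
    res$assignments <- cons
    fam <- family_abundance(cons, tags)
    res$families <- fam
    files["family_counts"] <- write_tsv(fam$counts,
                                        file.path(outd, "family_counts.tsv"))
    if (!is.null(fam$share_of_total)) {
      pct <- fam$share_of_total
      pct[-1] <- lapply(pct[-1], function(x) round(100 * x, 2))
      files["family_percent"] <- write_tsv(pct, file.path(outd, "family_percent.tsv"))
    }
    .stage_msg("conserved", "%d families", nrow(fam$counts))
  }

  ## novel miRNAs
  novel <- NULL
  transcripts <- NULL
  if (on("novel") || on("degradome")) {
    transcripts <- tryCatch(read_fasta(file.path(ind, "transcripts.fa")),
                            error = function(e) fail("novel", e))
  }
  if (on("novel")) {
    novel <- tryCatch({
      cand <- rep(TRUE, nrow(tags))
      if (!is.null(ann)) cand <- cand & ann$annotation$category == "unannotated"
      if (!is.null(assignments)) cand <- cand & is.na(assignments$family)
      sub <- tags[cand, , drop = FALSE]
      attr(sub, "libraries") <- tag_libraries(tags)
      class(sub) <- class(tags)
      find_novel_mirnas(sub, transcripts, config$criteria)
    }, error = function(e) fail("novel", e))
    res$novel <- novel
    acc <- novel[novel$accepted, , drop = FALSE]
    files["novel_mirnas"] <- write_tsv(
      acc[, c("tag", "energy", "arm", "tx_start", "tx_end")],
      file.path(outd, "novel_mirnas.tsv"))
    if (nrow(acc)) {
      write_fasta(setNames(acc$precursor, paste0("novel_", seq_len(nrow(acc)))),
                  file.path(outd, "novel_precursors.fa"))
      con <- file(file.path(outd, "novel_structures.txt"), "wb")
      writeLines(paste0(">novel_", seq_len(nrow(acc)), "\n", acc$precursor,
                        "\n", acc$structure, " (", acc$energy, ")"), con)
      close(con)
    }
    .stage_msg("novel", "%d accepted of %d candidates", nrow(acc), nrow(novel))
  }

  ## unique-miRNA sharing (needs conserved and/or novel sets)
  if (on("conserved")) {
    mirna_seqs <- unique(c(
      if (!is.null(assignments)) assignments$sequence[!is.na(assignments$family)],
      if (!is.null(novel)) novel$tag[novel$accepted]))
    sets <- unique_mirna_sets(tags, mirna_seqs)
    res$mirna_sets <- sets
    sharing <- do.call(rbind, lapply(config$pairs, function(pr) {
      sh <- unique_mirna_sharing(sets, pr)
      data.frame(library_a = pr[1], library_b = pr[2],
                 exclusive_a_pct = round(sh[["exclusiveA"]], 2),
                 exclusive_b_pct = round(sh[["exclusiveB"]], 2),
                 shared_pct = round(sh[["shared"]], 2),
                 stringsAsFactors = FALSE)
    }))
    files["sharing"] <- write_tsv(sharing, file.path(outd, "sharing.tsv"))
  }

  ## differential expression per pair
  if (on("de")) {
    de_all <- lapply(config$pairs, function(pr) {
      de <- tryCatch(
        call_differential(tags, pr, alpha = config$alpha,
                          min_abs_log2fc = config$min_abs_log2fc),
        error = function(e) fail("de", e))
      p <- file.path(outd, sprintf("de_%s_vs_%s.tsv", pr[1], pr[2]))
      write_tsv(de, p)
      p
    })
    names(de_all) <- vapply(config$pairs, paste, character(1), collapse = "_vs_")
    files[paste0("de_", names(de_all))] <- unlist(de_all)
    res$de_files <- unlist(de_all)
  }

  ## degradome
  if (on("degradome")) {
    dg <- tryCatch({
      reads <- read_small_rna(file.path(ind, "degradome.fa"))
      sigs <- map_degradome(reads, transcripts)
      mirnas <- unique(c(
        if (file.exists(file.path(ind, "mature_species.fa")))
          unname(read_fasta(file.path(ind, "mature_species.fa"))),
        if (file.exists(file.path(ind, "mature_allplant.fa")))
          unname(read_fasta(file.path(ind, "mature_allplant.fa"))),
        if (!is.null(novel)) novel$tag[novel$accepted]))
      mirnas <- mirnas[nchar(mirnas) >= 18 & nchar(mirnas) <= 26]
      sites <- do.call(rbind, lapply(mirnas, find_candidate_sites,
                                     transcripts = transcripts,
                                     max_score = config$max_score))
      calls <- call_cleavage(sites, sigs)
      list(signatures = sigs, sites = sites, calls = calls)
    }, error = function(e) fail("degradome", e))
    res$degradome <- dg
    files["degradome_calls"] <- write_tsv(dg$calls,
                                          file.path(outd, "degradome_calls.tsv"))
    tdir <- file.path(outd, "tplots")
    if (!dir.exists(tdir)) dir.create(tdir)
    for (tx in unique(dg$calls$transcript)) {
      write_tsv(tplot_table(tx, dg$signatures, dg$calls),
                file.path(tdir, paste0(tx, ".tsv")))
    }
    .stage_msg("degradome", "%d cleavage calls", nrow(dg$calls))
  }

  ## manifest: every parameter, no absolute paths (determinism across runs)
  manifest <- list(
    package = "anthersmallrna",
    version = as.character(utils::packageVersion("anthersmallrna")),
    seed = config$seed,
    stages = config$stages,
    parameters = list(
      adapter3 = config$adapter3, min_len = config$min_len,
      max_len = config$max_len, max_mismatch = config$max_mismatch,
      criteria = config$criteria, alpha = config$alpha,
      min_abs_log2fc = config$min_abs_log2fc, max_score = config$max_score),
    libraries = libs,
    report_files = basename(unname(files)))
  jsonlite::write_json(manifest, file.path(outd, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  files["manifest"] <- file.path(outd, "manifest.json")
  res$files <- files
  invisible(res)
}
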