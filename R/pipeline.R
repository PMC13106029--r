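# End-to-end orchestration: one config in, a reproducible report plus TSV
# artifacts out. All thresholds default to the study's stated cutoffs
# (candidate RPM > 25 on fungus-mapped reads, sizes 21-24 nt, target score
# <= 4.5, free-energy ratio >= 0.7, zero mock reads) and are echoed into
# the report.

#' Build a pipeline run configuration
#'
#' @param host_genome,fungus_genome FASTA paths of the two reference genomes.
#' @param host_gff,fungus_gff GFF3 annotation paths.
#' @param sample_sheet TSV sample sheet path (see [read_sample_sheet()]).
#' @param cds optional FASTA of host transcript CDS for target prediction.
#' @param adapter 3' adapter sequence.
#' @param out_dir output directory for artifacts.
#' @param min_rpm,sizes,max_mock_count candidate-selection thresholds.
#' @param score_cutoff,ratio_cutoff target-prediction cutoffs.
#' @param min_len,max_len insert length bounds for adapter clipping.
#' @param seed seed echoed into the report (the pipeline itself is
#'   deterministic).
#' @return list of class `run_config`.
#' @export
run_config <- function(host_genome, fungus_genome, host_gff, fungus_gff,
                       sample_sheet, cds = NULL, adapter, out_dir,
                       min_rpm = 25, sizes = 21:24, max_mock_count = 0,
                       score_cutoff = 4.5, ratio_cutoff = 0.7,
                       min_len = 15L, max_len = 34L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(min_rpm > 0, score_cutoff > 0, ratio_cutoff > 0)
  for (p in c("host_genome", "fungus_genome", "host_gff", "fungus_gff",
              "sample_sheet")) {
    if (!file.exists(cfg[[p]])) stop("config path not found: ", p, " = ",
                                     cfg[[p]])
  }
  if (!is.null(cds) && !file.exists(cds)) stop("config path not found: cds")
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline run configuration from YAML
#' @param path YAML file with the fields of [run_config()]; relative paths
#'   are resolved against the YAML file's directory.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  for (p in c("host_genome", "fungus_genome", "host_gff", "fungus_gff",
              "sample_sheet", "cds")) y[[p]] <- fix(y[[p]])
  if (!is.null(y$sizes)) y$sizes <- as.integer(y$sizes)
  do.call(run_config, y)
}

#' Write a pipeline run configuration to YAML
#' @param config a `run_config`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$sizes <- as.integer(y$sizes)
  yaml::write_yaml(y, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full discovery pipeline
#'
#' Preprocesses every library on the sample sheet (adapter clip, collapse),
#' classifies unique reads by subtractive perfect-match mapping against the
#' host and fungal genomes, profiles sizes and 5' nucleotides, computes the
#' fungal feature-class composition, selects cross-kingdom sRNA candidates,
#' and (when a CDS set is configured) predicts their host targets with
#' cleavability calls. Writes TSV tables and a JSON report with read
#' accounting, thresholds and md5 checksums of every artifact; the run is
#' deterministic given the config and inputs.
#'
#' @param config a [run_config()].
#' @return the run report (list), invisibly also written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }

  log_msg("load", "reading genomes and annotations")
  host_fa <- read_fasta(config$host_genome)
  fungus_fa <- read_fasta(config$fungus_genome)
  host_contigs <- stats::setNames(host_fa$seq, host_fa$id)
  fungus_contigs <- stats::setNames(fungus_fa$seq, fungus_fa$id)
  host <- annotated_genome("host", host_contigs,
                           read_gff3(config$host_gff, host_contigs,
                                     keep_types = c(feature_classes(), "miRNA")))
  fungus <- annotated_genome("fungus", fungus_contigs,
                             read_gff3(config$fungus_gff, fungus_contigs))
  sheet <- read_sample_sheet(config$sample_sheet)
  # FASTQ paths may be relative to the sample sheet's directory
  rel <- !file.exists(sheet$path)
  sheet$path[rel] <- file.path(dirname(config$sample_sheet),
                               sheet$path[rel])
  if (!any(sheet$condition == "AM")) {
    stop("candidate selection requires at least one AM library ",
         "(stage: candidates)")
  }

  log_msg("preprocess", "clipping adapters and collapsing ", nrow(sheet),
          " libraries")
  libs <- lapply(seq_len(nrow(sheet)), function(i) {
    tryCatch(
      preprocess_fastq(sheet$path[i], sheet$sample_id[i], sheet$condition[i],
                       config$adapter, config$min_len, config$max_len),
      error = function(e) stop("stage preprocess, sample ",
                               sheet$sample_id[i], ": ",
                               conditionMessage(e), call. = FALSE))
  })
  names(libs) <- sheet$sample_id

  log_msg("classify", "mapping unique reads against both genomes")
  host_index <- build_index(host)
  fungal_index <- build_index(fungus)
  all_seqs <- sort(unique(unlist(lapply(libs, function(l) names(l$reads)))))
  classification <- classify_sequences(all_seqs, host_index, fungal_index)

  per_sample <- list()
  profile_rows <- list()
  comp_rows <- list()
  for (sid in names(libs)) {
    cls <- classify_origin(libs[[sid]], host_index, fungal_index,
                           classification)
    s <- cls$summary
    per_sample[[sid]] <- data.frame(
      sample_id = sid, condition = s$condition, total_raw = s$total_raw,
      total_after_preprocess = s$total_after_preprocess,
      host = s$reads_by_origin[["host"]],
      fungal = s$reads_by_origin[["fungal"]],
      ambiguous = s$reads_by_origin[["ambiguous"]],
      unassigned = s$reads_by_origin[["unassigned"]],
      fungal_pct = s$fungal_pct, stringsAsFactors = FALSE)
    for (subset in c("host", "fungal")) {
      if (subset == "fungal" && s$condition == "mock" &&
          s$reads_by_origin[["fungal"]] == 0) next
      prof <- size_nt_profile(libs[[sid]], cls$origins, subset)
      long <- data.frame(sample_id = sid, subset = subset,
                         length = as.integer(rep(rownames(prof), 4L)),
                         nt5 = rep(colnames(prof), each = nrow(prof)),
                         rpm = as.vector(prof), stringsAsFactors = FALSE)
      profile_rows[[paste(sid, subset)]] <- long
    }
    if (s$condition == "AM") {
      comp <- feature_composition(cls$origins, classification$fungal_loci,
                                  fungus$features)
      comp_rows[[sid]] <- data.frame(sample_id = sid, class = names(comp),
                                     fraction = as.numeric(comp),
                                     stringsAsFactors = FALSE)
    }
  }
  accounting <- do.call(rbind, c(per_sample, list(make.row.names = FALSE)))

  log_msg("candidates", "selecting cross-kingdom sRNA candidates")
  am_libs <- libs[sheet$sample_id[sheet$condition == "AM"]]
  mock_libs <- libs[sheet$sample_id[sheet$condition == "mock"]]
  cand <- select_candidates(am_libs, mock_libs, classification,
                            fungal_features = fungus$features,
                            min_rpm = config$min_rpm, sizes = config$sizes,
                            max_mock_count = config$max_mock_count)
  candidates <- cand[cand$candidate, , drop = FALSE]
  log_msg("candidates", nrow(candidates), " candidate(s) selected from ",
          nrow(cand), " non-host sequences")

  targets <- NULL
  if (!is.null(config$cds) && nrow(candidates)) {
    log_msg("targets", "predicting host transcript targets")
    cds <- read_fasta(config$cds)
    srnas <- stats::setNames(candidates$sequence,
                             sprintf("cand%02d", seq_len(nrow(candidates))))
    targets <- predict_targets(srnas, cds, score_cutoff = config$score_cutoff,
                               ratio_cutoff = config$ratio_cutoff)
    targets$srna_sequence <- dna_to_rna(unname(srnas[targets$srna_id]))
  }

  # ---- artifacts -------------------------------------------------------------
  out <- function(...) file.path(config$out_dir, ...)
  files <- character(0)
  files["accounting"] <- write_tsv(accounting, out("read_accounting.tsv"))
  files["profiles"] <- write_tsv(do.call(rbind, c(profile_rows,
                                                  list(make.row.names = FALSE))),
                                 out("size_nt_profiles.tsv"))
  if (length(comp_rows)) {
    files["composition"] <- write_tsv(
      do.call(rbind, c(comp_rows, list(make.row.names = FALSE))),
      out("feature_composition.tsv"))
  }
  cand_out <- cand
  cand_out$sequence <- dna_to_rna(cand_out$sequence)  # report in RNA alphabet
  files["filter_table"] <- write_tsv(cand_out, out("filter_table.tsv"))
  cand_sel <- candidates
  cand_sel$sequence <- dna_to_rna(cand_sel$sequence)
  files["candidates"] <- write_tsv(cand_sel, out("candidates.tsv"))
  if (!is.null(targets)) {
    files["targets"] <- write_tsv(targets, out("target_hits.tsv"))
  }

  report <- list(
    config = list(min_rpm = config$min_rpm, sizes = config$sizes,
                  max_mock_count = config$max_mock_count,
                  score_cutoff = config$score_cutoff,
                  ratio_cutoff = config$ratio_cutoff,
                  adapter = config$adapter, seed = config$seed,
                  min_len = config$min_len, max_len = config$max_len),
    samples = accounting,
    fungal_pct_range = range(accounting$fungal_pct[accounting$condition == "AM"]),
    n_candidates = nrow(candidates),
    candidates = cand_sel[, c("sequence", "length", "n_fungal_loci",
                              "feature_class", "min_am_rpm")],
    n_target_hits = if (is.null(targets)) NA_integer_ else nrow(targets),
    checksums = as.list(stats::setNames(unname(tools::md5sum(unname(files))),
                                        basename(unname(files)))))
  json <- out("report.json")
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  report$paths <- c(as.list(files), report = json)
  invisible(report)
}
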