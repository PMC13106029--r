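# Read preprocessing, subtractive perfect-match classification, size/5'
# nucleotide profiling, feature-class assignment and cross-kingdom candidate
# selection.
#
# Mapping is perfect-match only, on both strands, with every locus of a
# multi-mapping read retained. Reads are classified "host" when they match
# the host genome anywhere, "fungal" when they match the fungal genome but
# not the host, "ambiguous" when they match both and "unassigned" when they
# match neither; only fungus-exclusive reads are eligible as cross-kingdom
# candidates.

#' Clip the 3' adapter from raw reads
#'
#' The insert is the prefix before the first exact occurrence of the first
#' 8 nt of the adapter. Reads without the adapter seed or whose insert falls
#' outside `[min_len, max_len]` are rejected with a reason.
#'
#' @param reads character vector of raw read sequences.
#' @param adapter adapter sequence (>= 8 nt).
#' @param min_len,max_len allowed insert length range.
#' @return data.frame with columns `insert` and `status` (one of "ok",
#'   "no_adapter", "too_short", "too_long").
#' @export
clip_adapter <- function(reads, adapter, min_len = 15L, max_len = 34L) {
  if (nchar(adapter) < 8L) stop("adapter must be at least 8 nt")
  seed <- substr(fold_dna(adapter), 1L, 8L)
  reads <- fold_dna(reads)
  pos <- regexpr(seed, reads, fixed = TRUE)
  insert <- ifelse(pos > 0L, substr(reads, 1L, pos - 1L), NA_character_)
  len <- nchar(insert)
  status <- rep("ok", length(reads))
  status[pos < 0L] <- "no_adapter"
  status[pos > 0L & len < min_len] <- "too_short"
  status[pos > 0L & len > max_len] <- "too_long"
  data.frame(insert = ifelse(status == "ok", insert, NA_character_),
             status = status, stringsAsFactors = FALSE)
}

#' Collapse an insert stream into a read library
#'
#' @param inserts character vector of preprocessed insert sequences.
#' @param sample_id,condition library metadata.
#' @param total_raw raw read count before preprocessing (defaults to
#'   `length(inserts)`).
#' @return a [read_library()].
#' @export
collapse_reads <- function(inserts, sample_id, condition,
                           total_raw = length(inserts)) {
  if (!length(inserts)) {
    return(read_library(sample_id, condition,
                        stats::setNames(numeric(0), character(0)),
                        total_raw = total_raw))
  }
  tab <- table(inserts)
  read_library(sample_id, condition,
               stats::setNames(as.numeric(tab), names(tab)),
               total_raw = total_raw)
}

#' Preprocess a FASTQ file into a read library
#'
#' Reads, adapter-clips and collapses one library.
#'
#' @param path FASTQ path.
#' @param sample_id,condition library metadata.
#' @param adapter adapter sequence.
#' @param min_len,max_len allowed insert length range.
#' @return a [read_library()] with `total_raw` set to the raw read count.
#' @export
preprocess_fastq <- function(path, sample_id, condition, adapter,
                             min_len = 15L, max_len = 34L) {
  raw <- read_fastq(path)
  clipped <- clip_adapter(raw, adapter, min_len, max_len)
  collapse_reads(clipped$insert[clipped$status == "ok"], sample_id, condition,
                 total_raw = length(raw))
}

# ---- exact-match mapping -----------------------------------------------------

#' Build an exact-match mapping index for a genome
#'
#' Supports perfect full-length matching of 15-34 nt queries on both strands;
#' reverse-complement occurrences are reported on the minus strand with
#' forward-strand coordinates.
#'
#' @param genome an [annotated_genome()].
#' @return object of class `mapping_index`.
#' @export
build_index <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  contigs <- Biostrings::DNAStringSet(genome$contigs)
  structure(list(label = genome$label, contigs = contigs,
                 rc_contigs = Biostrings::reverseComplement(contigs),
                 contig_len = stats::setNames(nchar(genome$contigs),
                                              names(genome$contigs))),
            class = "mapping_index")
}

#' Map sequences to a genome by perfect full-length match
#'
#' Returns every perfect occurrence of every query on either strand
#' (multi-mapping loci are all retained). Coordinates are internal 0-based
#' half-open on the forward strand.
#'
#' @param seqs character vector of query sequences (15-34 nt).
#' @param index a [build_index()] mapping index.
#' @return data.frame with columns `seq`, `contig`, `start`, `end`, `strand`.
#' @export
map_reads_exact <- function(seqs, index, pdicts = NULL) {
  stopifnot(inherits(index, "mapping_index"))
  empty <- data.frame(seq = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  seqs <- unique(seqs)
  if (!length(seqs)) return(empty)
  lens <- nchar(seqs)
  if (any(lens < 15L | lens > 34L)) {
    stop("query length outside the supported 15-34 nt range")
  }
  clean <- !grepl("[^ACGT]", seqs)  # reads with N cannot match perfectly
  if (is.null(pdicts)) pdicts <- build_query_pdicts(seqs[clean])
  if (is.null(pdicts)) return(empty)
  widths <- pdicts$widths
  acc <- list(seq = list(), contig = list(), start = list(), strand = list(),
              w = list())
  push <- function(qi, cn, st, sd) {
    i <- length(acc$seq) + 1L
    acc$seq[[i]] <<- pdicts$seqs[qi]; acc$contig[[i]] <<- rep(cn, length(qi))
    acc$start[[i]] <<- st; acc$strand[[i]] <<- rep(sd, length(qi))
    acc$w[[i]] <<- widths[qi]
  }
  contig_names <- names(index$contig_len)
  for (ci in seq_along(contig_names)) {
    cname <- contig_names[ci]
    clen <- index$contig_len[[ci]]
    fwd <- Biostrings::matchPDict(pdicts$pdict, index$contigs[[ci]])
    sidx <- Biostrings::startIndex(fwd)
    n_fwd <- lengths(sidx)
    if (sum(n_fwd)) {
      push(rep(seq_along(sidx), n_fwd), cname, unlist(sidx) - 1L, "+")
    }
    rev <- Biostrings::matchPDict(pdicts$pdict, index$rc_contigs[[ci]])
    sidx <- Biostrings::startIndex(rev)
    n_rev <- lengths(sidx)
    if (sum(n_rev)) {
      qi <- rep(seq_along(sidx), n_rev)
      push(qi, cname, clen - (unlist(sidx) - 1L) - widths[qi], "-")
    }
  }
  if (!length(acc$seq)) return(empty)
  # matchPDict reports each full-length occurrence exactly once per strand,
  # so (seq, contig, start, strand) rows are already unique
  res <- data.frame(seq = unlist(acc$seq), contig = unlist(acc$contig),
                    start = unlist(acc$start),
                    end = unlist(acc$start) + unlist(acc$w),
                    strand = unlist(acc$strand), stringsAsFactors = FALSE)
  res[order(res$seq, res$contig, res$start, res$strand, method = "radix"), ,
      drop = FALSE]
}

# preprocess variable-width queries into one PDict with a trusted band over
# the first 15 nt (the minimum query length); matchPDict then verifies the
# remaining tail exactly, so reported hits are full-length perfect matches
# (reused across genomes by classify_sequences)
build_query_pdicts <- function(seqs) {
  if (!length(seqs)) return(NULL)
  list(seqs = seqs, widths = nchar(seqs),
       pdict = Biostrings::PDict(Biostrings::DNAStringSet(seqs),
                                 tb.start = 1L, tb.end = 15L))
}

#' Map one sequence to a genome
#'
#' @param seq a single query sequence (15-34 nt).
#' @param index a [build_index()] mapping index.
#' @return data.frame of loci (possibly empty); see [map_reads_exact()].
#' @export
map_exact <- function(seq, index) {
  stopifnot(length(seq) == 1L)
  hits <- map_reads_exact(fold_dna(seq), index)
  hits[, c("contig", "start", "end", "strand")]
}

# ---- origin classification ---------------------------------------------------

#' Classify sequences by subtractive perfect-match mapping
#'
#' @param seqs character vector of unique read sequences.
#' @param host_index,fungal_index mapping indexes of the two genomes.
#' @return object of class `origin_classification`: list with `origins`
#'   (data.frame `seq`, `origin`, `n_host_loci`, `n_fungal_loci`),
#'   `host_loci` and `fungal_loci` (per-sequence locus tables).
#' @export
classify_sequences <- function(seqs, host_index, fungal_index) {
  seqs <- unique(seqs)
  lens <- nchar(seqs)
  if (length(seqs) && any(lens < 15L | lens > 34L)) {
    stop("query length outside the supported 15-34 nt range")
  }
  pdicts <- build_query_pdicts(seqs[!grepl("[^ACGT]", seqs)])
  host_hits <- map_reads_exact(seqs, host_index, pdicts)
  fungal_hits <- map_reads_exact(seqs, fungal_index, pdicts)
  n_host <- tabulate(match(host_hits$seq, seqs), nbins = length(seqs))
  n_fungal <- tabulate(match(fungal_hits$seq, seqs), nbins = length(seqs))
  origin <- ifelse(n_host > 0L, ifelse(n_fungal > 0L, "ambiguous", "host"),
                   ifelse(n_fungal > 0L, "fungal", "unassigned"))
  structure(list(
    origins = data.frame(seq = seqs, origin = origin,
                         n_host_loci = n_host,
                         n_fungal_loci = n_fungal,
                         stringsAsFactors = FALSE),
    host_loci = host_hits, fungal_loci = fungal_hits),
    class = "origin_classification")
}

#' Classify one library's reads and summarise read accounting
#'
#' @param lib a [read_library()].
#' @param host_index,fungal_index mapping indexes.
#' @param classification optional precomputed [classify_sequences()] result
#'   covering the library's sequences (lets several libraries share one
#'   mapping pass).
#' @return list with `origins` (per unique read, with counts), `summary`
#'   (read accounting incl. the fungus-mapped percentage of total reads) and
#'   the shared `classification`.
#' @export
classify_origin <- function(lib, host_index, fungal_index,
                            classification = NULL) {
  stopifnot(inherits(lib, "read_library"))
  if (is.null(classification)) {
    classification <- classify_sequences(names(lib$reads), host_index,
                                         fungal_index)
  }
  ori <- classification$origins
  idx <- match(names(lib$reads), ori$seq)
  if (anyNA(idx)) stop("classification does not cover all library sequences")
  df <- data.frame(seq = names(lib$reads), count = unname(lib$reads),
                   length = nchar(names(lib$reads)),
                   origin = ori$origin[idx],
                   n_host_loci = ori$n_host_loci[idx],
                   n_fungal_loci = ori$n_fungal_loci[idx],
                   stringsAsFactors = FALSE)
  by_origin <- vapply(c("host", "fungal", "ambiguous", "unassigned"),
                      function(o) sum(df$count[df$origin == o]), numeric(1))
  total <- lib$total_after_preprocess
  list(origins = df,
       summary = list(sample_id = lib$sample_id, condition = lib$condition,
                      total_raw = lib$total_raw,
                      total_after_preprocess = total,
                      reads_by_origin = by_origin,
                      fungal_pct = if (total > 0) 100 * by_origin[["fungal"]] / total else 0),
       classification = classification)
}

# ---- size / 5' nucleotide profiling -----------------------------------------

#' Size and 5'-terminal nucleotide profile of a mapped read subset
#'
#' Reads-per-million matrix over read length (15-34) and 5' nucleotide
#' (A/C/G/U), normalized against the subset's own total read count (the
#' fungal subset is normalized on total fungus-mapped reads per million).
#'
#' @param lib a [read_library()].
#' @param origins per-read origin table from [classify_origin()] (`$origins`).
#' @param subset which mapped subset to profile: "fungal" or "host".
#' @param lengths read lengths spanned by the profile rows.
#' @return matrix of RPM values (`length x nucleotide`) with attributes
#'   `denominator` (subset read total) and `subset`.
#' @export
size_nt_profile <- function(lib, origins, subset = c("fungal", "host"),
                            lengths = 15:34) {
  subset <- match.arg(subset)
  df <- origins[origins$origin == subset, , drop = FALSE]
  nts <- c("A", "C", "G", "U")
  m <- matrix(0, nrow = length(lengths), ncol = 4L,
              dimnames = list(as.character(lengths), nts))
  denom <- sum(df$count)
  if (denom == 0) {
    warning("empty ", subset, "-mapped subset in library '", lib$sample_id,
            "'; returning an all-zero profile")
  } else {
    nt5 <- dna_to_rna(substr(df$seq, 1L, 1L))
    agg <- stats::aggregate(df$count,
                            by = list(len = df$length, nt = nt5), FUN = sum)
    agg <- agg[agg$len %in% lengths & agg$nt %in% nts, , drop = FALSE]
    m[cbind(as.character(agg$len), agg$nt)] <- agg$x / denom * 1e6
  }
  attr(m, "denominator") <- denom
  attr(m, "subset") <- subset
  m
}

# ---- feature-class assignment ------------------------------------------------

features_to_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    class = features$class)
}

#' Assign a genomic feature class to a read's loci
#'
#' The class is the highest-priority feature overlapping (by >= 1 base) any
#' of the read's loci, with priority rRNA > tRNA > snRNA > snoRNA > repeat >
#' mRNA > intergenic. Overlap ignores strand.
#'
#' @param loci data.frame of loci (`contig`, `start`, `end`; 0-based
#'   half-open) as returned by [map_exact()].
#' @param features feature table of the genome (see [feature_table()]).
#' @return a single feature class string.
#' @export
assign_feature <- function(loci, features) {
  if (is.null(loci) || !nrow(loci)) return("intergenic")
  assign_features_batch(cbind(loci, seq = "q"), features)[["q"]]
}

# Vectorised feature assignment: loci must have a `seq` column; returns a
# named vector seq -> class.
assign_features_batch <- function(loci, features) {
  seqs <- unique(loci$seq)
  cls <- stats::setNames(rep("intergenic", length(seqs)), seqs)
  if (!nrow(loci) || !nrow(features)) return(cls)
  fg <- features_to_granges(features[features$class %in% feature_classes(), ,
                                     drop = FALSE])
  if (!length(fg)) return(cls)
  lg <- GenomicRanges::GRanges(
    seqnames = loci$contig,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end))
  ov <- GenomicRanges::findOverlaps(lg, fg, ignore.strand = TRUE)
  if (!length(ov)) return(cls)
  pri <- stats::setNames(seq_along(feature_classes()), feature_classes())
  hit_seq <- loci$seq[S4Vectors::queryHits(ov)]
  hit_pri <- unname(pri[fg$class[S4Vectors::subjectHits(ov)]])
  o <- order(hit_seq, hit_pri)
  first <- !duplicated(hit_seq[o])
  cls[hit_seq[o][first]] <- feature_classes()[hit_pri[o][first]]
  cls
}

#' Feature-class composition of a library's fungus-mapped reads
#'
#' Fractions of fungus-mapped read counts per feature class (the pie-chart
#' breakdown), using highest-priority assignment over all loci of each read.
#'
#' @param origins per-read origin table from [classify_origin()] (`$origins`).
#' @param fungal_loci locus table of fungus-mapped sequences (from
#'   [classify_sequences()] `$fungal_loci`).
#' @param fungal_features fungal genome feature table.
#' @return named numeric vector of fractions over
#'   `c(feature_classes(), "intergenic")`, summing to 1 (all zero if there
#'   are no fungus-mapped reads).
#' @export
feature_composition <- function(origins, fungal_loci, fungal_features) {
  classes <- c(feature_classes(), "intergenic")
  out <- stats::setNames(rep(0, length(classes)), classes)
  df <- origins[origins$origin == "fungal", , drop = FALSE]
  if (!nrow(df)) return(out)
  loci <- fungal_loci[fungal_loci$seq %in% df$seq, , drop = FALSE]
  cls <- assign_features_batch(loci, fungal_features)
  read_cls <- cls[df$seq]
  read_cls[is.na(read_cls)] <- "intergenic"
  agg <- tapply(df$count, read_cls, sum)
  out[names(agg)] <- agg / sum(df$count)
  out
}

# ---- candidate selection -----------------------------------------------------

#' Select cross-kingdom sRNA candidates
#'
#' A sequence is a candidate when all four filters hold: length within
#' `sizes`; RPM strictly above `min_rpm` in every AM library, where RPM is
#' normalized on the library's total fungus-mapped reads per million; raw
#' count of at most `max_mock_count` (default 0) in every mock library; and
#' fungus-exclusive origin (>= 1 perfect fungal locus, none in the host).
#' Near-identical sequences are kept as distinct candidates. The evaluated
#' universe is every unique AM-library sequence that does not map to the
#' host genome.
#'
#' @param am_libs list of AM-condition [read_library()] objects.
#' @param mock_libs list of mock-condition [read_library()] objects.
#' @param classification an [classify_sequences()] result covering all AM
#'   library sequences.
#' @param fungal_features optional fungal feature table; when supplied, each
#'   row is annotated with its feature class.
#' @param min_rpm RPM threshold (strictly greater than).
#' @param sizes allowed candidate lengths.
#' @param max_mock_count maximum tolerated raw count in any mock library.
#' @return data.frame with one row per evaluated sequence: `sequence`,
#'   `length`, `origin`, `n_fungal_loci`, `feature_class`, the four filter
#'   flags (`size_ok`, `rpm_ok_all_am`, `absent_in_mock`, `fungal_exclusive`),
#'   `candidate`, `min_am_rpm`, and per-sample `rpm.*` / `count.*` /
#'   `mock_count.*` columns. Attribute `fungal_totals` records each AM
#'   library's fungus-mapped read total.
#' @export
select_candidates <- function(am_libs, mock_libs, classification,
                              fungal_features = NULL, min_rpm = 25,
                              sizes = 21:24, max_mock_count = 0) {
  if (!length(am_libs)) stop("at least one AM library is required")
  ori <- classification$origins
  am_seqs <- sort(unique(unlist(lapply(am_libs, function(l) names(l$reads)))))
  idx <- match(am_seqs, ori$seq)
  if (anyNA(idx)) stop("classification does not cover all AM library sequences")
  origin <- ori$origin[idx]
  keep <- origin != "host"
  universe <- am_seqs[keep]
  origin <- origin[keep]
  n_fungal_loci <- ori$n_fungal_loci[idx][keep]
  if (!length(universe)) {
    stop("no non-host sequences found in the AM libraries")
  }

  am_ids <- vapply(am_libs, function(l) l$sample_id, character(1))
  mock_ids <- vapply(mock_libs, function(l) l$sample_id, character(1))
  count_col <- function(l) {
    x <- l$reads[match(universe, names(l$reads))]
    x[is.na(x)] <- 0
    unname(x)
  }
  counts <- matrix(vapply(am_libs, count_col, numeric(length(universe))),
                   nrow = length(universe),
                   dimnames = list(universe, am_ids))
  # fungus-mapped denominator per AM library
  fungal_seqs <- ori$seq[ori$origin == "fungal"]
  fungal_totals <- vapply(am_libs, function(l) {
    sum(l$reads[!is.na(match(names(l$reads), fungal_seqs))])
  }, numeric(1))
  names(fungal_totals) <- am_ids
  rpm <- sweep(counts, 2L, ifelse(fungal_totals > 0, fungal_totals, Inf), "/") * 1e6

  mock_counts <- if (length(mock_libs)) {
    matrix(vapply(mock_libs, count_col, numeric(length(universe))),
           nrow = length(universe), dimnames = list(universe, mock_ids))
  } else {
    matrix(0, nrow = length(universe), ncol = 0L,
           dimnames = list(universe, NULL))
  }

  len <- nchar(universe)
  size_ok <- len %in% sizes
  rpm_ok_all_am <- rowSums(rpm > min_rpm) == ncol(rpm)
  absent_in_mock <- if (ncol(mock_counts)) {
    rowSums(mock_counts <= max_mock_count) == ncol(mock_counts)
  } else rep(TRUE, length(universe))
  fungal_exclusive <- origin == "fungal"
  candidate <- size_ok & rpm_ok_all_am & absent_in_mock & fungal_exclusive

  feature_class <- rep(NA_character_, length(universe))
  if (!is.null(fungal_features)) {
    loci <- classification$fungal_loci
    loci <- loci[loci$seq %in% universe, , drop = FALSE]
    cls <- assign_features_batch(loci, fungal_features)
    feature_class <- unname(cls[universe])
    feature_class[is.na(feature_class) & fungal_exclusive] <- "intergenic"
  }

  out <- data.frame(sequence = universe, length = len, origin = origin,
                    n_fungal_loci = n_fungal_loci,
                    feature_class = feature_class,
                    size_ok = size_ok, rpm_ok_all_am = rpm_ok_all_am,
                    absent_in_mock = absent_in_mock,
                    fungal_exclusive = fungal_exclusive,
                    candidate = candidate,
                    min_am_rpm = apply(rpm, 1L, min),
                    stringsAsFactors = FALSE)
  colnames(rpm) <- paste0("rpm.", am_ids)
  colnames(counts) <- paste0("count.", am_ids)
  out <- cbind(out, as.data.frame(rpm), as.data.frame(counts))
  if (ncol(mock_counts)) {
    colnames(mock_counts) <- paste0("mock_count.", mock_ids)
    out <- cbind(out, as.data.frame(mock_counts))
  }
  out <- out[order(-out$candidate, -out$min_am_rpm, out$sequence), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fungal_totals") <- fungal_totals
  out
}
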