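# Readers/writers for FASTA, FASTQ, GFF3 and the sample sheet, plus the
# in-memory containers shared by every stage.
#
# Coordinate convention: internal feature/locus coordinates are 0-based
# half-open; everything written to GFF3 (and read back) is 1-based inclusive,
# the GFF3 standard. `gff_to_internal()` / `internal_to_gff()` are exact
# inverses of each other.

#' Feature classes used for fungal read assignment
#'
#' The closed set of RNA-gene / repeat classes recognised in annotations and
#' used (in this priority order) when assigning fungus-mapped reads to
#' genomic feature classes. Reads overlapping none of them are "intergenic".
#'
#' @return character vector of feature classes, highest priority first.
#' @export
feature_classes <- function() {
  c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat", "mRNA")
}

#' Read a FASTA file
#'
#' Parses a FASTA file into a data frame of records. Lowercase input is
#' folded to uppercase and RNA (U) is folded to the internal DNA alphabet.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id` (first header token), `desc`
#'   (remainder of the header) and `seq`, in file order.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  headers <- names(set)
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) {
    i <- which(nchar(seqs) == 0L)[1L]
    # locate the offending header line for the error message
    ln <- which(startsWith(readLines(path, warn = FALSE), ">"))[i]
    stop("empty sequence for record '", headers[i], "' (header at line ",
         ln, ") in '", path, "'", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id '", ids[anyDuplicated(ids)],
         "' in '", path, "'", call. = FALSE)
  }
  data.frame(id = ids, desc = desc, seq = fold_dna(seqs),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records data.frame with columns `id`, `seq` and optionally `desc`,
#'   or a named character vector of sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), desc = "", seq = unname(records),
                          stringsAsFactors = FALSE)
  }
  desc <- if ("desc" %in% names(records)) records$desc else ""
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  lines <- as.vector(rbind(paste0(">", hdr), records$seq))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file as a sequence stream
#'
#' Qualities are parsed but not interpreted: the analysis uses only
#' demultiplexed, adapter-clipped sequences, so no quality filtering is
#' applied anywhere in the pipeline.
#'
#' @param path path to a FASTQ file (4-line records).
#' @return character vector of read sequences (each an implicit count of 1),
#'   named by read id.
#' @export
read_fastq <- function(path) {
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines == 0L) return(character(0))
  if (n_lines %% 4L != 0L) {
    stop("truncated FASTQ record in '", path, "': ", n_lines,
         " lines is not a multiple of 4", call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq"),
    error = function(e) stop("truncated or malformed FASTQ in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  out <- fold_dna(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write reads to a FASTQ file
#'
#' @param seqs character vector of read sequences (named by read id; unnamed
#'   reads get sequential ids).
#' @param path output path.
#' @param quality_char single character used to fill the quality line.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(seqs, path, quality_char = "I") {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("r%07d", seq_along(seqs))
  qual <- strrep(quality_char, nchar(seqs))
  lines <- as.vector(rbind(paste0("@", ids), unname(seqs), "+", qual))
  writeLines(lines, path)
  invisible(path)
}

# ---- coordinate conversion -------------------------------------------------

# GFF3 1-based inclusive -> internal 0-based half-open
gff_to_internal <- function(start1, end1) {
  list(start = start1 - 1L, end = end1)
}

# internal 0-based half-open -> GFF3 1-based inclusive
internal_to_gff <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}

# ---- feature tables --------------------------------------------------------

#' Construct a feature interval table
#'
#' @param contig,start,end,strand,class,subtype,name vectors describing
#'   feature intervals; `start`/`end` are internal 0-based half-open
#'   coordinates, `class` must come from [feature_classes()] (plus "miRNA",
#'   accepted for host annotations), `subtype` carries repeat subtypes
#'   (transposon, simple_inverted, tandem) and `name` an identifier.
#' @return data.frame of features.
#' @export
feature_table <- function(contig = character(), start = integer(),
                          end = integer(), strand = character(),
                          class = character(), subtype = "", name = "") {
  n <- length(contig)
  df <- data.frame(contig = as.character(contig),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), class = as.character(class),
                   subtype = rep_len(as.character(subtype), n),
                   name = rep_len(as.character(name), n),
                   stringsAsFactors = FALSE)
  ok_class <- c(feature_classes(), "miRNA")
  if (nrow(df) && !all(df$class %in% ok_class)) {
    stop("feature class outside the recognised set: ",
         paste(unique(setdiff(df$class, ok_class)), collapse = ", "))
  }
  if (nrow(df) && !all(df$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (nrow(df) && any(df$start < 0L | df$end <= df$start)) {
    stop("feature intervals must satisfy 0 <= start < end")
  }
  df
}

#' Bundle contigs and features into an annotated genome
#'
#' @param label genome label, one of "host" or "fungus".
#' @param contigs named character vector of contig sequences (DNA alphabet).
#' @param features feature table as returned by [feature_table()].
#' @return object of class `annotated_genome`.
#' @export
annotated_genome <- function(label, contigs, features = feature_table()) {
  stopifnot(label %in% c("host", "fungus"), is.character(contigs),
            !is.null(names(contigs)))
  contigs <- fold_dna(contigs)
  if (nrow(features)) {
    unknown <- setdiff(features$contig, names(contigs))
    if (length(unknown)) {
      stop("features reference unknown contig(s): ",
           paste(unknown, collapse = ", "))
    }
    len <- nchar(contigs)[features$contig]
    if (any(features$end > len)) stop("feature end beyond contig length")
  }
  structure(list(label = label, contigs = contigs, features = features),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome '%s': %d contig(s), %s bp, %d feature(s)\n",
              x$label, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","),
              nrow(x$features)))
  invisible(x)
}

#' Read feature intervals from a GFF3 file
#'
#' Coordinates are converted from GFF3 1-based inclusive to the internal
#' 0-based half-open convention. Feature types outside `keep_types` are
#' dropped; the number of dropped lines is reported via `message()` and
#' attached as the `n_dropped` attribute.
#'
#' @param path path to a GFF3 file.
#' @param genome optional [annotated_genome()] (or named character vector of
#'   contigs) used to validate contig names and bounds.
#' @param keep_types feature types to retain; defaults to the closed set of
#'   [feature_classes()].
#' @return feature table (see [feature_table()]) with attribute `n_dropped`.
#' @export
read_gff3 <- function(path, genome = NULL, keep_types = feature_classes()) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- feature_table()
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad_ncol <- lengths(fields) != 9L
  errors <- character(0)
  if (any(bad_ncol)) {
    errors <- c(errors, sprintf("line %d: expected 9 tab-separated columns",
                                lineno[bad_ncol]))
    fields <- fields[!bad_ncol]
    lineno <- lineno[!bad_ncol]
  }
  m <- do.call(rbind, fields)
  type <- m[, 3L]
  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  bad_coord <- is.na(start1) | is.na(end1) | end1 < start1 | start1 < 1L
  if (any(bad_coord)) {
    errors <- c(errors, sprintf("line %d: invalid coordinates %s..%s",
                                lineno[bad_coord], m[bad_coord, 4L],
                                m[bad_coord, 5L]))
  }
  contigs <- NULL
  if (!is.null(genome)) {
    contigs <- if (inherits(genome, "annotated_genome")) genome$contigs else genome
    bad_contig <- !(m[, 1L] %in% names(contigs))
    if (any(bad_contig)) {
      errors <- c(errors, sprintf("line %d: unknown contig '%s'",
                                  lineno[bad_contig], m[bad_contig, 1L]))
    }
  }
  if (length(errors)) {
    stop("GFF3 errors in '", path, "':\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  sel <- type %in% keep_types
  n_dropped <- sum(!sel)
  if (n_dropped > 0L) {
    message("read_gff3: dropped ", n_dropped,
            " feature line(s) with types outside the recognised set")
  }
  attrs <- strsplit(m[sel, 9L], ";", fixed = TRUE)
  get_attr <- function(key) {
    prefix <- paste0(key, "=")
    vapply(attrs, function(kv) {
      hit <- kv[startsWith(trimws(kv), prefix)]
      if (length(hit)) sub("^[^=]*=", "", trimws(hit[1L])) else ""
    }, character(1))
  }
  conv <- gff_to_internal(start1[sel], end1[sel])
  out <- feature_table(contig = m[sel, 1L], start = conv$start, end = conv$end,
                       strand = ifelse(m[sel, 7L] %in% c("+", "-"), m[sel, 7L], "+"),
                       class = type[sel], subtype = get_attr("subtype"),
                       name = get_attr("ID"))
  if (!is.null(contigs) && nrow(out)) {
    len <- nchar(contigs)[out$contig]
    if (any(out$end > len)) {
      stop("GFF3 errors in '", path, "': feature end beyond contig length",
           call. = FALSE)
    }
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write feature intervals to a GFF3 file
#'
#' Internal 0-based half-open coordinates are converted back to GFF3
#' 1-based inclusive. Writing then re-reading restores the feature table
#' exactly (bit-stable given fixed input).
#'
#' @param features feature table (see [feature_table()]).
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(features, path, source = "ckRNAi") {
  conv <- internal_to_gff(features$start, features$end)
  attrs <- paste0("ID=", features$name)
  has_sub <- nzchar(features$subtype)
  attrs[has_sub] <- paste0(attrs[has_sub], ";subtype=", features$subtype[has_sub])
  lines <- paste(features$contig, source, features$class, conv$start, conv$end,
                 ".", features$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a sample sheet
#'
#' A sample sheet is a TSV with header columns `sample_id`, `condition` and
#' `path` assigning each sRNA library to the mock or AM (fungus-colonized)
#' condition. Conditions are matched case-insensitively.
#'
#' @param path path to the TSV sample sheet.
#' @return data.frame with columns `sample_id`, `condition` (one of
#'   "mock"/"AM") and `path`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "path")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns sample_id, condition, path")
  }
  cond <- tolower(df$condition)
  if (!all(cond %in% c("mock", "am"))) {
    stop("unknown condition(s): ",
         paste(unique(df$condition[!cond %in% c("mock", "am")]), collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ", df$sample_id[anyDuplicated(df$sample_id)])
  }
  data.frame(sample_id = as.character(df$sample_id),
             condition = ifelse(cond == "am", "AM", "mock"),
             path = as.character(df$path), stringsAsFactors = FALSE)
}

#' Write a sample sheet
#' @param sheet data.frame with columns `sample_id`, `condition`, `path`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet[, c("sample_id", "condition", "path")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- read libraries --------------------------------------------------------

#' Construct a collapsed read library
#'
#' @param sample_id library identifier.
#' @param condition "mock" or "AM".
#' @param counts named integer vector: unique read sequence -> count (>= 1).
#' @param total_raw total raw reads before preprocessing; defaults to the sum
#'   of counts.
#' @param min_len minimum allowed sequence length.
#' @return object of class `read_library`.
#' @export
read_library <- function(sample_id, condition, counts,
                         total_raw = NULL, min_len = 15L) {
  stopifnot(condition %in% c("mock", "AM"))
  counts <- counts[order(names(counts))]
  storage.mode(counts) <- "double"  # totals can exceed .Machine$integer.max
  if (length(counts) && any(counts < 1)) stop("read counts must be >= 1")
  if (length(counts) && any(nchar(names(counts)) < min_len)) {
    stop("read sequences shorter than the configured minimum (", min_len, ")")
  }
  total <- sum(counts)
  if (is.null(total_raw)) total_raw <- total
  if (total > total_raw) stop("sum of counts exceeds total_raw")
  structure(list(sample_id = sample_id, condition = condition, reads = counts,
                 total_raw = total_raw, total_after_preprocess = total),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat(sprintf("read_library '%s' (%s): %s reads, %s unique sequences\n",
              x$sample_id, x$condition,
              format(x$total_after_preprocess, big.mark = ","),
              format(length(x$reads), big.mark = ",")))
  invisible(x)
}
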