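# Synthetic host/fungus dataset generator with planted ground truth.
#
# The generator emulates the study design the pipeline is built for: five
# AM (fungus-colonized) and three mock AGO co-IP sRNA libraries; host
# background reads (miRNA-like 21-nt 5'-U reads plus genome fragments)
# present in all libraries; fungal sRNAs present only in AM libraries at a
# small fraction of total reads (matching the observed 0.09-3.6% per-sample
# range of fungus-derived reads); planted cross-kingdom sRNAs of 21-24 nt
# with a 5'-U bias, some encoded by a repeat family at exactly four
# dispersed genomic copies and the rest by single intergenic loci; one decoy
# per candidate filter, violating exactly that filter; and host transcripts
# carrying target sites at graded complementarity (perfect, sub-cutoff,
# position-10 wobble, non-target). Everything is seeded and byte-stable.

#' Default read-length distribution
#'
#' Probability mass over read lengths 15-34 nt with the main peak at 21 nt
#' and a minor secondary peak at 17 nt (a feature of AGO-loaded sRNA
#' libraries whose biological relevance is unclear; it carries no truth
#' label).
#'
#' @return named numeric vector over "15".."34" summing to 1.
#' @export
default_size_distribution <- function() {
  p <- stats::setNames(rep(0.014, 20L), as.character(15:34))
  p[c("15", "16", "17", "18", "19", "20", "21", "22", "23", "24")] <-
    c(0.01, 0.02, 0.08, 0.02, 0.03, 0.06, 0.30, 0.14, 0.10, 0.10)
  p / sum(p)
}

#' Simulation configuration
#'
#' @param seed integer seed controlling all randomness.
#' @param host_genome_bp,fungus_genome_bp genome sizes.
#' @param n_host_contigs,n_fungus_contigs contig counts.
#' @param n_mock,n_am numbers of mock and AM libraries (defaults mirror the
#'   study design: five colonized libraries, three mock).
#' @param n_planted_ck_srnas number of planted cross-kingdom sRNAs (default
#'   12, the number of AGO-loaded fungal sRNAs passing all filters).
#' @param n_repeat_family_srnas how many of the planted sRNAs are encoded by
#'   the four-copy repeat family (multi-locus sRNAs); the rest have a single
#'   intergenic locus each.
#' @param planted_rpm_range per-library planted abundance range, in reads
#'   per million of total library reads; the lower bound must exceed 25 so
#'   every planted sRNA passes the RPM filter.
#' @param five_prime_u_fraction probability that a simulated AGO-loaded read
#'   starts with U.
#' @param size_distribution named probability vector over lengths 15-34.
#' @param adapter 3' adapter ligated to every read.
#' @param background_reads_per_library total reads per library.
#' @param mirna_fraction fraction of host background reads drawn from host
#'   miRNA loci.
#' @param n_host_mirna_loci,n_host_mrna_loci host annotation sizes.
#' @param n_unique_host_fragments unique host genome fragments per library.
#' @param fungal_fraction_range per-AM-library range for the fraction of
#'   reads that are fungus-derived.
#' @param fungal_class_mix mixing proportions of fungal background reads
#'   over genomic feature classes (repeat-dominated, mRNA second, mirroring
#'   the observed feature composition).
#' @param n_background_transcripts host CDS without planted sites.
#' @param cds_length_range CDS length range (nt).
#' @param junk_read_fraction fraction of extra raw reads that fail
#'   preprocessing (no adapter / insert too short); written only to FASTQ.
#' @param read_length on-disk read length (insert + adapter, padded/truncated).
#' @param error_rate optional per-base substitution rate applied to read
#'   copies (default 0: the analysis relies on perfect-match mapping).
#' @param decoy_spec named logical vector enabling one decoy per violated
#'   candidate filter.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       host_genome_bp = 200000L, fungus_genome_bp = 100000L,
                       n_host_contigs = 4L, n_fungus_contigs = 2L,
                       n_mock = 3L, n_am = 5L,
                       n_planted_ck_srnas = 12L, n_repeat_family_srnas = 2L,
                       planted_rpm_range = c(30, 120),
                       five_prime_u_fraction = 0.8,
                       size_distribution = default_size_distribution(),
                       adapter = "AGATCGGAAGAGCACACGTCT",
                       background_reads_per_library = 1e6,
                       mirna_fraction = 0.25,
                       n_host_mirna_loci = 30L, n_host_mrna_loci = 20L,
                       n_unique_host_fragments = 2500L,
                       fungal_fraction_range = c(0.010, 0.035),
                       fungal_class_mix = c("rRNA" = 0.08, "tRNA" = 0.04,
                                            "snRNA" = 0.03, "snoRNA" = 0.03,
                                            "repeat" = 0.45, "mRNA" = 0.25,
                                            "intergenic" = 0.12),
                       n_background_transcripts = 8L,
                       cds_length_range = c(300L, 600L),
                       junk_read_fraction = 0.01,
                       read_length = 50L,
                       error_rate = 0,
                       decoy_spec = c(size = TRUE, rpm = TRUE,
                                      present_in_mock = TRUE,
                                      no_perfect_fungal_match = TRUE,
                                      matches_host = TRUE)) {
  if (abs(sum(size_distribution) - 1) > 1e-9) {
    stop("size_distribution probabilities must sum to 1")
  }
  if (planted_rpm_range[1] <= 25) {
    stop("planted_rpm_range lower bound must exceed 25 RPM")
  }
  if (nchar(adapter) < 8L) stop("adapter must be at least 8 nt")
  if (five_prime_u_fraction < 0 || five_prime_u_fraction > 1) {
    stop("five_prime_u_fraction must be in [0, 1]")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# ---- interval helpers --------------------------------------------------------

# non-overlapping random interval placement; returns df(contig, start, end)
# 0-based half-open, or errors when the genome is too small
place_intervals <- function(contig_len, lens, occupied, margin = 30L,
                            max_tries = 500L) {
  out <- data.frame(contig = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  for (len in lens) {
    placed <- FALSE
    for (i in seq_len(max_tries)) {
      ci <- sample(names(contig_len), 1L, prob = contig_len)
      lmax <- contig_len[[ci]] - len
      if (lmax < 1L) next
      st <- sample.int(lmax, 1L) - 1L
      occ <- occupied[[ci]]
      if (!is.null(occ) && nrow(occ) &&
          any(st < occ$end + margin & occ$start - margin < st + len)) next
      out <- rbind(out, data.frame(contig = ci, start = st, end = st + len,
                                   stringsAsFactors = FALSE))
      occupied[[ci]] <- rbind(occ, data.frame(start = st, end = st + len))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("genome too small to place a ", len,
           " bp feature; increase the configured genome size")
    }
  }
  list(intervals = out, occupied = occupied)
}

# complement of a set of intervals within contigs (0-based half-open),
# keeping only gaps of at least min_width
complement_intervals <- function(contig_len, intervals, min_width = 60L) {
  out <- lapply(names(contig_len), function(ci) {
    iv <- intervals[intervals$contig == ci, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L, end = iv$end))
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, contig_len[[ci]]), ir)
    gaps <- gaps[IRanges::width(gaps) >= min_width]
    if (!length(gaps)) return(NULL)
    data.frame(contig = ci, start = IRanges::start(gaps) - 1L,
               end = IRanges::end(gaps), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# split regions into chunks and deal them round-robin into n_parts disjoint
# pools (0-based half-open); used to keep each AM library's background
# fragment loci private to that library, so stochastic background can never
# recur across all colonized libraries the way genuine sRNA species do
partition_regions <- function(regions, n_parts, chunk_len = 80L,
                              min_chunk = 40L) {
  if (is.null(regions) || !nrow(regions)) {
    return(replicate(n_parts, NULL, simplify = FALSE))
  }
  chunks <- list()
  for (i in seq_len(nrow(regions))) {
    st <- seq(regions$start[i], regions$end[i] - 1L, by = chunk_len)
    en <- pmin(st + chunk_len, regions$end[i])
    keep <- en - st >= min_chunk
    if (!any(keep)) next
    # merge a short trailing piece into the previous chunk
    if (!keep[length(keep)] && sum(keep)) en[max(which(keep))] <- max(en)
    chunks[[i]] <- data.frame(contig = regions$contig[i], start = st[keep],
                              end = en[keep], stringsAsFactors = FALSE)
  }
  chunks <- do.call(rbind, chunks)
  if (is.null(chunks)) return(replicate(n_parts, NULL, simplify = FALSE))
  part <- (seq_len(nrow(chunks)) - 1L) %% n_parts + 1L
  lapply(seq_len(n_parts), function(p) {
    out <- chunks[part == p, , drop = FALSE]
    if (nrow(out)) out else NULL
  })
}

# subtract exclusion intervals from region intervals (all 0-based half-open)
subtract_intervals <- function(regions, exclude, min_width = 40L) {
  if (is.null(exclude) || !nrow(exclude) || is.null(regions) || !nrow(regions)) {
    return(regions)
  }
  out <- lapply(unique(regions$contig), function(ci) {
    rr <- regions[regions$contig == ci, , drop = FALSE]
    ee <- exclude[exclude$contig == ci, , drop = FALSE]
    ir <- IRanges::IRanges(start = rr$start + 1L, end = rr$end)
    if (nrow(ee)) {
      ir <- IRanges::setdiff(ir, IRanges::IRanges(start = ee$start + 1L,
                                                  end = ee$end))
    }
    ir <- ir[IRanges::width(ir) >= min_width]
    if (!length(ir)) return(NULL)
    data.frame(contig = ci, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# count perfect occurrences of a pattern in a set of contig strings,
# both strands (brute-force substring scan)
count_occurrences <- function(pattern, contigs) {
  n <- 0L
  rc <- revcomp(pattern)
  for (s in contigs) {
    m1 <- gregexpr(pattern, s, fixed = TRUE)[[1L]]
    if (m1[1L] != -1L) n <- n + length(m1)
    m2 <- gregexpr(rc, s, fixed = TRUE)[[1L]]
    if (m2[1L] != -1L) n <- n + length(m2)
  }
  n
}

# ---- fragment sampling -------------------------------------------------------

# sample n genome fragments from the given regions with the configured
# 5'-U probability (exactly: with prob q the 5' base is T, otherwise it is
# not) and no adapter seed inside the fragment
sample_fragments <- function(contigs, regions, n, len_probs, q_u, adapter_seed,
                             max_iter = 40L) {
  if (n <= 0L || is.null(regions) || !nrow(regions)) return(character(0))
  lens_avail <- as.integer(names(len_probs))
  widths <- regions$end - regions$start
  draw <- function(m, want_u) {
    ri <- sample.int(nrow(regions), m, replace = TRUE, prob = widths)
    len <- sample(lens_avail, m, replace = TRUE, prob = len_probs)
    len <- pmin(len, widths[ri])
    st <- regions$start[ri] +
      floor(stats::runif(m) * (widths[ri] - len + 1L))
    strand <- sample(c("+", "-"), m, replace = TRUE)
    seq <- substring(contigs[regions$contig[ri]], st + 1L, st + len)
    neg <- strand == "-"
    if (any(neg)) seq[neg] <- revcomp(seq[neg])
    list(seq = seq, ok = ((substr(seq, 1L, 1L) == "T") == want_u) &
           !grepl(adapter_seed, seq, fixed = TRUE) &
           !grepl("[^ACGT]", seq))
  }
  want_u <- stats::runif(n) < q_u
  res <- draw(n, want_u)
  seqs <- res$seq
  todo <- which(!res$ok)
  it <- 0L
  while (length(todo) && it < max_iter) {
    r2 <- draw(length(todo), want_u[todo])
    seqs[todo] <- r2$seq
    todo <- todo[!r2$ok]
    it <- it + 1L
  }
  seqs
}

# random sRNA-like sequence: length drawn from 21-24 (renormalized size
# distribution), 5' base U with probability q, position 10 always G or U
# (so a wobble-design target site exists), adapter-seed free
draw_srna_sequence <- function(len_probs, q_u, adapter_seed) {
  p <- len_probs[as.character(21:24)]
  len <- sample(21:24, 1L, prob = p / sum(p))
  repeat {
    s <- strsplit(random_dna(len), "", fixed = TRUE)[[1L]]
    s[1L] <- if (stats::runif(1) < q_u) "T" else sample(c("A", "C", "G"), 1L)
    s[10L] <- sample(c("G", "T"), 1L)
    seq <- paste(s, collapse = "")
    if (!grepl(adapter_seed, seq, fixed = TRUE)) return(seq)
  }
}

# ---- genome simulation -------------------------------------------------------

#' Simulate annotated host and fungus genomes with planted sRNA loci
#'
#' The fungal genome carries at least one interval of every feature class,
#' including a tandem-repeat family ("F1") present at exactly four dispersed
#' identical copies which encodes the multi-locus planted sRNAs; the
#' remaining planted cross-kingdom sRNAs get one intergenic locus each.
#' Planted sRNAs never perfectly match the host genome (rejected by
#' construction and verified by a brute-force substring scan). The host
#' genome carries miRNA loci (sources of the AGO-loaded host background)
#' and mRNA loci.
#'
#' @param config a [sim_config()].
#' @return list with `host` and `fungus` ([annotated_genome()]s) and `truth`
#'   (planted sRNA table with loci, decoy sequences and loci, miRNA table,
#'   repeat unit sequence).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- save_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  adapter_seed <- substr(fold_dna(config$adapter), 1L, 8L)
  q_u <- config$five_prime_u_fraction

  # --- host ---
  h_len <- rep(config$host_genome_bp %/% config$n_host_contigs,
               config$n_host_contigs)
  host <- stats::setNames(random_dna(h_len[1L], config$n_host_contigs),
                          sprintf("h_chr%d", seq_len(config$n_host_contigs)))
  h_contig_len <- stats::setNames(nchar(host), names(host))
  occ <- stats::setNames(vector("list", length(host)), names(host))
  pl <- place_intervals(h_contig_len, rep(120L, config$n_host_mirna_loci), occ)
  mirna_iv <- pl$intervals; occ <- pl$occupied
  pl <- place_intervals(h_contig_len, rep(800L, config$n_host_mrna_loci), occ)
  h_mrna_iv <- pl$intervals; occ <- pl$occupied

  # write miRNA mature reads (21 nt at offset 50 of the precursor, forward
  # strand) with the configured 5'-U probability, avoiding the adapter seed
  mirnas <- vector("list", nrow(mirna_iv))
  for (i in seq_len(nrow(mirna_iv))) {
    ci <- mirna_iv$contig[i]
    mstart <- mirna_iv$start[i] + 50L  # 0-based mature start
    repeat {
      mat <- strsplit(random_dna(21L), "", fixed = TRUE)[[1L]]
      mat[1L] <- if (stats::runif(1) < q_u) "T" else sample(c("A", "C", "G"), 1L)
      mat <- paste(mat, collapse = "")
      if (!grepl(adapter_seed, mat, fixed = TRUE)) break
    }
    substr(host[[ci]], mstart + 1L, mstart + 21L) <- mat
    mirnas[[i]] <- data.frame(mirna_id = sprintf("miR%03d", i), contig = ci,
                              start = mstart, end = mstart + 21L, seq = mat,
                              stringsAsFactors = FALSE)
  }
  mirnas <- do.call(rbind, mirnas)

  host_features <- feature_table(
    contig = c(mirna_iv$contig, h_mrna_iv$contig),
    start = c(mirna_iv$start, h_mrna_iv$start),
    end = c(mirna_iv$end, h_mrna_iv$end),
    strand = "+",
    class = c(rep("miRNA", nrow(mirna_iv)), rep("mRNA", nrow(h_mrna_iv))),
    name = c(mirnas$mirna_id, sprintf("hmRNA%03d", seq_len(nrow(h_mrna_iv)))))

  # --- fungus ---
  f_len <- rep(config$fungus_genome_bp %/% config$n_fungus_contigs,
               config$n_fungus_contigs)
  fungus <- stats::setNames(random_dna(f_len[1L], config$n_fungus_contigs),
                            sprintf("f_chr%d", seq_len(config$n_fungus_contigs)))
  f_contig_len <- stats::setNames(nchar(fungus), names(fungus))
  focc <- stats::setNames(vector("list", length(fungus)), names(fungus))

  fspec <- list(
    list(class = "rRNA", subtype = "", n = 2L, len = 2000L),
    list(class = "tRNA", subtype = "", n = 8L, len = 90L),
    list(class = "snRNA", subtype = "", n = 3L, len = 200L),
    list(class = "snoRNA", subtype = "", n = 3L, len = 160L),
    list(class = "repeat", subtype = "transposon", n = 6L, len = 500L),
    list(class = "repeat", subtype = "simple_inverted", n = 3L, len = 300L),
    list(class = "repeat", subtype = "tandem", n = 2L, len = 300L),
    list(class = "mRNA", subtype = "", n = 8L, len = 900L))
  feats <- list()
  for (sp in fspec) {
    pl <- place_intervals(f_contig_len, rep(sp$len, sp$n), focc)
    focc <- pl$occupied
    iv <- pl$intervals
    feats[[length(feats) + 1L]] <- feature_table(
      contig = iv$contig, start = iv$start, end = iv$end,
      strand = sample(c("+", "-"), nrow(iv), replace = TRUE),
      class = sp$class, subtype = sp$subtype,
      name = sprintf("%s%s_%d", sp$class,
                     if (nzchar(sp$subtype)) paste0("_", sp$subtype) else "",
                     seq_len(nrow(iv))))
  }

  # planted cross-kingdom sRNAs: unique sequences absent from the host
  n_pl <- config$n_planted_ck_srnas
  n_rep <- min(config$n_repeat_family_srnas, n_pl)
  planted_seq <- character(0)
  while (length(planted_seq) < n_pl) {
    s <- draw_srna_sequence(config$size_distribution, q_u, adapter_seed)
    if (s %in% planted_seq) next
    if (count_occurrences(s, host) > 0L) next
    planted_seq <- c(planted_seq, s)
  }

  # the four-copy tandem repeat family F1 embeds the multi-locus sRNAs
  unit_len <- 150L
  repeat_unit <- NULL
  if (n_rep > 0L) {
    offsets <- c(10L, 60L, 110L)[seq_len(min(n_rep, 3L))]
    if (n_rep > 3L) stop("at most 3 sRNAs fit in the repeat unit")
    repeat {
      unit <- strsplit(random_dna(unit_len), "", fixed = TRUE)[[1L]]
      for (i in seq_len(n_rep)) {
        s <- planted_seq[i]
        unit[(offsets[i] + 1L):(offsets[i] + nchar(s))] <-
          strsplit(s, "", fixed = TRUE)[[1L]]
      }
      unit <- paste(unit, collapse = "")
      if (!grepl(adapter_seed, unit, fixed = TRUE) &&
          count_occurrences(unit, host) == 0L) break
    }
    repeat_unit <- unit
  } else {
    repeat_unit <- random_dna(unit_len)
  }
  pl <- place_intervals(f_contig_len, rep(unit_len, 4L), focc)
  focc <- pl$occupied
  f1_iv <- pl$intervals
  for (i in seq_len(4L)) {
    substr(fungus[[f1_iv$contig[i]]], f1_iv$start[i] + 1L, f1_iv$end[i]) <-
      repeat_unit
  }
  feats[[length(feats) + 1L]] <- feature_table(
    contig = f1_iv$contig, start = f1_iv$start, end = f1_iv$end,
    strand = "+", class = "repeat", subtype = "tandem",
    name = sprintf("F1_copy%d", 1:4))
  fungal_features <- do.call(rbind, feats)

  # single intergenic loci for the remaining planted sRNAs and for the
  # fungus-encoded decoys
  planted <- data.frame(srna_id = sprintf("ckRNA%02d", seq_len(n_pl)),
                        sequence = planted_seq, length = nchar(planted_seq),
                        family = c(rep("F1", n_rep), rep("", n_pl - n_rep)),
                        stringsAsFactors = FALSE)
  loci_list <- vector("list", n_pl)
  for (i in seq_len(n_rep)) {
    loci_list[[i]] <- data.frame(
      contig = f1_iv$contig, start = f1_iv$start + offsets[i],
      end = f1_iv$start + offsets[i] + planted$length[i], strand = "+",
      stringsAsFactors = FALSE)
  }

  plant_intergenic <- function(seq) {
    repeat {
      pl <- place_intervals(f_contig_len, nchar(seq), focc)
      iv <- pl$intervals
      focc <<- pl$occupied
      substr(fungus[[iv$contig]], iv$start + 1L, iv$end) <<- seq
      return(iv)
    }
  }
  for (i in seq((n_rep + 1L), length.out = n_pl - n_rep)) {
    # re-draw any sequence already present in the evolving fungal genome
    while (count_occurrences(planted$sequence[i], fungus) > 0L ||
           planted$sequence[i] %in% planted$sequence[seq_len(i - 1L)]) {
      s <- draw_srna_sequence(config$size_distribution, q_u, adapter_seed)
      if (count_occurrences(s, host) == 0L) planted$sequence[i] <- s
    }
    planted$length[i] <- nchar(planted$sequence[i])
    iv <- plant_intergenic(planted$sequence[i])
    loci_list[[i]] <- data.frame(contig = iv$contig, start = iv$start,
                                 end = iv$end, strand = "+",
                                 stringsAsFactors = FALSE)
  }
  planted$n_loci <- vapply(loci_list, nrow, integer(1))

  # decoys: each violates exactly one candidate filter
  decoy_defs <- list(
    size = list(len = 19L, in_fungus = TRUE, in_host = FALSE),
    rpm = list(len = 22L, in_fungus = TRUE, in_host = FALSE),
    present_in_mock = list(len = 23L, in_fungus = TRUE, in_host = FALSE),
    no_perfect_fungal_match = list(len = 22L, in_fungus = FALSE,
                                   in_host = FALSE),
    matches_host = list(len = 21L, in_fungus = TRUE, in_host = TRUE))
  enabled <- names(decoy_defs)[names(decoy_defs) %in%
                                 names(config$decoy_spec)[config$decoy_spec]]
  decoys <- list()
  decoy_loci <- list()
  host_decoy_loci <- list()
  for (nm in enabled) {
    def <- decoy_defs[[nm]]
    repeat {
      s <- strsplit(random_dna(def$len), "", fixed = TRUE)[[1L]]
      s[1L] <- if (stats::runif(1) < q_u) "T" else sample(c("A", "C", "G"), 1L)
      s <- paste(s, collapse = "")
      if (!grepl(adapter_seed, s, fixed = TRUE) &&
          count_occurrences(s, fungus) == 0L &&
          count_occurrences(s, host) == 0L) break
    }
    iv <- NULL
    if (def$in_fungus) iv <- plant_intergenic(s)
    if (def$in_host) {
      # also plant in a host intergenic region
      h_all <- rbind(mirna_iv, h_mrna_iv)
      h_gaps <- complement_intervals(h_contig_len, h_all, min_width = 100L)
      gi <- sample.int(nrow(h_gaps), 1L)
      hst <- h_gaps$start[gi] +
        sample.int(h_gaps$end[gi] - h_gaps$start[gi] - def$len, 1L)
      substr(host[[h_gaps$contig[gi]]], hst + 1L, hst + def$len) <- s
      host_decoy_loci[[nm]] <- data.frame(
        contig = h_gaps$contig[gi], start = hst, end = hst + def$len,
        stringsAsFactors = FALSE)
    }
    decoys[[nm]] <- data.frame(decoy_id = paste0("decoy_", nm), sequence = s,
                               length = def$len, violated_filter = nm,
                               stringsAsFactors = FALSE)
    decoy_loci[[nm]] <- iv
  }
  decoys <- if (length(decoys)) do.call(rbind, decoys) else
    data.frame(decoy_id = character(), sequence = character(),
               length = integer(), violated_filter = character(),
               stringsAsFactors = FALSE)
  rownames(decoys) <- NULL

  # verification scans: planted loci counts and host absence
  for (i in seq_len(n_pl)) {
    stopifnot(count_occurrences(planted$sequence[i], fungus) ==
                planted$n_loci[i],
              count_occurrences(planted$sequence[i], host) == 0L)
  }
  stopifnot(count_occurrences(repeat_unit, fungus) == 4L)

  truth <- list(planted = planted, planted_loci = loci_list,
                decoys = decoys, decoy_loci = decoy_loci,
                host_decoy_loci = host_decoy_loci,
                mirnas = mirnas, repeat_unit = repeat_unit)
  list(host = annotated_genome("host", host, host_features),
       fungus = annotated_genome("fungus", fungus, fungal_features),
       truth = truth)
}

# ---- transcriptome simulation -------------------------------------------------

# introduce a mismatch (neither WC nor wobble) opposite sRNA position k
site_set_mm <- function(site, srna, k) {
  L <- nchar(srna)
  i <- L - k + 1L
  a <- substr(srna, k, k)
  forbidden <- c(comp_base(a), switch(a, G = "T", T = "G", NULL))
  repl <- sample(setdiff(c("A", "C", "G", "T"), c(forbidden)), 1L)
  substr(site, i, i) <- repl
  site
}

# introduce a G:U wobble opposite sRNA position k (requires srna[k] in G/T)
site_set_gu <- function(site, srna, k) {
  L <- nchar(srna)
  i <- L - k + 1L
  a <- substr(srna, k, k)
  repl <- switch(a, G = "T", T = "G",
                 stop("no wobble possible opposite ", a))
  substr(site, i, i) <- repl
  site
}

#' Simulate a host transcriptome with planted target sites
#'
#' For every planted sRNA, four transcripts are generated carrying one site
#' each: a perfect site (exact reverse complement), a sub-cutoff site
#' (passes both target-prediction cutoffs but is not perfect), a
#' position-10 G:U wobble site (predicted hit, non-cleavable) and a
#' non-target site (penalty score above the cutoff). Each design is
#' verified with the package's own scorer at build time. Additional
#' background transcripts carry no sites.
#'
#' @param config a [sim_config()].
#' @param genomes output of [simulate_genomes()].
#' @return list with `cds` (data.frame `id`, `desc`, `seq`) and `targets`
#'   (data.frame `transcript_id`, `site_start` 0-based, `site_len`,
#'   `design`, `srna_id`).
#' @export
simulate_transcriptome <- function(config, genomes) {
  old <- save_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed + 1L)
  planted <- genomes$truth$planted
  cds <- list(); targets <- list()
  tx_n <- 0L
  add_tx <- function(seq, site_start0 = NA, site_len = NA, design = NA,
                     srna_id = NA) {
    tx_n <<- tx_n + 1L
    id <- sprintf("TX%04d", tx_n)
    cds[[tx_n]] <<- data.frame(id = id, desc = "synthetic CDS", seq = seq,
                               stringsAsFactors = FALSE)
    if (!is.na(design)) {
      targets[[length(targets) + 1L]] <<- data.frame(
        transcript_id = id, site_start = site_start0, site_len = site_len,
        design = design, srna_id = srna_id, stringsAsFactors = FALSE)
    }
    id
  }
  embed <- function(site) {
    len <- sample(seq(config$cds_length_range[1], config$cds_length_range[2]),
                  1L)
    offset <- sample.int(len - nchar(site) - 20L, 1L) + 10L  # 0-based
    tx <- random_dna(len)
    substr(tx, offset + 1L, offset + nchar(site)) <- site
    list(tx = tx, offset = offset)
  }

  for (i in seq_len(nrow(planted))) {
    srna <- planted$sequence[i]
    sid <- planted$srna_id[i]
    L <- nchar(srna)
    perfect <- revcomp(srna)

    # sub-cutoff: edits in the 3' half, tried from strongest to mildest so
    # the site passes both cutoffs regardless of the sRNA's stack content
    guk <- NULL
    for (k in c(19L, 18L, 17L, 16L, 20L)) {
      if (substr(srna, k, k) %in% c("G", "T")) { guk <- k; break }
    }
    sub_trials <- list()
    if (!is.null(guk)) {
      sub_trials <- c(sub_trials,
                      list(site_set_gu(site_set_mm(perfect, srna, 15L),
                                       srna, guk)),
                      list(site_set_gu(perfect, srna, guk)))
    }
    sub_trials <- c(sub_trials,
                    list(site_set_mm(perfect, srna, 15L)),
                    list(site_set_mm(perfect, srna, L)))
    sub <- NULL
    for (cand_site in sub_trials) {
      sc <- score_alignment(align_duplex(srna, cand_site))
      if (sc > 0 && sc <= 4.5 && energy_ratio(srna, cand_site) >= 0.7) {
        sub <- cand_site
        break
      }
    }
    stopifnot(!is.null(sub))

    # wobble at position 10: binds, passes cutoffs, but is not cleavable
    wob <- site_set_gu(perfect, srna, 10L)
    aw <- align_duplex(srna, wob)
    stopifnot(score_alignment(aw) <= 4.5, !call_cleavage(aw)$cleavable)

    # non-target: enough seed mismatches that no alignment passes
    non <- perfect
    for (k in c(3L, 5L, 7L, 9L, 11L)) non <- site_set_mm(non, srna, k)
    while (score_alignment(align_duplex(srna, non)) <= 4.5) {
      non <- site_set_mm(non, srna, sample(c(2L, 4L, 6L, 8L, 12L), 1L))
    }

    for (design in c("perfect", "sub_cutoff", "wobble_10_11", "non_target")) {
      site <- switch(design, perfect = perfect, sub_cutoff = sub,
                     wobble_10_11 = wob, non_target = non)
      e <- embed(site)
      add_tx(e$tx, e$offset, nchar(site), design, sid)
    }
  }
  for (j in seq_len(config$n_background_transcripts)) {
    len <- sample(seq(config$cds_length_range[1], config$cds_length_range[2]),
                  1L)
    add_tx(random_dna(len))
  }
  list(cds = do.call(rbind, cds), targets = do.call(rbind, targets))
}

# ---- library simulation --------------------------------------------------------

#' Simulate mock and AM read libraries with a ground-truth manifest
#'
#' AM libraries contain host background (miRNA-like reads plus genome
#' fragments, all perfect host-genome substrings), planted cross-kingdom
#' sRNA reads at the configured per-library RPM, per-filter decoys, and
#' fungus-derived background reads drawn from annotated fungal loci with
#' the configured feature-class mix and 5'-U bias. Mock libraries contain
#' host background only (plus the present-in-mock decoy read). Optionally
#' writes FASTQ files (inserts with the adapter appended, plus raw junk
#' reads that fail preprocessing), the genomes, annotations, CDS set,
#' sample sheet and JSON manifest.
#'
#' @param config a [sim_config()].
#' @param genomes output of [simulate_genomes()].
#' @param transcriptome optional output of [simulate_transcriptome()]
#'   (embedded into the manifest).
#' @param out_dir optional directory; when given, all artifacts are written
#'   there.
#' @return list with `libraries` (named list of [read_library()]s),
#'   `manifest` (ground truth) and `paths` (when written).
#' @export
simulate_libraries <- function(config, genomes, transcriptome = NULL,
                               out_dir = NULL) {
  old <- save_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed + 2L)
  adapter <- fold_dna(config$adapter)
  adapter_seed <- substr(adapter, 1L, 8L)
  q_u <- config$five_prime_u_fraction
  D <- config$background_reads_per_library
  host <- genomes$host; fungus <- genomes$fungus
  truth <- genomes$truth
  planted <- truth$planted
  decoys <- truth$decoys
  n_pl <- nrow(planted)

  sample_ids <- c(sprintf("mock%d", seq_len(config$n_mock)),
                  sprintf("AM%d", seq_len(config$n_am)))
  conditions <- c(rep("mock", config$n_mock), rep("AM", config$n_am))
  am_ids <- sample_ids[conditions == "AM"]
  mock_ids <- sample_ids[conditions == "mock"]
  if (any(decoys$violated_filter == "rpm") && config$n_am < 2L) {
    warning("rpm decoy requires >= 2 AM libraries; disabling it")
    decoys <- decoys[decoys$violated_filter != "rpm", , drop = FALSE]
  }
  if (any(decoys$violated_filter == "present_in_mock") && config$n_mock < 1L) {
    warning("present_in_mock decoy requires >= 1 mock library; disabling it")
    decoys <- decoys[decoys$violated_filter != "present_in_mock", , drop = FALSE]
  }

  # planted per-AM-library counts from the configured RPM range (relative to
  # total library reads)
  rpm_target <- matrix(stats::runif(n_pl * config$n_am,
                                    config$planted_rpm_range[1],
                                    config$planted_rpm_range[2]),
                       nrow = n_pl, dimnames = list(planted$srna_id, am_ids))
  planted_counts <- round(rpm_target * D / 1e6)
  if (any(planted_counts < 1)) {
    stop("requested planted RPM not representable at library depth ",
         format(D, big.mark = ","))
  }
  decoy_counts <- matrix(0, nrow(decoys), config$n_am,
                         dimnames = list(decoys$decoy_id, am_ids))
  if (nrow(decoys)) {
    dc <- round(stats::runif(nrow(decoys) * config$n_am,
                             config$planted_rpm_range[1],
                             config$planted_rpm_range[2]) * D / 1e6)
    decoy_counts[] <- pmax(dc, 1)
    if ("decoy_rpm" %in% rownames(decoy_counts)) {
      decoy_counts["decoy_rpm", 1L] <- 0  # absent from the first AM library
    }
  }

  # fungal background sampling regions per class, excluding planted/decoy loci
  f_feats <- fungus$features
  excl <- do.call(rbind, c(
    lapply(truth$planted_loci, function(x) x[, c("contig", "start", "end")]),
    lapply(Filter(Negate(is.null), truth$decoy_loci),
           function(x) x[, c("contig", "start", "end")])))
  f_contig_len <- stats::setNames(nchar(fungus$contigs), names(fungus$contigs))
  # copies 2-4 of the identical F1 repeat are excluded from background
  # sampling: they alias the same sequences as copy 1 and would leak
  # fragments across the per-library pools below
  f1_dup <- f_feats[grepl("^F1_copy[234]$", f_feats$name),
                    c("contig", "start", "end"), drop = FALSE]
  bg_excl <- rbind(excl, f1_dup)
  class_regions <- lapply(feature_classes(), function(cl) {
    iv <- f_feats[f_feats$class == cl, c("contig", "start", "end"),
                  drop = FALSE]
    subtract_intervals(iv, bg_excl)
  })
  names(class_regions) <- feature_classes()
  all_iv <- rbind(f_feats[, c("contig", "start", "end")],
                  if (is.null(excl)) NULL else excl)
  class_regions[["intergenic"]] <- complement_intervals(f_contig_len, all_iv)
  # each AM library samples fungal background from its own disjoint pool
  class_pools <- lapply(class_regions, partition_regions,
                        n_parts = config$n_am)
  class_mix <- config$fungal_class_mix

  host_regions <- data.frame(contig = names(host$contigs), start = 0L,
                             end = nchar(host$contigs),
                             stringsAsFactors = FALSE)
  # host fragments must not re-create the host-planted decoy sequence, which
  # would break that decoy's "violates exactly one filter" contract
  host_excl <- do.call(rbind, unname(truth$host_decoy_loci))
  host_regions <- subtract_intervals(host_regions, host_excl)
  mirna_weights <- stats::rlnorm(nrow(truth$mirnas), 0, 1)

  libraries <- list()
  sample_rows <- list()
  comp_rows <- list()
  n_junk <- round(config$junk_read_fraction * D)

  for (li in seq_along(sample_ids)) {
    sid <- sample_ids[li]
    cond <- conditions[li]
    parts <- list()
    truth_class_counts <- stats::setNames(
      rep(0, length(feature_classes()) + 1L),
      c(feature_classes(), "intergenic"))
    fungal_total <- 0

    if (cond == "AM") {
      ai <- match(sid, am_ids)
      pc <- planted_counts[, ai]
      parts$planted <- stats::setNames(as.numeric(pc), planted$sequence)
      fam_class <- ifelse(planted$family == "F1", "repeat", "intergenic")
      for (cl in unique(fam_class)) {
        truth_class_counts[cl] <- truth_class_counts[cl] +
          sum(pc[fam_class == cl])
      }
      fungal_total <- fungal_total + sum(pc)
      if (nrow(decoys)) {
        dcnt <- decoy_counts[, ai]
        keep <- dcnt > 0
        parts$decoys <- stats::setNames(as.numeric(dcnt[keep]),
                                        decoys$sequence[keep])
        fung_decoy <- decoys$violated_filter %in%
          c("size", "rpm", "present_in_mock")
        fungal_total <- fungal_total + sum(dcnt[keep & fung_decoy])
        truth_class_counts["intergenic"] <-
          truth_class_counts["intergenic"] + sum(dcnt[keep & fung_decoy])
      }
      # fungal background up to the library's fungus-derived read target
      f_frac <- stats::runif(1, config$fungal_fraction_range[1],
                             config$fungal_fraction_range[2])
      T_target <- round(f_frac * D)
      B <- max(0, T_target - fungal_total)
      if (B > 0) {
        cls_counts <- as.vector(stats::rmultinom(1L, B, class_mix))
        names(cls_counts) <- names(class_mix)
        frags <- character(0)
        for (cl in names(cls_counts)) {
          if (cls_counts[[cl]] == 0L) next
          fr <- sample_fragments(fungus$contigs, class_pools[[cl]][[ai]],
                                 cls_counts[[cl]], config$size_distribution,
                                 q_u, adapter_seed)
          truth_class_counts[cl] <- truth_class_counts[cl] + length(fr)
          frags <- c(frags, fr)
        }
        if (length(frags)) {
          parts$fungal_bg <- stats::setNames(rep(1, length(frags)), frags)
          fungal_total <- fungal_total + length(frags)
        }
      }
    }

    # host background fills the library to exactly D reads
    non_host <- sum(unlist(lapply(parts, sum)))
    mock_decoy_here <- cond == "mock" && sid == mock_ids[1L] &&
      "present_in_mock" %in% decoys$violated_filter
    if (mock_decoy_here) {
      dseq <- decoys$sequence[decoys$violated_filter == "present_in_mock"]
      parts$mock_decoy <- stats::setNames(1, dseq)
      non_host <- non_host + 1
      fungal_total <- fungal_total + 1  # the decoy read maps to the fungus
    }
    H <- D - non_host
    n_mi <- round(config$mirna_fraction * H)
    mi_counts <- as.vector(stats::rmultinom(1L, n_mi, mirna_weights))
    keep <- mi_counts > 0
    parts$mirna <- stats::setNames(as.numeric(mi_counts[keep]),
                                   truth$mirnas$seq[keep])
    n_frag <- H - n_mi
    n_u <- min(config$n_unique_host_fragments, n_frag)
    if (n_u > 0L && n_frag > 0L) {
      frag_seqs <- sample_fragments(host$contigs, host_regions, n_u,
                                    config$size_distribution, q_u,
                                    adapter_seed)
      w <- stats::rlnorm(length(frag_seqs), 0, 1)
      fc <- as.vector(stats::rmultinom(1L, n_frag, w))
      keep <- fc > 0
      parts$host_frags <- stats::setNames(as.numeric(fc[keep]),
                                          frag_seqs[keep])
    }

    all_counts <- unlist(unname(parts))
    rs <- rowsum(unname(all_counts), names(all_counts))
    counts <- stats::setNames(as.numeric(rs), rownames(rs))
    if (config$error_rate > 0) {
      counts <- apply_sequencing_errors(counts, config$error_rate)
    }
    libraries[[sid]] <- read_library(sid, cond, counts,
                                     total_raw = sum(counts) + n_junk)
    sample_rows[[sid]] <- data.frame(
      sample_id = sid, condition = cond, total_raw = sum(counts) + n_junk,
      total_after_preprocess = sum(counts),
      fungal_mapped_total = fungal_total, n_junk = n_junk,
      stringsAsFactors = FALSE)
    if (cond == "AM") {
      comp_rows[[sid]] <- data.frame(
        sample_id = sid, class = names(truth_class_counts),
        count = as.numeric(truth_class_counts),
        fraction = if (fungal_total > 0)
          as.numeric(truth_class_counts) / fungal_total else 0,
        stringsAsFactors = FALSE)
    }
  }

  planted_out <- cbind(planted,
                       sequence_rna = dna_to_rna(planted$sequence),
                       as.data.frame(planted_counts) |>
                         stats::setNames(paste0("count.", am_ids)),
                       as.data.frame(planted_counts / D * 1e6) |>
                         stats::setNames(paste0("rpm.", am_ids)))
  decoys_out <- if (nrow(decoys)) {
    cbind(decoys, as.data.frame(decoy_counts) |>
            stats::setNames(paste0("count.", am_ids)))
  } else decoys

  manifest <- list(
    samples = do.call(rbind, sample_rows),
    planted = planted_out,
    planted_loci = stats::setNames(truth$planted_loci, planted$srna_id),
    decoys = decoys_out,
    targets = if (!is.null(transcriptome)) transcriptome$targets else NULL,
    composition = if (length(comp_rows)) do.call(rbind, comp_rows) else NULL,
    mirnas = truth$mirnas,
    repeat_unit = truth$repeat_unit,
    params = list(seed = config$seed, n_mock = config$n_mock,
                  n_am = config$n_am,
                  background_reads_per_library = D,
                  planted_rpm_range = config$planted_rpm_range,
                  five_prime_u_fraction = q_u, adapter = adapter))
  rownames(manifest$samples) <- NULL

  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- write_simulated_dataset(config, genomes, transcriptome,
                                     libraries, manifest, out_dir)
  }
  list(libraries = libraries, manifest = manifest, paths = paths)
}

# inject per-copy single-base substitution errors; errored copies become new
# low-count sequences and must never rescue a failed filter
apply_sequencing_errors <- function(counts, error_rate) {
  lens <- nchar(names(counts))
  p_read <- 1 - (1 - error_rate)^lens
  n_err <- stats::rbinom(length(counts), size = counts, prob = p_read)
  n_err <- pmin(n_err, counts - (counts >= 1))  # keep >= 1 intact copy
  err_seqs <- character(0)
  for (i in which(n_err > 0)) {
    s <- names(counts)[i]
    for (k in seq_len(n_err[i])) {
      pos <- sample.int(nchar(s), 1L)
      base <- substr(s, pos, pos)
      sub <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
      e <- s
      substr(e, pos, pos) <- sub
      err_seqs <- c(err_seqs, e)
    }
  }
  counts[n_err > 0] <- counts[n_err > 0] - n_err[n_err > 0]
  counts <- counts[counts > 0]
  if (length(err_seqs)) {
    extra <- tapply(rep(1, length(err_seqs)), err_seqs, sum)
    all <- c(counts, stats::setNames(as.numeric(extra), names(extra)))
    counts <- tapply(all, names(all), sum)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  counts
}

# write all dataset artifacts (FASTA/GFF3/FASTQ/TSV/JSON) to out_dir
write_simulated_dataset <- function(config, genomes, transcriptome, libraries,
                                    manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_fasta(genomes$host$contigs, p("host_genome.fasta"))
  write_fasta(genomes$fungus$contigs, p("fungus_genome.fasta"))
  write_gff3(genomes$host$features, p("host_features.gff3"))
  write_gff3(genomes$fungus$features, p("fungus_features.gff3"))
  if (!is.null(transcriptome)) write_fasta(transcriptome$cds, p("cds.fasta"))

  adapter <- fold_dna(config$adapter)
  # paths are relative to the sample sheet so the dataset is relocatable
  # (and byte-identical across output directories)
  sheet <- data.frame(sample_id = names(libraries),
                      condition = vapply(libraries, function(l) l$condition,
                                         character(1)),
                      path = paste0(names(libraries), ".fastq"),
                      stringsAsFactors = FALSE)
  for (sid in names(libraries)) {
    lib <- libraries[[sid]]
    inserts <- rep(names(lib$reads), lib$reads)
    n_junk <- lib$total_raw - lib$total_after_preprocess
    junk <- character(0)
    if (n_junk > 0) {
      n_noad <- ceiling(n_junk / 2)
      noad <- random_dna(config$read_length, n_noad)
      # make sure junk reads really lack the adapter seed
      bad <- grepl(substr(adapter, 1L, 8L), noad, fixed = TRUE)
      while (any(bad)) {
        noad[bad] <- random_dna(config$read_length, sum(bad))
        bad <- grepl(substr(adapter, 1L, 8L), noad, fixed = TRUE)
      }
      shorties <- paste0(random_dna(8L, n_junk - n_noad), adapter)
      junk <- c(noad, shorties)
    }
    reads <- c(paste0(inserts, adapter), junk)
    reads <- paste0(reads, strrep("A", config$read_length))
    reads <- substr(reads, 1L, config$read_length)
    reads <- sample(reads)  # seeded shuffle
    names(reads) <- sprintf("%s_r%07d", sid, seq_along(reads))
    write_fastq(reads, p(paste0(sid, ".fastq")))
  }
  write_sample_sheet(sheet, p("sample_sheet.tsv"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  list(dir = out_dir, sample_sheet = p("sample_sheet.tsv"),
       manifest = p("manifest.json"),
       host_genome = p("host_genome.fasta"),
       fungus_genome = p("fungus_genome.fasta"),
       host_gff = p("host_features.gff3"),
       fungus_gff = p("fungus_features.gff3"),
       cds = if (!is.null(transcriptome)) p("cds.fasta") else NULL)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_genomes()],
#' [simulate_transcriptome()] and [simulate_libraries()] under one seed,
#' optionally writing every artifact to disk.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list with `genomes`, `transcriptome`, `libraries`, `manifest`,
#'   `paths`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  genomes <- simulate_genomes(config)
  transcriptome <- simulate_transcriptome(config, genomes)
  libs <- simulate_libraries(config, genomes, transcriptome, out_dir)
  list(genomes = genomes, transcriptome = transcriptome,
       libraries = libs$libraries, manifest = libs$manifest,
       paths = libs$paths)
}
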