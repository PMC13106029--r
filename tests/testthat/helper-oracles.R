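# Independent brute-force oracles and small fixtures shared across tests.
# These deliberately re-derive results from first principles (substring
# scans, exhaustive enumeration) without touching the package's optimised
# code paths.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# brute-force perfect-match scan of one query against named contig strings;
# returns data.frame(contig, start, end, strand) in 0-based half-open coords
naive_map_scan <- function(query, contigs) {
  w <- nchar(query)
  out <- list()
  for (cn in names(contigs)) {
    s <- contigs[[cn]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") query else rc_chr(query)
      m <- gregexpr(pat, s, fixed = TRUE)[[1L]]
      if (m[1L] == -1L) next
      out[[length(out) + 1L]] <- data.frame(
        contig = cn, start = as.integer(m) - 1L,
        end = as.integer(m) - 1L + w, strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$start, res$strand), , drop = FALSE]
}

# exhaustive enumeration of every <=1-gap duplex configuration, scored from
# first principles on the sense-orientation site; returns the minimum score
oracle_min_duplex_score <- function(srna, site) {
  L <- nchar(srna)
  Ls <- nchar(site)
  sv <- strsplit(srna, "", fixed = TRUE)[[1L]]
  tv <- strsplit(site, "", fixed = TRUE)[[1L]]
  mult <- ifelse(seq_len(L) %in% 2:12, 2, 1)
  pair_pen <- function(a, b) {
    # a = sRNA base, b = site base (sense); WC and G:U checked directly
    if (b == chartr("ACGT", "TGCA", a)) return(0)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(0.5)
    1
  }
  # sRNA position k pairs site position (Ls - k + 1) after removing a
  # skipped site index / inserting an sRNA gap
  score_config <- function(gap_srna = 0L, skip_site_rc = 0L) {
    sc <- 0
    for (k in seq_len(L)) {
      if (gap_srna == k) {
        sc <- sc + 2 * mult[k]
        next
      }
      ridx <- k
      if (gap_srna > 0L && k > gap_srna) ridx <- k - 1L
      if (skip_site_rc > 0L && k >= skip_site_rc) ridx <- k + 1L
      site_idx <- Ls - ridx + 1L
      sc <- sc + mult[k] * pair_pen(sv[k], tv[site_idx])
    }
    if (skip_site_rc > 0L) {
      pb <- min(max(skip_site_rc - 1L, 1L), L)
      sc <- sc + 2 * mult[pb]
    }
    sc
  }
  if (Ls == L) return(score_config())
  if (Ls == L - 1L) return(min(vapply(1:L, function(g) score_config(gap_srna = g),
                                      numeric(1))))
  if (Ls == L + 1L) return(min(vapply(1:(L + 1L),
                                      function(b) score_config(skip_site_rc = b),
                                      numeric(1))))
  stop("oracle: unsupported length combination")
}

# naive adapter clip: first exact occurrence of the 8-nt adapter seed found
# by sliding-window comparison
naive_clip <- function(read, seed8) {
  n <- nchar(read)
  for (i in seq_len(max(0L, n - 7L))) {
    if (substr(read, i, i + 7L) == seed8) return(substr(read, 1L, i - 1L))
  }
  NA_character_
}

# scaled-down simulation settings used by the fast unit tests (the
# acceptance suite runs the full default configuration)
small_cfg <- function(seed = 1L, ...) {
  args <- list(seed = seed,
               host_genome_bp = 100000L, fungus_genome_bp = 60000L,
               background_reads_per_library = 20000,
               n_unique_host_fragments = 400L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
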