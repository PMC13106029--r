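# Plant-miRNA-style target prediction for candidate cross-kingdom sRNAs.
#
# An sRNA (5'->3') is aligned antiparallel to a candidate target site given
# in transcript sense orientation. Pair states per sRNA position are
# Watson-Crick (WC), G:U wobble (GU), mismatch (MM) or gap (GAP). The
# penalty score follows the standard plant target-prediction convention
# (miRU-style penalties): MM = 1, GU = 0.5,
# GAP = 2, each doubled at sRNA positions 2-12 (the seed and central
# region); reported hits must satisfy score <= 4.5 and a duplex
# free-energy ratio >= 0.7 against the perfect-complement duplex.

.BASE_LEVELS <- c("A", "C", "G", "T", "N")

encode_dna <- function(x) {
  match(strsplit(x, "", fixed = TRUE)[[1L]], .BASE_LEVELS)
}

# Penalty of pairing sRNA base a (row) against the corresponding base of the
# reverse-complemented site (column). Equal bases on the rc-site are WC pairs;
# G:U wobbles are sRNA-G vs rc-site-A (site U) and sRNA-U vs rc-site-C
# (site G). Column 5 (N) never pairs.
.PAIR_PENALTY <- {
  m <- matrix(1, 4L, 5L, dimnames = list(.BASE_LEVELS[1:4], .BASE_LEVELS))
  diag(m[, 1:4]) <- 0
  m[cbind(1:4, 1:4)] <- 0
  m["G", "A"] <- 0.5
  m["T", "C"] <- 0.5
  m
}

.PAIR_STATE <- {
  m <- matrix("MM", 4L, 5L, dimnames = list(.BASE_LEVELS[1:4], .BASE_LEVELS))
  m[cbind(1:4, 1:4)] <- "WC"
  m["G", "A"] <- "GU"
  m["T", "C"] <- "GU"
  m
}

# positional penalty multipliers: doubled in the seed/central region 2-12
position_multipliers <- function(len, seed_range = 2:12, seed_multiplier = 2) {
  w <- rep(1, len)
  w[intersect(seq_len(len), seed_range)] <- seed_multiplier
  w
}

#' Nearest-neighbour RNA/RNA duplex energy model
#'
#' Stack free energies (kcal/mol, 37 C) for adjacent Watson-Crick pairs,
#' keyed by the sRNA-strand dinucleotide, following the standard
#' nearest-neighbour parameterisation of RNA/RNA duplexes (Turner-style
#' values; the table is symmetric under reverse complement). Stacks in which
#' either pair is a G:U wobble contribute a fixed weak term `gu_stack`;
#' mismatched, gapped or bulge-interrupted neighbours contribute nothing.
#' The duplex initiation term defaults to 0: the free-energy *ratio* used
#' for target filtering compares two duplexes of the same sRNA, so a common
#' additive initiation offset is omitted by convention here, which also keeps
#' every partially paired duplex non-positive.
#'
#' @param gu_stack stack term (kcal/mol) for stacks involving a G:U pair.
#' @param initiation duplex initiation term (kcal/mol).
#' @return object of class `energy_model`.
#' @export
energy_model <- function(gu_stack = -0.5, initiation = 0) {
  stack <- c(AA = -0.93, AC = -2.24, AG = -2.08, AT = -1.10,
             CA = -2.11, CC = -3.26, CG = -2.36, CT = -2.08,
             GA = -2.35, GC = -3.42, GG = -3.26, GT = -2.24,
             TA = -1.33, TC = -2.35, TG = -2.11, TT = -0.93)
  stopifnot(all(stack <= 0), gu_stack <= 0)
  structure(list(stack = stack, gu_stack = gu_stack, initiation = initiation),
            class = "energy_model")
}

.duplex_lengths_ok <- function(n) n >= 15L && n <= 34L

# Build a duplex_alignment object from one enumerated configuration.
# srna/site are character strings; states is the per-sRNA-position state
# vector; site_pair_index maps each sRNA position to the 1-based sense
# coordinate of its partner base within the site (NA for GAP);
# gap_type/gap_pos/bulge_after describe the single allowed gap.
new_duplex_alignment <- function(srna, site, states, site_pair_index,
                                 gap_type = "none", gap_pos = 0L,
                                 bulge_after = NA_integer_, bulge_len = 0L) {
  structure(list(srna = srna, site = site, pair_states = states,
                 site_pair_index = site_pair_index, gap_type = gap_type,
                 gap_pos = as.integer(gap_pos),
                 bulge_after = as.integer(bulge_after),
                 bulge_len = as.integer(bulge_len)),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  sym <- c(WC = "|", GU = "o", MM = "x", GAP = "-")
  cat("sRNA 5'-", dna_to_rna(x$srna), "-3'\n", sep = "")
  cat("       ", paste(sym[x$pair_states], collapse = ""), "\n", sep = "")
  cat("site   ", dna_to_rna(x$site), " (sense 5'->3')",
      if (x$gap_type == "site_bulge")
        sprintf("  [%d-nt site bulge after sRNA position %d]",
                x$bulge_len, x$bulge_after) else "",
      "\n", sep = "")
  invisible(x)
}

#' Align an sRNA against a candidate target site
#'
#' Enumerates all duplex configurations with at most one gap (an unpaired
#' sRNA base when the site is one nucleotide shorter, or a single bulged
#' site base when it is one nucleotide longer) and returns the
#' minimum-score alignment of the sRNA to the reverse complement of the
#' site. Ties are broken in favour of fewer gaps, then the leftmost gap.
#'
#' @param srna sRNA sequence, 5'->3' (RNA or DNA alphabet, 15-34 nt).
#' @param site candidate site in transcript sense orientation, 5'->3';
#'   length within 1 nt of the sRNA length.
#' @return object of class `duplex_alignment`.
#' @export
align_duplex <- function(srna, site) {
  srna <- fold_dna(srna); site <- fold_dna(site)
  L <- nchar(srna); Ls <- nchar(site)
  if (!.duplex_lengths_ok(L) || !.duplex_lengths_ok(Ls)) {
    stop("sRNA and site lengths must be within 15-34 nt")
  }
  if (abs(Ls - L) > 1L) stop("site length must be within 1 nt of sRNA length")
  s <- encode_dna(srna)
  rcsite <- revcomp(site)
  r <- encode_dna(rcsite)
  w <- position_multipliers(L)
  state_of <- function(k, ridx) .PAIR_STATE[cbind(s[k], r[ridx])]
  pen_of <- function(k, ridx) sum(w[k] * .PAIR_PENALTY[cbind(s[k], r[ridx])])
  # site sense index of rc-site position j
  sense <- function(j) Ls - j + 1L

  best <- NULL
  consider <- function(score, ngap, gapleft, build) {
    key <- c(score, ngap, gapleft)
    if (is.null(best) || score < best$key[1] - 1e-12 ||
        (abs(score - best$key[1]) <= 1e-12 &&
         (ngap < best$key[2] ||
          (ngap == best$key[2] && gapleft < best$key[3])))) {
      best <<- list(key = key, build = build)
    }
  }

  if (Ls == L) {
    sc <- pen_of(1:L, 1:L)
    consider(sc, 0L, Inf, function() {
      new_duplex_alignment(srna, site, state_of(1:L, 1:L), sense(1:L))
    })
  }
  if (Ls == L - 1L) {
    for (g in 1:L) {
      k1 <- seq_len(g - 1L); k2 <- if (g < L) (g + 1L):L else integer(0)
      sc <- pen_of(k1, k1) + 2 * w[g] + pen_of(k2, k2 - 1L)
      local({
        g <- g; k1 <- k1; k2 <- k2
        consider(sc, 1L, g, function() {
          states <- character(L); spi <- rep(NA_integer_, L)
          states[k1] <- state_of(k1, k1); spi[k1] <- sense(k1)
          states[g] <- "GAP"
          if (length(k2)) { states[k2] <- state_of(k2, k2 - 1L); spi[k2] <- sense(k2 - 1L) }
          new_duplex_alignment(srna, site, states, spi,
                               gap_type = "srna_gap", gap_pos = g)
        })
      })
    }
  }
  if (Ls == L + 1L) {
    for (b in 1:(L + 1L)) {
      k1 <- seq_len(b - 1L); k2 <- if (b <= L) b:L else integer(0)
      pb <- min(max(b - 1L, 1L), L)
      sc <- pen_of(k1, k1) + 2 * w[pb] + pen_of(k2, k2 + 1L)
      local({
        b <- b; k1 <- k1; k2 <- k2; pb <- pb
        consider(sc, 1L, b, function() {
          states <- character(L); spi <- rep(NA_integer_, L)
          states[k1] <- state_of(k1, k1); spi[k1] <- sense(k1)
          if (length(k2)) { states[k2] <- state_of(k2, k2 + 1L); spi[k2] <- sense(k2 + 1L) }
          new_duplex_alignment(srna, site, states, spi,
                               gap_type = "site_bulge", gap_pos = pb,
                               bulge_after = b - 1L, bulge_len = 1L)
        })
      })
    }
  }
  best$build()
}

#' Score a duplex alignment
#'
#' Penalty sum: mismatch 1, G:U wobble 0.5, gap 2, each multiplied by 2 at
#' sRNA positions 2-12. A bulged site base contributes the gap penalty at
#' the sRNA position 5' of the bulge.
#'
#' @param aln a `duplex_alignment`.
#' @param mm,gu,gap base penalties.
#' @param seed_range sRNA positions at which penalties are doubled.
#' @param seed_multiplier penalty multiplier within `seed_range`.
#' @return non-negative numeric score.
#' @export
score_alignment <- function(aln, mm = 1, gu = 0.5, gap = 2,
                            seed_range = 2:12, seed_multiplier = 2) {
  L <- nchar(aln$srna)
  w <- position_multipliers(L, seed_range, seed_multiplier)
  base <- c(WC = 0, GU = gu, MM = mm, GAP = gap)
  sc <- sum(w * base[aln$pair_states])
  if (aln$gap_type == "site_bulge") sc <- sc + gap * w[aln$gap_pos]
  sc
}

#' Hybridization free energy of a duplex alignment
#'
#' Sums nearest-neighbour stack terms over adjacent paired sRNA positions
#' whose site partners are also adjacent (a gap or bulge interrupts
#' stacking), plus the initiation term. Stacks between two Watson-Crick
#' pairs take the model's sequence-dependent value; stacks involving a G:U
#' pair take the model's fixed `gu_stack` term.
#'
#' @param aln a `duplex_alignment`.
#' @param model an [energy_model()].
#' @return duplex free energy in kcal/mol (<= initiation term).
#' @export
duplex_energy <- function(aln, model = energy_model()) {
  L <- nchar(aln$srna)
  states <- aln$pair_states
  spi <- aln$site_pair_index
  paired <- states %in% c("WC", "GU")
  e <- model$initiation
  if (L >= 2L) {
    k <- 1:(L - 1L)
    stackable <- paired[k] & paired[k + 1L] & !is.na(spi[k]) &
      !is.na(spi[k + 1L]) & (spi[k] - spi[k + 1L] == 1L)
    if (any(stackable)) {
      kk <- k[stackable]
      din <- substr(rep(aln$srna, length(kk)), kk, kk + 1L)
      wc <- states[kk] == "WC" & states[kk + 1L] == "WC"
      e <- e + sum(ifelse(wc, model$stack[din], model$gu_stack))
    }
  }
  unname(e)
}

#' Free-energy ratio of an sRNA-site duplex
#'
#' Ratio of the hybridization energy of the observed duplex to that of the
#' perfect-complement duplex of the same sRNA, clamped to \[0, 1\]; 1 for a
#' perfect site, near 0 for unrelated sequence.
#'
#' @param srna sRNA sequence (5'->3').
#' @param site candidate site, transcript sense.
#' @param model an [energy_model()].
#' @return numeric in \[0, 1\].
#' @export
energy_ratio <- function(srna, site, model = energy_model()) {
  srna <- fold_dna(srna)
  perfect <- align_duplex(srna, revcomp(srna))
  e_perf <- duplex_energy(perfect, model)
  if (e_perf >= 0) stop("degenerate sRNA: perfect-complement duplex energy >= 0")
  aln <- align_duplex(srna, site)
  min(max(duplex_energy(aln, model) / e_perf, 0), 1)
}

# ---- vectorised transcript scan ---------------------------------------------

# Minimum duplex score for every window of lengths L-1, L, L+1 of one
# transcript, computed with the same enumeration as align_duplex() but
# vectorised over window starts. Returns a data.frame of windows with
# columns rstart (start on the reverse-complemented transcript), site_len,
# score.
scan_transcript_scores <- function(srna, transcript) {
  L <- nchar(srna)
  N <- nchar(transcript)
  if (N < L - 1L) {
    return(data.frame(rstart = integer(), site_len = integer(),
                      score = numeric()))
  }
  s <- encode_dna(srna)
  r <- encode_dna(revcomp(transcript))
  w <- position_multipliers(L)
  rpad <- c(5L, r, 5L)  # sentinels; padded cells are never part of a valid sum
  Cn <- N - L + 3L      # columns c = d + 2, offsets d in -1 .. N-L+1
  idx <- outer(1:L, 1:Cn, function(k, cc) cc + k - 1L)
  B <- matrix(.PAIR_PENALTY[cbind(rep(s, Cn), rpad[idx])], nrow = L) * w
  Bz <- rbind(0, apply(B, 2L, cumsum))  # Bz[g+1, c] = sum over k <= g

  out <- vector("list", 3L)
  # ungapped: window start j uses offset d = j - 1 (column j + 1)
  j0 <- seq_len(N - L + 1L)
  out[[1L]] <- data.frame(rstart = j0, site_len = L,
                          score = Bz[L + 1L, j0 + 1L])
  # sRNA gap at g: site length L-1, window start j; k<g at d=j-1 (col j+1),
  # k>g at d=j-2 (col j)
  if (N >= L - 1L) {
    j1 <- seq_len(N - L + 2L)
    sc <- matrix(Inf, length(j1), L)
    for (g in 1:L) {
      sc[, g] <- Bz[g, j1 + 1L] + 2 * w[g] + (Bz[L + 1L, j1] - Bz[g + 1L, j1])
    }
    out[[2L]] <- data.frame(rstart = j1, site_len = L - 1L,
                            score = apply(sc, 1L, min))
  }
  # bulged site base before sRNA position b: site length L+1, window start j;
  # k<b at d=j-1 (col j+1), k>=b at d=j (col j+2)
  if (N >= L + 1L) {
    j2 <- seq_len(N - L)
    sc <- matrix(Inf, length(j2), L + 1L)
    for (b in 1:(L + 1L)) {
      pb <- min(max(b - 1L, 1L), L)
      sc[, b] <- Bz[b, j2 + 1L] + 2 * w[pb] +
        (Bz[L + 1L, j2 + 2L] - Bz[b, j2 + 2L])
    }
    out[[3L]] <- data.frame(rstart = j2, site_len = L + 1L,
                            score = apply(sc, 1L, min))
  }
  do.call(rbind, out)
}

#' Predict host transcript targets of sRNAs
#'
#' Scans every window of each transcript (window lengths within 1 nt of the
#' sRNA length), aligns the sRNA to the window, and reports hits passing
#' both cutoffs: penalty score <= `score_cutoff` and free-energy ratio >=
#' `ratio_cutoff`. Overlapping windows on the same transcript are clustered
#' and only the best hit (lowest score, then highest ratio) per cluster is
#' reported. Cleavability is called on each hit (see [call_cleavage()]).
#'
#' @param srnas named character vector of sRNA sequences (names are sRNA ids).
#' @param transcripts named character vector of transcript (CDS) sequences,
#'   or a data.frame as returned by [read_fasta()].
#' @param score_cutoff maximum penalty score for a reported hit.
#' @param ratio_cutoff minimum free-energy ratio for a reported hit.
#' @param model an [energy_model()].
#' @return data.frame of target hits with columns `srna_id`, `transcript_id`,
#'   `site_start` (0-based), `site_len`, `site`, `score`, `energy_ratio`,
#'   `cleavable`, `cleavage_site` (1-based transcript coordinate of the base
#'   opposite sRNA position 10; cleavage occurs between it and the preceding
#'   base) and `alignment` (pair-state string, sRNA 5'->3').
#' @export
predict_targets <- function(srnas, transcripts, score_cutoff = 4.5,
                            ratio_cutoff = 0.7, model = energy_model()) {
  if (is.data.frame(transcripts)) {
    transcripts <- stats::setNames(transcripts$seq, transcripts$id)
  }
  if (is.null(names(srnas))) {
    names(srnas) <- sprintf("sRNA%02d", seq_along(srnas))
  }
  srnas <- vapply(srnas, fold_dna, character(1))
  transcripts <- vapply(transcripts, fold_dna, character(1))
  empty <- data.frame(srna_id = character(), transcript_id = character(),
                      site_start = integer(), site_len = integer(),
                      site = character(), score = numeric(),
                      energy_ratio = numeric(), cleavable = logical(),
                      cleavage_site = integer(), alignment = character(),
                      stringsAsFactors = FALSE)
  if (!length(transcripts)) {
    warning("empty transcriptome; no targets predicted")
    return(empty)
  }
  res <- list()
  for (sid in names(srnas)) {
    srna <- srnas[[sid]]
    for (tid in names(transcripts)) {
      tx <- transcripts[[tid]]
      N <- nchar(tx)
      wins <- scan_transcript_scores(srna, tx)
      wins <- wins[wins$score <= score_cutoff + 1e-9, , drop = FALSE]
      if (!nrow(wins)) next
      # convert rc-transcript window start to sense coordinates
      wins$start0 <- N - (wins$rstart + wins$site_len - 1L)
      hits <- lapply(seq_len(nrow(wins)), function(i) {
        st0 <- wins$start0[i]; len <- wins$site_len[i]
        site <- substr(tx, st0 + 1L, st0 + len)
        aln <- align_duplex(srna, site)
        sc <- score_alignment(aln)
        if (sc > score_cutoff + 1e-9) return(NULL)
        er <- {
          e_perf <- duplex_energy(align_duplex(srna, revcomp(srna)), model)
          min(max(duplex_energy(aln, model) / e_perf, 0), 1)
        }
        if (er < ratio_cutoff - 1e-9) return(NULL)
        cl <- call_cleavage(aln)
        data.frame(srna_id = sid, transcript_id = tid, site_start = st0,
                   site_len = len, site = site, score = sc, energy_ratio = er,
                   cleavable = cl$cleavable,
                   cleavage_site = if (is.na(cl$site_index)) NA_integer_
                                   else st0 + cl$site_index,
                   alignment = paste(c(WC = "|", GU = "o", MM = "x",
                                       GAP = "-")[aln$pair_states],
                                     collapse = ""),
                   stringsAsFactors = FALSE)
      })
      hits <- do.call(rbind, hits)
      if (is.null(hits) || !nrow(hits)) next
      # cluster overlapping windows; keep the best hit per cluster
      hits <- hits[order(hits$score, -hits$energy_ratio, hits$site_start,
                         hits$site_len), , drop = FALSE]
      kept <- list()
      for (i in seq_len(nrow(hits))) {
        h <- hits[i, ]
        ov <- any(vapply(kept, function(k) {
          h$site_start < k$site_start + k$site_len &&
            k$site_start < h$site_start + h$site_len
        }, logical(1)))
        if (!ov) kept[[length(kept) + 1L]] <- h
      }
      res[[length(res) + 1L]] <- do.call(rbind, kept)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$score, -out$energy_ratio, out$srna_id,
                   out$transcript_id, out$site_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call AGO-mediated cleavability of a duplex
#'
#' A target is called cleavable when sRNA positions 10 and 11 (5'-counted)
#' are both Watson-Crick paired and no bulge interrupts the duplex between
#' them; a G:U wobble at position 10-11 blocks slicing. The predicted
#' cleavage site lies between the site bases opposite positions 11 and 10.
#'
#' @param aln a `duplex_alignment`.
#' @param positions the two sRNA positions that must be Watson-Crick paired.
#' @return list with `cleavable` (logical) and `site_index` (1-based sense
#'   position within the site of the base opposite `positions[1]`).
#' @export
call_cleavage <- function(aln, positions = c(10L, 11L)) {
  states <- aln$pair_states
  ok <- all(states[positions] == "WC")
  if (ok && aln$gap_type == "site_bulge" && !is.na(aln$bulge_after) &&
      aln$bulge_after >= positions[1L] && aln$bulge_after < positions[2L]) {
    ok <- FALSE
  }
  idx <- aln$site_pair_index[positions[1L]]
  list(cleavable = ok, site_index = if (is.na(idx)) NA_integer_ else idx)
}

# ---- STTM design ------------------------------------------------------------

# 48-nt spacer used between tandem mimic sites, following the short tandem
# target mimic literature
.STTM_SPACER48 <- "GTTGTTGTTGTTATGGTCTAATTTAAATATGGTCTAAAGAAGAAGAAT"

# alignment of an sRNA with its own bulged mimic site (all WC, 3-nt bulge
# between positions 10 and 11)
mimic_alignment <- function(srna, mimic, bulge_len = 3L) {
  L <- nchar(srna)
  spi <- integer(L)
  spi[1:10] <- (L - (1:10) + 1L) + bulge_len
  spi[11:L] <- L - (11:L) + 1L
  new_duplex_alignment(srna, mimic, rep("WC", L), spi,
                       gap_type = "site_bulge", gap_pos = 10L,
                       bulge_after = 10L, bulge_len = bulge_len)
}

#' Design a short tandem target mimic (STTM) construct
#'
#' Each mimic site is the reverse complement of its sRNA with a 3-nt "CTA"
#' bulge inserted between the bases opposite sRNA positions 10 and 11, so
#' the sRNA binds but cannot slice; mimics are joined by spacers. Every
#' mimic is validated to be non-cleavable by [call_cleavage()] while still
#' binding-competent (penalty score of the bulge-free duplex within the
#' target-prediction cutoff).
#'
#' @param srnas named character vector of 1-8 distinct sRNA sequences.
#' @param spacer_length spacer length in nt; the canonical 48-nt STTM spacer
#'   is used (recycled/truncated for other lengths).
#' @param score_cutoff binding-competence threshold for validation.
#' @return object of class `sttm_construct`: list with `mimics` (data.frame
#'   of per-sRNA mimic sites and validation flags) and `construct` (full
#'   construct sequence).
#' @export
design_sttm <- function(srnas, spacer_length = 48L, score_cutoff = 4.5) {
  if (length(srnas) < 1L || length(srnas) > 8L) stop("provide 1-8 sRNAs")
  srnas <- vapply(srnas, fold_dna, character(1))
  if (anyDuplicated(srnas)) stop("duplicate input sRNAs")
  if (is.null(names(srnas))) names(srnas) <- sprintf("sRNA%02d", seq_along(srnas))
  spacer <- substr(strrep(.STTM_SPACER48, ceiling(spacer_length / 48L)),
                   1L, spacer_length)
  mimics <- lapply(names(srnas), function(id) {
    srna <- srnas[[id]]
    L <- nchar(srna)
    rc <- revcomp(srna)
    # bases opposite positions 11..L occupy rc[1..L-10]; insert the bulge
    # between them and the bases opposite positions 10..1
    mimic <- paste0(substr(rc, 1L, L - 10L), "CTA", substr(rc, L - 9L, L))
    aln <- mimic_alignment(srna, mimic)
    bind_score <- score_alignment(align_duplex(srna, rc))
    data.frame(srna_id = id, srna = srna, mimic = mimic,
               mimic_len = nchar(mimic),
               non_cleavable = !call_cleavage(aln)$cleavable,
               binding_score = bind_score,
               binding_ok = bind_score <= score_cutoff,
               stringsAsFactors = FALSE)
  })
  mimics <- do.call(rbind, mimics)
  construct <- paste(mimics$mimic, collapse = spacer)
  structure(list(mimics = mimics, spacer = spacer, construct = construct),
            class = "sttm_construct")
}

#' @export
print.sttm_construct <- function(x, ...) {
  cat(sprintf("STTM construct: %d mimic site(s), %d-nt spacer, %d nt total\n",
              nrow(x$mimics), nchar(x$spacer), nchar(x$construct)))
  cat(sprintf("  all non-cleavable: %s; all binding-competent: %s\n",
              all(x$mimics$non_cleavable), all(x$mimics$binding_ok)))
  invisible(x)
}

#' Scramble a target site into a composition-matched negative control
#'
#' Returns a seeded uniform permutation of the site's bases, redrawn until
#' the permuted site no longer passes the target-prediction score cutoff
#' against its cognate sRNA. Composition is preserved exactly.
#'
#' @param site target site sequence (>= 15 nt).
#' @param seed integer seed for the permutation.
#' @param cognate_srna the sRNA the site must no longer be complementary to.
#' @param score_cutoff score above which the site counts as decomplementarized.
#' @param max_tries bounded number of redraws before giving up.
#' @return scrambled site sequence.
#' @export
scramble_site <- function(site, seed, cognate_srna, score_cutoff = 4.5,
                          max_tries = 100L) {
  site <- fold_dna(site); cognate_srna <- fold_dna(cognate_srna)
  if (nchar(site) < 15L) stop("site must be >= 15 nt")
  bases <- strsplit(site, "", fixed = TRUE)[[1L]]
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  for (i in seq_len(max_tries)) {
    perm <- paste(sample(bases), collapse = "")
    sc <- score_alignment(align_duplex(cognate_srna, perm))
    if (sc > score_cutoff) return(perm)
  }
  stop("could not decomplementarize site within ", max_tries,
       " permutations (low-complexity site?)")
}
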