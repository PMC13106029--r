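mk_srna <- function(len = 21) {
  s <- strsplit(rand_seq(len), "", fixed = TRUE)[[1]]
  s[10] <- sample(c("G", "T"), 1)  # keep a wobble-capable central position
  paste(s, collapse = "")
}

test_that("a perfect site aligns all Watson-Crick with no gap", {
  set.seed(1)
  srna <- mk_srna()
  aln <- align_duplex(srna, rc_chr(srna))
  expect_true(all(aln$pair_states == "WC"))
  expect_equal(aln$gap_type, "none")
  expect_equal(score_alignment(aln), 0)
})

test_that("a single site edit produces the designed pair state", {
  srna <- "TGACTAGGATCAGGTCAATGT"
  site <- rc_chr(srna)
  # G opposite the sRNA U at position 15 -> G:U wobble
  k <- 15
  stopifnot(substr(srna, k, k) == "T")
  substr(site, 21 - k + 1, 21 - k + 1) <- "G"
  aln <- align_duplex(srna, site)
  expect_equal(aln$pair_states[k], "GU")
  expect_equal(score_alignment(aln), 0.5)
})

test_that("alignment scores equal the exhaustive <=1-gap enumeration", {
  set.seed(99)
  for (i in seq_len(200)) {
    L <- sample(15:28, 1)
    srna <- rand_seq(L)
    type <- sample(1:3, 1)
    site <- switch(type,
      rand_seq(L + sample(c(-1L, 0L, 1L), 1)),      # unrelated
      {                                              # degraded complement
        s <- rc_chr(srna)
        for (j in sample(L, sample(1:6, 1))) {
          substr(s, j, j) <- sample(c("A", "C", "G", "T"), 1)
        }
        s
      },
      {                                              # complement with indel
        s <- rc_chr(srna)
        p <- sample(L - 1, 1)
        if (runif(1) < 0.5) {
          paste0(substr(s, 1, p), sample(c("A", "C", "G", "T"), 1),
                 substr(s, p + 1, L))
        } else {
          paste0(substr(s, 1, p - 1), substr(s, p + 1, L))
        }
      })
    if (nchar(site) < 15 || nchar(site) > 34) next
    got <- score_alignment(align_duplex(srna, site))
    expect_equal(got, oracle_min_duplex_score(srna, site),
                 info = paste(srna, site))
  }
})

test_that("scoring closed forms match the penalty scheme", {
  srna <- "TGACTAGGATCAGGTCAATGT"
  perfect <- rc_chr(srna)
  expect_equal(score_alignment(align_duplex(srna, perfect)), 0)
  gu15 <- perfect
  substr(gu15, 21 - 15 + 1, 21 - 15 + 1) <- "G"   # wobble outside the seed
  expect_equal(score_alignment(align_duplex(srna, gu15)), 0.5)
  mm5 <- perfect
  substr(mm5, 21 - 5 + 1, 21 - 5 + 1) <- "T"      # mismatch in the seed
  aln <- align_duplex(srna, mm5)
  expect_equal(aln$pair_states[5], "MM")
  expect_equal(score_alignment(aln), 2)
})

test_that("duplex energy equals an independent sum over the stack table", {
  model <- energy_model()
  srna <- "TGACTAGGATCAGGTCAATGT"
  aln <- align_duplex(srna, rc_chr(srna))
  expected <- model$initiation
  for (k in 1:(nchar(srna) - 1)) {
    expected <- expected + model$stack[[substr(srna, k, k + 1)]]
  }
  expect_equal(duplex_energy(aln, model), expected)
  # no paired positions -> initiation only
  all_mm <- chartr("ACGT", "CAGT", rc_chr(srna))  # break A/C pairings
  aln2 <- align_duplex(srna, all_mm)
  paired <- aln2$pair_states %in% c("WC", "GU")
  expected2 <- duplex_energy(aln2, model)
  if (!any(paired)) expect_equal(expected2, model$initiation)
  expect_lte(expected2, model$initiation)
})

test_that("any single edit destabilizes a perfect duplex", {
  set.seed(5)
  model <- energy_model()
  for (i in 1:100) {
    srna <- rand_seq(21)
    perfect <- rc_chr(srna)
    e0 <- duplex_energy(align_duplex(srna, perfect), model)
    p <- sample(21, 1)
    variant <- perfect
    cur <- substr(variant, p, p)
    substr(variant, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    e1 <- duplex_energy(align_duplex(srna, variant), model)
    expect_lt(e0, e1, label = paste(srna, p))
  }
})

test_that("the energy ratio is 1 for perfect sites and decays with edits", {
  set.seed(6)
  srna <- mk_srna()
  expect_equal(energy_ratio(srna, rc_chr(srna)), 1)
  # monotone non-increasing along a single-edit degradation series
  site <- rc_chr(srna)
  prev <- 1
  for (p in c(16, 13, 9, 5, 19, 2)) {
    cur <- substr(site, p, p)
    substr(site, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    r <- energy_ratio(srna, site)
    expect_lte(r, prev + 1e-12)
    expect_gte(r, 0); expect_lte(r, 1)
    prev <- r
  }
  scrambled <- scramble_site(rc_chr(srna), seed = 42, cognate_srna = srna)
  expect_lt(energy_ratio(srna, scrambled), 0.7)
})

test_that("target prediction recovers planted sites and only those", {
  cfg <- small_cfg(seed = 301)
  g <- simulate_genomes(cfg)
  tx <- simulate_transcriptome(cfg, g)
  srnas <- stats::setNames(g$truth$planted$sequence, g$truth$planted$srna_id)
  hits <- predict_targets(srnas, tx$cds)
  expected <- tx$targets[tx$targets$design != "non_target", ]
  expect_equal(nrow(hits), nrow(expected))
  key <- function(d) paste(d$srna_id, d$transcript_id)
  expect_setequal(key(hits), key(expected))
  m <- merge(hits, tx$targets, by = c("srna_id", "transcript_id"))
  expect_equal(m$site_start.x, m$site_start.y)
  expect_true(all(m$cleavable[m$design == "perfect"]))
  expect_true(all(!m$cleavable[m$design == "wobble_10_11"]))
  # hits pass the cutoffs they were filtered on
  expect_true(all(hits$score <= 4.5 & hits$energy_ratio >= 0.7))
  # relaxing both cutoffs can only grow the hit set
  sub_cds <- tx$cds[tx$cds$id %in% tx$targets$transcript_id[1:4], ]
  relaxed <- predict_targets(srnas[1], sub_cds, score_cutoff = 12,
                             ratio_cutoff = 0)
  strict <- predict_targets(srnas[1], sub_cds)
  expect_gte(nrow(relaxed), nrow(strict))
  expect_true(all(key(strict) %in% key(relaxed)))
  expect_warning(none <- predict_targets(srnas[1], character(0)), "empty")
  expect_equal(nrow(none), 0L)
})

test_that("cleavability requires Watson-Crick pairing at positions 10-11", {
  srna <- "TGACTAGGAGCAGGTCAATGT"   # position 10 is G
  perfect <- rc_chr(srna)
  aln <- align_duplex(srna, perfect)
  cl <- call_cleavage(aln)
  expect_true(cl$cleavable)
  expect_equal(cl$site_index, 21 - 10 + 1)
  # G:U wobble opposite position 10 blocks slicing
  wob <- perfect
  substr(wob, 21 - 10 + 1, 21 - 10 + 1) <- "T"
  aw <- align_duplex(srna, wob)
  expect_equal(aw$pair_states[10], "GU")
  expect_false(call_cleavage(aw)$cleavable)
  # a mismatch at position 3 alone leaves the site cleavable
  mm3 <- perfect
  substr(mm3, 21 - 3 + 1, 21 - 3 + 1) <- "C"  # A:C mismatch
  am <- align_duplex(srna, mm3)
  expect_equal(am$pair_states[3], "MM")
  expect_true(call_cleavage(am)$cleavable)
})

test_that("STTM constructs carry bulged, non-cleavable, binding mimics", {
  set.seed(8)
  one <- design_sttm(stats::setNames(mk_srna(21), "a"))
  expect_equal(one$mimics$mimic_len, 24L)  # 21 + 3-nt bulge
  srnas <- stats::setNames(vapply(c(21, 22, 23, 24), mk_srna, character(1)),
                           paste0("s", 1:4))
  quad <- design_sttm(srnas)
  expect_equal(nrow(quad$mimics), 4L)
  expect_equal(nchar(quad$construct),
               sum(nchar(srnas) + 3) + 3 * 48)
  expect_true(all(quad$mimics$non_cleavable))
  expect_true(all(quad$mimics$binding_ok))
  for (i in 1:4) {
    expect_equal(length(gregexpr(quad$mimics$mimic[i], quad$construct,
                                 fixed = TRUE)[[1]]), 1L)
  }
  expect_error(design_sttm(c(a = srnas[[1]], b = srnas[[1]])), "duplicate")
})

test_that("scrambled controls preserve composition but lose complementarity", {
  set.seed(12)
  srna <- mk_srna()
  site <- rc_chr(srna)
  scr <- scramble_site(site, seed = 3, cognate_srna = srna)
  expect_equal(sort(strsplit(scr, "")[[1]]), sort(strsplit(site, "")[[1]]))
  expect_gt(score_alignment(align_duplex(srna, scr)), 4.5)
  # scrambled versions of planted sites are no longer predicted targets
  tx <- stats::setNames(paste0(rand_seq(80), scr, rand_seq(80)), "scrambled")
  expect_equal(nrow(predict_targets(stats::setNames(srna, "s"), tx)), 0L)
  # a mononucleotide site cannot be decomplementarized from its cognate
  expect_error(scramble_site(strrep("A", 16), 1, strrep("T", 16)),
               "permutations")
})
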