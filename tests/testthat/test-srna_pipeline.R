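# Shared scaled-down dataset with planted ground truth.
cfg <- small_cfg(seed = 202)
sim <- simulate_dataset(cfg)
genomes <- sim$genomes
manifest <- sim$manifest
host_index <- build_index(genomes$host)
fungal_index <- build_index(genomes$fungus)
all_seqs <- sort(unique(unlist(lapply(sim$libraries,
                                      function(l) names(l$reads)))))
cls <- classify_sequences(all_seqs, host_index, fungal_index)
am_libs <- sim$libraries[grepl("^AM", names(sim$libraries))]
mock_libs <- sim$libraries[grepl("^mock", names(sim$libraries))]

adapter <- "AGATCGGAAGAGCACACGTCT"

test_that("adapter clipping recovers inserts and rejects bad reads", {
  insert <- rand_seq(21)
  res <- clip_adapter(paste0(insert, adapter), adapter)
  expect_equal(res$status, "ok")
  expect_equal(res$insert, insert)
  expect_equal(clip_adapter(rand_seq(40), adapter)$status, "no_adapter")
  expect_equal(clip_adapter(paste0(rand_seq(8), adapter), adapter)$status,
               "too_short")
  expect_equal(clip_adapter(paste0(rand_seq(35), adapter), adapter)$status,
               "too_long")
  expect_error(clip_adapter("ACGT", "ACGTAC"), "at least 8")
})

test_that("clipping agrees with a naive substring-search oracle", {
  set.seed(33)
  seed8 <- substr(adapter, 1, 8)
  reads <- vapply(seq_len(1000), function(i) {
    paste0(rand_seq(sample(10:40, 1)), adapter, rand_seq(5))
  }, character(1))
  got <- clip_adapter(reads, adapter, min_len = 1, max_len = 60)
  naive <- vapply(reads, naive_clip, character(1), seed8 = seed8,
                  USE.NAMES = FALSE)
  expect_equal(got$insert, naive)
})

test_that("collapsing conserves read counts", {
  lib <- collapse_reads(c("ACGTACGTACGTACGTA", "ACGTACGTACGTACGTA",
                          "GGGTACGTACGTACGTA"), "s", "AM")
  expect_equal(unname(lib$reads), c(2, 1))
  empty <- collapse_reads(character(0), "s", "mock")
  expect_equal(empty$total_after_preprocess, 0)
  set.seed(4)
  pool <- vapply(1:50, function(i) rand_seq(20), character(1))
  stream <- sample(pool, 10000, replace = TRUE)
  lib2 <- collapse_reads(stream, "s", "AM")
  expect_equal(sum(lib2$reads), 10000)
})

test_that("exact mapping honours the strand contract", {
  contigs <- c(c1 = paste0(rand_seq(200), "ACGGATTACGGATCAGGTCAA",
                           rand_seq(200)))
  g <- annotated_genome("fungus", contigs)
  idx <- build_index(g)
  hit <- map_exact("ACGGATTACGGATCAGGTCAA", idx)
  expect_equal(hit$start, 200L)
  expect_equal(hit$strand, "+")
  rc_hit <- map_exact(rc_chr("ACGGATTACGGATCAGGTCAA"), idx)
  expect_equal(rc_hit$start, 200L)  # forward-strand coordinates
  expect_equal(rc_hit$strand, "-")
  # palindromic query: both strands reported at the same position
  pal <- "ACGTACGTACGTACGTACGT"
  pal <- paste0(pal, rc_chr(pal))  # hmm too long; build true palindrome
  pal16 <- "ACGTGCAT"
  pal16 <- paste0(pal16, rc_chr(pal16))  # 16-nt reverse-complement palindrome
  g2 <- annotated_genome("host", c(c1 = paste0(rand_seq(50), pal16,
                                               rand_seq(50))))
  hits <- map_exact(pal16, build_index(g2))
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(unique(hits$start), 50L)
  expect_error(map_exact(rand_seq(10), idx), "15-34")
})

test_that("exact mapping equals a naive full-genome scan on random queries", {
  set.seed(77)
  contigs <- genomes$fungus$contigs
  planted_sub <- vapply(manifest$planted$sequence[1:6], function(s) {
    substr(s, 1, 15 + sample(0:6, 1))
  }, character(1))
  queries <- unique(c(
    planted_sub,
    manifest$planted$sequence,
    vapply(seq_len(300), function(i) {  # substrings of the genome
      cn <- sample(names(contigs), 1)
      w <- sample(15:34, 1)
      st <- sample(nchar(contigs[[cn]]) - w, 1)
      s <- substr(contigs[[cn]], st + 1, st + w)
      if (runif(1) < 0.5) rc_chr(s) else s
    }, character(1)),
    vapply(seq_len(200), function(i) rand_seq(sample(15:34, 1)),
           character(1))))
  expect_gte(length(queries), 500L)
  got <- map_reads_exact(queries, fungal_index)
  for (q in queries) {
    mine <- got[got$seq == q, c("contig", "start", "end", "strand")]
    rownames(mine) <- NULL
    ref <- naive_map_scan(q, contigs)
    rownames(ref) <- NULL
    expect_equal(mine, ref, info = q)
  }
})

test_that("origin classification matches the planted truth", {
  ori <- cls$origins
  planted <- manifest$planted
  idx <- match(planted$sequence, ori$seq)
  expect_true(all(ori$origin[idx] == "fungal"))
  expect_equal(ori$n_fungal_loci[idx], planted$n_loci)
  d <- manifest$decoys
  expect_equal(ori$origin[match(d$sequence[d$violated_filter == "matches_host"],
                                ori$seq)], "ambiguous")
  expect_equal(ori$origin[match(
    d$sequence[d$violated_filter == "no_perfect_fungal_match"], ori$seq)],
    "unassigned")
  # host background maps to host
  mir <- manifest$mirnas$seq
  expect_true(all(ori$origin[match(mir, ori$seq)] == "host"))
})

test_that("origin classes partition each library's reads", {
  for (lib in sim$libraries) {
    co <- classify_origin(lib, host_index, fungal_index, cls)
    expect_equal(sum(co$summary$reads_by_origin),
                 lib$total_after_preprocess)
    expect_equal(sum(co$origins$count), lib$total_after_preprocess)
  }
})

test_that("size/5'-nt profiles are correctly normalized", {
  lib <- read_library("t", "AM", c(TGACTAGGATCAGGTCAATGT = 10))
  ori <- data.frame(seq = "TGACTAGGATCAGGTCAATGT", count = 10, length = 21,
                    origin = "fungal", n_host_loci = 0, n_fungal_loci = 1,
                    stringsAsFactors = FALSE)
  prof <- size_nt_profile(lib, ori, "fungal")
  expect_equal(sum(prof), 1e6)
  expect_equal(prof["21", "U"], 1e6)
  expect_equal(sum(prof != 0), 1L)
  expect_warning(empty <- size_nt_profile(lib, ori, "host"), "all-zero")
  expect_true(all(empty == 0))
})

test_that("profiles of simulated AM libraries total 1e6 RPM", {
  co <- classify_origin(sim$libraries$AM2, host_index, fungal_index, cls)
  for (subset in c("host", "fungal")) {
    prof <- size_nt_profile(sim$libraries$AM2, co$origins, subset)
    expect_equal(sum(prof), 1e6, tolerance = 1e-6)
  }
})

test_that("feature assignment uses the class priority order", {
  feats <- feature_table(contig = c("c1", "c1"), start = c(100L, 150L),
                         end = c(300L, 400L), strand = c("+", "-"),
                         class = c("repeat", "mRNA"),
                         name = c("r1", "m1"))
  locus_in_repeat <- data.frame(contig = "c1", start = 120L, end = 141L,
                                strand = "+", stringsAsFactors = FALSE)
  expect_equal(assign_feature(locus_in_repeat, feats), "repeat")
  # overlapping both repeat and mRNA: repeat wins by priority
  locus_both <- data.frame(contig = "c1", start = 280L, end = 301L,
                           strand = "+", stringsAsFactors = FALSE)
  expect_equal(assign_feature(locus_both, feats), "repeat")
  locus_outside <- data.frame(contig = "c1", start = 500L, end = 521L,
                              strand = "+", stringsAsFactors = FALSE)
  expect_equal(assign_feature(locus_outside, feats), "intergenic")
})

test_that("feature composition reproduces the generator's class mix", {
  for (sid in c("AM1", "AM4")) {
    co <- classify_origin(sim$libraries[[sid]], host_index, fungal_index, cls)
    comp <- feature_composition(co$origins, cls$fungal_loci,
                                genomes$fungus$features)
    expect_equal(sum(comp), 1, tolerance = 1e-9)
    truth <- manifest$composition[manifest$composition$sample_id == sid, ]
    expect_equal(comp[truth$class], stats::setNames(truth$fraction,
                                                    truth$class),
                 tolerance = 0.02)
  }
})

test_that("candidate selection recovers the planted truth exactly", {
  cand <- select_candidates(am_libs, mock_libs, cls,
                            fungal_features = genomes$fungus$features)
  sel <- cand$sequence[cand$candidate]
  expect_setequal(sel, manifest$planted$sequence)
  flag_for <- c(size = "size_ok", rpm = "rpm_ok_all_am",
                present_in_mock = "absent_in_mock",
                no_perfect_fungal_match = "fungal_exclusive",
                matches_host = "fungal_exclusive")
  flags <- c("size_ok", "rpm_ok_all_am", "absent_in_mock", "fungal_exclusive")
  d <- manifest$decoys
  for (i in seq_len(nrow(d))) {
    row <- cand[cand$sequence == d$sequence[i], ]
    expect_equal(nrow(row), 1L)
    failing <- flags[!unlist(row[flags])]
    expect_equal(failing, unname(flag_for[d$violated_filter[i]]),
                 info = d$violated_filter[i])
  }
  # multi-locus candidates report all four repeat loci
  rep_rows <- cand[cand$sequence %in%
                     manifest$planted$sequence[manifest$planted$family == "F1"], ]
  expect_true(all(rep_rows$n_fungal_loci == 4L))
  expect_true(all(rep_rows$feature_class == "repeat"))
})

test_that("the RPM filter boundary is strict and mock reads disqualify", {
  srna <- rand_seq(22)
  other <- rand_seq(22)
  fungus <- annotated_genome("fungus",
                             c(f1 = paste0(rand_seq(60), srna, rand_seq(30),
                                           other, rand_seq(60))))
  host <- annotated_genome("host", c(h1 = rand_seq(300)))
  hidx <- build_index(host); fidx <- build_index(fungus)
  cls2 <- classify_sequences(c(srna, other), hidx, fidx)
  # exactly 25.0 RPM: 1 read among 40,000 fungus-mapped reads
  am <- list(read_library("AM1", "AM",
                          stats::setNames(c(1, 39999), c(srna, other))))
  mock <- list(read_library("mock1", "mock",
                            stats::setNames(2, rand_seq(21))))
  cand <- suppressWarnings(
    select_candidates(am, mock, classify_sequences(
      c(srna, other, names(mock[[1]]$reads)), hidx, fidx)))
  row <- cand[cand$sequence == srna, ]
  expect_equal(row$rpm.AM1, 25)
  expect_false(row$rpm_ok_all_am)
  expect_false(row$candidate)
  # a single raw mock read disqualifies an otherwise perfect candidate
  am2 <- list(read_library("AM1", "AM",
                           stats::setNames(c(50, 100), c(srna, other))))
  mock2 <- list(read_library("mock1", "mock", stats::setNames(1, srna)))
  cand2 <- select_candidates(am2, mock2, cls2)
  row2 <- cand2[cand2$sequence == srna, ]
  expect_false(row2$absent_in_mock)
  expect_false(row2$candidate)
  expect_true(row2$rpm_ok_all_am)
  expect_error(select_candidates(list(), mock2, cls2), "at least one AM")
})
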