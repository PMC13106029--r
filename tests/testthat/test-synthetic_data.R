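# One scaled-down simulated dataset is shared by most checks in this file.
cfg <- small_cfg(seed = 101)
sim <- simulate_dataset(cfg)
genomes <- sim$genomes
manifest <- sim$manifest

test_that("the same seed reproduces byte-identical artifacts", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- small_cfg(seed = 11, background_reads_per_library = 5000,
                  planted_rpm_range = c(300, 800))
  simulate_dataset(c1, d1)
  simulate_dataset(c1, d2)
  f1 <- list.files(d1)
  expect_true(length(f1) > 10)
  expect_identical(f1, list.files(d2))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # a different seed yields different genomes
  d3 <- withr::local_tempdir()
  c2 <- small_cfg(seed = 12, background_reads_per_library = 5000,
                  planted_rpm_range = c(300, 800))
  simulate_dataset(c2, d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "fungus_genome.fasta"))),
    unname(tools::md5sum(file.path(d3, "fungus_genome.fasta")))))
})

test_that("the tandem repeat family has exactly four dispersed copies", {
  ft <- genomes$fungus$features
  f1 <- ft[grepl("^F1_copy", ft$name), ]
  expect_equal(nrow(f1), 4L)
  expect_true(all(f1$class == "repeat" & f1$subtype == "tandem"))
  # scanning the emitted genome confirms the copy number
  n <- ckRNAi:::count_occurrences(manifest$repeat_unit,
                                  genomes$fungus$contigs)
  expect_equal(n, 4L)
})

test_that("planted sRNAs never perfectly match the host genome", {
  for (s in manifest$planted$sequence) {
    expect_equal(nrow(naive_map_scan(s, genomes$host$contigs)), 0L, info = s)
  }
})

test_that("manifest loci are confirmed by an independent substring scan", {
  for (i in seq_len(nrow(manifest$planted))) {
    found <- naive_map_scan(manifest$planted$sequence[i],
                            genomes$fungus$contigs)
    truth <- manifest$planted_loci[[manifest$planted$srna_id[i]]]
    expect_equal(nrow(found), manifest$planted$n_loci[i])
    expect_setequal(paste(found$contig[found$strand == "+"],
                          found$start[found$strand == "+"]),
                    paste(truth$contig, truth$start))
  }
})

test_that("planted read counts in the libraries match the manifest", {
  am_ids <- manifest$samples$sample_id[manifest$samples$condition == "AM"]
  for (ai in seq_along(am_ids)) {
    lib <- sim$libraries[[am_ids[ai]]]
    counts <- manifest$planted[[paste0("count.", am_ids[ai])]]
    expect_equal(unname(lib$reads[manifest$planted$sequence]), counts)
    # realized per-library RPM is above the candidate threshold
    expect_true(all(counts / lib$total_after_preprocess * 1e6 > 25))
  }
  for (mid in manifest$samples$sample_id[manifest$samples$condition == "mock"]) {
    lib <- sim$libraries[[mid]]
    expect_true(all(is.na(match(manifest$planted$sequence,
                                names(lib$reads)))))
  }
})

test_that("decoys are constructed to violate exactly their named filter", {
  d <- manifest$decoys
  expect_setequal(d$violated_filter,
                  c("size", "rpm", "present_in_mock",
                    "no_perfect_fungal_match", "matches_host"))
  expect_equal(d$length[d$violated_filter == "size"], 19L)
  # the rpm decoy is missing from the first AM library only
  rpm_counts <- unlist(d[d$violated_filter == "rpm",
                         grepl("^count\\.", names(d))])
  expect_equal(unname(rpm_counts[1]), 0)
  expect_true(all(rpm_counts[-1] > 0))
  # the mock decoy has exactly one read in the first mock library
  mock1 <- sim$libraries$mock1
  dseq <- d$sequence[d$violated_filter == "present_in_mock"]
  expect_equal(unname(mock1$reads[dseq]), 1)
  # genome membership of the sequence matches the violated filter
  for (i in seq_len(nrow(d))) {
    in_f <- nrow(naive_map_scan(d$sequence[i], genomes$fungus$contigs)) > 0
    in_h <- nrow(naive_map_scan(d$sequence[i], genomes$host$contigs)) > 0
    vf <- d$violated_filter[i]
    expect_equal(in_f, vf != "no_perfect_fungal_match", info = vf)
    expect_equal(in_h, vf == "matches_host", info = vf)
  }
})

test_that("planted target sites carry the designed pairing defects", {
  tg <- sim$transcriptome$targets
  cds <- stats::setNames(sim$transcriptome$cds$seq, sim$transcriptome$cds$id)
  expect_setequal(unique(tg$design),
                  c("perfect", "sub_cutoff", "wobble_10_11", "non_target"))
  pl <- stats::setNames(manifest$planted$sequence, manifest$planted$srna_id)
  for (i in seq_len(nrow(tg))) {
    site <- substr(cds[[tg$transcript_id[i]]], tg$site_start[i] + 1L,
                   tg$site_start[i] + tg$site_len[i])
    srna <- pl[[tg$srna_id[i]]]
    aln <- align_duplex(srna, site)
    sc <- score_alignment(aln)
    switch(tg$design[i],
      perfect = expect_equal(sc, 0),
      sub_cutoff = {
        expect_gt(sc, 0); expect_lte(sc, 4.5)
        expect_gte(energy_ratio(srna, site), 0.7)
      },
      wobble_10_11 = {
        expect_equal(aln$pair_states[10], "GU")
        expect_false(call_cleavage(aln)$cleavable)
      },
      non_target = expect_gt(sc, 4.5))
  }
})

test_that("5'-U fractions follow the configured AGO-loading bias", {
  # unique sequences are independent draws at the configured probability
  q <- cfg$five_prime_u_fraction
  lib <- sim$libraries$AM1
  host_seqs <- names(lib$reads)
  frac <- mean(substr(host_seqs, 1, 1) == "T")
  n <- length(host_seqs)
  expect_lt(abs(frac - q), 3 * sqrt(q * (1 - q) / n))
})

test_that("unrepresentable planted RPM at low depth raises an error", {
  tiny <- small_cfg(seed = 3, background_reads_per_library = 5000,
                    planted_rpm_range = c(26, 40))
  g <- simulate_genomes(tiny)
  expect_error(simulate_libraries(tiny, g), "not representable")
})

test_that("sequencing errors conserve totals and stay at count 1", {
  ecfg <- small_cfg(seed = 9, error_rate = 0.01)
  g <- simulate_genomes(ecfg)
  s2 <- simulate_libraries(ecfg, g)
  lib <- s2$libraries$AM1
  expect_equal(sum(lib$reads), lib$total_after_preprocess)
  expect_equal(lib$total_after_preprocess,
               ecfg$background_reads_per_library)
})

test_that("library totals and fungal totals are internally consistent", {
  s <- manifest$samples
  expect_true(all(s$total_after_preprocess ==
                    cfg$background_reads_per_library))
  expect_true(all(s$total_raw >= s$total_after_preprocess))
  # the only fungus-mapped mock read is the planted present_in_mock decoy
  expect_equal(sum(s$fungal_mapped_total[s$condition == "mock"]), 1)
  expect_true(all(s$fungal_mapped_total[s$condition == "AM"] > 0))
  for (sid in s$sample_id) {
    expect_equal(sum(sim$libraries[[sid]]$reads),
                 s$total_after_preprocess[s$sample_id == sid])
  }
})
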