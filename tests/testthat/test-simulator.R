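test_that("synthetic references are deterministic and carry a faithful truth table", {
  sp <- synthetic_spec(seed = 7L)
  sr <- make_synthetic_reference(sp)
  sr2 <- make_synthetic_reference(sp)
  expect_identical(as.character(sr$reference[[1]]),
                   as.character(sr2$reference[[1]]))
  expect_identical(sr$truth$true_variants, sr2$truth$true_variants)
  # planted structures are found by the scanners at exactly their extent
  win <- fetch_window(sr$reference, gintervals(sp$chrom, 0L, sp$length))
  ih <- select_planted_hits(sr, scan_ivs(win))
  ph <- select_planted_hits(sr, scan_ps(win))
  expect_length(ih$hits, length(sp$planted_ivs))
  expect_length(ph$hits, length(sp$planted_ps))
  # truth sites equal the blacklist entries of the planted structures
  bl <- rbind(ivs_blacklist(ih), ps_blacklist(ph))
  expect_setequal(entry_key(sr$truth$expected_sites), entry_key(bl))
  # true variants sit on reference bases and off every blacklist site
  s <- as.character(sr$reference[[1]])
  tv <- sr$truth$true_variants
  expect_identical(substring(s, tv$pos, tv$pos), tv$ref)
  full <- build_blacklist(sr$reference, gintervals(sp$chrom, 0L, sp$length))
  ov <- outer(tv$pos - 1L, full$entries$start, ">=") &
    outer(tv$pos - 1L, full$entries$end, "<")
  expect_false(any(ov))
})

test_that("plants that cannot fit are rejected", {
  sp <- synthetic_spec(length = 200L,
                       planted_ivs = rep(list(list(arm_len = 30L,
                                                   spacer_len = 10L,
                                                   interruption = list(
                                                     offset = 5L,
                                                     kind = "mismatch",
                                                     len = 1L))), 4))
  expect_error(make_synthetic_reference(sp), "overlap")
})

test_that("a planted gap interruption produces indel truth sites that are recovered", {
  sp <- synthetic_spec(seed = 12L,
                       planted_ivs = list(list(arm_len = 14L,
                                               spacer_len = 6L,
                                               interruption = list(
                                                 offset = 5L, kind = "gap",
                                                 len = 2L))),
                       planted_ps = list(), true_variants = list())
  sr <- make_synthetic_reference(sp)
  bed <- gintervals(sp$chrom, 0L, sp$length)
  bl <- build_blacklist(sr$reference, bed)
  expect_true(all(entry_key(sr$truth$expected_sites) %in%
                    entry_key(bl$entries)))
  lens <- nchar(sr$truth$expected_sites$ref) -
    nchar(sr$truth$expected_sites$predicted_alt)
  expect_setequal(lens, c(2L, -2L))  # one deletion and one insertion
})

test_that("sonication chimeras are heteroduplex with the induced allele on one strand", {
  sp <- synthetic_spec(seed = 3L, planted_ps = list(), true_variants = list())
  sr <- make_synthetic_reference(sp)
  win <- fetch_window(sr$reference, gintervals(sp$chrom, 0L, sp$length))
  ih <- select_planted_hits(sr, scan_ivs(win))
  tpl <- simulate_sonication_chimeras(sr$reference, ih, 3000L, seed = 5L)
  expect_length(tpl, 3000L)
  het <- Filter(function(t) t$is_chimeric && t$het, tpl)
  expect_gt(length(het), 10L)
  site_keys <- entry_key(sr$truth$expected_sites)
  for (t in het[1:5]) {
    ev <- t$induced_site
    expect_true(paste(sp$chrom, ev$pos0, ev$pos0 + nchar(ev$ref), ev$alt)
                %in% site_keys)
  }
  # breaks missing the arms give non-chimeric templates
  expect_true(any(!vapply(tpl, `[[`, TRUE, "is_chimeric")))
  # a perfect IVS yields chimeric templates but no induced site
  spp <- synthetic_spec(seed = 4L, planted_ivs = list(list(
    arm_len = 12L, spacer_len = 6L,
    interruption = list(offset = 4L, kind = "mismatch", len = 1L))),
    planted_ps = list(), true_variants = list())
  # build a perfect structure by scanning a mismatch-free plant
  perfect <- Biostrings::DNAStringSet(c(synth1 = paste0(
    strrep("C", 60), "TTTTATTT", strrep("C", 6), revcomp("TTTTATTT"),
    strrep("C", 60))))
  winp <- fetch_window(perfect, gintervals("synth1", 0L, 142L))
  ihp <- scan_ivs(winp, ivs_params(min_spacer = 5L))
  tplp <- simulate_sonication_chimeras(perfect, ihp, 500L, seed = 6L)
  chim <- Filter(function(t) t$is_chimeric, tplp)
  expect_gt(length(chim), 0L)
  expect_true(all(vapply(chim, function(t) is.null(t$induced_site),
                         logical(1))))
})

test_that("enzymatic chimeras write the induced allele into both strands", {
  sp <- synthetic_spec(seed = 9L, planted_ivs = list(), true_variants = list())
  sr <- make_synthetic_reference(sp)
  win <- fetch_window(sr$reference, gintervals(sp$chrom, 0L, sp$length))
  ph <- select_planted_hits(sr, scan_ps(win))
  tpl <- simulate_enzymatic_chimeras(sr$reference, ph, 400L, seed = 8L)
  expect_true(all(vapply(tpl, `[[`, TRUE, "is_chimeric")))
  expect_true(all(!vapply(tpl, `[[`, TRUE, "het")))  # homoduplex
  ind <- Filter(function(t) length(t$events) > 0, tpl)
  expect_gt(length(ind), 0L)
  # reads from a single induced homoduplex template all carry the allele
  reads <- pcr_and_sample(ind[1], sr$reference, cycles = 4L,
                          n_reads = 300L, seed = 10L)
  expect_true(all(reads$carries_mutation))
  expect_true(all(reads$is_chimeric))
})

test_that("PCR doubles molecules exactly and reads are seed-reproducible", {
  sp <- synthetic_spec(seed = 11L, planted_ps = list(), true_variants = list())
  sr <- make_synthetic_reference(sp)
  win <- fetch_window(sr$reference, gintervals(sp$chrom, 0L, sp$length))
  ih <- select_planted_hits(sr, scan_ivs(win))
  tpl <- Filter(function(t) t$is_chimeric && t$het,
                simulate_sonication_chimeras(sr$reference, ih, 3000L,
                                             seed = 2L))
  r1 <- pcr_and_sample(tpl, sr$reference, cycles = 1L, n_reads = 50L,
                       seed = 21L)
  expect_equal(attr(r1, "molecules_per_template"), 2)  # one per strand
  r2 <- pcr_and_sample(tpl, sr$reference, cycles = 1L, n_reads = 50L,
                       seed = 21L)
  expect_identical(r1$seq, r2$seq)
  expect_identical(r1$carries_mutation, r2$carries_mutation)
})

test_that("heteroduplex templates put the mutation in half the chimeric reads", {
  sp <- synthetic_spec(seed = 13L, planted_ps = list(), true_variants = list())
  sr <- make_synthetic_reference(sp)
  win <- fetch_window(sr$reference, gintervals(sp$chrom, 0L, sp$length))
  ih <- select_planted_hits(sr, scan_ivs(win))
  het <- Filter(function(t) t$is_chimeric && t$het,
                simulate_sonication_chimeras(sr$reference, ih, 4000L,
                                             seed = 14L))
  reads <- pcr_and_sample(het, sr$reference, cycles = 10L,
                          n_reads = 10000L, seed = 15L)
  expect_true(all(reads$is_chimeric))
  frac <- mean(reads$carries_mutation)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(reads)))
})

test_that("every chimeric read carries an alignable reverse-complement tail", {
  sp <- synthetic_spec(seed = 17L)
  sr <- make_synthetic_reference(sp)
  s <- as.character(sr$reference[[1]])
  win <- fetch_window(sr$reference, gintervals(sp$chrom, 0L, sp$length))
  ih <- select_planted_hits(sr, scan_ivs(win))
  ph <- select_planted_hits(sr, scan_ps(win))
  tpl <- c(Filter(function(t) t$is_chimeric,
                  simulate_sonication_chimeras(sr$reference, ih, 2000L,
                                               seed = 18L)),
           simulate_enzymatic_chimeras(sr$reference, ph, 50L, seed = 19L))
  reads <- pcr_and_sample(tpl, sr$reference, cycles = 5L, n_reads = 200L,
                          seed = 20L)
  for (i in seq_len(nrow(reads))) {
    clip <- if (reads$clip_side[i] == "right")
      substr(reads$seq[i], nchar(reads$seq[i]) - reads$clip_len[i] + 1L,
             nchar(reads$seq[i]))
    else substr(reads$seq[i], 1L, reads$clip_len[i])
    expect_true(grepl(revcomp(clip), s, fixed = TRUE))
  }
})

test_that("naive pileup calls planted variants and respects thresholds", {
  sp <- synthetic_spec(seed = 23L, planted_ivs = list(), planted_ps = list(),
                       true_variants = list(list(vaf = 0.3)))
  sr <- make_synthetic_reference(sp)
  bg <- background_templates(sr$reference, 300L, sr$truth$true_variants,
                             seed = 24L)
  reads <- pcr_and_sample(bg, sr$reference, cycles = 6L, n_reads = 3000L,
                          seed = 25L)
  calls <- naive_pileup(reads, sr$reference, min_vaf = 0.05,
                        min_alt_reads = 2L)
  tv <- sr$truth$true_variants
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, tv$pos)
  expect_equal(calls$alt, tv$alt)
  expect_lt(abs(calls$vaf - tv$vaf), 0.1)
  # raising min_alt_reads above the simulated support silences the call
  expect_equal(nrow(naive_pileup(reads, sr$reference, min_vaf = 0.05,
                                 min_alt_reads = 100000L)), 0L)
  # zero templates sample zero reads
  expect_equal(nrow(pcr_and_sample(bg, sr$reference, cycles = 2L,
                                   n_reads = 0L, seed = 1L)), 0L)
})

test_that("simulated FASTQ keeps truth flags in comments", {
  sp <- synthetic_spec(seed = 29L, planted_ps = list(), true_variants = list())
  sr <- make_synthetic_reference(sp)
  win <- fetch_window(sr$reference, gintervals(sp$chrom, 0L, sp$length))
  ih <- select_planted_hits(sr, scan_ivs(win))
  tpl <- Filter(function(t) t$is_chimeric,
                simulate_sonication_chimeras(sr$reference, ih, 2000L,
                                             seed = 30L))
  reads <- pcr_and_sample(tpl[1:5], sr$reference, cycles = 3L,
                          n_reads = 10L, seed = 31L)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  lines <- readLines(fq)
  expect_length(lines, 40L)
  expect_true(all(grepl("^@read", lines[seq(1, 40, 4)])))
  expect_identical(lines[seq(2, 40, 4)], reads$seq)
})
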