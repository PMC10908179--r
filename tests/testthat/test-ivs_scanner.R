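test_that("k-mer census counts follow the closed form", {
  expect_equal(kmer_census(strrep("A", 10), 3, 3)$total, 8L)
  cc <- kmer_census(strrep("C", 10), 2, 5)
  expect_equal(cc$total, 30L)  # 9 + 8 + 7 + 6
  expect_equal(unname(cc$by_k), c(9L, 8L, 7L, 6L))
  aa <- kmer_census("AAAA", 2, 2)
  expect_equal(aa$total, 3L)
  expect_equal(aa$kmers, c("AA", "AA", "AA"))  # duplicates retained
  expect_error(kmer_census(strrep("A", 10), 2, 6), "L/2")
  # formula equals direct substring enumeration
  set.seed(3)
  for (rep in 1:10) {
    L <- sample(10:60, 1)
    kmin <- sample(2:4, 1)
    kmax <- sample(kmin:(L %/% 2L), 1)
    cs <- kmer_census(rand_seq(L), kmin, kmax)
    expect_equal(cs$total, sum(L - (kmin:kmax) + 1L))
    expect_equal(length(cs$kmers), cs$total)
  }
})

test_that("scan_ivs finds a perfect planted inverted repeat", {
  w <- mkwin(paste0("AACCGGTA", "TTTTT", "TACCGGTT"))
  h <- scan_ivs(w, ivs_params())
  expect_length(h$hits, 1L)
  expect_equal(h$hits[[1]]$aligned_len, 8L)
  expect_equal(h$hits[[1]]$spacer_len, 5L)
  expect_length(h$hits[[1]]$interruptions, 0L)
  expect_equal(unname(h$hits[[1]]$arm1), c(0L, 8L))
  expect_equal(unname(h$hits[[1]]$arm2), c(13L, 21L))
})

test_that("scan_ivs reports a single internal mismatch with its bases", {
  w <- mkwin(paste0("AACCGGTA", "TTTTT", "TACGGGTT"))
  h <- scan_ivs(w, ivs_params(seed_len = 3L))
  expect_length(h$hits, 1L)
  it <- h$hits[[1]]$interruptions[[1]]
  expect_equal(it$kind, "mismatch")
  expect_equal(it$pos1, 4L)   # arm1 offset 4
  expect_equal(it$pos2, 16L)  # mirrored arm2 site
  expect_equal(c(it$bases1, it$bases2), c("G", "G"))
})

test_that("scan_ivs bridges a gap on one arm", {
  # arm1 = AACCGGTA, arm2 = rc(arm1) with GG inserted 3 bp from its start
  arm1 <- "AACCGGTA"
  arm2 <- paste0(substr(revcomp(arm1), 1, 3), "GG",
                 substr(revcomp(arm1), 4, 8))
  w <- mkwin(paste0(arm1, "TTTTT", arm2))
  h <- scan_ivs(w, ivs_params(seed_len = 3L))
  kinds <- unlist(lapply(h$hits, function(x)
    vapply(x$interruptions, `[[`, "", "kind")))
  expect_true("gap_arm2" %in% kinds)
  gh <- h$hits[[which(vapply(h$hits, function(x)
    any(vapply(x$interruptions, `[[`, "", "kind") == "gap_arm2"),
    logical(1)))[1]]]
  it <- gh$interruptions[[which(vapply(gh$interruptions, `[[`, "",
                                       "kind") == "gap_arm2")]]
  expect_equal(it$length, 2L)
  expect_equal(it$bases2, "GG")
})

test_that("random-window hits always satisfy the structural contract", {
  set.seed(11)
  p <- ivs_params()
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (rep in 1:20) {
    s <- rand_seq(150)
    h <- scan_ivs(mkwin(s), p)
    for (hit in h$hits) {
      expect_gte(hit$spacer_len, p$min_spacer)
      expect_lte(hit$spacer_len, p$max_spacer)
      expect_gte(hit$aligned_len, p$min_arm)
      expect_lte(hit$arm1[["end"]], hit$arm2[["start"]])
      # arms are exact reverse complements outside interruptions:
      # remove interrupted bases from each arm and compare
      v <- strsplit(s, "")[[1]]
      a <- (hit$arm1[["start"]] + 1L):hit$arm1[["end"]]
      b <- (hit$arm2[["start"]] + 1L):hit$arm2[["end"]]
      drop1 <- drop2 <- integer(0)
      for (it in hit$interruptions) {
        if (!is.na(it$pos1))
          drop1 <- c(drop1, (it$pos1 + 1L):(it$pos1 + ifelse(
            it$kind == "gap_arm1", it$length, 1L)))
        if (!is.na(it$pos2))
          drop2 <- c(drop2, (it$pos2 + 1L):(it$pos2 + ifelse(
            it$kind == "gap_arm2", it$length, 1L)))
      }
      a <- setdiff(a, drop1); b <- setdiff(b, drop2)
      expect_identical(paste(v[a], collapse = ""),
                       revcomp(paste(v[b], collapse = "")))
    }
  }
})

test_that("scanning the reverse complement mirrors the structure set", {
  set.seed(23)
  for (rep in 1:10) {
    s <- rand_seq(200)
    L <- nchar(s)
    h1 <- scan_ivs(mkwin(s), ivs_params(max_interrupt = 1L))
    h2 <- scan_ivs(mkwin(revcomp(s)), ivs_params(max_interrupt = 1L))
    arms1 <- sort(vapply(h1$hits, function(h)
      sprintf("%d-%d/%d-%d", h$arm1[["start"]], h$arm1[["end"]],
              h$arm2[["start"]], h$arm2[["end"]]), ""))
    # mirror: arm1' = L - arm2 end .. L - arm2 start, roles swapped
    arms2m <- sort(vapply(h2$hits, function(h)
      sprintf("%d-%d/%d-%d", L - h$arm2[["end"]], L - h$arm2[["start"]],
              L - h$arm1[["end"]], L - h$arm1[["start"]]), ""))
    expect_identical(arms1, arms2m)
  }
})

test_that("scan_ivs equals the brute-force oracle at max_interrupt 1", {
  set.seed(101)
  p <- ivs_params(max_interrupt = 1L)
  for (rep in 1:15) {
    s <- rand_seq(140)
    expect_identical(scan_ivs_signatures(scan_ivs(mkwin(s), p)),
                     oracle_scan_ivs1(s), label = paste("window", rep))
  }
})

test_that("ivs_blacklist applies the complement-of-partner rule on both sides", {
  w <- mkwin(paste0("AACCGGTA", "TTTTT", "TACGGGTT"))
  h <- scan_ivs(w, ivs_params(seed_len = 3L))
  bl <- ivs_blacklist(h)
  expect_equal(nrow(bl), 2L)
  expect_equal(sort(bl$start), c(4L, 16L))
  expect_true(all(bl$predicted_alt == "C"))  # complement of partner G
  expect_true(all(bl$ref == "G"))
  # perfect structure contributes nothing
  hp <- scan_ivs(mkwin(paste0("AACCGGTA", "TTTTT", "TACCGGTT")))
  expect_equal(nrow(ivs_blacklist(hp)), 0L)
  # interruption too close to an arm end is excluded
  expect_equal(nrow(ivs_blacklist(h, ivs_params(min_edge = 4L))), 0L)
  # roi restriction drops sites outside the target
  roi <- gintervals("chrT", 0L, 10L)
  blr <- ivs_blacklist(h, roi = roi)
  expect_equal(blr$start, 4L)
})

test_that("gap interruptions yield left-normalized deletion and insertion entries", {
  arm1 <- "AACCGGTA"
  arm2 <- paste0(substr(revcomp(arm1), 1, 3), "GG",
                 substr(revcomp(arm1), 4, 8))
  s <- paste0(arm1, "TTTTT", arm2)
  h <- scan_ivs(mkwin(s), ivs_params(seed_len = 3L))
  bl <- ivs_blacklist(h)
  types <- ifelse(nchar(bl$ref) > nchar(bl$predicted_alt), "del",
                  ifelse(nchar(bl$ref) < nchar(bl$predicted_alt), "ins",
                         "snv"))
  expect_true("del" %in% types && "ins" %in% types)
  # every entry's ref matches the reference at its span
  for (i in seq_len(nrow(bl)))
    expect_identical(substr(s, bl$start[i] + 1L, bl$end[i]), bl$ref[i])
  # deletion removes the gap bases (GG) on arm2
  del <- bl[types == "del", ][1, ]
  expect_equal(nchar(del$ref) - nchar(del$predicted_alt), 2L)
})

test_that("raising thresholds never adds blacklist entries", {
  set.seed(31)
  for (rep in 1:8) {
    s <- rand_seq(200)
    h0 <- scan_ivs(mkwin(s))
    n0 <- nrow(ivs_blacklist(h0))
    for (p in list(ivs_params(min_arm = 10L), ivs_params(min_spacer = 8L),
                   ivs_params(min_edge = 3L))) {
      expect_lte(nrow(ivs_blacklist(scan_ivs(mkwin(s), p), p)), n0)
    }
  }
})
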