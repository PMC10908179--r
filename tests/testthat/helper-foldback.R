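# Shared fixtures and independent brute-force oracles.

# A reference_window directly from a sequence string (0-based offset).
mkwin <- function(s, start = 0L, chrom = "chrT") {
  fetch_window(Biostrings::DNAStringSet(stats::setNames(s, chrom)),
               gintervals(chrom, start, start + nchar(s)))
}

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

entry_key <- function(d) paste(d$chrom, d$start, d$end, d$predicted_alt)

# canonical signature of an IVS structure for set comparison
# (0-based genomic arm intervals plus interruption descriptors)
ivs_signature <- function(a1s, a1e, a2s, a2e, ints) {
  paste0(a1s, "-", a1e, "/", a2s, "-", a2e, "|",
         paste(ints, collapse = ";"))
}

scan_ivs_signatures <- function(hits) {
  sort(vapply(hits$hits, function(h) {
    ints <- vapply(h$interruptions, function(it)
      sprintf("%s@%s/%s", it$kind,
              ifelse(is.na(it$pos1), ".", it$pos1),
              ifelse(is.na(it$pos2), ".", it$pos2)), "")
    ivs_signature(h$arm1[["start"]], h$arm1[["end"]],
                  h$arm2[["start"]], h$arm2[["end"]], ints)
  }, ""))
}

# Brute-force oracle for scan_ivs at max_interrupt = 1: per anti-diagonal
# run decomposition; candidates are maximal exact pairing runs, joins of
# two runs across one internal mismatch column, and joins across a single
# 1-base gap on either arm (adjacent anti-diagonal). Criteria filters and
# containment-among-satisfying are then applied, mirroring the contract
# but through an entirely different algorithm than the scanner.
oracle_scan_ivs1 <- function(s, min_spacer = 5L, max_spacer = 300L,
                             min_arm = 8L) {
  L <- nchar(s)
  v <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  cands <- list()
  runs_by_d <- vector("list", 2L * L)
  for (d in 3:(2L * L - 1L)) {
    xlo <- max(1L, d - L); xhi <- (d - 1L) %/% 2L
    if (xlo > xhi) next
    xs <- xlo:xhi
    ys <- d - xs
    ok <- v[xs] != "N" & v[ys] != "N" & v[ys] == comp[v[xs]]
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    rx1 <- xs[starts[r$values]]; rx2 <- xs[ends[r$values]]
    if (length(rx1))
      runs_by_d[[d]] <- data.frame(x1 = rx1, x2 = rx2)
    for (k in seq_along(rx1))
      cands[[length(cands) + 1L]] <- list(a1 = rx1[k], a2 = rx2[k],
                                          b1 = d - rx2[k], b2 = d - rx1[k],
                                          ints = character(0))
    # joins across one internal mismatch column
    for (p in which(!ok)) {
      if (p == 1L || p == length(ok)) next
      if (!ok[p - 1L] || !ok[p + 1L]) next
      xp <- xs[p]; yp <- d - xp
      if (v[xp] == "N" || v[yp] == "N") next
      lk <- which(rx2 == xp - 1L); rk <- which(rx1 == xp + 1L)
      cands[[length(cands) + 1L]] <- list(
        a1 = rx1[lk], a2 = rx2[rk], b1 = d - rx2[rk], b2 = d - rx1[lk],
        ints = sprintf("mismatch@%d/%d", xp - 1L, yp - 1L))
    }
  }
  # joins across a single 1-base gap on one arm
  for (d in 3:(2L * L - 1L)) {
    r1s <- runs_by_d[[d]]
    if (is.null(r1s)) next
    for (k in seq_len(nrow(r1s))) {
      e1 <- r1s$x2[k]
      r2s <- if (d + 1L <= 2L * L - 1L) runs_by_d[[d + 1L]] else NULL
      if (!is.null(r2s)) {
        j <- which(r2s$x1 == e1 + 2L)
        if (length(j) && v[e1 + 1L] != "N")
          cands[[length(cands) + 1L]] <- list(
            a1 = r1s$x1[k], a2 = r2s$x2[j],
            b1 = d + 1L - r2s$x2[j], b2 = d - r1s$x1[k],
            ints = sprintf("gap_arm1@%d/.", e1))
      }
      r2s <- if (d >= 4L) runs_by_d[[d - 1L]] else NULL
      if (!is.null(r2s)) {
        j <- which(r2s$x1 == e1 + 1L)
        if (length(j) && v[d - e1 - 1L] != "N")
          cands[[length(cands) + 1L]] <- list(
            a1 = r1s$x1[k], a2 = r2s$x2[j],
            b1 = d - 1L - r2s$x2[j], b2 = d - r1s$x1[k],
            ints = sprintf("gap_arm2@./%d", d - e1 - 2L))
      }
    }
  }
  if (!length(cands)) return(character(0))
  a1 <- vapply(cands, `[[`, 0L, "a1"); a2 <- vapply(cands, `[[`, 0L, "a2")
  b1 <- vapply(cands, `[[`, 0L, "b1"); b2 <- vapply(cands, `[[`, 0L, "b2")
  spacer <- b1 - a2 - 1L
  armlen <- pmin(a2 - a1 + 1L, b2 - b1 + 1L)
  pass <- spacer >= min_spacer & spacer <= max_spacer & armlen >= min_arm
  keep <- logical(length(cands))
  for (i in which(pass)) {
    contained <- pass & a1 <= a1[i] & a2 >= a2[i] & b1 <= b1[i] &
      b2 >= b2[i] & !(a1 == a1[i] & a2 == a2[i] & b1 == b1[i] & b2 == b2[i])
    keep[i] <- !any(contained)
  }
  sort(vapply(which(keep), function(i)
    ivs_signature(a1[i] - 1L, a2[i], b1[i] - 1L, b2[i], cands[[i]]$ints),
    ""))
}

# Position-by-position brute-force palindrome oracle: for every center,
# vectorized pairing columns, second-mismatch cutoff via cumulative
# mismatch counts, terminal-mismatch trimming, threshold, containment
# with identical mismatch pair.
oracle_scan_ps <- function(s, min_helix = 17L, stop_mismatches = 2L) {
  L <- nchar(s)
  v <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- list()
  for (c0 in seq_len(L)) {
    kmax <- min(c0 - 1L, L - c0)
    if (kmax < 1L) next
    lp <- c0 - seq_len(kmax); rp <- c0 + seq_len(kmax)
    ok <- v[lp] != "N" & v[rp] != "N" & v[lp] == comp[v[rp]]
    nbad <- cumsum(!ok)
    kend <- if (any(nbad >= stop_mismatches))
      which(nbad >= stop_mismatches)[1L] - 1L else kmax
    mm <- which(!ok)
    mm <- mm[mm <= kend]
    while (length(mm) && mm[length(mm)] == kend) {
      kend <- kend - 1L
      mm <- mm[-length(mm)]
    }
    if (kend < 1L || 2L * kend + 1L < min_helix) next
    out[[length(out) + 1L]] <- list(
      center = c0, s1 = c0 - kend, s2 = c0 + kend,
      helix = 2L * kend + 1L,
      mm = if (length(mm)) sprintf("%d/%d", c0 - mm, c0 + mm)
           else character(0))
  }
  if (!length(out)) return(character(0))
  sig <- vapply(out, function(p) paste(p$mm, collapse = ","), "")
  s1 <- vapply(out, `[[`, 0L, "s1"); s2 <- vapply(out, `[[`, 0L, "s2")
  hl <- vapply(out, `[[`, 0L, "helix")
  keep <- vapply(seq_along(out), function(i)
    !any(sig == sig[i] & hl > hl[i] & s1 <= s1[i] & s2 >= s2[i]),
    logical(1))
  sort(vapply(which(keep), function(i)
    sprintf("%d:%d-%d|%s", out[[i]]$center - 1L, s1[i] - 1L, s2[i],
            paste(out[[i]]$mm, collapse = ",")), ""))
}

scan_ps_signatures <- function(hits) {
  sort(vapply(hits$hits, function(h)
    sprintf("%d:%d-%d|%s", h$center_g, h$span[["start"]], h$span[["end"]],
            paste(vapply(h$mismatches, function(m)
              sprintf("%d/%d", m$left + 0L, m$right + 0L), ""),
              collapse = ",")), ""))
}

# Hand-buildable mini reference: poly-A background cannot base-pair with
# itself, so only deliberately planted fold-back structures are found.
polyA_reference <- function(segments, chrom = "mini") {
  Biostrings::DNAStringSet(stats::setNames(paste(segments, collapse = ""),
                                           chrom))
}
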