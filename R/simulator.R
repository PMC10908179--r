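#' Specification of a synthetic reference with planted structures
#'
#' Describes a random background sequence plus planted imperfect
#' inverted repeats, planted imperfect palindromes, and planted true
#' variants. Defaults emulate a small capture-panel target: a 1 kb
#' region at balanced GC with one qualifying IVS (arm 12 bp, spacer
#' 6 bp, one internal mismatch 4 bp from the arm end), one qualifying PS
#' (helix 21 bp, internal mismatch 5 bp from the center), and two
#' germline-like true variants at typical somatic-panel allele
#' fractions.
#'
#' @param length Reference length (bp).
#' @param gc GC fraction of the random background.
#' @param planted_ivs List of IVS plants: each
#'   `list(arm_len, spacer_len, interruption = list(offset, kind, len))`
#'   with `kind` `"mismatch"` (len 1) or `"gap"` (len extra unpaired
#'   bases on the downstream arm); `offset` is the 0-based interruption
#'   offset within the upstream arm.
#' @param planted_ps List of PS plants: each
#'   `list(helix_len, mismatch_off)` with odd `helix_len` and the
#'   mismatch `mismatch_off` columns from the center.
#' @param true_variants List of `list(vaf = ...)`; positions and alleles
#'   are drawn away from all structure and blacklist sites.
#' @param seed Integer seed; the construction is fully deterministic.
#' @param chrom Sequence name.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(length = 1000L, gc = 0.5,
                           planted_ivs = list(list(
                             arm_len = 12L, spacer_len = 6L,
                             interruption = list(offset = 4L,
                                                 kind = "mismatch",
                                                 len = 1L))),
                           planted_ps = list(list(helix_len = 21L,
                                                  mismatch_off = 5L)),
                           true_variants = list(list(vaf = 0.3),
                                                list(vaf = 0.2)),
                           seed = 1L, chrom = "synth1") {
  stopifnot(length >= 200L, gc > 0, gc < 1)
  structure(list(length = as.integer(length), gc = gc,
                 planted_ivs = planted_ivs, planted_ps = planted_ps,
                 true_variants = true_variants,
                 seed = as.integer(seed), chrom = chrom),
            class = "synthetic_spec")
}

.rand_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Replace base at i (1-based) with a random base excluding `not`.
.break_pairing <- function(v, i, not) {
  v[i] <- sample(setdiff(c("A", "C", "G", "T"), not), 1L)
  v
}

#' Generate a synthetic reference with planted structures
#'
#' Builds a random background at the requested GC, inserts the planted
#' structures at evenly spaced, non-overlapping positions (plants that
#' cannot be placed without overlap are rejected), and deliberately
#' breaks base pairing in the immediate flanks and spacer so a planted
#' structure's natural extent is exactly what was planted. True-variant
#' positions are drawn by rejection sampling away from structure spans
#' and away from every blacklist site of the finished sequence (random
#' sequence contains qualifying fold-backs by chance, and a true variant
#' on such a site would be indistinguishable from an artifact). The
#' construction is byte-deterministic for a fixed spec.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_reference`: `reference`
#'   (`DNAStringSet`), `truth` (list: `structures` data.frame,
#'   `expected_sites` blacklist-style data.frame computed from the
#'   pairing rule, `true_variants` data.frame), and `spec`.
#' @export
make_synthetic_reference <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, .make_synthetic_reference(spec))
}

.make_synthetic_reference <- function(spec) {
  L <- spec$length
  v <- .rand_bases(L, spec$gc)
  plants <- list()
  for (p in spec$planted_ivs) plants[[length(plants) + 1L]] <-
    c(list(type = "IVS"), p)
  for (p in spec$planted_ps) plants[[length(plants) + 1L]] <-
    c(list(type = "PS"), p)
  plant_len <- vapply(plants, function(p) {
    if (p$type == "IVS") {
      g <- if (identical(p$interruption$kind, "gap")) p$interruption$len else 0L
      2L * p$arm_len + p$spacer_len + g
    } else p$helix_len
  }, integer(1))
  n <- length(plants)
  gap <- if (n) (L - sum(plant_len)) %/% (n + 1L) else 0L
  if (n && gap < 30L)
    .stopf("planted structures do not fit without overlap in %d bp", L)
  structures <- list()
  sites <- list()
  offset <- gap
  for (pi in seq_along(plants)) {
    p <- plants[[pi]]
    P <- offset  # 0-based plant start
    if (p$type == "IVS") {
      arm <- p$arm_len; sp <- p$spacer_len
      it <- p$interruption
      a1 <- .rand_bases(arm, spec$gc)
      spacer <- .rand_bases(sp, spec$gc)
      a2 <- .complement_vec(rev(a1))
      if (identical(it$kind, "mismatch")) {
        o <- it$offset
        m <- arm - o  # 1-based mirror index in a2
        a2 <- .break_pairing(a2, m, .complement(a1[o + 1L]))
      } else if (identical(it$kind, "gap")) {
        o <- it$offset
        gapb <- .rand_bases(it$len, spec$gc)
        a2 <- append(a2, gapb, after = arm - o)
      } else .stopf("unknown interruption kind '%s'", it$kind)
      plant <- c(a1, spacer, a2)
      # spacer must not extend pairing inward
      for (t in 0:2) {
        li <- 1L + t; ri <- sp - t
        if (li < ri &&
            spacer[ri] == .complement(spacer[li]))
          spacer <- .break_pairing(spacer, ri, .complement(spacer[li]))
      }
      plant <- c(a1, spacer, a2)
      v[(P + 1L):(P + length(plant))] <- plant
      arm1_s <- P; arm2_s <- P + arm + sp
      structures[[length(structures) + 1L]] <- data.frame(
        type = "IVS", start = P, end = P + length(plant),
        arm1_start = arm1_s, arm1_end = arm1_s + arm,
        arm2_start = arm2_s, arm2_end = arm2_s + length(a2),
        center = NA_integer_,
        detail = sprintf("arm=%d;spacer=%d;%s@%d", arm, sp, it$kind,
                         it$offset), stringsAsFactors = FALSE)
      if (identical(it$kind, "mismatch")) {
        o <- it$offset
        p1 <- arm1_s + o
        p2 <- arm2_s + arm - 1L - o
        bx <- a1[o + 1L]; by <- a2[arm - o]
        sites[[length(sites) + 1L]] <- data.frame(
          chrom = spec$chrom,
          start = c(p1, p2), end = c(p1 + 1L, p2 + 1L),
          ref = c(bx, by),
          predicted_alt = c(.complement(by), .complement(bx)),
          source = "IVS", stringsAsFactors = FALSE)
      }
      # gap truth sites are appended after assembly (need normalization)
      if (identical(it$kind, "gap"))
        structures[[length(structures)]]$gap_info <- I(list(list(
          o = it$offset, len = it$len, arm1_s = arm1_s, arm2_s = arm2_s,
          arm = arm)))
    } else {
      hl <- p$helix_len
      if (hl %% 2L == 0L) .stopf("planted PS helix_len must be odd")
      al <- (hl - 1L) %/% 2L
      k <- p$mismatch_off
      stopifnot(k >= 1L, k <= al)
      left <- .rand_bases(al, spec$gc)
      center <- .rand_bases(1L, spec$gc)
      right <- .complement_vec(rev(left))
      right <- .break_pairing(right, k, .complement(left[al - k + 1L]))
      plant <- c(left, center, right)
      v[(P + 1L):(P + hl)] <- plant
      cg <- P + al  # 0-based center
      pl <- cg - k; pr <- cg + k
      bl <- plant[al - k + 1L]; br <- right[k]
      structures[[length(structures) + 1L]] <- data.frame(
        type = "PS", start = P, end = P + hl,
        arm1_start = NA_integer_, arm1_end = NA_integer_,
        arm2_start = NA_integer_, arm2_end = NA_integer_,
        center = cg,
        detail = sprintf("helix=%d;mismatch_off=%d", hl, k),
        stringsAsFactors = FALSE)
      sites[[length(sites) + 1L]] <- data.frame(
        chrom = spec$chrom,
        start = c(pl, pr), end = c(pl + 1L, pr + 1L),
        ref = c(bl, br),
        predicted_alt = c(.complement(br), .complement(bl)),
        source = "PS", stringsAsFactors = FALSE)
    }
    # break pairing just outside the plant so its extent is exact
    for (t in 0:3) {
      li <- P - t; ri <- P + plant_len[pi] + 1L + t
      if (li >= 1L && ri <= L && v[ri] == .complement(v[li]))
        v <- .break_pairing(v, ri, .complement(v[li]))
    }
    offset <- offset + plant_len[pi] + gap
  }
  s <- paste(v, collapse = "")
  # normalized truth sites for gap plants, from the pairing rule
  for (st in structures) {
    if (is.null(st$gap_info)) next
    gi <- st$gap_info[[1]]
    gstart <- gi$arm2_s + gi$arm - gi$o  # 0-based first gap base on arm2
    gseq <- substr(s, gstart + 1L, gstart + gi$len)
    del <- .normalize_allele(gstart - 1L, substr(s, gstart, gstart + gi$len),
                             substr(s, gstart, gstart), s)
    xA <- gi$arm1_s + gi$o - 1L  # 0-based arm1 insertion anchor
    ins <- .normalize_allele(xA, substr(s, xA + 1L, xA + 1L),
                             paste0(substr(s, xA + 1L, xA + 1L),
                                    .revcomp_chr(gseq)), s)
    sites[[length(sites) + 1L]] <- data.frame(
      chrom = spec$chrom,
      start = c(del$start, ins$start),
      end = c(del$start + nchar(del$ref), ins$start + nchar(ins$ref)),
      ref = c(del$ref, ins$ref),
      predicted_alt = c(del$alt, ins$alt),
      source = "IVS", stringsAsFactors = FALSE)
  }
  reference <- Biostrings::DNAStringSet(stats::setNames(s, spec$chrom))
  # place true variants away from structures and from every blacklist site
  tv <- .place_true_variants(spec, reference, structures)
  structures_df <- if (length(structures))
    do.call(rbind, lapply(structures, function(x) {
      x$gap_info <- NULL
      as.data.frame(x)
    })) else
    data.frame(type = character(0), start = integer(0), end = integer(0))
  expected <- .finalize_entries(sites, NULL)
  expected$structure_id <- NULL
  structure(list(reference = reference,
                 truth = list(structures = structures_df,
                              expected_sites = expected,
                              true_variants = tv),
                 spec = spec),
            class = "synthetic_reference")
}

.place_true_variants <- function(spec, reference, structures) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      vaf = numeric(0), stringsAsFactors = FALSE)
  if (!length(spec$true_variants)) return(empty)
  L <- spec$length
  win <- fetch_window(reference, gintervals(spec$chrom, 0L, L))
  bl <- rbind(ivs_blacklist(scan_ivs(win)), ps_blacklist(scan_ps(win)))
  forbidden <- rep(FALSE, L)
  if (nrow(bl)) for (i in seq_len(nrow(bl)))
    forbidden[(bl$start[i] + 1L):min(L, bl$end[i])] <- TRUE
  edge <- 150L  # keep variants in well-covered territory
  forbidden[1:min(L, edge)] <- TRUE
  forbidden[max(1L, L - edge):L] <- TRUE
  allowed <- which(!forbidden)
  if (length(allowed) < length(spec$true_variants))
    .stopf("no room to place true variants")
  pos1 <- sort(sample(allowed, length(spec$true_variants)))
  s <- as.character(reference[[spec$chrom]])
  refb <- substring(s, pos1, pos1)
  altb <- vapply(refb, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  data.frame(chrom = spec$chrom, pos = pos1, ref = refb,
             alt = unname(altb),
             vaf = vapply(spec$true_variants, `[[`, 0, "vaf"),
             stringsAsFactors = FALSE)
}

#' Restrict scan hits to the planted structures of a synthetic reference
#'
#' Random background sequence contains chance fold-back structures of
#' its own; for controlled experiments the chimera simulators are
#' usually driven by the planted structures only. Matches IVS hits by
#' exact arm intervals and PS hits by center position.
#'
#' @param synthref A `synthetic_reference` from
#'   [make_synthetic_reference()].
#' @param hits An `ivs_hits` or `ps_hits` object scanned from it.
#' @return The hits object reduced to planted structures.
#' @export
select_planted_hits <- function(synthref, hits) {
  st <- synthref$truth$structures
  if (inherits(hits, "ivs_hits")) {
    st <- st[st$type == "IVS", , drop = FALSE]
    keep <- vapply(hits$hits, function(h)
      any(st$arm1_start == h$arm1[["start"]] &
            st$arm1_end == h$arm1[["end"]] &
            st$arm2_start == h$arm2[["start"]] &
            st$arm2_end == h$arm2[["end"]]), logical(1))
  } else if (inherits(hits, "ps_hits")) {
    st <- st[st$type == "PS", , drop = FALSE]
    keep <- vapply(hits$hits, function(h)
      any(st$center == h$center_g), logical(1))
  } else .stopf("hits must be ivs_hits or ps_hits")
  hits$hits <- hits$hits[keep]
  hits
}

# ---- chimera formation -----------------------------------------------------

# Per-hit artifact events by chimera copy direction. Direction B breaks in
# the downstream arm and copies the upstream arm onto it (events appear at
# arm2-side sites when the junction j satisfies j <= thr); direction A is
# the mirror (events at arm1-side sites when j >= thr). Positions genomic,
# 0-based; alleles normalized like the blacklist.
.ivs_sim_events <- function(hits) {
  s <- hits$window$seq
  off <- hits$window$interval$start
  lapply(hits$hits, function(h) {
    lay <- .ivs_groups(h)
    dirA <- list(); dirB <- list()
    for (g in lay$groups) {
      if (g$kind == "mismatch") {
        for (m in seq_along(g$xs)) {
          x <- g$xs[m]; y <- g$ys[m]
          bx <- substr(s, x, x); by <- substr(s, y, y)
          if (bx == "N" || by == "N") next
          dirB[[length(dirB) + 1L]] <- list(pos0 = off + y - 1L, ref = by,
                                            alt = .complement(bx),
                                            thr = off + y - 1L)
          dirA[[length(dirA) + 1L]] <- list(pos0 = off + x - 1L, ref = bx,
                                            alt = .complement(by),
                                            thr = off + x)
        }
      } else if (g$kind == "gap_arm1") {
        g1 <- min(g$xs); g2 <- max(g$xs)
        gseq <- substr(s, g1, g2)
        if (grepl("N", gseq, fixed = TRUE) || g1 < 2L) next
        del <- .normalize_allele(g1 - 2L, substr(s, g1 - 1L, g2),
                                 substr(s, g1 - 1L, g1 - 1L), s)
        dirA[[length(dirA) + 1L]] <- list(pos0 = off + del$start,
                                          ref = del$ref, alt = del$alt,
                                          thr = off + g2)
        yA <- g$ynext
        ins <- .normalize_allele(yA - 1L, substr(s, yA, yA),
                                 paste0(substr(s, yA, yA),
                                        .revcomp_chr(gseq)), s)
        dirB[[length(dirB) + 1L]] <- list(pos0 = off + ins$start,
                                          ref = ins$ref, alt = ins$alt,
                                          thr = off + yA - 1L)
      } else {  # gap_arm2
        h1 <- min(g$ys); h2 <- max(g$ys)
        gseq <- substr(s, h1, h2)
        if (grepl("N", gseq, fixed = TRUE) || h1 < 2L) next
        del <- .normalize_allele(h1 - 2L, substr(s, h1 - 1L, h2),
                                 substr(s, h1 - 1L, h1 - 1L), s)
        dirB[[length(dirB) + 1L]] <- list(pos0 = off + del$start,
                                          ref = del$ref, alt = del$alt,
                                          thr = off + h1 - 2L)
        xA <- g$xprev
        ins <- .normalize_allele(xA - 1L, substr(s, xA, xA),
                                 paste0(substr(s, xA, xA),
                                        .revcomp_chr(gseq)), s)
        dirA[[length(dirA) + 1L]] <- list(pos0 = off + ins$start,
                                          ref = ins$ref, alt = ins$alt,
                                          thr = off + xA)
      }
    }
    list(dirA = dirA, dirB = dirB)
  })
}

.template <- function(chrom, align_lo, align_hi, clip_side, clip_anchor,
                      clip_max, events, het, chemistry, structure_id,
                      junction, is_chimeric) {
  structure(list(chrom = chrom, align_lo = align_lo, align_hi = align_hi,
                 clip_side = clip_side, clip_anchor = clip_anchor,
                 clip_max = clip_max, events = events, het = het,
                 chemistry = chemistry, structure_id = structure_id,
                 junction = junction, is_chimeric = is_chimeric,
                 induced_site = if (length(events)) events[[1L]] else NULL),
            class = "chimeric_template")
}

#' Simulate sonication-chemistry chimeric templates
#'
#' Models PDSM chimera formation for sonication libraries: random
#' double-strand breaks expose partial single strands; when a break
#' falls inside one arm of an inverted repeat the strand folds onto the
#' partner arm, 3' overhangs are trimmed and the gap is filled by
#' copying the partner strand. The filled strand carries the induced
#' allele (the complement of the partner arm's base) at every covered
#' interruption site while the partner strand keeps the original base,
#' so induced templates are heteroduplexes; breaks that miss the arms
#' give ordinary non-chimeric templates, and perfect structures give
#' chimeric templates with no induced site (pure soft-clip artifacts).
#'
#' @param reference A `DNAStringSet`.
#' @param ivs An `ivs_hits` object for this reference.
#' @param n_templates Number of fragmentation events to draw.
#' @param seed Optional seed.
#' @param mol_flank Molecule extent kept on the un-copied side (bp).
#' @param tail Maximum fold-back copy tail beyond the arm (bp).
#' @return List of `chimeric_template` objects.
#' @export
simulate_sonication_chimeras <- function(reference, ivs, n_templates,
                                         seed = NULL, mol_flank = 120L,
                                         tail = 60L) {
  stopifnot(inherits(ivs, "ivs_hits"))
  chrom <- ivs$window$interval$chrom
  reflen <- chrom_sizes(reference)[[chrom]]
  ev <- .ivs_sim_events(ivs)
  .with_seed(seed, {
    breaks <- sample.int(reflen, n_templates, replace = TRUE) - 1L
    lapply(breaks, function(b) {
      for (hi in seq_along(ivs$hits)) {
        h <- ivs$hits[[hi]]
        a1 <- h$arm1[["start"]]; e1 <- h$arm1[["end"]]
        b1 <- h$arm2[["start"]]; e2 <- h$arm2[["end"]]
        sid <- sprintf("IVS:%s:%d-%d/%d-%d", chrom, a1, e1, b1, e2)
        if (b >= b1 && b < e2) {  # direction B: copy arm1 onto arm2
          evs <- Filter(function(e) b <= e$thr, ev[[hi]]$dirB)
          return(.template(chrom, max(0L, b - mol_flank), e2, "right",
                           a1, min(a1, tail), evs, het = length(evs) > 0L,
                           "sonication", sid, b, TRUE))
        }
        if (b >= a1 && b < e1) {  # direction A: copy arm2 onto arm1
          evs <- Filter(function(e) b >= e$thr, ev[[hi]]$dirA)
          return(.template(chrom, a1, min(reflen, b + mol_flank), "left",
                           e2, min(reflen - e2, tail), evs,
                           het = length(evs) > 0L,
                           "sonication", sid, b, TRUE))
        }
      }
      .template(chrom, max(0L, b - mol_flank), min(reflen, b + mol_flank),
                "none", NA_integer_, 0L, list(), FALSE, "sonication",
                NA_character_, b, FALSE)
    })
  })
}

#' Simulate enzymatic-chemistry chimeric templates
#'
#' Models PDSM chimera formation for enzymatic fragmentation: the enzyme
#' cocktail nicks inside a palindrome, the exposed partial single strand
#' folds back onto the partner arm and end repair writes the induced
#' allele into the template before any amplification — so induced
#' templates are homoduplexes (both strands carry the induced base) and
#' the chimeric span is bounded by the palindrome arms.
#'
#' @param reference A `DNAStringSet`.
#' @param ps A `ps_hits` object for this reference.
#' @param n_templates Number of nicking events to draw.
#' @param seed Optional seed.
#' @param mol_flank Molecule extent kept on the un-copied side (bp).
#' @param tail Maximum fold-back copy tail beyond the span (bp).
#' @return List of `chimeric_template` objects.
#' @export
simulate_enzymatic_chimeras <- function(reference, ps, n_templates,
                                        seed = NULL, mol_flank = 120L,
                                        tail = 60L) {
  stopifnot(inherits(ps, "ps_hits"), length(ps$hits) > 0L)
  chrom <- ps$window$interval$chrom
  reflen <- chrom_sizes(reference)[[chrom]]
  .with_seed(seed, {
    his <- sample.int(length(ps$hits), n_templates, replace = TRUE)
    lapply(his, function(hi) {
      h <- ps$hits[[hi]]
      sp1 <- h$span[["start"]]; sp2 <- h$span[["end"]]  # 0-based half-open
      cg <- h$center_g
      sid <- sprintf("PS:%s:%d", chrom, cg)
      mm <- if (length(h$mismatches)) h$mismatches[[1L]] else NULL
      side <- sample(c("left", "right"), 1L)
      if (side == "right") {  # nick in the right arm, copy left arm
        j <- sample((cg + 1L):(sp2 - 1L), 1L)
        evs <- if (!is.null(mm) && j <= mm$right_g &&
                   mm$base_left != "N" && mm$base_right != "N")
          list(list(pos0 = mm$right_g, ref = mm$base_right,
                    alt = .complement(mm$base_left), thr = mm$right_g))
          else list()
        .template(chrom, max(0L, j - mol_flank), sp2, "right", sp1,
                  min(sp1, tail), evs, het = FALSE, "enzymatic", sid, j,
                  TRUE)
      } else {  # nick in the left arm, copy right arm
        j <- sample((sp1 + 1L):(cg - 1L + 1L), 1L)
        evs <- if (!is.null(mm) && j >= mm$left_g + 1L &&
                   mm$base_left != "N" && mm$base_right != "N")
          list(list(pos0 = mm$left_g, ref = mm$base_left,
                    alt = .complement(mm$base_right), thr = mm$left_g))
          else list()
        .template(chrom, sp1, min(reflen, j + mol_flank), "left", sp2,
                  min(reflen - sp2, tail), evs, het = FALSE, "enzymatic",
                  sid, j, TRUE)
      }
    })
  })
}

#' Ordinary (non-chimeric) template molecules carrying true variants
#'
#' Draws uniformly placed insert-sized molecules; each molecule carries
#' each true variant it spans on both strands with probability equal to
#' the variant's allele fraction.
#'
#' @param reference A `DNAStringSet`.
#' @param n_templates Number of molecules.
#' @param true_variants data.frame `chrom, pos (1-based), ref, alt, vaf`
#'   (e.g. from [make_synthetic_reference()] truth), or `NULL`.
#' @param insert Molecule length (bp).
#' @param seed Optional seed.
#' @return List of non-chimeric `chimeric_template` objects.
#' @export
background_templates <- function(reference, n_templates,
                                 true_variants = NULL, insert = 160L,
                                 seed = NULL) {
  chrom <- names(reference)[1L]
  reflen <- chrom_sizes(reference)[[chrom]]
  stopifnot(insert < reflen)
  .with_seed(seed, {
    lo <- sample.int(reflen - insert + 1L, n_templates, replace = TRUE) - 1L
    lapply(lo, function(l) {
      evs <- list()
      if (!is.null(true_variants) && nrow(true_variants)) {
        for (i in seq_len(nrow(true_variants))) {
          p0 <- true_variants$pos[i] - 1L
          if (p0 >= l && p0 + nchar(true_variants$ref[i]) <= l + insert &&
              stats::runif(1) < true_variants$vaf[i])
            evs[[length(evs) + 1L]] <- list(pos0 = p0,
                                            ref = true_variants$ref[i],
                                            alt = true_variants$alt[i],
                                            thr = p0)
        }
      }
      .template(chrom, l, l + insert, "none", NA_integer_, 0L, evs,
                FALSE, "none", NA_character_, NA_integer_, FALSE)
    })
  })
}

# Apply events (VCF-style anchored, fully contained in [lo, hi)) to the
# reference substring of that span; events applied right to left.
.apply_events <- function(chrseq, lo, hi, events) {
  s <- substr(chrseq, lo + 1L, hi)
  if (length(events)) {
    ord <- order(-vapply(events, `[[`, 0L, "pos0"))
    for (e in events[ord]) {
      rel <- e$pos0 - lo  # 0-based offset within the segment
      s <- paste0(substr(s, 1L, rel), e$alt,
                  substr(s, rel + nchar(e$ref) + 1L, nchar(s)))
    }
  }
  s
}

#' Amplify templates by error-free PCR and sample reads
#'
#' Each cycle copies every single strand faithfully (exact unbiased
#' doubling, no polymerase error), so after any number of cycles exactly
#' half the molecules descend from each founding strand of a template.
#' Reads are sampled uniformly from the final molecules: a template and
#' a founding strand are drawn uniformly, and the read carries that
#' strand's alleles. For a heteroduplex template only the filled strand
#' (founder 1) carries the induced allele; for homoduplex templates both
#' do. Chimeric reads are windowed around the clip boundary so they
#' retain `min_clip`..`max_clip` soft-clipped fold-back bases.
#'
#' @param templates List of `chimeric_template` objects.
#' @param reference A `DNAStringSet`.
#' @param cycles PCR cycles (>= 1).
#' @param n_reads Number of reads to sample.
#' @param read_len Read length (bp).
#' @param seed Optional seed.
#' @param min_clip,max_clip Soft-clip length bounds for chimeric reads.
#' @return data.frame of reads: `template_id, strand, chrom,
#'   align_start, align_end` (aligned apparent span, 0-based half-open),
#'   `clip_len, clip_side, seq, is_chimeric, carries_mutation`, plus an
#'   `events` list-column; attribute `molecules_per_template` records
#'   the `2^cycles` final molecules each template contributed.
#' @export
pcr_and_sample <- function(templates, reference, cycles = 10L, n_reads,
                           read_len = 100L, seed = NULL, min_clip = 5L,
                           max_clip = 40L) {
  stopifnot(cycles >= 1L, length(templates) > 0L)
  chrseqs <- lapply(stats::setNames(names(reference), names(reference)),
                    function(nm) as.character(reference[[nm]]))
  .with_seed(seed, {
    ti <- sample.int(length(templates), n_reads, replace = TRUE)
    strand <- sample.int(2L, n_reads, replace = TRUE)
    rows <- vector("list", n_reads)
    for (r in seq_len(n_reads)) {
      tp <- templates[[ti[r]]]
      chrseq <- chrseqs[[tp$chrom]]
      if (tp$is_chimeric) {
        cmax <- max(min_clip, min(tp$clip_max, max_clip, read_len - 20L))
        clip_len <- if (cmax <= min_clip) min_clip
                    else min_clip + sample.int(cmax - min_clip + 1L, 1L) - 1L
        alen <- read_len - clip_len
        if (tp$clip_side == "right") {
          hi <- tp$align_hi
          lo <- max(tp$align_lo, hi - alen)
          clip_seq <- .revcomp_chr(substr(chrseq,
                                          tp$clip_anchor - clip_len + 1L,
                                          tp$clip_anchor))
        } else {
          lo <- tp$align_lo
          hi <- min(tp$align_hi, lo + alen)
          clip_seq <- .revcomp_chr(substr(chrseq, tp$clip_anchor + 1L,
                                          tp$clip_anchor + clip_len))
        }
      } else {
        span <- tp$align_hi - tp$align_lo
        lo <- tp$align_lo +
          (if (span > read_len) sample.int(span - read_len + 1L, 1L) - 1L
           else 0L)
        hi <- min(tp$align_hi, lo + read_len)
        clip_len <- 0L
        clip_seq <- ""
      }
      carries <- strand[r] == 1L || !tp$het
      evs <- if (carries && length(tp$events))
        Filter(function(e) e$pos0 >= lo && e$pos0 + nchar(e$ref) <= hi,
               tp$events) else list()
      aseq <- .apply_events(chrseq, lo, hi, evs)
      seqr <- if (clip_len == 0L) aseq
              else if (tp$clip_side == "right") paste0(aseq, clip_seq)
              else paste0(clip_seq, aseq)
      rows[[r]] <- list(template_id = ti[r], strand = strand[r],
                        chrom = tp$chrom, align_start = lo, align_end = hi,
                        clip_len = clip_len,
                        clip_side = if (clip_len) tp$clip_side else "none",
                        seq = seqr, is_chimeric = tp$is_chimeric,
                        carries_mutation = length(evs) > 0L,
                        events = evs)
    }
    out <- data.frame(
      template_id = vapply(rows, `[[`, 0L, "template_id"),
      strand = vapply(rows, `[[`, 0L, "strand"),
      chrom = vapply(rows, `[[`, "", "chrom"),
      align_start = vapply(rows, `[[`, 0L, "align_start"),
      align_end = vapply(rows, `[[`, 0L, "align_end"),
      clip_len = vapply(rows, `[[`, 0L, "clip_len"),
      clip_side = vapply(rows, `[[`, "", "clip_side"),
      seq = vapply(rows, `[[`, "", "seq"),
      is_chimeric = vapply(rows, `[[`, TRUE, "is_chimeric"),
      carries_mutation = vapply(rows, `[[`, TRUE, "carries_mutation"),
      stringsAsFactors = FALSE)
    out$events <- lapply(rows, `[[`, "events")
    attr(out, "molecules_per_template") <- 2^cycles
    out
  })
}

#' Naive pileup variant calling on simulated reads
#'
#' Desk-scale stand-in for an alignment-plus-caller pipeline: reads are
#' placed by their truth coordinates, with the mis-copied fold-back
#' portion already mapped to its apparent position (exactly the
#' misalignment through which a chimeric artifact becomes a variant
#' call). Counts alleles per site and emits variants passing the depth
#' and allele-fraction thresholds.
#'
#' @param reads Read data.frame from [pcr_and_sample()].
#' @param reference A `DNAStringSet`.
#' @param min_vaf Minimum allele fraction.
#' @param min_alt_reads Minimum supporting reads.
#' @return Variant record data.frame compatible with
#'   [filter_variants()]: `chrom, pos (1-based), id, ref, alt, qual,
#'   filter, info, vaf, depth, alt_count`.
#' @export
naive_pileup <- function(reads, reference, min_vaf = 0.05,
                         min_alt_reads = 2L) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      id = character(0), ref = character(0),
                      alt = character(0), qual = character(0),
                      filter = character(0), info = character(0),
                      vaf = numeric(0), depth = integer(0),
                      alt_count = integer(0), stringsAsFactors = FALSE)
  evs <- do.call(rbind, lapply(seq_len(nrow(reads)), function(i) {
    e <- reads$events[[i]]
    if (!length(e)) return(NULL)
    data.frame(chrom = reads$chrom[i],
               pos0 = vapply(e, `[[`, 0L, "pos0"),
               ref = vapply(e, `[[`, "", "ref"),
               alt = vapply(e, `[[`, "", "alt"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(evs) || !nrow(evs)) return(empty)
  key <- paste(evs$chrom, evs$pos0, evs$ref, evs$alt, sep = "\r")
  cnt <- table(key)
  uk <- names(cnt)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[[`, "", 1L),
                    pos0 = as.integer(vapply(parts, `[[`, "", 2L)),
                    ref = vapply(parts, `[[`, "", 3L),
                    alt = vapply(parts, `[[`, "", 4L),
                    alt_count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out$depth <- vapply(seq_len(nrow(out)), function(i)
    sum(reads$chrom == out$chrom[i] & reads$align_start <= out$pos0[i] &
          reads$align_end > out$pos0[i]), integer(1))
  out$vaf <- out$alt_count / pmax(1L, out$depth)
  out <- out[out$vaf >= min_vaf & out$alt_count >= min_alt_reads, ,
             drop = FALSE]
  if (!nrow(out)) return(empty)
  out <- out[order(out$chrom, out$pos0), , drop = FALSE]
  data.frame(chrom = out$chrom, pos = out$pos0 + 1L, id = ".",
             ref = out$ref, alt = out$alt, qual = ".", filter = ".",
             info = sprintf("AF=%.6g;DP=%d;AC=%d", out$vaf, out$depth,
                            out$alt_count),
             vaf = out$vaf, depth = out$depth, alt_count = out$alt_count,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write simulated reads as FASTQ
#'
#' Constant quality (no error model is simulated); truth flags are kept
#' in the read comment.
#'
#' @param reads Read data.frame from [pcr_and_sample()].
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(c(sprintf("@read%d tmpl=%d chimeric=%s mut=%s",
                         i, reads$template_id[i],
                         reads$is_chimeric[i], reads$carries_mutation[i]),
                 reads$seq[i], "+",
                 strrep("I", nchar(reads$seq[i]))), con)
  }
  invisible(path)
}
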