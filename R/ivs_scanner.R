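#' Parameters for imperfect inverted repeat (IVS) scanning
#'
#' Defaults follow the blacklist criteria used for sonication-chemistry
#' artifact prediction: spacer `N >= 5` bp between the two arms, per-arm
#' aligned length `>= 8` bp, and interruption-to-arm-end distance
#' `>= 2` bp. A reported structure is nearly perfect: at most one
#' contiguous interrupted region, with at most `max_interrupt`
#' discrepant (mismatched or gapped) bases on each arm.
#' `max_spacer` bounds the arm-to-arm search horizon to intra-fragment
#' distances (library inserts are a few hundred bp). `seed_len` is the
#' requested exact-match seed length; the effective seed used is capped
#' at run time (`min(seed_len, min_edge + 1)`, floor 2) so that every
#' structure whose interruptions keep `min_edge` clear of the arm ends
#' still contains a findable exact seed block.
#'
#' @param min_spacer,max_spacer Spacer bounds in bp.
#' @param min_arm Minimum per-arm aligned length in bp.
#' @param min_edge Minimum distance (alignment columns) from an
#'   interruption to both arm ends for it to be blacklisted.
#' @param seed_len Requested exact seed length in bp.
#' @param max_interrupt Maximum per-arm size of the (single) interrupted
#'   region of a structure.
#' @param kmin,kmax k-mer bounds for [kmer_census()]; `kmax = NULL`
#'   means `floor(L/2)` at census time.
#' @return An `ivs_params` list.
#' @export
ivs_params <- function(min_spacer = 5L, min_arm = 8L, min_edge = 2L,
                       seed_len = 8L, max_interrupt = 3L, max_spacer = 300L,
                       kmin = 2L, kmax = NULL) {
  stopifnot(min_spacer >= 0L, min_edge >= 1L, max_interrupt >= 1L,
            min_arm >= 1L, seed_len >= 2L, max_spacer >= min_spacer)
  structure(list(min_spacer = as.integer(min_spacer),
                 min_arm = as.integer(min_arm),
                 min_edge = as.integer(min_edge),
                 seed_len = as.integer(seed_len),
                 max_interrupt = as.integer(max_interrupt),
                 max_spacer = as.integer(max_spacer),
                 kmin = as.integer(kmin),
                 kmax = if (is.null(kmax)) NULL else as.integer(kmax)),
            class = "ivs_params")
}

.effective_seed_len <- function(params) {
  max(2L, min(params$seed_len, params$min_edge + 1L))
}

#' Enumerate all k-mers of a sequence over a range of lengths
#'
#' Emits every substring of length `K` for `K = kmin..kmax`; for each
#' `K` there are `L - K + 1` of them, so the reported total is
#' `sum_K (L - K + 1)`. This is the conceptual all-K enumeration from
#' which inverted-repeat assembly is defined; the scanner itself uses
#' fixed-length seeds plus extension, which is equivalent on the
#' structures it must report and avoids the quadratic enumeration.
#'
#' @param seq Nucleotide string (or a `reference_window`).
#' @param kmin,kmax k-mer length bounds; `2 <= kmin <= kmax <= L/2`.
#' @return List with `total` (count), `by_k` (named per-K counts) and
#'   `kmers` (character vector, duplicates retained).
#' @export
kmer_census <- function(seq, kmin = 2L, kmax = NULL) {
  if (inherits(seq, "reference_window")) seq <- seq$seq
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  if (is.null(kmax)) kmax <- L %/% 2L
  kmin <- as.integer(kmin); kmax <- as.integer(kmax)
  if (kmin < 2L) .stopf("kmin must be >= 2")
  if (kmax > L %/% 2L) .stopf("kmax (%d) exceeds L/2 (%d)", kmax, L %/% 2L)
  if (kmin > kmax) .stopf("kmin > kmax")
  ks <- kmin:kmax
  kmers <- unlist(lapply(ks, function(K)
    substring(seq, 1:(L - K + 1L), K:L)), use.names = FALSE)
  by_k <- stats::setNames(L - ks + 1L, ks)
  list(total = sum(by_k), by_k = by_k, kmers = kmers)
}

# ---- detection -------------------------------------------------------------

# All criteria-satisfying candidate structures of a window sequence:
# maximal exact reverse-complement seed blocks per anti-diagonal, then
# budgeted extension outward and inward from each block (compiled; see
# src/ivs_candidates.cpp). Coordinates are 1-based inclusive window
# positions; `ints` holds single-column interruptions in alignment order.
.ivs_candidates <- function(s, params) {
  L <- nchar(s)
  empty <- data.frame(a1 = integer(0), a2 = integer(0),
                      b1 = integer(0), b2 = integer(0), cost = integer(0))
  empty$ints <- list()
  k <- .effective_seed_len(params)
  if (L < 2L * k) return(empty)
  res <- .ivs_candidates_cpp(s, k, params$max_interrupt,
                             params$min_spacer, params$max_spacer,
                             params$min_arm)
  if (!length(res$a1)) return(empty)
  out <- data.frame(a1 = res$a1, a2 = res$a2, b1 = res$b1, b2 = res$b2,
                    cost = res$cost)
  # dedupe identical arm pairs, preferring the cheapest alignment
  key <- paste(out$a1, out$a2, out$b1, out$b2)
  ord <- order(key, out$cost)
  sel <- ord[!duplicated(key[ord])]
  out <- out[sel, , drop = FALSE]
  # reconstruct the interruption columns of the single region:
  # min(g1,g2) mismatches adjacent to the outer run, then the gap
  out$ints <- lapply(sel, function(i) {
    g1 <- res$g1[i]; g2 <- res$g2[i]
    if (g1 == 0L && g2 == 0L) return(list())
    rx <- res$rx[i]; ryhi <- res$ryhi[i]
    m <- min(g1, g2)
    ints <- lapply(seq_len(m) - 1L, function(t)
      list(kind = "mismatch", p1 = rx + t, p2 = ryhi - t))
    if (g1 > g2)
      ints <- c(ints, lapply(m:(g1 - 1L), function(t)
        list(kind = "gap_arm1", p1 = rx + t, p2 = NA_integer_)))
    else if (g2 > g1)
      ints <- c(ints, lapply(m:(g2 - 1L), function(t)
        list(kind = "gap_arm2", p1 = NA_integer_, p2 = ryhi - t)))
    ints
  })
  rownames(out) <- NULL
  out
}

#' Scan a reference window for imperfect inverted repeats
#'
#' Finds maximal nearly perfect fold-back structures: two same-strand
#' segments (arms) where the downstream arm is the reverse complement of
#' the upstream arm apart from at most one contiguous interrupted region
#' (mismatched pairs and/or a gap; at most `max_interrupt` discrepant
#' bases per arm), separated by a spacer of `min_spacer..max_spacer` bp.
#' Detection finds maximal exact reverse-complement pairing blocks of at
#' least the effective seed length and joins block pairs across a single
#' bridgeable region; arms extend to their natural (non-extendable)
#' limits. Structures contained (both arms) in another reported
#' structure are dropped; overlapping structures are kept. Output is
#' ordered by `(arm1 start, arm2 start)`.
#'
#' @param window A `reference_window` from [fetch_window()].
#' @param params An [ivs_params()] object.
#' @return An `ivs_hits` object: list with `hits` (list of structures),
#'   `window`, `params`. Each hit carries genomic arm intervals
#'   (0-based half-open), `spacer_len`, `aligned_len` and its
#'   interruptions (kind, length, genomic positions, bases).
#' @export
scan_ivs <- function(window, params = ivs_params()) {
  stopifnot(inherits(window, "reference_window"))
  s <- window$seq
  cand <- .ivs_candidates(s, params)
  # containment is judged among reportable structures only: a structure
  # is dropped when a larger structure that itself satisfies the
  # criteria covers both of its arms (candidates are all satisfying here)
  keep <- if (nrow(cand))
    which(!.ivs_contained_cpp(cand$a1, cand$a2, cand$b1, cand$b2))
  else integer(0)
  off <- window$interval$start  # genomic 0-based offset of window position 1
  v <- strsplit(s, "")[[1]]
  hits <- lapply(keep, function(i) {
    ints <- .merge_interruptions(cand$ints[[i]], v, off)
    list(chrom = window$interval$chrom,
         arm1 = c(start = off + cand$a1[i] - 1L, end = off + cand$a2[i]),
         arm2 = c(start = off + cand$b1[i] - 1L, end = off + cand$b2[i]),
         local = c(a1 = cand$a1[i], a2 = cand$a2[i],
                   b1 = cand$b1[i], b2 = cand$b2[i]),
         spacer_len = cand$b1[i] - cand$a2[i] - 1L,
         aligned_len = min(cand$a2[i] - cand$a1[i] + 1L,
                           cand$b2[i] - cand$b1[i] + 1L),
         interruptions = ints,
         ints_raw = cand$ints[[i]])
  })
  ord <- order(vapply(hits, function(h) h$local[["a1"]], 0L),
               vapply(hits, function(h) h$local[["b1"]], 0L))
  structure(list(hits = hits[ord], window = window, params = params),
            class = "ivs_hits")
}

# Merge consecutive single-column gap interruptions into multi-base gaps;
# mismatches stay as length-1 interruptions. Adds genomic positions/bases.
.merge_interruptions <- function(ints, v, off) {
  out <- list()
  i <- 1L
  while (i <= length(ints)) {
    it <- ints[[i]]
    if (it$kind == "mismatch") {
      out[[length(out) + 1L]] <- list(
        kind = "mismatch", length = 1L,
        pos1 = off + it$p1 - 1L, pos2 = off + it$p2 - 1L,
        bases1 = v[it$p1], bases2 = v[it$p2],
        local1 = it$p1, local2 = it$p2)
      i <- i + 1L
    } else {
      j <- i
      while (j + 1L <= length(ints) && ints[[j + 1L]]$kind == it$kind &&
             ((it$kind == "gap_arm1" &&
                 ints[[j + 1L]]$p1 == ints[[j]]$p1 + 1L) ||
              (it$kind == "gap_arm2" &&
                 ints[[j + 1L]]$p2 == ints[[j]]$p2 - 1L)))
        j <- j + 1L
      if (it$kind == "gap_arm1") {
        p <- vapply(ints[i:j], `[[`, 0L, "p1")
        out[[length(out) + 1L]] <- list(
          kind = "gap_arm1", length = length(p),
          pos1 = off + min(p) - 1L, pos2 = NA_integer_,
          bases1 = paste(v[sort(p)], collapse = ""), bases2 = NA_character_,
          local1 = min(p), local2 = NA_integer_)
      } else {
        p <- vapply(ints[i:j], `[[`, 0L, "p2")
        out[[length(out) + 1L]] <- list(
          kind = "gap_arm2", length = length(p),
          pos1 = NA_integer_, pos2 = off + min(p) - 1L,
          bases1 = NA_character_, bases2 = paste(v[sort(p)], collapse = ""),
          local1 = NA_integer_, local2 = min(p))
      }
      i <- j + 1L
    }
  }
  out
}

#' @exportS3Method base::print
print.ivs_hits <- function(x, ...) {
  cat(sprintf("ivs_hits: %d structure(s) in window %s:%d-%d\n",
              length(x$hits), x$window$interval$chrom,
              x$window$interval$start, x$window$interval$end))
  for (h in x$hits)
    cat(sprintf("  arm1 %d-%d  arm2 %d-%d  spacer %d  aligned %d  interruptions %d\n",
                h$arm1[["start"]], h$arm1[["end"]],
                h$arm2[["start"]], h$arm2[["end"]],
                h$spacer_len, h$aligned_len, length(h$interruptions)))
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.ivs_hits <- function(x, ...) {
  if (!length(x$hits))
    return(data.frame(chrom = character(0), arm1_start = integer(0),
                      arm1_end = integer(0), arm2_start = integer(0),
                      arm2_end = integer(0), spacer_len = integer(0),
                      aligned_len = integer(0), n_interruptions = integer(0),
                      interruptions = character(0)))
  do.call(rbind, lapply(x$hits, function(h) data.frame(
    chrom = h$chrom,
    arm1_start = h$arm1[["start"]], arm1_end = h$arm1[["end"]],
    arm2_start = h$arm2[["start"]], arm2_end = h$arm2[["end"]],
    spacer_len = h$spacer_len, aligned_len = h$aligned_len,
    n_interruptions = length(h$interruptions),
    interruptions = paste(vapply(h$interruptions, function(it)
      sprintf("%s@%s/%s", it$kind,
              ifelse(is.na(it$pos1), ".", it$pos1),
              ifelse(is.na(it$pos2), ".", it$pos2)), ""), collapse = ";"),
    stringsAsFactors = FALSE)))
}

# Walk the alignment layout of one hit without materializing columns:
# groups consecutive same-kind interruption columns and records, for each
# group, its column span within the alignment, the member positions on
# each arm, and the flanking pair coordinates (used as indel anchors).
# Runs in O(number of interruptions).
.ivs_groups <- function(hit) {
  a1 <- hit$local[["a1"]]; a2 <- hit$local[["a2"]]
  b1 <- hit$local[["b1"]]; b2 <- hit$local[["b2"]]
  x <- a1; y <- b2; col <- 0L
  groups <- list(); cur <- NULL
  for (it in hit$ints_raw) {
    np <- if (it$kind == "gap_arm2") y - it$p2 else it$p1 - x
    if (np > 0L) {
      col <- col + np; x <- x + np; y <- y - np
      if (!is.null(cur)) {
        groups[[length(groups) + 1L]] <- cur
        cur <- NULL
      }
    }
    if (is.null(cur) || cur$kind != it$kind) {
      if (!is.null(cur)) groups[[length(groups) + 1L]] <- cur
      cur <- list(kind = it$kind, colstart = col + 1L,
                  xs = integer(0), ys = integer(0),
                  xprev = x - 1L, yprev = y + 1L)
    }
    col <- col + 1L
    if (it$kind == "mismatch") {
      cur$xs <- c(cur$xs, x); cur$ys <- c(cur$ys, y)
      x <- x + 1L; y <- y - 1L
    } else if (it$kind == "gap_arm1") {
      cur$xs <- c(cur$xs, x); x <- x + 1L
    } else {
      cur$ys <- c(cur$ys, y); y <- y - 1L
    }
    cur$colend <- col
    cur$xnext <- x; cur$ynext <- y
  }
  if (!is.null(cur)) groups[[length(groups) + 1L]] <- cur
  col <- col + (a2 - x + 1L)
  stopifnot(y - (a2 - x + 1L) == b1 - 1L)
  list(groups = groups, nc = col)
}

#' Derive blacklist entries from IVS interruptions
#'
#' For every interruption of every structure that satisfies the spacer,
#' arm-length and edge-distance criteria, predicts the artifact allele a
#' chimeric fold-back copy would write and emits one entry per affected
#' arm. A mismatched pair blacklists both genomic sites (the copy
#' direction is not fixed): at the arm1 site the predicted allele is the
#' complement of the arm2 base, and symmetrically. A gap of g bases on
#' one arm predicts a g-base deletion at its own site and a g-base
#' insertion (reverse complement of the gap bases) at the partner
#' junction; indel entries are left-normalized against the reference.
#' Interruptions involving `N` produce no entries. Entries outside `roi`
#' are dropped; duplicates by `(chrom, start, end, predicted_alt)` are
#' collapsed.
#'
#' @param hits An `ivs_hits` object from [scan_ivs()].
#' @param params Criteria to apply (defaults to the scan parameters).
#' @param roi Optional `genomic_intervals` restricting entries
#'   (typically the unpadded target regions).
#' @return A data.frame of entries: `chrom, start, end, ref,
#'   predicted_alt, source, structure_id` (0-based half-open spans).
#' @export
ivs_blacklist <- function(hits, params = hits$params, roi = NULL) {
  stopifnot(inherits(hits, "ivs_hits"))
  s <- hits$window$seq
  off <- hits$window$interval$start
  chrom <- hits$window$interval$chrom
  rows <- vector("list", 0L)
  add <- function(start, end, ref, alt, sid) {
    rows[[length(rows) + 1L]] <<- list(start = start, end = end, ref = ref,
                                       alt = alt, sid = sid)
  }
  for (h in hits$hits) {
    if (h$spacer_len < params$min_spacer || h$spacer_len > params$max_spacer ||
        h$aligned_len < params$min_arm || !length(h$ints_raw))
      next
    lay <- .ivs_groups(h)
    nc <- lay$nc
    sid <- sprintf("IVS:%s:%d-%d/%d-%d", chrom,
                   h$arm1[["start"]], h$arm1[["end"]],
                   h$arm2[["start"]], h$arm2[["end"]])
    for (g in lay$groups) {
      if (g$colstart - 1L < params$min_edge ||
          nc - g$colend < params$min_edge) next
      if (g$kind == "mismatch") {
        for (m in seq_along(g$xs)) {  # mismatch runs stay per-column events
          ci <- g$colstart + m - 1L
          if (ci - 1L < params$min_edge || nc - ci < params$min_edge) next
          x <- g$xs[m]; y <- g$ys[m]
          bx <- substr(s, x, x); by <- substr(s, y, y)
          if (bx == "N" || by == "N") next
          add(off + x - 1L, off + x, bx, .complement(by), sid)
          add(off + y - 1L, off + y, by, .complement(bx), sid)
        }
      } else if (g$kind == "gap_arm1") {
        g1 <- min(g$xs); g2 <- max(g$xs)
        gapseq <- substr(s, g1, g2)
        if (grepl("N", gapseq, fixed = TRUE) || g1 < 2L) next
        # deletion of the gap bases at the arm1 site
        del <- .normalize_allele(g1 - 2L, substr(s, g1 - 1L, g2),
                                 substr(s, g1 - 1L, g1 - 1L), s)
        add(off + del$start, off + del$start + nchar(del$ref),
            del$ref, del$alt, sid)
        # insertion of their reverse complement at the arm2 junction
        yA <- g$ynext
        ins <- .normalize_allele(yA - 1L, substr(s, yA, yA),
                                 paste0(substr(s, yA, yA),
                                        .revcomp_chr(gapseq)), s)
        add(off + ins$start, off + ins$start + nchar(ins$ref),
            ins$ref, ins$alt, sid)
      } else {  # gap_arm2
        h1 <- min(g$ys); h2 <- max(g$ys)
        gapseq <- substr(s, h1, h2)
        if (grepl("N", gapseq, fixed = TRUE) || h1 < 2L) next
        del <- .normalize_allele(h1 - 2L, substr(s, h1 - 1L, h2),
                                 substr(s, h1 - 1L, h1 - 1L), s)
        add(off + del$start, off + del$start + nchar(del$ref),
            del$ref, del$alt, sid)
        xA <- g$xprev
        ins <- .normalize_allele(xA - 1L, substr(s, xA, xA),
                                 paste0(substr(s, xA, xA),
                                        .revcomp_chr(gapseq)), s)
        add(off + ins$start, off + ins$start + nchar(ins$ref),
            ins$ref, ins$alt, sid)
      }
    }
  }
  entries <- if (length(rows)) list(data.frame(
    chrom = chrom,
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    ref = vapply(rows, `[[`, "", "ref"),
    predicted_alt = vapply(rows, `[[`, "", "alt"),
    source = "IVS",
    structure_id = vapply(rows, `[[`, "", "sid"),
    stringsAsFactors = FALSE)) else list()
  .finalize_entries(entries, roi)
}

# Shared entry post-processing: roi restriction, dedupe, sort.
.finalize_entries <- function(entries, roi) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), ref = character(0),
                      predicted_alt = character(0), source = character(0),
                      structure_id = character(0), stringsAsFactors = FALSE)
  if (!length(entries)) return(empty)
  e <- do.call(rbind, entries)
  if (!is.null(roi) && nrow(e)) {
    inroi <- vapply(seq_len(nrow(e)), function(i)
      any(roi$chrom == e$chrom[i] & roi$start < e$end[i] &
            roi$end > e$start[i]), logical(1))
    e <- e[inroi, , drop = FALSE]
  }
  if (!nrow(e)) return(empty)
  key <- paste(e$chrom, e$start, e$end, e$predicted_alt)
  e <- e[!duplicated(key), , drop = FALSE]
  e <- e[order(e$chrom, e$start, e$end, e$predicted_alt), , drop = FALSE]
  rownames(e) <- NULL
  e
}
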