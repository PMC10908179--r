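#' Parameters for imperfect palindrome (PS) scanning
#'
#' Defaults follow the blacklist criteria used for enzymatic-chemistry
#' artifact prediction: reported palindromes span (`helix length`, both
#' arms plus the unpaired center) at least 17 bp, and central expansion
#' halts immediately before the second non-pairing column, so a reported
#' structure contains at most one internal mismatched pair and its
#' longest continuously matched stretch is `helix_len - 2` (center and
#' mismatch column excluded).
#'
#' @param min_helix Minimum total span of a reported palindrome (bp).
#' @param stop_mismatches Expansion halts at this mismatch count
#'   (default 2; raising it admits more internal mismatches).
#' @param include_even_centers Also scan even (between-base) centers.
#' @return A `ps_params` list.
#' @export
ps_params <- function(min_helix = 17L, stop_mismatches = 2L,
                      include_even_centers = FALSE) {
  stopifnot(min_helix >= 3L, stop_mismatches >= 1L)
  structure(list(min_helix = as.integer(min_helix),
                 stop_mismatches = as.integer(stop_mismatches),
                 include_even_centers = isTRUE(include_even_centers)),
            class = "ps_params")
}

#' Expand a palindrome around a center position
#'
#' Compares `seq[center - k]` with the complement of `seq[center + k]`
#' for `k = 1, 2, ...`, recording non-pairing columns (an `N` on either
#' side counts as a mismatch) and halting immediately before the
#' `stop_mismatches`-th one or at either sequence end. A structure whose
#' outermost column is its only non-pairing column is trimmed to the
#' perfect core. The center base itself is always unpaired.
#'
#' @param seq Nucleotide string (uppercase `ACGTN`).
#' @param center_index 1-based center position (the unpaired base). With
#'   `even = TRUE` the center sits between `center_index` and
#'   `center_index + 1`.
#' @param stop_mismatches Halt at this mismatch count.
#' @param even Expand around a between-base center.
#' @return A list (`center`, `span_start`, `span_end`, `helix_len`,
#'   `matched_len`, `mismatches` — list of `(left, right, base_left,
#'   base_right)` 1-based positions) or `NULL` when no column pairs.
#' @export
expand_palindrome <- function(seq, center_index, stop_mismatches = 2L,
                              even = FALSE) {
  L <- nchar(seq)
  stopifnot(center_index >= 1L, center_index <= L)
  v <- strsplit(seq, "")[[1]]
  cv <- .complement_vec(v)
  if (even) {  # center between center_index and center_index + 1
    kmax <- min(center_index, L - center_index)
    if (kmax < 1L) return(NULL)
    lpos <- center_index - (1:kmax) + 1L
  } else {
    kmax <- min(center_index - 1L, L - center_index)
    if (kmax < 1L) return(NULL)
    lpos <- center_index - (1:kmax)
  }
  rpos <- center_index + (1:kmax)
  okc <- v[lpos] != "N" & v[rpos] != "N" & v[lpos] == cv[rpos]
  bad <- which(!okc)
  kend <- if (length(bad) >= stop_mismatches) bad[stop_mismatches] - 1L
          else kmax
  mm <- bad[bad <= kend]
  # trim terminal mismatch columns to the perfect core
  while (length(mm) && mm[length(mm)] == kend) {
    kend <- mm[length(mm)] - 1L
    mm <- mm[-length(mm)]
  }
  if (kend < 1L) return(NULL)
  mismatches <- lapply(mm, function(k) list(
    left = lpos[k], right = rpos[k],
    base_left = v[lpos[k]], base_right = v[rpos[k]]))
  helix <- if (even) 2L * kend else 2L * kend + 1L
  list(center = center_index,
       even = even,
       span_start = lpos[kend], span_end = rpos[kend],
       helix_len = helix,
       matched_len = helix - (if (even) 0L else 1L) - length(mm),
       mismatches = mismatches)
}

#' Scan a reference window for imperfect palindromes
#'
#' Runs central expansion at every nucleotide (and every between-base
#' center when `include_even_centers`), keeps structures with
#' `helix_len >= min_helix`, removes structures wholly contained in a
#' longer reported structure with the same mismatch pair, and returns
#' them sorted by center. Positions in the returned hits are genomic
#' (0-based).
#'
#' @param window A `reference_window` from [fetch_window()].
#' @param params A [ps_params()] object.
#' @return A `ps_hits` object: list with `hits`, `window`, `params`.
#' @export
scan_ps <- function(window, params = ps_params()) {
  stopifnot(inherits(window, "reference_window"))
  s <- window$seq
  L <- nchar(s)
  if (L < params$min_helix)
    return(structure(list(hits = list(), window = window, params = params),
                     class = "ps_hits"))
  raw <- list()
  for (c0 in seq_len(L)) {
    p <- expand_palindrome(s, c0, params$stop_mismatches, even = FALSE)
    if (!is.null(p) && p$helix_len >= params$min_helix)
      raw[[length(raw) + 1L]] <- p
    if (params$include_even_centers && c0 < L) {
      p <- expand_palindrome(s, c0, params$stop_mismatches, even = TRUE)
      if (!is.null(p) && p$helix_len >= params$min_helix)
        raw[[length(raw) + 1L]] <- p
    }
  }
  raw <- .ps_drop_contained(raw)
  off <- window$interval$start
  hits <- lapply(raw, function(p) {
    p$chrom <- window$interval$chrom
    p$center_g <- off + p$center - 1L
    p$span <- c(start = off + p$span_start - 1L, end = off + p$span_end)
    p$mismatches <- lapply(p$mismatches, function(m) {
      m$left_g <- off + m$left - 1L
      m$right_g <- off + m$right - 1L
      m
    })
    p
  })
  structure(list(hits = hits, window = window, params = params),
            class = "ps_hits")
}

# Containment removal: drop a structure wholly inside a longer one with an
# identical mismatch-pair set (which pins the same center geometry).
.ps_drop_contained <- function(raw) {
  if (length(raw) < 2L) return(raw)
  sig <- vapply(raw, function(p)
    paste(vapply(p$mismatches, function(m)
      sprintf("%d:%d", m$left, m$right), ""), collapse = ","), "")
  s1 <- vapply(raw, `[[`, 0L, "span_start")
  s2 <- vapply(raw, `[[`, 0L, "span_end")
  hl <- vapply(raw, `[[`, 0L, "helix_len")
  keep <- vapply(seq_along(raw), function(i) {
    !any(sig == sig[i] & hl > hl[i] & s1 <= s1[i] & s2 >= s2[i])
  }, logical(1))
  raw <- raw[keep]
  raw[order(vapply(raw, `[[`, 0L, "center"))]
}

#' @exportS3Method base::print
print.ps_hits <- function(x, ...) {
  cat(sprintf("ps_hits: %d palindrome(s) in window %s:%d-%d\n",
              length(x$hits), x$window$interval$chrom,
              x$window$interval$start, x$window$interval$end))
  for (h in x$hits)
    cat(sprintf("  center %d  span %d-%d  helix %d  mismatches %d\n",
                h$center_g, h$span[["start"]], h$span[["end"]],
                h$helix_len, length(h$mismatches)))
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.ps_hits <- function(x, ...) {
  if (!length(x$hits))
    return(data.frame(chrom = character(0), center = integer(0),
                      span_start = integer(0), span_end = integer(0),
                      helix_len = integer(0), matched_len = integer(0),
                      mismatches = character(0)))
  do.call(rbind, lapply(x$hits, function(h) data.frame(
    chrom = h$chrom, center = h$center_g,
    span_start = h$span[["start"]], span_end = h$span[["end"]],
    helix_len = h$helix_len, matched_len = h$matched_len,
    mismatches = paste(vapply(h$mismatches, function(m)
      sprintf("%d%s/%d%s", m$left_g, m$base_left, m$right_g, m$base_right),
      ""), collapse = ";"),
    stringsAsFactors = FALSE)))
}

#' Derive blacklist entries from palindrome mismatches
#'
#' Every reported palindrome with an internal mismatched pair
#' contributes entries at both genomic sites: the predicted artifact
#' allele at each site is the complement of the partner column's base
#' (the base a fold-back copy would write to perfect the pairing).
#' Perfect palindromes contribute nothing; mismatches involving `N`
#' produce no entries. Entries outside `roi` are dropped and duplicates
#' collapsed, as in [ivs_blacklist()].
#'
#' @param hits A `ps_hits` object from [scan_ps()].
#' @param params Criteria to apply (defaults to the scan parameters).
#' @param roi Optional `genomic_intervals` restriction.
#' @return A data.frame of entries (same columns as [ivs_blacklist()]).
#' @export
ps_blacklist <- function(hits, params = hits$params, roi = NULL) {
  stopifnot(inherits(hits, "ps_hits"))
  chrom <- hits$window$interval$chrom
  entries <- list()
  for (h in hits$hits) {
    if (h$helix_len < params$min_helix || !length(h$mismatches)) next
    sid <- sprintf("PS:%s:%d", chrom, h$center_g)
    for (m in h$mismatches) {
      if (m$base_left == "N" || m$base_right == "N") next
      entries[[length(entries) + 1L]] <- data.frame(
        chrom = chrom,
        start = c(m$left_g, m$right_g),
        end = c(m$left_g + 1L, m$right_g + 1L),
        ref = c(m$base_left, m$base_right),
        predicted_alt = c(.complement(m$base_right),
                          .complement(m$base_left)),
        source = "PS", structure_id = sid,
        stringsAsFactors = FALSE)
    }
  }
  .finalize_entries(entries, roi)
}
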