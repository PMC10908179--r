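#' Reverse complement of a nucleotide sequence
#'
#' Strict Watson-Crick reverse complement over the alphabet `{A,C,G,T,N}`
#' (case-insensitive input, uppercase output; `N` maps to `N`). Ambiguity
#' codes other than `N` are rejected rather than silently mapped, because
#' arm pairing in the scanners is only defined over `{A,C,G,T}`.
#'
#' @param seq A single nucleotide string.
#' @return The reverse complement, uppercase.
#' @examples
#' revcomp("AAA")      # "TTT"
#' revcomp("ACCGGT")   # its own reverse complement
#' revcomp("GACCN")    # "NGGTC"
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  up <- toupper(seq)
  bad <- regexpr("[^ACGTN]", up)
  if (bad > 0L)
    .stopf("non-ACGTN character '%s' at position %d",
           substr(up, bad, bad), bad)
  if (nchar(up) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(up)))
}

#' Construct a set of genomic intervals
#'
#' Intervals are 0-based half-open (BED convention) on named sequences;
#' this is the single coordinate convention used throughout the package.
#' VCF positions are converted at the boundary (`pos - 1`).
#'
#' @param chrom Character vector of sequence names.
#' @param start,end Integer vectors, 0-based half-open (`0 <= start < end`).
#' @return A `data.frame` of class `genomic_intervals` with columns
#'   `chrom`, `start`, `end`.
#' @export
gintervals <- function(chrom, start, end) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.integer(start),
                  end = as.integer(end),
                  stringsAsFactors = FALSE)
  if (any(x$start < 0L)) .stopf("interval start < 0")
  if (any(x$start >= x$end)) .stopf("interval with start >= end")
  class(x) <- c("genomic_intervals", "data.frame")
  x
}

.check_against_sizes <- function(x, chrom_sizes) {
  missing_chr <- setdiff(unique(x$chrom), names(chrom_sizes))
  if (length(missing_chr))
    .stopf("chrom '%s' absent from reference", missing_chr[1L])
  over <- x$end > chrom_sizes[x$chrom]
  if (any(over))
    .stopf("interval %s:%d-%d extends beyond chromosome end (%d)",
           x$chrom[over][1L], x$start[over][1L], x$end[over][1L],
           chrom_sizes[x$chrom[over]][1L])
  invisible(x)
}

#' Pad and merge target intervals
#'
#' Grows every interval by `pad` bases on each side (default 50, the
#' flank within which a fold-back structure can still place an artifact
#' site inside the target), clamps to `[0, chromosome length]`, and
#' merges overlapping or abutting results per chromosome. Each merged
#' interval remembers its contributing original intervals in the
#' `origin` list-column.
#'
#' @param intervals A `genomic_intervals` object (or data.frame with
#'   `chrom`, `start`, `end`).
#' @param pad Non-negative pad in bp.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return A `genomic_intervals` data.frame sorted by `(chrom, start)`,
#'   with an `origin` list-column of contributing input intervals.
#' @export
pad_and_merge <- function(intervals, pad = 50L, chrom_sizes) {
  stopifnot(pad >= 0L)
  x <- gintervals(intervals$chrom, intervals$start, intervals$end)
  .check_against_sizes(x, chrom_sizes)
  x$start_p <- pmax(0L, x$start - as.integer(pad))
  x$end_p <- pmin(as.integer(chrom_sizes[x$chrom]), x$end + as.integer(pad))
  out <- lapply(split(seq_len(nrow(x)), x$chrom), function(idx) {
    ir <- IRanges::IRanges(start = x$start_p[idx] + 1L, end = x$end_p[idx])
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    rv <- S4Vectors::mcols(red)$revmap
    data.frame(chrom = x$chrom[idx][1L],
               start = IRanges::start(red) - 1L,
               end = IRanges::end(red),
               origin = I(lapply(rv, function(k)
                 x[idx[k], c("chrom", "start", "end")])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Read / write BED intervals
#'
#' BED 3+ columns; a strand column, if present, is ignored (scanning is
#' strand-symmetric by construction). Coordinates stay 0-based half-open.
#'
#' @param path File path.
#' @return `read_bed`: a `genomic_intervals` data.frame (with `name` when
#'   present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) .stopf("BED file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) .stopf("malformed BED '%s': %s",
                                            path, conditionMessage(e)))
  out <- gintervals(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L,
                    GenomicRanges::end(gr))
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' @rdname read_bed
#' @param intervals Intervals to write.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  if (!is.null(intervals$name)) S4Vectors::mcols(gr)$name <- intervals$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write a FASTA reference
#'
#' @param path FASTA path (plain text). Names are truncated at the first
#'   whitespace.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' @rdname read_reference
#' @param reference A named `DNAStringSet` (or named character vector).
#' @export
write_reference <- function(reference, path) {
  if (is.character(reference))
    reference <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

#' Chromosome lengths of a reference
#' @param reference A `DNAStringSet`.
#' @return Named integer vector of sequence lengths.
#' @export
chrom_sizes <- function(reference) {
  stats::setNames(Biostrings::width(reference), names(reference))
}

#' Extract a padded reference window
#'
#' Fetches the (uppercased) reference sequence of a padded interval and
#' keeps the unpadded origin interval for later region-of-interest
#' restriction. Soft-masked (lowercase) bases are accepted and
#' uppercased; IUPAC ambiguity codes other than `N` are converted to `N`
#' with a warning, since pairing is undefined over them.
#'
#' @param reference A `DNAStringSet` (see [read_reference()]).
#' @param padded Single-row interval of the padded window.
#' @param origin Single-row interval it derives from (must be contained
#'   in `padded`); defaults to `padded`.
#' @return A `reference_window`: list with `seq` (uppercase string),
#'   `interval` (padded) and `origin`.
#' @export
fetch_window <- function(reference, padded, origin = padded) {
  stopifnot(nrow(padded) == 1L, nrow(origin) == 1L)
  .check_against_sizes(padded, chrom_sizes(reference))
  if (origin$chrom != padded$chrom ||
      origin$start < padded$start || origin$end > padded$end)
    .stopf("origin interval not contained in padded interval")
  s <- toupper(as.character(
    Biostrings::subseq(reference[[padded$chrom]],
                       start = padded$start + 1L, end = padded$end)))
  if (grepl("[^ACGTN]", s)) {
    .warnf("ambiguity codes other than N converted to N in window %s:%d-%d",
           padded$chrom, padded$start, padded$end)
    s <- gsub("[^ACGTN]", "N", s)
  }
  structure(list(seq = s,
                 interval = as.data.frame(padded)[, c("chrom", "start", "end")],
                 origin = as.data.frame(origin)[, c("chrom", "start", "end")]),
            class = "reference_window")
}

#' @exportS3Method base::print
print.reference_window <- function(x, ...) {
  cat(sprintf("reference_window %s:%d-%d (%d bp; origin %d-%d)\n",
              x$interval$chrom, x$interval$start, x$interval$end,
              nchar(x$seq), x$origin$start, x$origin$end))
  invisible(x)
}

# ---- VCF -------------------------------------------------------------------

#' Read variant records from a VCF
#'
#' Parses VCF v4.2 into a plain data.frame of per-allele records:
#' multi-allelic records are split into one row per ALT on read (the
#' filter operates per allele). `vaf` is extracted from an `AF=` INFO key
#' when present (per-allele for split records), else `NA`. Remaining
#' columns pass through verbatim; the meta header is preserved in the
#' `"meta"` attribute for lossless round-tripping of supported columns.
#'
#' @param path VCF path (plain or bgzipped).
#' @return data.frame with columns `chrom, pos, id, ref, alt, qual,
#'   filter, info, vaf` (`pos` is 1-based, VCF convention).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) .stopf("VCF file not found: %s", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) .stopf("malformed VCF '%s': %s",
                                           path, conditionMessage(e)))
  fx <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1L,
                                     dimnames = list(NULL, names(fx)))
  df <- data.frame(chrom = fx[, "CHROM"],
                   pos = as.integer(fx[, "POS"]),
                   id = fx[, "ID"],
                   ref = toupper(fx[, "REF"]),
                   alt = toupper(fx[, "ALT"]),
                   qual = fx[, "QUAL"],
                   filter = fx[, "FILTER"],
                   info = fx[, "INFO"],
                   stringsAsFactors = FALSE)
  # split multi-allelic records, one row per ALT
  alts <- strsplit(df$alt, ",", fixed = TRUE)
  n <- lengths(alts)
  out <- df[rep(seq_len(nrow(df)), n), , drop = FALSE]
  out$alt <- unlist(alts)
  out$allele_index <- unlist(lapply(n, seq_len))
  af <- vapply(strsplit(out$info, ";", fixed = TRUE), function(kv) {
    hit <- grep("^AF=", kv, value = TRUE)
    if (length(hit)) sub("^AF=", "", hit[1L]) else NA_character_
  }, character(1))
  afl <- strsplit(ifelse(is.na(af), "", af), ",", fixed = TRUE)
  out$vaf <- suppressWarnings(as.numeric(mapply(
    function(a, i) if (length(a) >= i) a[i]
                   else if (length(a)) a[1L] else NA_character_,
    afl, out$allele_index)))
  rownames(out) <- NULL
  bad <- out$ref == "" | out$alt == "" | out$ref == out$alt
  if (any(bad)) .stopf("invalid VCF record at line with POS %d", out$pos[bad][1L])
  attr(out, "meta") <- v@meta
  out
}

#' Write variant records to a VCF
#'
#' Serializes a record data.frame (as produced by [read_vcf()]) to plain
#' VCF v4.2 text. Records that were split per allele are written back
#' split. Unrecognized INFO content passes through verbatim.
#'
#' @param variants Record data.frame.
#' @param path Output path.
#' @param meta Character vector of meta header lines; defaults to the
#'   `"meta"` attribute, or a minimal header.
#' @export
write_vcf <- function(variants, path, meta = attr(variants, "meta")) {
  if (is.null(meta) || !length(meta))
    meta <- "##fileformat=VCFv4.2"
  if (!any(grepl("^##fileformat", meta)))
    meta <- c("##fileformat=VCFv4.2", meta)
  filt <- variants$filter
  if (!is.null(filt) && any(filt == "ivps_blacklist", na.rm = TRUE) &&
      !any(grepl("^##FILTER=<ID=ivps_blacklist", meta)))
    meta <- c(meta, paste0("##FILTER=<ID=ivps_blacklist,Description=",
                           "\"Site on the IVS/PS potential mutation blacklist\">"))
  g <- function(col, default = ".") {
    x <- variants[[col]]
    if (is.null(x)) rep(default, nrow(variants))
    else ifelse(is.na(x) | x == "", default, as.character(x))
  }
  body <- paste(g("chrom"), g("pos"), g("id"), g("ref"), g("alt"),
                g("qual"), g("filter"), g("info"), sep = "\t")
  writeLines(c(meta,
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               body), path)
  invisible(path)
}

# ---- variant normalization -------------------------------------------------

#' Normalize variant records
#'
#' Trims shared suffix/prefix bases and left-aligns indels against the
#' reference, keeping the VCF anchor-base convention for indels. The
#' blacklist is built from normalized alleles, so calls must be
#' normalized the same way before filtering.
#'
#' @param variants Record data.frame (`chrom, pos, ref, alt`, 1-based).
#' @param reference A `DNAStringSet`.
#' @return The data.frame with `pos`, `ref`, `alt` normalized.
#' @export
normalize_variants <- function(variants, reference) {
  if (!nrow(variants)) return(variants)
  for (i in seq_len(nrow(variants))) {
    chrseq <- as.character(reference[[variants$chrom[i]]])
    norm <- .normalize_allele(variants$pos[i] - 1L, variants$ref[i],
                              variants$alt[i], chrseq)
    variants$pos[i] <- norm$start + 1L
    variants$ref[i] <- norm$ref
    variants$alt[i] <- norm$alt
  }
  variants
}

# Trim shared suffix then prefix; left-align indels. start is 0-based.
# chrseq is the full chromosome string (windows are small in this package).
.normalize_allele <- function(start, ref, alt, chrseq) {
  ref <- toupper(ref); alt <- toupper(alt)
  # trim common suffix
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # trim common prefix (keep at least one base each)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    start <- start + 1L
  }
  # left-align pure indels (anchored VCF style)
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (!((lr == 1L) != (la == 1L)) || lr == la) break
    if (substr(ref, lr, lr) != substr(alt, la, la)) break
    if (start <= 0L) break
    prev <- substr(chrseq, start, start)  # base at 0-based start-1
    ref <- paste0(prev, substr(ref, 1L, lr - 1L))
    alt <- paste0(prev, substr(alt, 1L, la - 1L))
    start <- start - 1L
  }
  list(start = start, ref = ref, alt = alt)
}
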