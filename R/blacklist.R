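#' Build the potential mutation blacklist for a target panel
#'
#' The full prediction workflow: pads each target region (default
#' +50 bp a side) and merges overlaps, extracts the padded reference
#' windows, scans each window for imperfect inverted repeats and
#' imperfect palindromes, derives the predicted artifact sites from
#' their interruptions, and restricts the union (PBIVS plus PBPS) to the
#' original unpadded regions. The result is deterministic for fixed
#' inputs and carries a parameter/reference fingerprint so a filter run
#' can detect a mismatched blacklist.
#'
#' @param reference A `DNAStringSet` or FASTA path.
#' @param bed A `genomic_intervals` data.frame or BED path.
#' @param iparams [ivs_params()] for the IVS scanner.
#' @param pparams [ps_params()] for the PS scanner.
#' @param pad Flank added to each region before scanning (bp).
#' @return A `mutation_blacklist`: list with `entries` (data.frame:
#'   `chrom, start, end, ref, predicted_alt, source, structure_id`,
#'   0-based half-open, sorted, deduplicated) and `fingerprint`.
#' @export
build_blacklist <- function(reference, bed, iparams = ivs_params(),
                            pparams = ps_params(), pad = 50L) {
  if (is.character(reference)) reference <- read_reference(reference)
  if (is.character(bed)) bed <- read_bed(bed)
  fp <- .blacklist_fingerprint(reference, iparams, pparams, pad)
  if (is.null(bed) || !nrow(bed)) {
    .warnf("empty BED: building an empty blacklist")
    return(structure(list(entries = .finalize_entries(list(), NULL),
                          fingerprint = fp), class = "mutation_blacklist"))
  }
  merged <- pad_and_merge(bed, pad = pad, chrom_sizes = chrom_sizes(reference))
  roi <- gintervals(bed$chrom, bed$start, bed$end)
  entries <- list()
  for (i in seq_len(nrow(merged))) {
    padded <- merged[i, c("chrom", "start", "end")]
    win <- fetch_window(reference, padded)
    e1 <- ivs_blacklist(scan_ivs(win, iparams), iparams, roi = roi)
    e2 <- ps_blacklist(scan_ps(win, pparams), pparams, roi = roi)
    if (nrow(e1)) entries[[length(entries) + 1L]] <- e1
    if (nrow(e2)) entries[[length(entries) + 1L]] <- e2
  }
  structure(list(entries = .finalize_entries(entries, NULL),
                 fingerprint = fp),
            class = "mutation_blacklist")
}

.blacklist_fingerprint <- function(reference, iparams, pparams, pad) {
  refid <- .fingerprint_hash(paste(names(reference),
                                   Biostrings::width(reference),
                                   collapse = ";"))
  sprintf(paste0("pad=%d;min_spacer=%d;min_arm=%d;min_edge=%d;seed_len=%d;",
                 "max_interrupt=%d;max_spacer=%d;min_helix=%d;",
                 "stop_mismatches=%d;even_centers=%s;ref=%s"),
          pad, iparams$min_spacer, iparams$min_arm, iparams$min_edge,
          iparams$seed_len, iparams$max_interrupt, iparams$max_spacer,
          pparams$min_helix, pparams$stop_mismatches,
          tolower(pparams$include_even_centers), refid)
}

#' @exportS3Method base::print
print.mutation_blacklist <- function(x, ...) {
  src <- table(factor(x$entries$source, levels = c("IVS", "PS")))
  cat(sprintf("mutation_blacklist: %d entr%s (IVS %d, PS %d)\n",
              nrow(x$entries), if (nrow(x$entries) == 1L) "y" else "ies",
              src[["IVS"]], src[["PS"]]))
  cat(sprintf("  fingerprint: %s\n", x$fingerprint))
  invisible(x)
}

#' Filter variant calls against a blacklist
#'
#' Partitions normalized variant records into retained and removed
#' sets. In `position` mode (the default; the blacklist records sites) a
#' variant is removed when its reference span overlaps an entry span by
#' any base. In `allele` mode it must additionally match an entry's
#' normalized `(start, ref, predicted_alt)` exactly. The partition is
#' exact (retained and removed are disjoint and together equal the
#' input), removed records are annotated with the matching structure id,
#' and the operation is idempotent.
#'
#' @param variants Normalized record data.frame ([read_vcf()] +
#'   [normalize_variants()]): `chrom, pos (1-based), ref, alt`, plus any
#'   pass-through columns.
#' @param blacklist A `mutation_blacklist` (or bare entry data.frame).
#' @param mode `"position"` or `"allele"`.
#' @param reference Optional `DNAStringSet`; when supplied, a warning is
#'   raised if the blacklist was built against a different reference.
#' @return List with `retained` and `removed` data.frames (`removed`
#'   gains a `structure_id` column).
#' @export
filter_variants <- function(variants, blacklist,
                            mode = c("position", "allele"),
                            reference = NULL) {
  mode <- match.arg(mode)
  e <- if (inherits(blacklist, "mutation_blacklist")) blacklist$entries
       else blacklist
  if (!is.null(reference) && inherits(blacklist, "mutation_blacklist")) {
    refid <- .fingerprint_hash(paste(names(reference),
                                     Biostrings::width(reference),
                                     collapse = ";"))
    if (!grepl(paste0("ref=", refid, "$"), blacklist$fingerprint))
      .warnf("blacklist was built against a different reference")
  }
  if (!nrow(variants)) {
    removed <- variants
    removed$structure_id <- character(0)
    return(list(retained = variants, removed = removed))
  }
  vstart <- variants$pos - 1L
  vend <- vstart + nchar(variants$ref)
  hit_id <- rep(NA_character_, nrow(variants))
  if (!is.null(e) && nrow(e)) {
    for (i in seq_len(nrow(variants))) {
      ov <- e$chrom == variants$chrom[i] & e$start < vend[i] &
        e$end > vstart[i]
      if (mode == "allele")
        ov <- ov & e$start == vstart[i] & e$ref == variants$ref[i] &
          e$predicted_alt == variants$alt[i]
      if (any(ov)) hit_id[i] <- e$structure_id[which(ov)[1L]]
    }
  }
  removed <- variants[!is.na(hit_id), , drop = FALSE]
  removed$structure_id <- hit_id[!is.na(hit_id)]
  retained <- variants[is.na(hit_id), , drop = FALSE]
  rownames(removed) <- rownames(retained) <- NULL
  list(retained = retained, removed = removed)
}

#' Serialize / parse a blacklist TSV
#'
#' Plain TSV with a `#params:` comment line carrying the build
#' fingerprint, then `chrom, start, end, ref, predicted_alt, source,
#' structure_id` (0-based half-open). Round-trips losslessly.
#'
#' @param blacklist A `mutation_blacklist`.
#' @param path File path.
#' @export
write_blacklist <- function(blacklist, path) {
  stopifnot(inherits(blacklist, "mutation_blacklist"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#params: ", blacklist$fingerprint), con)
  writeLines(paste(c("chrom", "start", "end", "ref", "predicted_alt",
                     "source", "structure_id"), collapse = "\t"), con)
  if (nrow(blacklist$entries))
    utils::write.table(blacklist$entries, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_blacklist
#' @param reference Optional `DNAStringSet` to verify that each entry's
#'   `ref` matches the reference sequence at its span.
#' @export
read_blacklist <- function(path, reference = NULL) {
  if (!file.exists(path)) .stopf("blacklist file not found: %s", path)
  lines <- readLines(path)
  fp <- NA_character_
  if (length(lines) && startsWith(lines[1L], "#params:")) {
    fp <- trimws(sub("^#params:", "", lines[1L]))
    lines <- lines[-1L]
  } else {
    .warnf("blacklist '%s' has no #params fingerprint line", path)
  }
  if (!length(lines) || !startsWith(lines[1L], "chrom"))
    .stopf("malformed blacklist '%s': missing header", path)
  body <- lines[-1L]
  if (length(body)) {
    e <- utils::read.table(text = body, sep = "\t",
                           col.names = c("chrom", "start", "end", "ref",
                                         "predicted_alt", "source",
                                         "structure_id"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "character",
                                          "character", "character"))
  } else {
    e <- .finalize_entries(list(), NULL)
  }
  if (!is.null(reference) && nrow(e)) {
    obs <- vapply(seq_len(nrow(e)), function(i)
      toupper(as.character(Biostrings::subseq(
        reference[[e$chrom[i]]], e$start[i] + 1L, e$end[i]))), "")
    if (any(obs != e$ref))
      .stopf("blacklist entry ref mismatch at %s:%d",
             e$chrom[obs != e$ref][1L], e$start[obs != e$ref][1L])
  }
  structure(list(entries = e, fingerprint = fp),
            class = "mutation_blacklist")
}
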