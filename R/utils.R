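# Internal helpers shared across modules.

# Per-base Watson-Crick complement over {A,C,G,T,N}; input assumed validated.
.complement <- function(x) chartr("ACGTN", "TGCAN", x)

# Character-vector complement (one base per element).
.complement_vec <- function(v) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[v])
}

# Vectorised reverse complement of validated uppercase strings.
.revcomp_chr <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Cheap stable content hash for parameter fingerprints (not cryptographic).
.fingerprint_hash <- function(x) {
  ints <- utf8ToInt(x)
  sprintf("%08x", sum(ints * (seq_along(ints) %% 251 + 1)) %% 0xFFFFFFF)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
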