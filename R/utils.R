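# shared internal helpers

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. Every stochastic operation in the package funnels its
# randomness through this so that identical (inputs, seed) give identical
# artifacts.
withSeed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory for stochastic calls")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one master seed (all < 2^31).
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Subgenome letter from a chromosome name: "chr6B" -> "B"; unparseable -> "Un".
subgenomeLetter <- function(chrom) {
  m <- regmatches(chrom, regexpr("[0-9]([ABD])", chrom))
  out <- ifelse(nchar(m) == 2L, substr(m, 2L, 2L), "Un")
  out[is.na(out) | !nzchar(m)] <- "Un"
  out
}

# Cheap deterministic content hash (no external digest dependency): FNV-1a
# over the UTF-8 bytes of a character representation.
contentHash <- function(x) {
  bytes <- as.integer(charToRaw(paste(format(x), collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)   # xor touches the low byte only
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Random DNA of length n as a single string (fast path via raw vectors).
randomDNA <- function(n) {
  bases <- charToRaw("ACGT")
  rawToChar(bases[sample.int(4L, n, replace = TRUE)])
}

reverseComplement1 <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

stopCodons <- c("TAA", "TAG", "TGA")

splitCodons <- function(x) {
  n <- nchar(x) %/% 3L
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

translateCDS <- function(x) {
  # Translate a (possibly pseudogenized) CDS, reading through internal stops
  # as '*'; trailing incomplete codon dropped.
  cod <- splitCodons(x)
  aa <- GENCODE[cod]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

GENCODE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})
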