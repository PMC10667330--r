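# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Standard nuclear genetic code, keyed by codon.
codon_table <- function() {
  as.list(Biostrings::GENETIC_CODE)
}

# codon -> amino acid (single letter, "*" for stop)
translate_codons <- function(codons) {
  unname(unlist(Biostrings::GENETIC_CODE[codons]))
}

# amino acid -> synonymous codons
synonym_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", s))))
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  intToUtf8(sample(c(65L, 67L, 71L, 84L), n, replace = TRUE))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# All start positions (0-based) of fixed pattern `pat` in `subject`.
find_all <- function(pat, subject) {
  if (nchar(pat) == 0L || nchar(subject) < nchar(pat)) return(integer(0))
  m <- gregexpr(pat, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
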