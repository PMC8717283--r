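## Shared low-level helpers: codon table, translation, hydropathy scale,
## interval arithmetic. Coordinates are 0-based half-open on the forward
## strand throughout the package; GFF3 output converts to 1-based inclusive.

#' @import Biostrings
#' @import IRanges
NULL

# 64-codon table as a named character vector ("TAA" -> "*")
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

.CODONS <- NULL # filled at load
.SENSE_CODONS <- NULL
.AA_OF <- NULL

.onLoad <- function(libname, pkgname) {
  tab <- .codon_table()
  assignInMyNamespace(".AA_OF", tab)
  assignInMyNamespace(".CODONS", names(tab))
  assignInMyNamespace(".SENSE_CODONS", names(tab)[tab != "*"])
}

# Kyte-Doolittle hydropathy values
.KD <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Translate an in-frame nucleotide string; stops become "*", codons with N
# or other ambiguity become "X". Trailing partial codon is dropped.
translate_nt <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return("")
  n <- n - n %% 3L
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- .AA_OF[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# split a string into single characters
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# split an in-frame nucleotide string into codons
.codons_of <- function(s) {
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return(character(0))
  substring(s, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
}

# scoring matrix used for all guided protein alignments
.blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

# local protein alignment score + coordinates (1-based in both sequences)
.protein_local_align <- function(pattern, subject,
                                 gap_open = 10, gap_ext = 0.5) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pattern), Biostrings::AAString(subject),
    substitutionMatrix = .blosum62(), type = "local",
    gapOpening = gap_open, gapExtension = gap_ext
  )
  list(
    score = Biostrings::score(al),
    p_start = Biostrings::start(Biostrings::pattern(al)),
    p_end = Biostrings::end(Biostrings::pattern(al)),
    s_start = Biostrings::start(Biostrings::subject(al)),
    s_end = Biostrings::end(Biostrings::subject(al))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a fixed seed without clobbering the caller's RNG stream
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
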