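#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   reverseComplement matchPattern writeXStringSet
#' @importFrom utils write.table read.table head modifyList
#' @importFrom stats setNames
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement. IUPAC degeneracy codes are complemented
#' correctly (R<->Y, S<->S, ...), so the helper is also safe on restriction
#' enzyme recognition sequences.
#'
#' @param x character vector of DNA strings (IUPAC alphabet).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## fast per-base split; returns character vector of single letters
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## scalar reverse complement for plain ACGTN strings; avoids DNAStringSet
## construction overhead in per-window verification loops
revcomp1 <- function(x) {
  paste(rev(seq_chars(chartr("ACGTN", "TGCAN", x))), collapse = "")
}

## count of G+C characters in each string of a vector
count_gc <- function(x) {
  vapply(gregexpr("[GC]", x), function(m) if (m[1] == -1L) 0L else length(m),
         integer(1))
}

is_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTNacgtn]*$" else "^[ACGTacgt]*$"
  grepl(pat, x)
}

## IUPAC code -> regex character class (used by enzyme scanning oracle-style
## paths and input validation)
IUPAC_CLASS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
  K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
  H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

iupac_to_regex <- function(pattern) {
  ch <- seq_chars(toupper(pattern))
  bad <- setdiff(unique(ch), names(IUPAC_CLASS))
  if (length(bad) > 0)
    stop("invalid IUPAC letter(s): ", paste(bad, collapse = ", "))
  paste0(IUPAC_CLASS[ch], collapse = "")
}

## 0-based half-open interval -> user-facing 1-based inclusive string
format_region <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, start + 1L, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic seed scoping: run expr with a given seed, restore RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
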