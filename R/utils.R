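# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAStringSet reverseComplement
NULL

## vectorised reverse complement of character sequences (ACGTN only)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## complement of single bases, vectorised, preserves N
comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

## two-decimal display used for LOEUF tables: truncation toward zero
trunc2 <- function(x) trunc(x * 100) / 100

is_snv <- function(ref, alt) nchar(ref) == 1L & nchar(alt) == 1L &
  ref != alt

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a single value in [0, 1]", call. = FALSE)
}
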