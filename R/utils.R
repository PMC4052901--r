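#' @importFrom stats cor runif rpois setNames aggregate median quantile
#' @importFrom utils read.delim write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over a character vector of A/C/G/T/N
#' sequences.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# integer encoding A=1 C=2 G=3 T=4, NA for anything else
seq_to_int <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
}

int_to_seq <- function(v) {
  paste(DNA_BASES[v], collapse = "")
}

# Hamming distance between equal-length strings
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Distance between two consensus sequences
#'
#' Minimum Hamming-style distance over both orientations and all ungapped
#' placements of the shorter sequence fully inside the longer one; a width
#' difference of d adds d to the distance.  Used to compare a recovered
#' motif consensus with a reference.
#'
#' @param a,b consensus DNA strings.
#' @return integer distance.
#' @export
consensus_distance <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  wa <- nchar(a); wb <- nchar(b)
  d <- wb - wa
  best <- Inf
  av <- strsplit(a, "")[[1]]
  for (bb in c(b, revcomp(b))) {
    bv <- strsplit(bb, "")[[1]]
    for (s in 0:d) {
      best <- min(best, sum(av != bv[(s + 1):(s + wa)]) + d)
    }
  }
  as.integer(best)
}

# run code with a private RNG stream, restoring the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# derive a stage seed from a root seed, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
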