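#' The universal genetic code
#'
#' Returns the standard (universal) genetic code as used throughout the
#' package. Codons are ordered lexicographically over the bases T, C, A, G
#' (the PAML convention), so that state indices are stable across every
#' module: state 1 is TTT, state 2 is TTC, ..., state 64 is GGG. The 61
#' sense codons keep this relative order after the three stops (TAA, TAG,
#' TGA) are removed.
#'
#' @return An object of class `genetic_code` with components:
#'   \item{codons}{character(64), all triplets in TCAG-lexicographic order.}
#'   \item{amino_acids}{character(64), one-letter amino acids, `*` for stops.}
#'   \item{sense_codons}{character(61), sense codons in the same order.}
#'   \item{stop_codons}{character(3).}
#'   \item{sense_index}{named integer(61), triplet -> sense-state index.}
#' @examples
#' gc <- genetic_code()
#' gc$sense_codons[1:4]
#' @export
genetic_code <- function() .universal_code

# Built once at load time. The amino-acid string is the standard code read
# in TCAG order (TTT=F, TTC=F, TTA=L, ...).
.build_universal_code <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  # codons is now TTT TTC TTA TTG TCT ... GGG (first base slowest)
  aa <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "")[[1]]
  stopifnot(length(codons) == 64L, length(aa) == 64L)
  sense <- codons[aa != "*"]
  code <- structure(
    list(
      codons       = codons,
      amino_acids  = aa,
      sense_codons = sense,
      stop_codons  = codons[aa == "*"],
      sense_index  = stats::setNames(seq_along(sense), sense),
      sense_aa     = aa[aa != "*"]
    ),
    class = "genetic_code"
  )
  code$pairs <- .sense_pair_table(code)
  code
}

# Table of single-nucleotide neighbour pairs among sense codons, with
# transition / non-synonymous flags. Drives rate-matrix construction.
.sense_pair_table <- function(code) {
  sense <- code$sense_codons
  aa <- code$sense_aa
  n <- length(sense)
  mat <- do.call(rbind, strsplit(sense, ""))
  is_transition <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  out_i <- integer(0); out_j <- integer(0)
  out_ts <- logical(0); out_ns <- logical(0)
  for (i in seq_len(n - 1L)) {
    diffs <- sweep(mat[(i + 1L):n, , drop = FALSE], 2L, mat[i, ], FUN = "!=")
    ndiff <- rowSums(diffs)
    hit <- which(ndiff == 1L)
    if (!length(hit)) next
    j <- i + hit
    pos <- apply(diffs[hit, , drop = FALSE], 1L, which)
    x <- mat[cbind(i, pos)]
    y <- mat[cbind(j, pos)]
    out_i <- c(out_i, rep.int(i, length(j)))
    out_j <- c(out_j, j)
    out_ts <- c(out_ts, is_transition(x, y))
    out_ns <- c(out_ns, aa[j] != aa[i])
  }
  data.frame(i = out_i, j = out_j, transition = out_ts, nonsyn = out_ns)
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Universal genetic code:", length(x$sense_codons), "sense codons,",
      length(x$stop_codons), "stops (", paste(x$stop_codons, collapse = ", "),
      ")\nCodon order: lexicographic over T, C, A, G\n")
  invisible(x)
}
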