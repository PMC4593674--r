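#' Codon alignments
#'
#' A `codon_alignment` stores one gene's in-frame alignment as a matrix of
#' sense-codon state indices (1..61, in the TCAG-lexicographic order of
#' [genetic_code()]) with `NA` marking missing data. Any triplet that is not
#' composed of exactly A, C, G, T (gaps, N, IUPAC ambiguity codes) is treated
#' as missing; no partial resolution of ambiguity codes is attempted.
#' Codon columns are 1-based on every user-facing surface.
#'
#' @param states integer matrix (taxa x codon columns) of sense-codon state
#'   indices, `NA` for missing; rownames are taxon names.
#' @param gene gene identifier.
#' @param code a [genetic_code()].
#' @return An object of class `codon_alignment` with elements `states`,
#'   `taxa`, `gene`, `n_codons`, `code`.
#' @export
codon_alignment <- function(states, gene = "gene", code = genetic_code()) {
  stopifnot(is.matrix(states))
  if (is.null(rownames(states)) || anyDuplicated(rownames(states)))
    stop("'states' must have unique rownames (taxon names)")
  s <- states[!is.na(states)]
  if (length(s) && (any(s < 1L) || any(s > length(code$sense_codons))))
    stop("codon states must be in 1..", length(code$sense_codons), " or NA")
  structure(
    list(states = states, taxa = rownames(states), gene = gene,
         n_codons = ncol(states), code = code),
    class = "codon_alignment")
}

#' Read an in-frame codon alignment from FASTA
#'
#' Reads a nucleotide FASTA alignment and converts it to codon states.
#' Sequences must be equal length and a multiple of 3. Triplets containing
#' gaps (`-`) or ambiguity codes (N and other IUPAC letters) become missing.
#' In-frame stop codons are an error unless `mask_stops = TRUE`, in which
#' case they are converted to missing (and counted in the returned object's
#' `masked_stops` attribute).
#'
#' @param path FASTA file.
#' @param gene gene identifier; defaults to the file name without extension.
#' @param mask_stops convert in-frame stops to missing instead of erroring.
#' @param code a [genetic_code()].
#' @return a [codon_alignment()].
#' @export
read_codon_alignment <- function(path, gene = NULL, mask_stops = FALSE,
                                 code = genetic_code()) {
  seqs <- ape::read.FASTA(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  chars <- lapply(as.character(seqs), toupper)
  if (is.null(gene))
    gene <- sub("\\.[^.]*$", "", basename(path))
  nm <- names(seqs)
  if (is.null(nm) || anyDuplicated(nm))
    stop("duplicate or absent taxon names in ", path)
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths differ (", path, ")")
  if (lens[1L] %% 3L != 0L)
    stop("alignment length ", lens[1L], " is not a multiple of 3 (", path, ")")
  mat <- do.call(rbind, chars)
  rownames(mat) <- nm
  codon_alignment_from_chars(mat, gene = gene, mask_stops = mask_stops,
                             code = code)
}

# character matrix (taxa x nucleotide columns) -> codon_alignment
codon_alignment_from_chars <- function(mat, gene = "gene",
                                       mask_stops = FALSE,
                                       code = genetic_code()) {
  L <- ncol(mat) %/% 3L
  n <- nrow(mat)
  trip <- matrix(paste0(mat[, seq(1L, by = 3L, length.out = L), drop = FALSE],
                        mat[, seq(2L, by = 3L, length.out = L), drop = FALSE],
                        mat[, seq(3L, by = 3L, length.out = L), drop = FALSE]),
                 nrow = n)
  st <- matrix(unname(code$sense_index[trip]), nrow = n)
  clean <- grepl("^[ACGT]{3}$", trip)
  is_stop <- clean & trip %in% code$stop_codons
  n_stop <- sum(is_stop)
  if (n_stop > 0L && !mask_stops)
    stop("in-frame stop codon(s) in gene '", gene,
         "' (use mask_stops = TRUE to convert to missing)")
  st[!clean | is_stop] <- NA_integer_
  rownames(st) <- rownames(mat)
  out <- codon_alignment(st, gene = gene, code = code)
  attr(out, "masked_stops") <- n_stop
  out
}

#' Write a codon alignment to FASTA
#'
#' Missing codons are written as `---`, so a write/read round trip
#' reproduces states (including missing placement) exactly.
#'
#' @param aln a [codon_alignment()].
#' @param path output file.
#' @export
write_codon_alignment <- function(aln, path) {
  sense <- aln$code$sense_codons
  seqs <- apply(aln$states, 1L, function(row) {
    trip <- ifelse(is.na(row), "---", sense[row])
    paste(trip, collapse = "")
  })
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", aln$taxa[i]), seqs[i]), con)
  invisible(path)
}

#' @export
print.codon_alignment <- function(x, ...) {
  miss <- mean(is.na(x$states)) * 100
  cat(sprintf("codon_alignment '%s': %d taxa x %d codons (%.1f%% missing)\n",
              x$gene, length(x$taxa), x$n_codons, miss))
  invisible(x)
}

#' GC content at third codon positions
#'
#' Fraction of a taxon's non-missing codons whose third nucleotide is G or
#' C. A taxon with no non-missing codons yields `NA` (undefined), never 0:
#' a fragmentary sequence must not masquerade as AT-rich.
#'
#' @param aln a [codon_alignment()].
#' @param taxon taxon name; if `NULL`, a named vector over all taxa.
#' @return numeric in \[0, 1\], or `NA` where undefined.
#' @export
gc3 <- function(aln, taxon = NULL) {
  third <- substr(aln$code$sense_codons, 3L, 3L)
  gc_state <- third %in% c("G", "C")
  one <- function(row) {
    row <- row[!is.na(row)]
    if (!length(row)) return(NA_real_)
    mean(gc_state[row])
  }
  if (is.null(taxon))
    return(apply(aln$states, 1L, one))
  if (!taxon %in% aln$taxa) stop("taxon '", taxon, "' not in alignment")
  one(aln$states[taxon, ])
}

#' Foreground-background GC3 contrast
#'
#' Mean GC3 over the foreground tips minus mean GC3 over the remaining
#' tips, a diagnostic for compositional (GC-biased) confounding of
#' selection signals. Tip means are used; taxa whose GC3 is undefined
#' (fully missing) are dropped from their group's mean.
#'
#' @param aln a [codon_alignment()].
#' @param foreground_tips nonempty proper subset of the alignment's taxa.
#' @return numeric in \[-1, 1\].
#' @export
delta_gc3 <- function(aln, foreground_tips) {
  if (!length(foreground_tips) || !all(foreground_tips %in% aln$taxa))
    stop("foreground_tips must be a nonempty subset of the alignment's taxa")
  bg <- setdiff(aln$taxa, foreground_tips)
  if (!length(bg))
    stop("foreground_tips must be a proper subset (background is empty)")
  g <- gc3(aln)
  mean(g[foreground_tips], na.rm = TRUE) - mean(g[bg], na.rm = TRUE)
}

# one-line per-gene log entry used by the scan
.aln_log_line <- function(aln) {
  sprintf("gene=%s taxa=%d L=%d missing=%.1f%%", aln$gene, length(aln$taxa),
          aln$n_codons, 100 * mean(is.na(aln$states)))
}
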