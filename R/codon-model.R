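#' F3x4 codon equilibrium frequencies
#'
#' Position-specific nucleotide frequencies (a 3 x 4 table pooled over all
#' taxa, missing codons excluded) multiplied per codon and renormalized
#' over the 61 sense codons — the codeml default frequency model for
#' branch-site analyses.
#'
#' @param aln a [codon_alignment()].
#' @return An object of class `codon_frequencies`: numeric(61) summing to
#'   1, named by sense codon, with the 3x4 table as attribute `nuc_freq`.
#' @export
f3x4_frequencies <- function(aln) {
  code <- aln$code
  st <- aln$states[!is.na(aln$states)]
  if (!length(st)) stop("alignment has no non-missing codons")
  trip <- code$sense_codons[st]
  nuc <- c("T", "C", "A", "G")
  tab <- sapply(1:3, function(p) {
    f <- table(factor(substr(trip, p, p), levels = nuc))
    as.numeric(f) / length(trip)
  })                                   # 4 x 3: rows TCAG, cols position
  cmat <- do.call(rbind, strsplit(code$sense_codons, ""))
  w <- tab[match(cmat[, 1L], nuc), 1L] *
       tab[match(cmat[, 2L], nuc), 2L] *
       tab[match(cmat[, 3L], nuc), 3L]
  if (sum(w) <= 0)
    stop("degenerate nucleotide composition: all sense codons have zero weight")
  pi <- w / sum(w)
  names(pi) <- code$sense_codons
  structure(pi, nuc_freq = t(tab), class = "codon_frequencies")
}

#' Uniform codon frequencies
#'
#' Equal weight on the 61 sense codons; convenient for simulation.
#' @param code a [genetic_code()].
#' @export
uniform_codon_frequencies <- function(code = genetic_code()) {
  n <- length(code$sense_codons)
  structure(stats::setNames(rep(1 / n, n), code$sense_codons),
            class = "codon_frequencies")
}

#' @export
print.codon_frequencies <- function(x, ...) {
  cat("codon_frequencies over", length(x), "sense codons; range [",
      signif(min(x), 3), ",", signif(max(x), 3), "]\n")
  invisible(x)
}

# C++-ready neighbour-pair table (0-based)
.cpp_pairs <- function(code = genetic_code()) {
  p <- code$pairs
  list(i = as.integer(p$i - 1L), j = as.integer(p$j - 1L),
       ts = as.integer(p$transition), ns = as.integer(p$nonsyn))
}

# floor tiny/zero stationary weights so the symmetrized eigenproblem is
# well posed; renormalize
.regularize_pi <- function(pi, floor = 1e-8) {
  pi <- pmax(as.numeric(pi), floor)
  pi / sum(pi)
}

#' Goldman-Yang instantaneous rate matrix
#'
#' Builds the 61 x 61 codon rate matrix with \eqn{q_{ij} = \pi_j
#' \kappa^{[\mathrm{transition}]} \omega^{[\mathrm{nonsynonymous}]}} for
#' single-nucleotide changes and 0 otherwise; the diagonal makes rows sum
#' to zero. With `scale = TRUE` the matrix is rescaled so that
#' \eqn{-\sum_i \pi_i q_{ii} = 1}: one expected substitution per codon per
#' unit time.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi [f3x4_frequencies()] or any `codon_frequencies`.
#' @param scale rescale to one expected substitution per unit time.
#' @param code a [genetic_code()].
#' @return class `codon_rate_matrix`: list with `Q` (61 x 61), `pi`,
#'   `scale_constant` (the unscaled expected rate), `kappa`, `omega`.
#' @export
build_rate_matrix <- function(kappa, omega, pi, scale = TRUE,
                              code = genetic_code()) {
  stopifnot(is.finite(kappa), kappa > 0, is.finite(omega), omega >= 0)
  pi <- .regularize_pi(pi)
  n <- length(code$sense_codons)
  stopifnot(length(pi) == n)
  p <- code$pairs
  Q <- matrix(0, n, n, dimnames = list(code$sense_codons, code$sense_codons))
  mult <- ifelse(p$transition, kappa, 1) * ifelse(p$nonsyn, omega, 1)
  Q[cbind(p$i, p$j)] <- pi[p$j] * mult
  Q[cbind(p$j, p$i)] <- pi[p$i] * mult
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (scale) Q <- Q / rate
  structure(list(Q = Q, pi = pi, scale_constant = rate,
                 kappa = kappa, omega = omega),
            class = "codon_rate_matrix")
}

#' @export
print.codon_rate_matrix <- function(x, ...) {
  cat(sprintf("codon_rate_matrix: kappa=%.3g omega=%.3g, mean rate before scaling %.4g\n",
              x$kappa, x$omega, x$scale_constant))
  invisible(x)
}

#' Transition probabilities P(t) = exp(Qt)
#'
#' Matrix exponential through the symmetrized eigendecomposition (Q is
#' time-reversible). Entries are clamped to \[0, 1\] after removing
#' round-off negatives smaller than 1e-12 in magnitude.
#'
#' @param rm a [build_rate_matrix()] result (or a plain matrix `Q` with
#'   `pi` supplied).
#' @param t branch length (>= 0), expected substitutions per codon when the
#'   matrix was built with `scale = TRUE`.
#' @param pi stationary frequencies, only needed when `rm` is a bare matrix.
#' @return 61 x 61 row-stochastic matrix.
#' @export
transition_probabilities <- function(rm, t, pi = NULL) {
  if (t < 0) stop("branch length t must be >= 0")
  if (inherits(rm, "codon_rate_matrix")) {
    Q <- rm$Q; pi <- rm$pi
  } else {
    Q <- rm
    if (is.null(pi)) stop("supply 'pi' when passing a bare rate matrix")
  }
  d <- sqrt(pi)
  B <- Q * d %o% (1 / d)          # B_ij = sqrt(pi_i) q_ij / sqrt(pi_j)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  P <- (e$vectors * rep(1 / d, times = 1)) %*%
       (t(e$vectors) * exp(e$values * t)) %*% diag(d)
  # the above: D^{-1/2} U diag(e^{lambda t}) U' D^{1/2}
  P[P < 0 & P > -1e-12] <- 0
  P[P < 0] <- 0                   # anything larger is still round-off at t>>0
  P[P > 1] <- 1
  dimnames(P) <- dimnames(Q)
  P
}
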