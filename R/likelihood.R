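#' Branch-site model parameters
#'
#' The four-class branch-site mixture: class 0 (background and foreground
#' omega0), class 1 (neutral, omega = 1 everywhere), classes 2a/2b
#' (omega0 or 1 on background branches, omega2 on the foreground branch).
#' Class proportions are (p0, p1, p2a, p2b) with p2a = (1-p0-p1) p0 /
#' (p0+p1) and p2b = (1-p0-p1) p1 / (p0+p1). The null model fixes
#' omega2 = 1.
#'
#' @param kappa transition/transversion ratio (> 0).
#' @param omega0 purifying-class omega, in (0, 1).
#' @param omega2 foreground selected-class omega (>= 1; 1 in the null).
#' @param p0,p1 mixture weights of classes 0 and 1 (p0 + p1 <= 1, both > 0).
#' @return class `branch_site_params`.
#' @export
branch_site_params <- function(kappa, omega0, omega2, p0, p1) {
  stopifnot(kappa > 0, omega0 > 0, omega0 < 1, omega2 >= 1,
            p0 > 0 || p1 > 0, p0 >= 0, p1 >= 0, p0 + p1 <= 1 + 1e-12)
  psum <- p0 + p1
  structure(list(kappa = kappa, omega0 = omega0, omega2 = omega2,
                 p0 = p0, p1 = p1,
                 p2a = (1 - psum) * p0 / psum,
                 p2b = (1 - psum) * p1 / psum),
            class = "branch_site_params")
}

#' @export
print.branch_site_params <- function(x, ...) {
  cat(sprintf(
    "branch_site_params: kappa=%.4g omega0=%.4g omega2=%.4g\n  proportions p0=%.4g p1=%.4g p2a=%.4g p2b=%.4g\n",
    x$kappa, x$omega0, x$omega2, x$p0, x$p1, x$p2a, x$p2b))
  invisible(x)
}

#' Class proportions of a branch-site parameter set
#' @param params a [branch_site_params()].
#' @return numeric(4): p0, p1, p2a, p2b (sums to 1).
#' @export
class_proportions <- function(params) {
  c(p0 = params$p0, p1 = params$p1, p2a = params$p2a, p2b = params$p2b)
}

# --- internal: precomputed per-gene likelihood workspace -------------------

# Aligns tree and alignment, collapses site patterns, and packages the
# 0-based structures the C++ engine wants. Tip rows missing from the
# alignment are all-missing (contribute nothing).
.likelihood_data <- function(aln, tree, require_fg = TRUE) {
  po <- .tree_postorder(tree)
  if (require_fg && length(po$fg_edge) != 1L)
    stop("tree must have exactly one foreground branch flagged ",
         "(use tag_foreground())")
  if (!all(po$tip_label %in% aln$taxa))
    stop("tree tips absent from alignment: ",
         paste(setdiff(po$tip_label, aln$taxa), collapse = ", "))
  st <- aln$states[po$tip_label, , drop = FALSE]
  st[is.na(st)] <- 0L                      # 0 -> -1 after the 1-based shift
  key <- apply(st, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  pat <- st[, first, drop = FALSE] - 1L    # 0-based, missing = -1
  patwt <- as.numeric(table(key)[key[first]])
  is_fg <- integer(length(po$tlen))
  is_fg[po$fg_edge] <- 1L
  list(parent = as.integer(po$parent), child = as.integer(po$child),
       tlen = po$tlen, is_fg = is_fg,
       ntip = po$ntip, nnode = po$nnode, root = po$root,
       tipstate = pat, patwt = patwt,
       pattern_of_column = match(key, key[first]),
       n_codons = aln$n_codons,
       pairs = .cpp_pairs(aln$code))
}

#' Branch-site mixture log-likelihood of one gene
#'
#' Felsenstein-pruning log-likelihood of a codon alignment under the
#' branch-site mixture: \eqn{\ln L = \sum_h \log \sum_c p_c L_c(x_h)},
#' where class c uses the background omega on unflagged branches and the
#' foreground omega on the flagged branch. Missing codons contribute
#' all-ones partial vectors; identical columns are collapsed into patterns
#' before evaluation. A column that is impossible under the model (e.g.
#' conflicting states on a zero-length tree) makes the result `-Inf`.
#'
#' @param aln a [codon_alignment()]; must cover all tree tips.
#' @param tree a tree with exactly one foreground branch flagged.
#' @param params a [branch_site_params()].
#' @param pi codon frequencies (default [f3x4_frequencies()] of `aln`).
#' @return the log-likelihood (scalar), with attributes `scale_bg` and
#'   `scale_fg`, the branch-type rate-scaling constants used.
#' @export
gene_log_likelihood <- function(aln, tree, params, pi = NULL) {
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  ld <- .likelihood_data(aln, tree)
  pi <- .regularize_pi(pi)
  res <- cpp_branch_site_loglik(params$kappa, params$omega0, params$omega2,
                                params$p0, params$p1, pi, ld$pairs,
                                ld$parent, ld$child, ld$tlen, ld$is_fg,
                                ld$ntip, ld$nnode, ld$root,
                                ld$tipstate, ld$patwt)
  structure(res$lnL, scale_bg = res$scale_bg, scale_fg = res$scale_fg)
}
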