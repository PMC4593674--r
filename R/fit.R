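# run expr with a local RNG stream; the caller's .Random.seed is restored
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.simplex2 <- function(a, b) {
  ea <- exp(a); eb <- exp(b)
  d <- 1 + ea + eb
  c(ea / d, eb / d)
}

# negative lnL on the transformed parameter scale
.bs_objective <- function(x, ld, pi, null) {
  kappa <- exp(x[1L])
  omega0 <- stats::plogis(x[2L])
  pp <- .simplex2(x[3L], x[4L])
  omega2 <- if (null) 1 else 1 + exp(x[5L])
  if (!all(is.finite(c(kappa, omega0, omega2, pp))) || sum(pp) <= 0)
    return(1e10)
  res <- cpp_branch_site_loglik(kappa, omega0, omega2, pp[1L], pp[2L],
                                pi, ld$pairs, ld$parent, ld$child, ld$tlen,
                                ld$is_fg, ld$ntip, ld$nnode, ld$root,
                                ld$tipstate, ld$patwt)
  if (!is.finite(res$lnL)) return(1e10)
  -res$lnL
}

.bs_encode <- function(p, null) {
  x <- c(log(p$kappa), stats::qlogis(p$omega0),
         log(p$p0) - log1p(-p$p0 - p$p1), log(p$p1) - log1p(-p$p0 - p$p1))
  if (!null) x <- c(x, log(max(p$omega2 - 1, 1e-8)))
  x
}

.bs_decode <- function(x, null) {
  pp <- .simplex2(x[3L], x[4L])
  branch_site_params(kappa = exp(x[1L]),
                     omega0 = stats::plogis(x[2L]),
                     omega2 = if (null) 1 else 1 + exp(x[5L]),
                     p0 = pp[1L], p1 = pp[2L])
}

.bs_bounds <- function(null) {
  lower <- c(log(0.01), stats::qlogis(1e-6), -30, -30)
  upper <- c(log(100), stats::qlogis(1 - 1e-6), 30, 30)
  if (!null) {
    lower <- c(lower, log(1e-8))
    upper <- c(upper, log(999))
  }
  list(lower = lower, upper = upper)
}

# dispersed starting points; deterministic given seed
.bs_starts <- function(n_starts, null, seed) {
  base <- branch_site_params(kappa = 2, omega0 = 0.2,
                             omega2 = if (null) 1 else 2,
                             p0 = 0.7, p1 = 0.2)
  starts <- list(base)
  if (n_starts > 1L) {
    extra <- .with_seed(seed, lapply(seq_len(n_starts - 1L), function(k) {
      pr <- stats::runif(2, 0.05, 0.45)
      branch_site_params(kappa = stats::runif(1, 0.5, 5),
                         omega0 = stats::runif(1, 0.02, 0.8),
                         omega2 = if (null) 1 else 1 + exp(stats::runif(1, -1, 2.5)),
                         p0 = max(1 - sum(pr), 0.05), p1 = pr[1L])
    }))
    starts <- c(starts, extra)
  }
  starts
}

#' Single-omega (M0) branch-length step
#'
#' Fits the one-ratio Goldman-Yang model to a gene, either re-estimating a
#' single multiplicative scale factor for the input tree's branch lengths
#' (`mode = "scale"`, the default: genes share a fixed species-tree shape)
#' or every branch length freely (`mode = "m0"`). The resulting lengths are
#' then held fixed in the branch-site fits, the standard practice for
#' genome-scale screens.
#'
#' @param aln a [codon_alignment()].
#' @param tree a tree whose tips are covered by `aln` (foreground flag not
#'   required).
#' @param pi codon frequencies (default F3x4 from the gene).
#' @param mode `"scale"` or `"m0"`.
#' @return list with `kappa`, `omega`, `scale` (for mode "scale"), `lnL`,
#'   `tlen` (fitted branch lengths, postorder edge order), `convergence`.
#' @export
fit_m0 <- function(aln, tree, pi = NULL, mode = c("scale", "m0")) {
  mode <- match.arg(mode)
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  pi <- .regularize_pi(pi)
  ld <- .likelihood_data(aln, tree, require_fg = FALSE)
  ne <- length(ld$tlen)
  obj <- function(x) {
    kappa <- exp(x[1L]); omega <- exp(x[2L])
    tl <- if (mode == "scale") exp(x[3L]) * ld$tlen else exp(x[-(1:2)])
    s <- cpp_rate_away(kappa, omega, pi, ld$pairs)
    ls <- cpp_class_site_loglik(kappa, omega, omega, s, s, pi, ld$pairs,
                                ld$parent, ld$child, tl, ld$is_fg,
                                ld$ntip, ld$nnode, ld$root, ld$tipstate)
    v <- sum(ld$patwt * ls)
    if (!is.finite(v)) 1e10 else -v
  }
  x0 <- c(log(2), log(0.3),
          if (mode == "scale") 0 else log(pmax(ld$tlen, 1e-4)))
  nb <- if (mode == "scale") 3L else 2L + ne
  fit <- stats::nlminb(x0, obj,
                       lower = c(log(0.01), log(1e-4), rep(log(1e-6), nb - 2L)),
                       upper = c(log(100), log(50), rep(log(50), nb - 2L)),
                       control = list(iter.max = 500, eval.max = 2000))
  tl <- if (mode == "scale") exp(fit$par[3L]) * ld$tlen else exp(fit$par[-(1:2)])
  list(kappa = exp(fit$par[1L]), omega = exp(fit$par[2L]),
       scale = if (mode == "scale") exp(fit$par[3L]) else NA_real_,
       lnL = -fit$objective, tlen = tl, convergence = fit$convergence == 0)
}

# shared driver for alternative / null fits on a prepared workspace
.fit_bs_ld <- function(ld, pi, null, n_starts, seed, extra_starts = list(),
                       reltol = 1e-8) {
  bounds <- .bs_bounds(null)
  starts <- c(if (n_starts > 0L) .bs_starts(n_starts, null, seed),
              extra_starts)
  best <- NULL
  n_used <- 0L
  for (s in starts) {
    n_used <- n_used + 1L
    x0 <- .bs_encode(s, null)
    fit <- tryCatch(
      stats::nlminb(x0, .bs_objective, ld = ld, pi = pi, null = null,
                    lower = bounds$lower, upper = bounds$upper,
                    control = list(iter.max = 500, eval.max = 2000,
                                   rel.tol = reltol)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best))
    return(list(params = NULL, lnL = -Inf, convergence = FALSE,
                n_starts = n_used))
  list(params = .bs_decode(best$par, null), lnL = -best$objective,
       convergence = best$convergence == 0 || best$objective < 1e9,
       n_starts = n_used)
}

#' Fit the branch-site model to one gene
#'
#' Maximum-likelihood fit of the branch-site mixture (alternative model,
#' omega2 >= 1 free) or its null (omega2 = 1) on the flagged foreground
#' branch. Parameters are box-constrained through transforms (log for
#' kappa and omega2 - 1, logistic for omega0, additive-logratio for the
#' mixture weights) and optimized with multiple dispersed starts.
#'
#' @param aln a [codon_alignment()].
#' @param tree a tree with exactly one foreground branch flagged.
#' @param null fit the omega2 = 1 null instead of the alternative.
#' @param pi codon frequencies; default F3x4 from the gene.
#' @param branch_lengths `"scale"` (default; M0 refit of a single tree
#'   scale factor), `"m0"` (M0 refit of every branch length) or `"fixed"`
#'   (use the input lengths as-is).
#' @param n_starts number of optimizer starts (first is a fixed standard
#'   point, the rest dispersed deterministically from `seed`).
#' @param seed integer seed controlling the dispersed starts.
#' @return object of class `branch_site_fit`: `params`
#'   ([branch_site_params()]), `lnL`, `model`, `convergence`, `n_starts`,
#'   `branch_lengths` (mode), `m0` (the M0 step, if run), plus the fitted
#'   workspace used by [beb_site_posteriors()].
#' @seealso [lrt()], [beb_site_posteriors()], [test_gene()]
#' @export
fit_branch_site <- function(aln, tree, null = FALSE, pi = NULL,
                            branch_lengths = c("scale", "m0", "fixed"),
                            n_starts = 3L, seed = 1L) {
  branch_lengths <- match.arg(branch_lengths)
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  pi <- .regularize_pi(pi)
  ld <- .likelihood_data(aln, tree)
  m0 <- NULL
  if (branch_lengths != "fixed") {
    m0 <- fit_m0(aln, tree, pi = pi,
                 mode = if (branch_lengths == "scale") "scale" else "m0")
    ld$tlen <- m0$tlen
  }
  res <- .fit_bs_ld(ld, pi, null, n_starts, seed)
  structure(
    list(params = res$params, lnL = res$lnL,
         model = if (null) "null" else "alternative",
         convergence = res$convergence, n_starts = res$n_starts,
         branch_lengths = branch_lengths, m0 = m0,
         gene = aln$gene, pi = pi, ld = ld),
    class = "branch_site_fit")
}

#' @export
print.branch_site_fit <- function(x, ...) {
  cat(sprintf("branch_site_fit (%s model), gene '%s'\n  lnL = %.4f  (%s)\n",
              x$model, x$gene, x$lnL,
              if (x$convergence) "converged" else "NOT converged"))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' @export
logLik.branch_site_fit <- function(object, ...) {
  val <- object$lnL
  attr(val, "df") <- if (object$model == "null") 4L else 5L
  class(val) <- "logLik"
  val
}

#' @export
coef.branch_site_fit <- function(object, ...) {
  p <- object$params
  c(kappa = p$kappa, omega0 = p$omega0, omega2 = p$omega2,
    p0 = p$p0, p1 = p$p1, p2a = p$p2a, p2b = p$p2b)
}

#' @export
summary.branch_site_fit <- function(object, ...) {
  print(object)
  props <- class_proportions(object$params)
  cat("  class proportions sum:", format(sum(props)), "\n")
  invisible(object)
}

#' Likelihood ratio test for positive selection
#'
#' Statistic \eqn{2(\ln L_1 - \ln L_0)}, clamped at 0 (optimizer noise can
#' leave the alternative a hair below the null), compared to the chi-square
#' distribution with 1 d.f. (upper tail). The chi-square(1) reference is
#' conservative for this boundary hypothesis.
#'
#' @param lnL_null,lnL_alt log-likelihoods, or `branch_site_fit` objects.
#' @return list with `statistic` and `p_value`.
#' @export
lrt <- function(lnL_null, lnL_alt) {
  if (inherits(lnL_null, "branch_site_fit")) lnL_null <- lnL_null$lnL
  if (inherits(lnL_alt, "branch_site_fit")) lnL_alt <- lnL_alt$lnL
  stopifnot(is.finite(lnL_null), is.finite(lnL_alt))
  stat <- max(0, 2 * (lnL_alt - lnL_null))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Full branch-site test of one gene
#'
#' Runs the branch-length step once, fits null and alternative on the same
#' fixed lengths, repairs optimizer-noise nesting violations (each model is
#' restarted from the other's optimum if it falls below it), computes the
#' LRT and, optionally, BEB site posteriors.
#'
#' @inheritParams fit_branch_site
#' @param beb also compute Bayes Empirical Bayes site posteriors.
#' @param pss_threshold strict posterior threshold for calling a PSS.
#' @return object of class `gene_selection_test`: `fit_null`, `fit_alt`,
#'   `lrt` (list), `beb` (data frame or NULL), `pss` (PSS data frame),
#'   `gene`, `converged`.
#' @export
test_gene <- function(aln, tree, pi = NULL,
                      branch_lengths = c("scale", "m0", "fixed"),
                      n_starts = 3L, seed = 1L, beb = TRUE,
                      pss_threshold = 0.5) {
  branch_lengths <- match.arg(branch_lengths)
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  pi <- .regularize_pi(pi)
  ld <- .likelihood_data(aln, tree)
  m0 <- NULL
  if (branch_lengths != "fixed") {
    m0 <- fit_m0(aln, tree, pi = pi,
                 mode = if (branch_lengths == "scale") "scale" else "m0")
    ld$tlen <- m0$tlen
  }
  f0 <- .fit_bs_ld(ld, pi, null = TRUE, n_starts, seed)
  f1 <- .fit_bs_ld(ld, pi, null = FALSE, n_starts, seed,
                   extra_starts = if (!is.null(f0$params))
                     list(branch_site_params(f0$params$kappa,
                                             f0$params$omega0, 1 + 1e-6,
                                             f0$params$p0, f0$params$p1))
                   else list())
  # repair: re-run the null from the alternative's optimum, omega2 clamped
  if (!is.null(f1$params) && f1$lnL < f0$lnL) {
    clamped <- branch_site_params(f1$params$kappa, f1$params$omega0, 1,
                                  f1$params$p0, f1$params$p1)
    f0b <- .fit_bs_ld(ld, pi, null = TRUE, n_starts = 0L, seed,
                      extra_starts = list(clamped))
    if (f0b$lnL > f0$lnL) f0 <- f0b
    if (f1$lnL < f0$lnL) {  # push the alternative back above the null
      f1b <- .fit_bs_ld(ld, pi, null = FALSE, n_starts = 0L, seed,
                        extra_starts = list(branch_site_params(
                          f0$params$kappa, f0$params$omega0, 1 + 1e-6,
                          f0$params$p0, f0$params$p1)))
      if (f1b$lnL > f1$lnL) f1 <- f1b
    }
  }
  mk <- function(res, null) structure(
    list(params = res$params, lnL = res$lnL,
         model = if (null) "null" else "alternative",
         convergence = res$convergence, n_starts = res$n_starts,
         branch_lengths = branch_lengths, m0 = m0,
         gene = aln$gene, pi = pi, ld = ld),
    class = "branch_site_fit")
  fit0 <- mk(f0, TRUE); fit1 <- mk(f1, FALSE)
  converged <- f0$convergence && f1$convergence &&
    is.finite(f0$lnL) && is.finite(f1$lnL)
  test <- lrt(f0$lnL, f1$lnL)
  bdf <- NULL; pss <- NULL
  if (beb && converged) {
    bdf <- beb_site_posteriors(fit1)
    pss <- pss_sites(bdf, threshold = pss_threshold)
  }
  structure(list(fit_null = fit0, fit_alt = fit1, lrt = test,
                 beb = bdf, pss = pss, gene = aln$gene,
                 converged = converged),
            class = "gene_selection_test")
}

#' @export
print.gene_selection_test <- function(x, ...) {
  cat(sprintf("gene_selection_test '%s': LRT = %.4f, p = %.4g%s\n",
              x$gene, x$lrt$statistic, x$lrt$p_value,
              if (x$converged) "" else " [NOT converged]"))
  if (!is.null(x$pss) && nrow(x$pss))
    cat("  PSSs:", paste(sprintf("%d:%.3f", x$pss$codon, x$pss$pp_selected),
                         collapse = "; "), "\n")
  invisible(x)
}
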