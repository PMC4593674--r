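#' Bayes Empirical Bayes site posteriors
#'
#' Per-column posterior probabilities of the four branch-site classes,
#' integrating parameter uncertainty over a discrete prior grid: 10
#' midpoints each for omega0 on (0, 1) and omega2 on (1, 11), and a
#' uniform 10 x 10 midpoint grid on the (p0, p1) simplex (the 45 points
#' with p0 + p1 < 1). kappa, branch lengths and the rate-scaling constants
#' stay fixed at their maximum-likelihood values; each grid point is
#' weighted by its likelihood over the whole gene. Sites in classes 2a/2b
#' are the candidates for positive selection on the foreground branch.
#'
#' @param fit an alternative-model [fit_branch_site()] / [test_gene()] fit.
#' @param grid_size points per prior dimension (default 10).
#' @return data frame with one row per codon column: `codon` (1-based),
#'   `pp_class0`, `pp_class1`, `pp_class2a`, `pp_class2b`, `pp_selected`
#'   (= 2a + 2b), `best_class`. Rows sum to 1 across the four classes.
#' @export
beb_site_posteriors <- function(fit, grid_size = 10L) {
  stopifnot(inherits(fit, "branch_site_fit"))
  if (fit$model != "null" && is.null(fit$params))
    stop("fit did not converge; no parameters to anchor the BEB grid")
  if (fit$model == "null")
    stop("BEB site posteriors are computed from the alternative fit")
  ld <- fit$ld
  pi <- fit$pi
  p <- fit$params
  kappa <- p$kappa
  # rate scalings frozen at the MLE
  r <- function(w) cpp_rate_away(kappa, w, pi, ld$pairs)
  r0 <- r(p$omega0); r1 <- r(1); r2 <- r(p$omega2)
  sbg <- (p$p0 + p$p2a) * r0 + (p$p1 + p$p2b) * r1
  sfg <- p$p0 * r0 + p$p1 * r1 + (p$p2a + p$p2b) * r2

  g <- grid_size
  mid <- (2 * seq_len(g) - 1) / (2 * g)
  w0_grid <- mid                  # (0, 1)
  w2_grid <- 1 + 10 * mid         # (1, 11)
  sim <- expand.grid(i = seq_len(g), j = seq_len(g))
  sim$p0 <- mid[sim$i]; sim$p1 <- mid[sim$j]
  sim <- sim[sim$p0 + sim$p1 < 1, ]

  cls <- function(wbg, wfg)
    as.numeric(cpp_class_site_loglik(kappa, wbg, wfg, sbg, sfg, pi,
                                     ld$pairs, ld$parent, ld$child, ld$tlen,
                                     ld$is_fg, ld$ntip, ld$nnode, ld$root,
                                     ld$tipstate))
  npat <- ncol(ld$tipstate)
  L1 <- cls(1, 1)
  L0 <- vapply(w0_grid, function(w) cls(w, w), numeric(npat))
  L2b <- vapply(w2_grid, function(w) cls(1, w), numeric(npat))
  L2a <- matrix(NA_real_, npat, g * g)
  for (k in seq_len(g))
    for (m in seq_len(g))
      L2a[, (k - 1L) * g + m] <- cls(w0_grid[k], w2_grid[m])

  M <- pmax(L1, apply(L0, 1L, max), apply(L2b, 1L, max),
            apply(L2a, 1L, max))
  E1 <- exp(L1 - M)
  E0 <- exp(L0 - M)
  E2b <- exp(L2b - M)
  E2a <- exp(L2a - M)

  pts <- expand.grid(k = seq_len(g), m = seq_len(g), s = seq_len(nrow(sim)))
  ng <- nrow(pts)
  loglik <- numeric(ng)
  prop_of <- function(s) {
    p0 <- sim$p0[s]; p1 <- sim$p1[s]
    p2 <- 1 - p0 - p1
    c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
  }
  mix_of <- function(gidx) {
    k <- pts$k[gidx]; m <- pts$m[gidx]
    pr <- prop_of(pts$s[gidx])
    list(pr = pr,
         mix = pr[1L] * E0[, k] + pr[2L] * E1 +
               pr[3L] * E2a[, (k - 1L) * g + m] + pr[4L] * E2b[, m])
  }
  for (gi in seq_len(ng)) {
    mm <- mix_of(gi)
    loglik[gi] <- sum(ld$patwt * (log(mm$mix) + M))
  }
  wlog <- loglik - max(loglik)
  W <- exp(wlog); W <- W / sum(W)    # uniform prior over the grid
  post <- matrix(0, npat, 4L)
  for (gi in seq_len(ng)) {
    if (W[gi] < 1e-12) next
    k <- pts$k[gi]; m <- pts$m[gi]
    mm <- mix_of(gi)
    post[, 1L] <- post[, 1L] + W[gi] * mm$pr[1L] * E0[, k] / mm$mix
    post[, 2L] <- post[, 2L] + W[gi] * mm$pr[2L] * E1 / mm$mix
    post[, 3L] <- post[, 3L] + W[gi] * mm$pr[3L] * E2a[, (k - 1L) * g + m] / mm$mix
    post[, 4L] <- post[, 4L] + W[gi] * mm$pr[4L] * E2b[, m] / mm$mix
  }
  post <- post / rowSums(post)       # exact normalization per site
  full <- post[ld$pattern_of_column, , drop = FALSE]
  data.frame(codon = seq_len(ld$n_codons),
             pp_class0 = full[, 1L], pp_class1 = full[, 2L],
             pp_class2a = full[, 3L], pp_class2b = full[, 4L],
             pp_selected = full[, 3L] + full[, 4L],
             best_class = c("0", "1", "2a", "2b")[max.col(full)])
}

#' Positively selected sites from BEB posteriors
#'
#' Sites whose posterior probability of the selected classes (2a + 2b)
#' strictly exceeds the threshold: a posterior of exactly 0.50 is not a
#' PSS under the "more than 0.50" rule.
#'
#' @param beb data frame from [beb_site_posteriors()].
#' @param threshold strict lower bound on `pp_selected` (default 0.5).
#' @return data frame with `codon` (1-based) and `pp_selected`, ordered by
#'   codon.
#' @export
pss_sites <- function(beb, threshold = 0.5) {
  keep <- beb$pp_selected > threshold
  out <- beb[keep, c("codon", "pp_selected")]
  rownames(out) <- NULL
  out
}
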