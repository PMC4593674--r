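# Independent brute-force oracles. These deliberately avoid the package's
# computational paths: enumeration instead of pruning, explicit step-up
# instead of p.adjust, factorial sums instead of phyper.

# step-up BH by hand
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1)
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# one-sided hypergeometric tail P(X >= k) by explicit summation
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# sort-diff-median, written naively
oracle_median_interval <- function(pos) {
  if (length(pos) < 2) return(NA_real_)
  s <- sort(pos)
  gaps <- s[-1] - s[-length(s)]
  g <- sort(gaps)
  n <- length(g)
  if (n %% 2 == 1) g[(n + 1) / 2] else (g[n / 2] + g[n / 2 + 1]) / 2
}

# GC3 by direct string scan over the raw FASTA characters
oracle_gc3_from_chars <- function(nucs) {
  stopifnot(length(nucs) %% 3 == 0)
  third <- nucs[seq(3, length(nucs), by = 3)]
  trip1 <- nucs[seq(1, length(nucs), by = 3)]
  trip2 <- nucs[seq(2, length(nucs), by = 3)]
  ok <- trip1 %in% c("A", "C", "G", "T") & trip2 %in% c("A", "C", "G", "T") &
        third %in% c("A", "C", "G", "T")
  trip <- paste0(trip1, trip2, third)
  ok <- ok & !trip %in% c("TAA", "TAG", "TGA")
  if (!any(ok)) return(NA_real_)
  mean(third[ok] %in% c("G", "C"))
}

# truncated Taylor series for exp(Qt)
oracle_pmat_series <- function(Q, t, terms = 60) {
  n <- nrow(Q)
  P <- diag(n)
  term <- diag(n)
  for (k in seq_len(terms)) {
    term <- term %*% (Q * t) / k
    P <- P + term
  }
  P
}

# Branch-site mixture log-likelihood by exhaustive enumeration over all
# internal-node state assignments (trees of <= 4 tips). Uses the R-side
# transition_probabilities and scale constants from build_rate_matrix,
# never the C++ pruning path.
oracle_exhaustive_loglik <- function(aln, tree, params, pi) {
  pi <- as.numeric(pi) / sum(pi)
  phy <- stats::reorder(tree, "postorder")
  ntip <- ape::Ntip(phy)
  nint <- phy$Nnode
  edges <- phy$edge
  tlen <- phy$edge.length
  fg_edge <- which(edges[, 2] == phy$foreground_node)
  internal <- sort(unique(edges[, 1]))
  root <- ntip + 1
  props <- class_proportions(params)
  wbg <- c(params$omega0, 1, params$omega0, 1)
  wfg <- c(params$omega0, 1, params$omega2, params$omega2)
  rate_of <- function(w)
    build_rate_matrix(params$kappa, w, pi, scale = FALSE)$scale_constant
  sbg <- sum(props * sapply(wbg, rate_of))
  sfg <- sum(props * sapply(wfg, rate_of))
  states <- aln$states[phy$tip.label, , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(1:61), nint)))
  colnames(grid) <- internal
  total_log <- 0
  Pcache <- lapply(1:4, function(cl) {
    lapply(seq_len(nrow(edges)), function(e) {
      fg <- length(fg_edge) && e == fg_edge
      w <- if (fg) wfg[cl] else wbg[cl]
      s <- if (fg) sfg else sbg
      transition_probabilities(
        build_rate_matrix(params$kappa, w, pi, scale = FALSE), tlen[e] / s)
    })
  })
  for (col in seq_len(ncol(states))) {
    mix <- 0
    for (cl in 1:4) {
      term <- pi[grid[, as.character(root)]]
      for (e in seq_len(nrow(edges))) {
        pa <- grid[, as.character(edges[e, 1])]
        ch <- edges[e, 2]
        P <- Pcache[[cl]][[e]]
        if (ch <= ntip) {
          obs <- states[ch, col]
          if (!is.na(obs)) term <- term * P[cbind(pa, obs)]
        } else {
          term <- term * P[cbind(pa, grid[, as.character(ch)])]
        }
      }
      mix <- mix + unname(props[cl]) * sum(term)
    }
    total_log <- total_log + log(mix)
  }
  total_log
}
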