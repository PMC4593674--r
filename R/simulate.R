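#' Simulate one gene under the branch-site generative model
#'
#' Each codon column draws a site class from (p0, p1, p2a, p2b); the root
#' codon is drawn from `pi`; states then evolve down the tree with the
#' class- and branch-appropriate omega (background omega on unflagged
#' branches, foreground omega on the flagged branch). The same branch-type
#' rate scaling as the likelihood engine is used, so branch lengths mean
#' expected substitutions per codon averaged over classes. Deterministic
#' given `seed`.
#'
#' @param tree tree with exactly one foreground branch flagged (a tree with
#'   no flag is allowed if no class-2 weight is used, but the scan expects
#'   flags).
#' @param params a [branch_site_params()]; use `omega2 = 1` for null genes.
#' @param pi codon frequencies.
#' @param L alignment length in codons (>= 1).
#' @param seed integer seed.
#' @param gene gene identifier.
#' @param class_assignment optional integer vector of length `L` with
#'   values 1..4 (classes 0, 1, 2a, 2b) overriding the i.i.d. class draw —
#'   e.g. to plant a contiguous run of selected sites mimicking an
#'   alignment artifact.
#' @return list with `alignment` (a [codon_alignment()] over the tree's
#'   tips) and `truth` (site classes as "0"/"1"/"2a"/"2b", params, seed).
#' @export
simulate_gene <- function(tree, params, pi, L, seed = 1L, gene = "gene",
                          class_assignment = NULL) {
  stopifnot(L >= 1)
  code <- genetic_code()
  pi <- .regularize_pi(pi)
  po <- .tree_postorder(tree)
  fg_edge <- po$fg_edge
  props <- class_proportions(params)
  wbg <- c(params$omega0, 1, params$omega0, 1)
  wfg <- c(params$omega0, 1, params$omega2, params$omega2)
  pairs <- .cpp_pairs(code)
  r <- vapply(c(params$omega0, 1, params$omega2),
              function(w) cpp_rate_away(params$kappa, w, pi, pairs),
              numeric(1))
  sbg <- sum(props * r[c(1, 2, 1, 2)])
  sfg <- sum(props * r[c(1, 2, 3, 3)])

  .with_seed(seed, {
    classes <- if (is.null(class_assignment))
      sample.int(4L, L, replace = TRUE, prob = props)
    else as.integer(class_assignment)
    stopifnot(length(classes) == L, all(classes %in% 1:4))

    # transition matrices per (edge, class); distinct omegas shared
    Pm <- vector("list", 3L)  # omega0, 1, omega2 (unscaled Q)
    for (k in 1:3)
      Pm[[k]] <- build_rate_matrix(params$kappa, c(params$omega0, 1,
                                                   params$omega2)[k],
                                   pi, scale = FALSE, code = code)
    edge_P <- function(e, cl) {
      fg <- length(fg_edge) && e %in% fg_edge
      widx <- if (fg) c(1L, 2L, 3L, 3L)[cl] else c(1L, 2L, 1L, 2L)[cl]
      s <- if (fg) sfg else sbg
      transition_probabilities(Pm[[widx]], po$tlen[e] / s)
    }

    states <- matrix(NA_integer_, po$nnode, L)
    states[po$root, ] <- sample.int(61L, L, replace = TRUE, prob = pi)
    for (e in rev(seq_along(po$parent))) {   # preorder
      pa <- po$parent[e]; ch <- po$child[e]
      for (cl in sort(unique(classes))) {
        cols <- which(classes == cl)
        if (!length(cols)) next
        P <- edge_P(e, cl)
        pstates <- states[pa, cols]
        for (s in unique(pstates)) {
          idx <- cols[pstates == s]
          states[ch, idx] <- sample.int(61L, length(idx), replace = TRUE,
                                        prob = P[s, ])
        }
      }
    }
    tip_states <- states[seq_len(po$ntip), , drop = FALSE]
    rownames(tip_states) <- po$tip_label
    aln <- codon_alignment(tip_states, gene = gene, code = code)
    list(alignment = aln,
         truth = list(site_class = c("0", "1", "2a", "2b")[classes],
                      params = params, seed = seed,
                      selected_site = classes >= 3L))
  })
}

#' Simulate a study of genes with known truth
#'
#' Generates `n_genes` alignments on `tree`; the first
#' `round(n_genes * fraction_selected)` genes are "selected" (omega2 drawn
#' from `param_ranges$omega2`), the rest null (omega2 = 1 exactly).
#' Missing data are block-structured to mimic fragmentary transcriptome
#' assemblies: whole-taxon dropout plus contiguous masked codon runs.
#'
#' @param n_genes number of genes.
#' @param fraction_selected fraction in \[0, 1\] of genes generated with
#'   omega2 > 1.
#' @param tree tree with one flagged foreground branch.
#' @param param_ranges list of c(min, max) ranges for `kappa`, `omega0`,
#'   `p0`, `p1`, `omega2`, and `L` (codons). Defaults emulate a
#'   transcriptome-scale screen scaled down.
#' @param dropout list: `taxa` (named per-taxon probability that a gene
#'   lacks that taxon entirely), `block_rate` (expected masked blocks per
#'   taxon per gene), `block_len` (mean block length, codons).
#' @param pi codon frequencies (default uniform over sense codons).
#' @param seed study seed; every per-gene seed derives from it.
#' @return list with `genes` (list of [codon_alignment()]) and `truth`
#'   (data frame: gene, selected, kappa, omega0, omega2, p0, p1, L, seed;
#'   plus `site_classes`, a list of per-gene class vectors).
#' @export
simulate_study <- function(n_genes, fraction_selected, tree,
                           param_ranges = list(), dropout = list(),
                           pi = uniform_codon_frequencies(), seed = 1L) {
  stopifnot(fraction_selected >= 0, fraction_selected <= 1)
  pr <- utils::modifyList(
    list(kappa = c(1.5, 3), omega0 = c(0.05, 0.5), p0 = c(0.45, 0.65),
         p1 = c(0.15, 0.3), omega2 = c(4, 8), L = c(150, 400)),
    param_ranges)
  dp <- utils::modifyList(
    list(taxa = numeric(0), block_rate = 0, block_len = 30), dropout)
  n_sel <- round(n_genes * fraction_selected)
  draws <- .with_seed(seed, {
    list(u = matrix(stats::runif(n_genes * 6L), n_genes, 6L),
         gene_seeds = sample.int(.Machine$integer.max - 1L, n_genes))
  })
  rng <- function(col, range) range[1L] + draws$u[, col] * diff(range)
  truth <- data.frame(
    gene = sprintf("g%04d", seq_len(n_genes)),
    selected = seq_len(n_genes) <= n_sel,
    kappa = rng(1L, pr$kappa),
    omega0 = rng(2L, pr$omega0),
    p0 = rng(3L, pr$p0),
    p1 = rng(4L, pr$p1),
    omega2 = ifelse(seq_len(n_genes) <= n_sel, rng(5L, pr$omega2), 1),
    L = round(rng(6L, pr$L)),
    seed = draws$gene_seeds)
  genes <- vector("list", n_genes)
  site_classes <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    par_i <- branch_site_params(truth$kappa[i], truth$omega0[i],
                                truth$omega2[i], truth$p0[i], truth$p1[i])
    sim <- simulate_gene(tree, par_i, pi, truth$L[i],
                         seed = truth$seed[i], gene = truth$gene[i])
    aln <- sim$alignment
    aln <- .apply_dropout(aln, dp, seed = truth$seed[i] %% 1000003L + i)
    genes[[i]] <- aln
    site_classes[[i]] <- sim$truth$site_class
  }
  names(genes) <- truth$gene
  list(genes = genes,
       truth = truth, site_classes = site_classes,
       tree = tree, dropout = dp, seed = seed)
}

# block-structured missingness: whole-taxon dropout + contiguous codon runs
.apply_dropout <- function(aln, dp, seed) {
  if (!length(dp$taxa) && dp$block_rate <= 0) return(aln)
  .with_seed(seed, {
    st <- aln$states
    L <- ncol(st)
    for (tx in aln$taxa) {
      p_tx <- if (tx %in% names(dp$taxa)) dp$taxa[[tx]] else 0
      if (p_tx > 0 && stats::runif(1) < p_tx) {
        st[tx, ] <- NA_integer_
        next
      }
      if (dp$block_rate > 0) {
        nb <- stats::rpois(1, dp$block_rate)
        for (b in seq_len(nb)) {
          len <- 1L + stats::rgeom(1, 1 / dp$block_len)
          from <- sample.int(L, 1L)
          st[tx, from:min(L, from + len - 1L)] <- NA_integer_
        }
      }
    }
    out <- codon_alignment(st, gene = aln$gene, code = aln$code)
    out
  })
}

#' Taxa with any sequence data in an alignment
#' @param aln a [codon_alignment()].
#' @return character vector of taxa with at least one non-missing codon.
#' @export
present_taxa <- function(aln) {
  aln$taxa[rowSums(!is.na(aln$states)) > 0L]
}

#' Planted-cluster protein network fixture
#'
#' A planted-partition graph over `n_proteins` proteins split into
#' `n_clusters` equal groups: within-cluster pairs are connected with
#' probability `within_edge_prob`, between-cluster pairs with
#' `between_edge_prob`; edges get STRING-style combined scores (integers,
#' 400-999). Every member of cluster k is annotated with that cluster's
#' planted GO terms; background noise terms are sprinkled uniformly.
#'
#' @param n_proteins,n_clusters sizes.
#' @param within_edge_prob,between_edge_prob edge probabilities; within
#'   must exceed between.
#' @param go_terms_per_cluster planted terms per cluster.
#' @param n_noise_terms pool of background terms (each protein gets one
#'   with probability 1/2).
#' @param seed integer seed.
#' @return list: `edges` (data frame protein1, protein2, combined_score),
#'   `annotation` (data frame gene, term), `truth` (data frame protein,
#'   cluster; plus `planted_terms`, a list per cluster).
#' @export
make_network_fixture <- function(n_proteins = 60L, n_clusters = 4L,
                                 within_edge_prob = 0.8,
                                 between_edge_prob = 0.02,
                                 go_terms_per_cluster = 1L,
                                 n_noise_terms = 5L, seed = 1L) {
  stopifnot(within_edge_prob > between_edge_prob)
  .with_seed(seed, {
    prot <- sprintf("P%03d", seq_len(n_proteins))
    cluster <- rep(seq_len(n_clusters), length.out = n_proteins)
    cluster <- sort(cluster)
    pairs <- utils::combn(n_proteins, 2L)
    same <- cluster[pairs[1L, ]] == cluster[pairs[2L, ]]
    p_edge <- ifelse(same, within_edge_prob, between_edge_prob)
    keep <- stats::runif(ncol(pairs)) < p_edge
    edges <- data.frame(
      protein1 = prot[pairs[1L, keep]],
      protein2 = prot[pairs[2L, keep]],
      combined_score = sample(400:999, sum(keep), replace = TRUE))
    planted <- lapply(seq_len(n_clusters), function(k)
      sprintf("GO:C%02dT%02d", k, seq_len(go_terms_per_cluster)))
    ann <- do.call(rbind, lapply(seq_len(n_proteins), function(i) {
      terms <- planted[[cluster[i]]]
      if (stats::runif(1) < 0.5)
        terms <- c(terms, sprintf("GO:NOISE%02d",
                                  sample.int(n_noise_terms, 1L)))
      data.frame(gene = prot[i], term = terms)
    }))
    rownames(ann) <- NULL
    list(edges = edges,
         annotation = ann,
         truth = list(membership = data.frame(protein = prot,
                                              cluster = cluster),
                      planted_terms = planted))
  })
}
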