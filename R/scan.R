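#' Median interval distance between positively selected sites
#'
#' Successive differences of the sorted 1-based PSS codon positions
#' (adjacent codons give an interval of 1); the median uses the mean of
#' the two middle values for an even interval count. With fewer than two
#' positions the statistic is undefined and `NA` is returned.
#'
#' @param positions distinct 1-based codon columns of PSSs.
#' @return median interval in codons, or `NA` if undefined.
#' @export
median_pss_interval <- function(positions) {
  if (anyDuplicated(positions)) stop("duplicate PSS positions")
  if (length(positions) < 2L) return(NA_real_)
  stats::median(diff(sort(positions)))
}

#' Aggregation filter for clustered selection signals
#'
#' Genes whose PSSs are tightly clustered along the alignment (median
#' interval distance <= `cutoff` codons, boundary inclusive) are excluded
#' as likely alignment artifacts. Genes with an undefined median interval
#' (fewer than two PSSs) are kept: "aggregated" is meaningless below two
#' sites.
#'
#' @param d_med numeric vector of median PSS intervals (`NA` = undefined).
#' @param cutoff exclusion threshold in codons (default 10, inclusive).
#' @return logical vector: `TRUE` where the gene is excluded.
#' @export
aggregation_filter <- function(d_med, cutoff = 10) {
  !is.na(d_med) & d_med <= cutoff
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment: with ascending p-values,
#' q(i) = min over j >= i of p(j) * m / j, mapped back to input order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Pearson correlation of LRT p-values against delta-GC3
#'
#' Confounder diagnostic: a strong correlation between model fit and
#' foreground-background GC3 contrast would indicate compositional
#' (GC-biased) artifacts behind the selection signals.
#'
#' @param p_values per-gene LRT p-values.
#' @param delta_gc3 per-gene [delta_gc3()] values, same order.
#' @return list with `r` (Pearson correlation) and `p_value` (two-sided,
#'   t transform).
#' @export
gc3_lrt_correlation <- function(p_values, delta_gc3) {
  ok <- is.finite(p_values) & is.finite(delta_gc3)
  if (sum(ok) < 3L) stop("need at least 3 genes with both quantities")
  if (stats::sd(p_values[ok]) == 0 || stats::sd(delta_gc3[ok]) == 0)
    stop("zero variance in p-values or delta-GC3")
  ct <- stats::cor.test(p_values[ok], delta_gc3[ok], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Genome-wide branch-site selection scan
#'
#' Runs the full cascade for each focal branch: per gene, prune the
#' species tree to the taxa the gene covers, skip the gene for a branch
#' whose defining clade does not survive pruning, fit null and
#' alternative branch-site models (branch lengths from a per-gene M0
#' step), LRT, BEB site posteriors, then — across each branch's tested
#' genes — the raw p < `alpha` gate, the PSS aggregation filter, and BH
#' FDR over the filtered raw-significant set (filter first, correct
#' after).
#'
#' @param genes named list of [codon_alignment()] objects.
#' @param tree species tree (`ape::phylo`), branch lengths in expected
#'   substitutions per codon.
#' @param clades named list: focal-branch name -> tip labels of the clade
#'   whose parent branch is tested (a single tip for a terminal branch).
#'   See [read_clade_definitions()].
#' @param alpha raw LRT significance gate (default 0.05).
#' @param fdr_cutoff q-value significance cutoff (default 0.10, strict).
#' @param agg_cutoff aggregation-filter cutoff in codons (default 10,
#'   exclusion inclusive).
#' @param pss_threshold strict BEB posterior threshold for a PSS.
#' @param branch_lengths,n_starts,seed passed to the per-gene fits.
#' @param min_taxa minimum taxa with data for a gene to be testable.
#' @return object of class `selection_scan`: `results` (one row per
#'   gene x branch), `summary` (Table-1-style per-branch cascade counts),
#'   `log` (per-gene log lines), `config`.
#' @export
run_scan <- function(genes, tree, clades, alpha = 0.05, fdr_cutoff = 0.10,
                     agg_cutoff = 10, pss_threshold = 0.5,
                     branch_lengths = c("scale", "m0", "fixed"),
                     n_starts = 3L, seed = 1L, min_taxa = 4L) {
  branch_lengths <- match.arg(branch_lengths)
  stopifnot(length(genes) >= 1L, length(clades) >= 1L)
  if (is.null(names(genes)))
    names(genes) <- vapply(genes, function(a) a$gene, character(1))
  log_lines <- character(0)
  push <- function(...) log_lines[[length(log_lines) + 1L]] <<- sprintf(...)
  rows <- list()
  for (branch in names(clades)) {
    clade_tips <- clades[[branch]]
    if (!all(clade_tips %in% tree$tip.label))
      stop("clade '", branch, "' has tips absent from the tree")
    for (gname in names(genes)) {
      aln <- genes[[gname]]
      taxa <- intersect(tree$tip.label, present_taxa(aln))
      if (length(taxa) < min_taxa) {
        push("branch=%s gene=%s SKIP too_few_taxa (%d)", branch, gname,
             length(taxa))
        next
      }
      full <- tag_foreground(tree, clade_tips)
      gtree <- tryCatch(prune_to_taxa(full, taxa), error = function(e) NULL)
      if (is.null(gtree) || isTRUE(attr(gtree, "fg_lost")) ||
          is.na(gtree$foreground_node)) {
        push("branch=%s gene=%s SKIP foreground_untestable", branch, gname)
        next
      }
      sub <- codon_alignment(aln$states[gtree$tip.label, , drop = FALSE],
                             gene = aln$gene, code = aln$code)
      gt <- tryCatch(
        test_gene(sub, gtree, branch_lengths = branch_lengths,
                  n_starts = n_starts,
                  seed = (seed + .gene_hash(gname)) %% 2147483647L,
                  beb = TRUE, pss_threshold = pss_threshold),
        error = function(e) NULL)
      if (is.null(gt) || !gt$converged) {
        push("branch=%s gene=%s SKIP non_convergence", branch, gname)
        next
      }
      pss <- gt$pss
      d_med <- median_pss_interval(pss$codon)
      dg <- tryCatch(delta_gc3(sub, foreground_clade(gtree)),
                     error = function(e) NA_real_)
      push("branch=%s %s lnL0=%.3f lnL1=%.3f p=%.3g nPSS=%d", branch,
           .aln_log_line(sub), gt$fit_null$lnL, gt$fit_alt$lnL,
           gt$lrt$p_value, nrow(pss))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gname, branch = branch,
        n_taxa = length(gtree$tip.label), L = sub$n_codons,
        lnL0 = gt$fit_null$lnL, lnL1 = gt$fit_alt$lnL,
        lrt = gt$lrt$statistic, p = gt$lrt$p_value,
        kappa = gt$fit_alt$params$kappa,
        omega0 = gt$fit_alt$params$omega0,
        omega2 = gt$fit_alt$params$omega2,
        p0 = gt$fit_alt$params$p0, p1 = gt$fit_alt$params$p1,
        n_pss = nrow(pss),
        pss = paste(sprintf("%d:%.3f", pss$codon, pss$pp_selected),
                    collapse = ";"),
        d_med = d_med, delta_gc3 = dg)
    }
  }
  if (!length(rows)) stop("no gene x branch combination was testable")
  res <- do.call(rbind, rows)
  res$raw_significant <- res$p < alpha
  res$aggregation_excluded <- aggregation_filter(res$d_med, agg_cutoff)
  res$q <- NA_real_
  res$fdr_significant <- FALSE
  for (branch in unique(res$branch)) {
    idx <- which(res$branch == branch & res$raw_significant &
                 !res$aggregation_excluded)
    if (length(idx)) {
      res$q[idx] <- bh_fdr(res$p[idx])
      res$fdr_significant[idx] <- res$q[idx] < fdr_cutoff
    }
  }
  summary <- do.call(rbind, lapply(unique(res$branch), function(b) {
    r <- res[res$branch == b, ]
    data.frame(branch = b,
               n_datasets = nrow(r),
               n_raw_significant = sum(r$raw_significant),
               n_filtered_significant = sum(r$raw_significant &
                                            !r$aggregation_excluded),
               n_fdr_significant = sum(r$fdr_significant))
  }))
  structure(list(results = res, summary = summary, log = log_lines,
                 config = list(alpha = alpha, fdr_cutoff = fdr_cutoff,
                               agg_cutoff = agg_cutoff,
                               pss_threshold = pss_threshold,
                               branch_lengths = branch_lengths,
                               n_starts = n_starts, seed = seed,
                               min_taxa = min_taxa)),
            class = "selection_scan")
}

.gene_hash <- function(x) {
  sum(utf8ToInt(x) * seq_len(nchar(x))) %% 97L
}

#' @export
print.selection_scan <- function(x, ...) {
  cat("selection_scan across", length(unique(x$results$branch)),
      "focal branch(es)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
summary.selection_scan <- function(object, ...) {
  print(object)
  cat("\nFDR-significant genes:\n")
  sig <- object$results[object$results$fdr_significant,
                        c("gene", "branch", "p", "q", "n_pss")]
  print(sig, row.names = FALSE)
  invisible(object$summary)
}

#' Write scan outputs as TSV
#'
#' @param scan a [run_scan()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_scan <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("results.tsv", "summary.tsv", "scan.log",
                            "config.json"))
  utils::write.table(scan$results, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scan$summary, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(scan$log, paths[3L])
  writeLines(.json_config(scan$config), paths[4L])
  invisible(paths)
}

# minimal flat-JSON config echo (numbers and strings only)
.json_config <- function(cfg) {
  enc <- vapply(cfg, function(v)
    if (is.character(v)) paste0('"', v, '"') else format(v, digits = 12),
    character(1))
  paste0("{", paste(sprintf('"%s": %s', names(cfg), enc), collapse = ", "),
         "}")
}

#' Read clade definitions from a JSON or TSV file
#'
#' JSON: an object mapping branch names to arrays of tip labels. TSV: two
#' columns, `branch` and `tip`, one row per (branch, tip).
#'
#' @param path file path; format chosen by extension (`.json` vs other).
#' @return named list of tip-label vectors, as [run_scan()] expects.
#' @export
read_clade_definitions <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON clade files requires the 'jsonlite' package")
    lst <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    return(lapply(lst, as.character))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("branch", "tip") %in% names(tab)))
  split(tab$tip, tab$branch)
}
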