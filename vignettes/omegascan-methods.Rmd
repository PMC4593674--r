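---
title: "Branch-site selection scans with omegascan: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch-site selection scans with omegascan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omegascan)
```

## The question and the model

A genome-wide scan for episodic positive selection asks, for each gene and
each focal branch of a species phylogeny, whether some codon sites evolved
with a nonsynonymous/synonymous rate ratio $\omega > 1$ on that branch.
The canonical instrument is the branch-site mixture ("model A") built on
the Goldman–Yang codon substitution process over the 61 sense codons:

$$q_{ij} = \pi_j\,\kappa^{[\text{transition}]}\,\omega^{[\text{nonsynonymous}]}$$

for codons $i \ne j$ differing at exactly one nucleotide, $0$ for
multi-nucleotide changes, with the diagonal closing rows to zero. $\pi$ is
estimated by F3×4: position-specific nucleotide frequencies pooled over
taxa (missing codons excluded), multiplied per codon and renormalized over
the sense codons. The mixture has four site classes with proportions
$(p_0, p_1, p_{2a}, p_{2b})$, where
$p_{2a} = (1-p_0-p_1)\,p_0/(p_0+p_1)$ and
$p_{2b} = (1-p_0-p_1)\,p_1/(p_0+p_1)$:

| class | background $\omega$ | foreground $\omega$ |
|-------|--------------------|---------------------|
| 0     | $\omega_0 \in (0,1)$ | $\omega_0$ |
| 1     | 1 | 1 |
| 2a    | $\omega_0$ | $\omega_2 \ge 1$ |
| 2b    | 1 | $\omega_2$ |

The alternative model frees $\omega_2 \ge 1$; the null fixes
$\omega_2 = 1$. Their maximized log-likelihoods give the statistic
$2(\ln L_1 - \ln L_0)$, referred to $\chi^2_1$ (upper tail). The
$\chi^2_1$ reference is deliberately conservative for this boundary
hypothesis (the asymptotic null is a 50:50 mixture of a point mass at 0
and $\chi^2_1$); we keep it because it is the reference the screening
literature uses, and the type-I simulations below confirm the
conservatism.

Sites driving a significant signal are localized by Bayes Empirical Bayes
(BEB): per-column posterior probabilities of the selected classes
(2a + 2b), integrating over a discrete prior grid on the mixture
parameters. A column is a *positively selected site* (PSS) when its
posterior strictly exceeds 0.50.

## The screening cascade

The scan applies, per focal branch, a three-stage cascade:

1. **Raw screen** — genes with LRT $p < 0.05$.
2. **Aggregation filter** — among raw-significant genes, compute the
   median interval distance $D_\mathrm{med}$ between consecutive PSS
   positions; genes with $D_\mathrm{med} \le 10$ codons are excluded.
   Tightly clustered "selected" sites are the signature of local
   alignment error rather than selection. The boundary is inclusive
   (exactly 10 is excluded); with fewer than two PSSs the statistic is
   undefined and the gene is kept — aggregation is meaningless below two
   sites.
3. **FDR control** — Benjamini–Hochberg step-up q-values across each
   branch's surviving raw-significant genes, significance at $q < 0.10$.
   The filter precedes the correction, so the BH family is the filtered
   set; families are per-branch because the scan reports per-branch
   counts.

These choices make the cascade counts monotone by construction: tested
$\ge$ raw-significant $\ge$ filter-surviving $\ge$ FDR-significant.

As a compositional diagnostic, the scan also reports each gene's
$\Delta$GC3 — mean GC content at third codon positions of the foreground
tips minus the background tips — and the Pearson correlation between LRT
p-values and $\Delta$GC3 across genes (`gc3_lrt_correlation`). A strong
correlation would indicate GC-biased conversion or compositional drift
masquerading as selection. $\Delta$GC3 here is a tip-mean contrast; an
ancestral-reconstruction version would need inferred ancestral sequences
and is out of scope.

## Parameters that matter

* `kappa` (> 0): transition/transversion rate ratio; typically 1.5–5 in
  mammalian coding sequence. Fitted per gene.
* `omega0` ∈ (0,1), `omega2` ≥ 1, `p0`, `p1`: the mixture described
  above. Fitted per gene; `omega2 = 1` in the null.
* Branch lengths are *expected substitutions per codon*. Each branch type
  (background/foreground) carries one rate-scaling constant — the
  class-proportion-weighted mean substitution rate under that type's
  $\omega$ set — so lengths keep that meaning averaged over classes.
* `agg_cutoff` (default 10 codons, inclusive), `fdr_cutoff` (default
  0.10, strict), `pss_threshold` (default 0.50, strict), `alpha` (raw
  gate, 0.05).
* `min_score` (network stage, default 400): STRING "medium confidence"
  combined-score cutoff; the source study states no cutoff, so it is
  surfaced as logged configuration.

## Numerical and design choices

**Branch lengths.** Genome-scale screens fix branch lengths per gene from
a single-$\omega$ (M0) fit rather than re-estimating them jointly under
each branch-site model. `fit_branch_site` does this with
`branch_lengths = "scale"` by default: an M0 fit of $\kappa$, $\omega$
and one multiplicative scale factor applied to the species-tree lengths.
Since every gene's tree is pruned from one fixed species tree, a single
scale factor captures the per-gene rate while keeping relative branch
lengths — and costs a 3-parameter optimization instead of a
$2n$-parameter one. Full per-branch M0 estimation (`"m0"`) and fixed
input lengths (`"fixed"`) are available.

**Optimization.** Parameters are unconstrained-transformed (log
$\kappa$, logit $\omega_0$, additive log-ratio for $(p_0, p_1)$, log
$(\omega_2 - 1)$) and maximized with `nlminb`, 3 starts by default: one
standard point and dispersed points drawn deterministically from the
seed. Nesting violations from optimizer noise ($\ln L_1 < \ln L_0$) are
repaired by restarting each model from the other's optimum (with
$\omega_2$ clamped for the null); any residual negative statistic is
clamped to 0. Convergence tolerance is 1e-8 on the log-likelihood.

**Likelihood engine.** Felsenstein pruning over collapsed site patterns,
with per-pattern rescaling against underflow; $P(t) = e^{Qt}$ via the
symmetrized eigendecomposition (the GY process is time-reversible), with
round-off negatives clamped at zero and $t = 0$ returning the exact
identity. Missing codons (any triplet not composed of A/C/G/T, including
gaps and ambiguity codes) contribute all-ones partial vectors; no partial
resolution of ambiguity codes is attempted, matching their treatment as
fully unknown in the pruning pass. The engine is verified against
exhaustive enumeration of internal-node states on small trees to 1e-10
relative error.

**BEB grid.** 10 points per prior dimension: midpoints of $(0,1)$ for
$\omega_0$, midpoints of $(1,11)$ for $\omega_2$, and the 45 midpoints of
the unit square falling inside the $(p_0, p_1)$ simplex (a uniform
triangular grid). $\kappa$, branch lengths and the rate-scaling constants
stay frozen at their MLEs across the grid; freezing the scalings makes
the class site-likelihoods factor over $(\omega_0, \omega_2)$, reducing
the pruning work from 4500 grid evaluations to 121 per gene while
changing posteriors negligibly (the scaling varies little over the grid
relative to likelihood weights).

**Foreground identifiability under missing taxa.** Genes are pruned from
the fixed species tree to the taxa they cover. A focal branch stays
testable only while it is identifiable in the pruned tree: a terminal
focal branch needs its tip; a clade branch needs surviving members whose
full-tree MRCA is still the flagged node (i.e. survivors span the
clade's basal split) plus at least one surviving outgroup. When, say,
the hippopotamus drops out of a Whippomorpha (hippo + cetaceans) test,
the Whippomorpha stem merges indistinguishably into the cetacean stem
and the gene is skipped for that branch — which is why scans of this
design report smaller denominators for hippo-dependent branches.

## What the simulator emulates — and what it does not

`simulate_gene` draws each column's class i.i.d. from
$(p_0, p_1, p_{2a}, p_{2b})$, the root codon from $\pi$, and evolves
states down the tree with the class- and branch-appropriate $\omega$,
using the same branch-type rate scaling as the likelihood. `simulate_study`
adds study structure: a fixed fraction of selected genes ($\omega_2 > 1$
draws; null genes exactly $\omega_2 = 1$), parameter draws from stated
ranges, and block-structured dropout (whole-taxon removal plus contiguous
masked codon runs) mimicking fragmentary transcriptome assemblies rather
than i.i.d. missingness.

It does **not** emulate alignment error, orthology mistakes, selection on
synonymous sites, indels, or autocorrelated site classes. Passing tests
on simulated data therefore demonstrate correctness of the inference
machinery under the model's own assumptions, not robustness to real-data
artifacts — that is precisely why the aggregation filter exists, and the
`class_assignment` argument lets tests plant contiguous high-$\omega$
runs to exercise it.

## Study conditions used by the checks

All sizes were fixed up front as scaled-down analogues of a
transcriptome-scale mammalian screen, sized for a single CPU:

* **Tree**: 6-taxon cetartiodactyl-like topology, foreground = the
  (dolphin, whale) ancestral branch, length 0.25; total tree length
  ≈ 2.2. Composition: GC-skewed F3×4-style $\pi$.
* **Type-I**: 100 null genes ($\omega_2 = 1$), L = 200 codons; rejection
  at $\alpha = 0.05$ must stay within the conservative band (≤ 0.10).
* **Power**: 50 genes with $\omega_2 = 8$ and $p_{2a} + p_{2b} = 0.2$
  ($p_0 = 0.45$, $p_1 = 0.35$), L = 400; expected: rejection ≥ 0.6,
  median $\hat\omega_2 > 2$, and BEB posteriors separating true class-2
  sites from class-0 sites.
* **Stationarity**: the simulator's pooled tip frequencies must sit
  within 0.01 total variation of $\pi$. Precision analysis done before
  running any check: with total tree length 50 and L = 5000 the pooled
  estimator's sampling noise alone has expected TV
  $\tfrac12\sum_i\sqrt{2\pi_i/(\pi N_\mathrm{eff})}$ with
  $N_\mathrm{eff} = nL/[1+(n-1)\bar\rho]$ and tip-tip correlation
  $\bar\rho$ computable from $P_{ii}(2t)$; the minimum over tip counts
  is ≈ 0.012 for a single alignment — above the band for *any* single
  fixture. The check therefore pools 3 replicate alignments from a
  20-tip star (branch 2.5, near-neutral parameters), for an expected TV
  ≈ 0.007: same conditions, adequate estimator precision.
* **Network stage**: planted-partition fixture, 4 clusters × 15
  proteins, within-cluster edge probability 0.8, between 0.02, 999 label
  permutations.

## Degenerate inputs and tie-breaks

* Zero-length branches give exact identity transition matrices; a column
  with conflicting states on a zero-length tree has likelihood 0 and the
  gene log-likelihood is $-\infty$, signalled as such.
* A taxon with no data contributes nothing: masking a row to all-missing
  equals pruning its tip.
* A fully missing taxon's GC3 is `NA` (undefined), never 0, so
  fragmentary rows cannot masquerade as AT-rich; group means in
  $\Delta$GC3 drop undefined taxa.
* F3×4 compositions with a zero-frequency nucleotide at some position
  zero out codons; stationary weights are floored at 1e-8 and
  renormalized before eigendecomposition for numerical stability.
* Hub rankings break degree ties lexicographically; BH q-value order is
  stabilized by (p, term).
* In-frame stop codons are an error by default; `mask_stops = TRUE`
  converts them to missing and counts them.

## Known limitations

* The $\chi^2_1$ reference is conservative; power figures here are
  therefore lower bounds relative to the mixture reference.
* F3×4 is the only frequency model; F61/F1×4 and multi-nucleotide
  substitution models are out of scope.
* The BEB grid is the standard 10-point design; very small genes can
  leave the grid weights diffuse, which manifests as shrunken
  posteriors, not false confidence.
* GO enrichment is classic one-sided Fisher without ancestry
  decorrelation (no elim/weight); optional true-path propagation can be
  emulated by closing the annotation table before input.
* The clade-based identifiability rule errs on the side of skipping: a
  gene missing all but one member of a focal clade is skipped even
  though a merged-branch test would be computable, because the merged
  branch no longer measures the intended lineage.

## A small worked run

```{r example, eval = FALSE}
dir <- system.file("extdata/synthetic_scan", package = "omegascan")
genes <- lapply(list.files(dir, pattern = "fasta$", full.names = TRUE),
                read_codon_alignment)
tree <- parse_newick(file = file.path(dir, "species_tree.nwk"))
clades <- read_clade_definitions(file.path(dir, "clades.json"))
scan <- run_scan(genes, tree, clades["cetacea"], seed = 1)
print(scan)
summary(scan)
```

The fixture is synthetic (generated by `simulate_study`, truth table
alongside), so the scan's calls can be compared against `truth.tsv`.
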