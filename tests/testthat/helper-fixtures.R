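# Shared fixtures, built in code. The 6-taxon tree is a scaled-down
# cetartiodactyl-like topology; the foreground branch used in simulation
# studies is the (dolphin, whale) ancestral branch, length 0.25.

h_tree6 <- function(foreground = c("dolphin", "whale")) {
  tr <- parse_newick(paste0(
    "(((dolphin:0.07,whale:0.07):0.25,hippo:0.30):0.10,",
    "((pig:0.30,camel:0.30):0.15,cow:0.35):0.05);"))
  if (length(foreground)) tr <- tag_foreground(tr, foreground)
  tr
}

h_clades6 <- function() {
  list(cetacea = c("dolphin", "whale"),
       whippomorpha = c("dolphin", "whale", "hippo"),
       hippo = "hippo")
}

# GC-skewed F3x4-style composition (mammal-like coding sequence)
h_pi_skew <- function() {
  nf <- rbind(c(.15, .35, .15, .35), c(.20, .30, .20, .30),
              c(.15, .35, .15, .35))
  code <- genetic_code()
  cmat <- do.call(rbind, strsplit(code$sense_codons, ""))
  nuc <- c("T", "C", "A", "G")
  w <- nf[1, match(cmat[, 1], nuc)] * nf[2, match(cmat[, 2], nuc)] *
       nf[3, match(cmat[, 3], nuc)]
  structure(w / sum(w), names = code$sense_codons,
            class = "codon_frequencies")
}

# tiny alignment straight from nucleotide strings
h_aln_from_strings <- function(seqs, gene = "toy", mask_stops = FALSE) {
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  omegascan:::codon_alignment_from_chars(mat, gene = gene,
                                         mask_stops = mask_stops)
}

# random small alignment with optional missing cells
h_random_aln <- function(taxa, L, seed, miss_prob = 0) {
  set.seed(seed)
  st <- matrix(sample.int(61L, length(taxa) * L, replace = TRUE),
               nrow = length(taxa), dimnames = list(taxa, NULL))
  if (miss_prob > 0)
    st[matrix(runif(length(st)) < miss_prob, nrow(st))] <- NA_integer_
  codon_alignment(st, gene = "rand")
}

h_params_null <- function() branch_site_params(2, 0.2, 1, 0.7, 0.2)
h_params_sel <- function(omega2 = 8)
  branch_site_params(2, 0.2, omega2, 0.45, 0.35)
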