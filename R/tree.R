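#' Species trees with a designated foreground branch
#'
#' Trees are `ape::phylo` objects carrying one extra element,
#' `foreground_node`: the number of the node (tip or internal) whose parent
#' edge is the focal branch on which positive selection is allowed. The
#' codeml-style Newick dialect is supported for interchange: a `#1` suffix
#' on a tip or internal-node label marks that node's parent edge as
#' foreground. Trees are treated as rooted as written, since focal branches
#' are directional.
#'
#' @name selection_tree
NULL

#' Parse a Newick tree, honouring codeml `#1` foreground tags
#'
#' @param text Newick string, or `file` a path.
#' @param file optional path to a Newick file (used if `text` is missing).
#' @return an `ape::phylo` with an extra `foreground_node` element
#'   (`NA_integer_` if no branch is tagged).
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.1)#1:0.05,C:0.2);")
#' foreground_clade(tr)
#' @export
parse_newick <- function(text, file = NULL) {
  if (!is.null(file)) text <- paste(readLines(file), collapse = "")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed Newick string")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop("negative branch lengths")
  fg <- NA_integer_
  tip_tag <- grepl("#1$", phy$tip.label)
  if (any(tip_tag)) {
    if (sum(tip_tag) > 1L) stop("more than one '#1' foreground tag")
    fg <- which(tip_tag)
    phy$tip.label <- sub("\\s*#1$", "", phy$tip.label)
  }
  if (!is.null(phy$node.label)) {
    node_tag <- grepl("#1$", phy$node.label)
    if (any(node_tag)) {
      if (sum(node_tag) > 1L || !is.na(fg))
        stop("more than one '#1' foreground tag")
      fg <- ape::Ntip(phy) + which(node_tag)
      phy$node.label <- sub("\\s*#1$", "", phy$node.label)
    }
  }
  if (!is.na(fg) && fg == ape::Ntip(phy) + 1L)
    stop("the root has no parent branch; it cannot be foreground")
  phy$foreground_node <- fg
  phy
}

#' Write a tree to Newick with the codeml `#1` tag
#'
#' @param tree a tree from [parse_newick()] or [tag_foreground()].
#' @param file optional path; if `NULL` the string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  phy <- tree
  fg <- phy$foreground_node
  ntip <- ape::Ntip(phy)
  if (!is.na(fg)) {
    if (fg <= ntip) {
      phy$tip.label[fg] <- paste0(phy$tip.label[fg], "#1")
    } else {
      if (is.null(phy$node.label)) phy$node.label <- rep("", phy$Nnode)
      phy$node.label[fg - ntip] <- paste0(phy$node.label[fg - ntip], "#1")
    }
  }
  phy$foreground_node <- NULL
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Flag the branch subtending a clade as foreground
#'
#' Flags exactly the single branch leading to the most recent common
#' ancestor of `clade_tips` (or to the tip itself, for a terminal branch),
#' clearing any previous flag. The tip set must be monophyletic: its MRCA
#' must subtend exactly those tips.
#'
#' @param tree an `ape::phylo`.
#' @param clade_tips character vector of tip labels.
#' @return the tree with `foreground_node` set.
#' @export
tag_foreground <- function(tree, clade_tips) {
  ntip <- ape::Ntip(tree)
  if (!length(clade_tips) || !all(clade_tips %in% tree$tip.label))
    stop("unknown tip name(s): ",
         paste(setdiff(clade_tips, tree$tip.label), collapse = ", "))
  if (length(clade_tips) == ntip)
    stop("clade cannot be the whole tip set (the root has no parent branch)")
  if (length(clade_tips) == 1L) {
    node <- match(clade_tips, tree$tip.label)
  } else {
    node <- ape::getMRCA(tree, clade_tips)
    below <- tree$tip.label[.tips_below(tree, node)]
    if (!setequal(below, clade_tips))
      stop("tip set is not monophyletic: MRCA also subtends ",
           paste(setdiff(below, clade_tips), collapse = ", "))
  }
  tree$foreground_node <- as.integer(node)
  tree
}

#' Tip labels of the flagged foreground clade
#'
#' @param tree a tree with a `foreground_node`.
#' @return character vector of tip labels (empty if untagged).
#' @export
foreground_clade <- function(tree) {
  fg <- tree$foreground_node
  if (is.null(fg) || is.na(fg)) return(character(0))
  tree$tip.label[.tips_below(tree, fg)]
}

.tips_below <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  if (node <= ntip) return(node)
  kids <- node
  tips <- integer(0)
  while (length(kids)) {
    ch <- phy$edge[phy$edge[, 1L] %in% kids, 2L]
    tips <- c(tips, ch[ch <= ntip])
    kids <- ch[ch > ntip]
  }
  tips
}

#' Prune a tree to a taxon subset
#'
#' Returns the induced subtree on `keep`: suppressed degree-2 nodes have
#' their branch lengths summed, so tip-to-tip path lengths among survivors
#' are unchanged.
#'
#' The foreground flag is re-derived on the pruned tree from the surviving
#' members of the flagged clade, and only when the focal branch stays
#' identifiable: for a terminal focal branch its tip must survive; for a
#' clade branch the surviving members' MRCA in the *original* tree must
#' still be the flagged node (i.e. the survivors span the clade's basal
#' split — otherwise the focal branch merges indistinguishably into a
#' descendant branch, as when the hippo drops out of a Whippomorpha test
#' and only the cetacean subclade remains). When the branch is not
#' identifiable, or no non-clade outgroup survives, `foreground_node` is
#' `NA` and attribute `fg_lost` is `TRUE`.
#'
#' @param tree an `ape::phylo`, optionally with a `foreground_node`.
#' @param keep tip labels to retain (at least 3).
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- intersect(tree$tip.label, keep)
  if (length(keep) < 3L) stop("fewer than 3 surviving tips")
  fg_tips <- foreground_clade(tree)
  pruned <- ape::keep.tip(tree, keep)
  pruned$foreground_node <- NA_integer_
  if (length(fg_tips)) {
    surv <- intersect(fg_tips, keep)
    identifiable <- length(surv) > 0L && length(surv) < length(keep) &&
      (length(fg_tips) == 1L ||
         (length(surv) >= 2L &&
            ape::getMRCA(tree, surv) == tree$foreground_node))
    if (identifiable) {
      pruned <- tag_foreground(pruned, surv)  # induced clades stay monophyletic
    } else {
      attr(pruned, "fg_lost") <- TRUE
    }
  }
  pruned
}

# postorder edge representation used by the likelihood engine
.tree_postorder <- function(phy) {
  phy2 <- stats::reorder(phy, "postorder")
  list(parent = phy2$edge[, 1L], child = phy2$edge[, 2L],
       tlen = phy2$edge.length,
       ntip = ape::Ntip(phy2), nnode = ape::Ntip(phy2) + phy2$Nnode,
       root = ape::Ntip(phy2) + 1L,
       tip_label = phy2$tip.label,
       fg_edge = if (is.null(phy2$foreground_node) ||
                     is.na(phy2$foreground_node)) integer(0)
                 else which(phy2$edge[, 2L] == phy2$foreground_node))
}
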