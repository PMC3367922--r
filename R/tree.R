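## Rooted phylogenies: Newick I/O and neighbor-joining (via ape), with
## deterministic node labeling so macros and hybrid-chain selectors can
## refer to every node.

setOldClass("phylo")

#' Rooted phylogenetic tree
#'
#' Wraps an \code{ape} \code{phylo} object, guaranteeing that every node
#' (tips and internals, including the root) carries a unique label.  Nodes
#' left unlabeled in the input get deterministic preorder names
#' \code{node1, node2, ...}.  Branch lengths are expected substitutions per
#' site and must be finite and nonnegative.
#'
#' @slot phylo the underlying \code{ape::phylo} tree.
#' @export
setClass("PhyloTree", representation(phylo = "phylo"))

setValidity("PhyloTree", function(object) {
  phy <- object@phylo
  msgs <- character(0)
  if (is.null(phy$edge.length)) msgs <- c(msgs, "tree has no branch lengths")
  else if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0))
    msgs <- c(msgs, "branch lengths must be finite and >= 0")
  if (anyDuplicated(phy$tip.label)) msgs <- c(msgs, "leaf names not unique")
  labs <- c(phy$tip.label, phy$node.label)
  if (length(phy$node.label) != phy$Nnode)
    msgs <- c(msgs, "missing internal node labels")
  else if (anyDuplicated(labs)) msgs <- c(msgs, "node labels not unique")
  if (length(msgs)) msgs else TRUE
})

## Preorder list of node indices (root first).
preorderNodes <- function(phy) {
  n <- length(phy$tip.label)
  root <- n + 1L
  childrenOf <- split(phy$edge[, 2L], phy$edge[, 1L])
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    kids <- childrenOf[[as.character(v)]]
    if (!is.null(kids)) stack <- c(stack, rev(kids))
  }
  out
}

#' @describeIn PhyloTree construct from an \code{ape::phylo}, auto-labeling
#'   unlabeled internal nodes in preorder.
#' @param phy an \code{ape::phylo} object.
#' @export
phyloTree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("need an ape 'phylo' object")
  if (is.null(phy$edge.length))
    phy$edge.length <- rep(0, nrow(phy$edge))
  ntip <- length(phy$tip.label)
  if (is.null(phy$node.label)) phy$node.label <- rep("", phy$Nnode)
  phy$node.label[is.na(phy$node.label)] <- ""
  if (any(!nzchar(phy$node.label))) {
    taken <- c(phy$tip.label, phy$node.label)
    counter <- 1L
    for (v in preorderNodes(phy)) {
      if (v <= ntip) next
      i <- v - ntip
      if (!nzchar(phy$node.label[i])) {
        repeat {
          cand <- paste0("node", counter)
          counter <- counter + 1L
          if (!(cand %in% taken)) break
        }
        phy$node.label[i] <- cand
        taken <- c(taken, cand)
      }
    }
  }
  new("PhyloTree", phylo = phy)
}

setMethod("show", "PhyloTree", function(object) {
  phy <- object@phylo
  cat("PhyloTree: ", length(phy$tip.label), " leaves, ", phy$Nnode,
      " internal nodes, total branch length ",
      format(sum(phy$edge.length), digits = 4), "\n", sep = "")
})

#' Tree accessors
#'
#' Labels in deterministic preorder (root first): all nodes, leaves only, or
#' branches (identified by their child node's label, so every non-root node
#' names one branch).
#'
#' @param tree a \code{\link{PhyloTree}}.
#' @return character vector of labels.
#' @export
treeNodeLabels <- function(tree) {
  phy <- tree@phylo
  labs <- c(phy$tip.label, phy$node.label)
  labs[preorderNodes(phy)]
}

#' @rdname treeNodeLabels
#' @export
treeLeafLabels <- function(tree) {
  ord <- preorderNodes(tree@phylo)
  ntip <- length(tree@phylo$tip.label)
  tree@phylo$tip.label[ord[ord <= ntip]]
}

#' @rdname treeNodeLabels
#' @export
treeBranchLabels <- function(tree) {
  phy <- tree@phylo
  labs <- c(phy$tip.label, phy$node.label)
  ord <- preorderNodes(phy)
  root <- length(phy$tip.label) + 1L
  labs[ord[ord != root]]
}

#' @rdname treeNodeLabels
#' @export
treeRootLabel <- function(tree) {
  phy <- tree@phylo
  c(phy$tip.label, phy$node.label)[length(phy$tip.label) + 1L]
}

nodeIndexOf <- function(tree, label) {
  phy <- tree@phylo
  i <- match(label, c(phy$tip.label, phy$node.label))
  if (is.na(i)) stop("node not in tree: ", label, call. = FALSE)
  i
}

## Postorder edge table: child index, parent index, length, child label.
treeEdgeTable <- function(tree) {
  phy <- ape::reorder.phylo(tree@phylo, "postorder")
  labs <- c(phy$tip.label, phy$node.label)
  data.frame(parent = phy$edge[, 1L], child = phy$edge[, 2L],
             length = phy$edge.length, childLabel = labs[phy$edge[, 2L]],
             stringsAsFactors = FALSE)
}

#' @rdname treeNodeLabels
#' @param label a node label.
#' @return for \code{subtreeNodeLabels}, the labels of all nodes in the
#'   clade rooted at \code{label} (the node itself included).
#' @export
subtreeNodeLabels <- function(tree, label) {
  phy <- tree@phylo
  labs <- c(phy$tip.label, phy$node.label)
  start <- nodeIndexOf(tree, label)
  childrenOf <- split(phy$edge[, 2L], phy$edge[, 1L])
  out <- integer(0)
  stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    kids <- childrenOf[[as.character(v)]]
    if (!is.null(kids)) stack <- c(stack, rev(kids))
  }
  labs[out]
}

#' Parse and write Newick trees
#'
#' Standard Newick with branch lengths and optional internal labels; parsing
#' wraps \code{ape::read.tree} and adds deterministic auto-labels for
#' unlabeled internal nodes; writing preserves topology, lengths and labels,
#' so a write/parse round trip is the identity.
#'
#' @param text Newick text.
#' @return \code{parseNewick}: a \code{\link{PhyloTree}};
#'   \code{writeNewick}: a Newick string.
#' @export
parseNewick <- function(text) {
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("malformed Newick: ", substr(paste(text, collapse = ""), 1, 60),
         call. = FALSE)
  phyloTree(phy)
}

#' @rdname parseNewick
#' @param tree a \code{\link{PhyloTree}}.
#' @export
writeNewick <- function(tree) {
  ape::write.tree(tree@phylo)
}

#' @rdname parseNewick
#' @param label node label at which to re-root (for reversible chains the
#'   likelihood is invariant to this choice).
#' @export
rerootTree <- function(tree, label) {
  i <- nodeIndexOf(tree, label)
  phy <- tree@phylo
  ntip <- length(phy$tip.label)
  if (i == ntip + 1L) return(tree)
  r <- if (i <= ntip) ape::root(phy, outgroup = i, resolve.root = TRUE)
       else ape::root(phy, node = i, resolve.root = TRUE)
  phyloTree(r)
}

#' Neighbor-joining tree estimation
#'
#' Agglomerates a symmetric distance matrix by neighbor-joining
#' (\code{ape::nj}); negative inferred branch lengths are clamped to zero
#' with a warning.  Two taxa yield a single split branch (half the distance
#' on each side of an arbitrary root); the general output is rooted
#' arbitrarily at the final join, which is harmless for reversible models.
#'
#' @param d symmetric numeric matrix with zero diagonal and taxon dimnames.
#' @return a \code{\link{PhyloTree}}.
#' @export
neighborJoining <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  taxa <- rownames(d)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(d)))
  if (nrow(d) < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (nrow(d) == 2L) {
    h <- d[1L, 2L] / 2
    return(parseNewick(sprintf("(%s:%s,%s:%s);", taxa[1L], formatNum(h),
                               taxa[2L], formatNum(h))))
  }
  dimnames(d) <- list(taxa, taxa)
  phy <- ape::nj(d)
  if (any(phy$edge.length < 0)) {
    warning("neighbor-joining produced negative branch length(s); ",
            "clamping to 0", call. = FALSE)
    phy$edge.length[phy$edge.length < 0] <- 0
  }
  phyloTree(phy)
}

#' Pairwise JC69-corrected distances from an alignment
#'
#' For each sequence pair, the proportion of differing tokens over shared
#' non-gap, non-wildcard columns is corrected with the Jukes-Cantor formula
#' d = -(3/4) log(1 - 4p/3); saturated pairs (p >= 3/4) are capped.
#'
#' @param rows named character vector of aligned rows (equal lengths).
#' @param alph the \code{\link{Alphabet}} (tokens/gaps/wildcards).
#' @param cap distance assigned to saturated pairs.
#' @return symmetric distance matrix.
#' @export
jcDistances <- function(rows, alph = dnaAlphabet(), cap = 10) {
  n <- length(rows)
  mat <- do.call(rbind, strsplit(tolower(rows), ""))
  ok <- matrix(mat %in% alph@tokens, nrow = n)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- ok[i, ] & ok[j, ]
    if (!any(use)) { d[i, j] <- d[j, i] <- cap; next }
    p <- mean(mat[i, use] != mat[j, use])
    dij <- if (p >= 0.75) cap else -0.75 * log(1 - 4 * p / 3)
    d[i, j] <- d[j, i] <- min(dij, cap)
  }
  d
}
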