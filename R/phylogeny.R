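## Profile-anchored alignment of p20 sub-domains, p-distances, a
## deterministic neighbour-joining tree, outgroup rooting and dyad-pure
## clade reports. Trees are ape "phylo" objects throughout.

#' Project p20 hits onto the profile match columns
#'
#' Builds a multiple alignment with one row per hit and one column per
#' profile match column: the residue each hit's column map points to, or
#' `-` where the column is deleted in the query. Query insertions relative
#' to the profile are discarded.
#'
#' @param hits hit table from [scanProteins()] (one hit per taxon; taxon ids
#'   are the protein ids and must be unique).
#' @param proteins protein table supplying the sequences.
#' @return character matrix, rownames = protein ids, one column per profile
#'   match column.
#' @export
projectAlignment <- function(hits, proteins) {
  if (anyDuplicated(hits$protein_id))
    stop("duplicate taxon id: ",
         hits$protein_id[duplicated(hits$protein_id)][1])
  key <- paste(proteins$strain_id, proteins$protein_id)
  L <- length(hits$col_map[[1]])
  M <- matrix("-", nrow = nrow(hits), ncol = L,
              dimnames = list(hits$protein_id, NULL))
  for (i in seq_len(nrow(hits))) {
    seqc <- proteins$sequence[match(paste(hits$strain_id[i],
                                          hits$protein_id[i]), key)]
    cm <- hits$col_map[[i]]
    ok <- !is.na(cm)
    M[i, ok] <- strsplit(seqc, "")[[1]][cm[ok]]
  }
  M
}

#' p-distance between two alignment rows
#'
#' Mismatches over compared columns, where compared columns carry no gap in
#' either row. Pairs sharing fewer than 20 compared columns get distance 1
#' with a warning.
#'
#' @param alignment character matrix from [projectAlignment()].
#' @param i,j row names or indices.
#' @return distance in `[0, 1]`.
#' @export
pDistance <- function(alignment, i, j) {
  a <- alignment[i, ]; b <- alignment[j, ]
  ok <- a != "-" & b != "-"
  if (sum(ok) < 20) {
    warning("fewer than 20 compared columns; distance set to 1")
    return(1)
  }
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Full p-distance matrix
#'
#' @param alignment character matrix from [projectAlignment()].
#' @return symmetric numeric matrix with zero diagonal, dimnames = taxa.
#' @export
pDistanceMatrix <- function(alignment) {
  n <- nrow(alignment)
  d <- matrix(0, n, n, dimnames = list(rownames(alignment),
                                       rownames(alignment)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- pDistance(alignment, i, j)
  d
}

#' Neighbour-joining tree
#'
#' Standard Saitou-Nei agglomeration on the Q-matrix. For bit
#' reproducibility, ties in the Q-matrix resolve to the pair with the
#' lowest node indices (leaves in input order, internal nodes in creation
#' order) and negative branch lengths are clamped to zero.
#'
#' @param dm symmetric distance matrix with taxon dimnames (at least 3
#'   taxa).
#' @return an unrooted `phylo` tree.
#' @export
njTree <- function(dm) {
  taxa <- rownames(dm)
  n <- nrow(dm)
  if (is.null(taxa) || n < 3) stop("need a named matrix with >= 3 taxa")
  if (!isTRUE(all.equal(dm, t(dm)))) stop("distance matrix must be symmetric")
  D <- dm
  nodes <- as.list(taxa)  # newick fragment per active node
  repeat {
    m <- length(nodes)
    if (m == 3) break
    r <- rowSums(D)
    best <- c(NA, NA); bestQ <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      q <- (m - 2) * D[i, j] - r[i] - r[j]
      if (q < bestQ - 1e-12) { bestQ <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    newDist <- (D[i, ] + D[j, ] - D[i, j]) / 2
    newick <- sprintf("(%s:%.10g,%s:%.10g)", nodes[[i]], li, nodes[[j]], lj)
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- matrix(0, m - 1, m - 1)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
    D2[m - 1, seq_along(keep)] <- D2[seq_along(keep), m - 1] <- newDist[keep]
    D <- D2
    nodes <- c(nodes[keep], newick)
  }
  ## final three-point formulas
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- max((d12 + d13 - d23) / 2, 0)
  l2 <- max((d12 + d23 - d13) / 2, 0)
  l3 <- max((d13 + d23 - d12) / 2, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[[1]], l1, nodes[[2]], l2, nodes[[3]], l3)
  ape::read.tree(text = txt)
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge.
#'
#' @param tree a `phylo` tree.
#' @param outgroupId tip label of the outgroup.
#' @return a rooted `phylo` tree.
#' @export
rootWithOutgroup <- function(tree, outgroupId) {
  if (!outgroupId %in% tree$tip.label)
    stop("outgroup not present in tree: ", outgroupId)
  rt <- ape::root(tree, outgroup = outgroupId, resolve.root = TRUE)
  rootNode <- ape::Ntip(rt) + 1L
  rootEdges <- which(rt$edge[, 1] == rootNode)
  tip <- match(outgroupId, rt$tip.label)
  ogEdge <- rootEdges[rt$edge[rootEdges, 2] == tip]
  if (length(ogEdge) == 1 && length(rootEdges) == 2) {
    other <- setdiff(rootEdges, ogEdge)
    total <- sum(rt$edge.length[rootEdges])
    rt$edge.length[ogEdge] <- total / 2
    rt$edge.length[other] <- total / 2
  }
  rt
}

#' Report maximal dyad-pure clades
#'
#' A single post-order pass finds every maximal clade whose leaves all
#' share one dyad label and whose size reaches `minSize`. A clade is
#' maximal when its parent clade is not label-pure (the root of a fully
#' pure tree is maximal by definition).
#'
#' @param tree a rooted `phylo` tree.
#' @param labels named character vector, leaf id to dyad label; every leaf
#'   must be labelled except those in `exclude`.
#' @param minSize minimum clade size to report; default 2.
#' @param exclude leaf ids (e.g. the outgroup) dropped before the scan.
#' @return data.frame `label`, `size`, plus a `leaves` list column;
#'   zero rows when no pure clade reaches `minSize`.
#' @export
pureClades <- function(tree, labels, minSize = 2L, exclude = NULL) {
  if (!is.null(exclude) && any(exclude %in% tree$tip.label)) {
    tree <- ape::drop.tip(tree, intersect(exclude, tree$tip.label))
  }
  tips <- tree$tip.label
  miss <- setdiff(tips, names(labels))
  if (length(miss)) stop("unlabelled leaf: ", miss[1])
  nt <- length(tips)
  nn <- nt + tree$Nnode
  ## post-order: children before parents
  eo <- ape::reorder.phylo(tree, "postorder")
  nodeLabel <- rep(NA_character_, nn)   # shared label, NA when impure
  pure <- rep(TRUE, nn)
  size <- rep(0L, nn)
  nodeLabel[seq_len(nt)] <- unname(labels[tips])
  size[seq_len(nt)] <- 1L
  for (k in seq_len(nrow(eo$edge))) {
    par <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    if (size[par] == 0L) {  # first child seen
      nodeLabel[par] <- nodeLabel[ch]
      pure[par] <- pure[ch]
      size[par] <- size[ch]
    } else {
      pure[par] <- pure[par] && pure[ch] &&
        identical(nodeLabel[par], nodeLabel[ch])
      if (!pure[par]) nodeLabel[par] <- NA_character_
      size[par] <- size[par] + size[ch]
    }
  }
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  rootNode <- nt + 1L
  maximal <- which(pure & !is.na(nodeLabel) & size >= minSize &
                     (is.na(parent) | !pure[ifelse(is.na(parent), 1L,
                                                   parent)]))
  leavesUnder <- function(node) {
    if (node <= nt) return(tips[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, leavesUnder))
  }
  if (!length(maximal))
    return(data.frame(label = character(), size = integer(),
                      leaves = I(list())))
  out <- data.frame(label = nodeLabel[maximal], size = size[maximal],
                    stringsAsFactors = FALSE)
  out$leaves <- I(lapply(maximal, leavesUnder))
  out <- out[order(-out$size, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
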