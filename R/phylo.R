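# Tree handling: deterministic neighbor-joining builder and rooting rules.
# ape's "phylo" is the tree carrier; newick I/O goes through ape.

#' Neighbor-joining tree with deterministic tie-breaks
#'
#' Standard neighbor-joining agglomeration. At every step the pair with the
#' minimal Q-criterion is joined; exact ties are resolved by the smallest
#' (row, column) index pair in the current matrix, so the output is a pure
#' function of the input matrix. Negative branch lengths arising from the
#' NJ formulas are clamped to zero. On additive matrices the reconstructed
#' tree reproduces the generating path metric exactly.
#'
#' @param d symmetric numeric matrix with zero diagonal, labelled rows and
#'   columns, at least 3 taxa.
#' @return an unrooted `ape::phylo` tree.
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' tr <- njTree(d)
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) .okitStop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  }
  if (any(d < 0)) .okitStop("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-12) .okitStop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) .okitStop("distance matrix diagonal must be zero")

  labels <- rownames(d)
  ## node ids: tips 1..n, internal nodes counted up from n+1
  active <- seq_len(n)
  next_node <- n + 1L
  edges <- matrix(integer(0), ncol = 2L)
  lengths <- numeric(0)
  D <- d

  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    lengths <<- c(lengths, max(0, len))
  }

  while (length(active) > 3L) {
    N <- length(active)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    ## minimal Q; ties -> smallest (row, col) with row < col
    qmin <- min(Q)
    idx <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    lj <- D[i, j] - li
    u <- next_node; next_node <- next_node + 1L
    add_edge(u, active[i], li)
    add_edge(u, active[j], lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    active <- c(active[keep], u)
  }

  ## final star join of the remaining three nodes
  u <- next_node; next_node <- next_node + 1L
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  add_edge(u, active[1L], l1)
  add_edge(u, active[2L], l2)
  add_edge(u, active[3L], l3)

  ## renumber internal nodes into ape convention (root = n+1, preorder)
  n_internal <- next_node - n - 1L
  children <- split(seq_len(nrow(edges)), edges[, 1L])
  newnum <- integer(next_node - 1L)
  newnum[seq_len(n)] <- seq_len(n)
  counter <- n
  assign_num <- function(node) {
    counter <<- counter + 1L
    newnum[node] <<- counter
    for (e in children[[as.character(node)]]) {
      child <- edges[e, 2L]
      if (child > n) assign_num(child)
    }
  }
  assign_num(u)
  edge_mat <- cbind(newnum[edges[, 1L]], newnum[edges[, 2L]])
  ## ape wants edges grouped in preorder; sort by parent then child
  ord <- order(edge_mat[, 1L], edge_mat[, 2L])
  tr <- structure(list(edge = edge_mat[ord, , drop = FALSE],
                       edge.length = lengths[ord],
                       tip.label = labels,
                       Nnode = n_internal),
                  class = "phylo", order = "cladewise")
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

## all-pairs tip path lengths
.tipDistances <- function(t) {
  ape::cophenetic.phylo(t)
}

#' Root a tree on an outgroup or the most distant tip
#'
#' Implements the rooting rule applied to orthogroup phylogenies: root with
#' the first available taxon of a ranked outgroup list, or -- when none is
#' present -- with the "most distant taxon", defined here as the tip whose
#' mean path length to all other tips is maximal (ties broken
#' lexicographically by tip label). The root is placed at the midpoint of
#' the chosen tip's pendant edge, so unrooted pairwise path lengths are
#' preserved exactly.
#'
#' @param t an `ape::phylo` with at least 3 tips and branch lengths.
#' @param outgroups ranked character vector of taxa (first present wins);
#'   may be empty.
#' @param taxon_of optional named character vector mapping tip label to
#'   taxon; when `NULL`, tip labels are taken as taxa. When an outgroup
#'   taxon has several tips, the lexicographically smallest tip is used.
#' @return a rooted `ape::phylo`.
#' @export
rerootTree <- function(t, outgroups = character(0), taxon_of = NULL) {
  if (length(t$tip.label) < 3L) .okitStop("tree must have at least 3 tips")
  tips <- t$tip.label
  taxa <- if (is.null(taxon_of)) stats::setNames(tips, tips) else taxon_of[tips]

  target <- NULL
  for (og in outgroups) {
    cand <- sort(tips[!is.na(taxa) & taxa == og])
    if (length(cand)) { target <- cand[1L]; break }
  }
  if (is.null(target)) {
    dmat <- .tipDistances(t)
    mean_d <- rowSums(dmat) / (nrow(dmat) - 1L)
    best <- max(mean_d)
    target <- sort(names(mean_d)[mean_d >= best - 1e-12])[1L]
  }

  tu <- if (ape::is.rooted(t)) ape::unroot(t) else t
  tip_idx <- match(target, tu$tip.label)
  pend <- which(tu$edge[, 2L] == tip_idx)
  L <- tu$edge.length[pend]
  rooted <- ape::root(tu, outgroup = target, resolve.root = TRUE)
  ## split the pendant edge at its midpoint: the root's two child edges get
  ## L/2 each (ape leaves the full length on the tip side and 0 on the other)
  root_node <- length(rooted$tip.label) + 1L
  child_edges <- which(rooted$edge[, 1L] == root_node)
  tip_edge <- child_edges[rooted$edge[child_edges, 2L] ==
                            match(target, rooted$tip.label)]
  other_edge <- setdiff(child_edges, tip_edge)
  excess <- rooted$edge.length[tip_edge] - L / 2
  rooted$edge.length[tip_edge] <- L / 2
  rooted$edge.length[other_edge] <- rooted$edge.length[other_edge] + excess
  rooted
}

#' Pairwise p-distances from an alignment
#'
#' Proportion of differing residues over the columns where both rows are
#' ungapped; rows sharing no ungapped column get the maximal observed
#' distance plus a small increment. Used as the input metric for [njTree()]
#' in the pipeline drivers.
#'
#' @param aln an [OrthoAlignment-class].
#' @return symmetric numeric matrix.
#' @export
alignmentDistances <- function(aln) {
  m <- aln@mat
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L) return(d)
  nog <- m != "-"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- nog[i, ] & nog[j, ]
      ns <- sum(shared)
      d[i, j] <- d[j, i] <-
        if (ns > 0L) sum(m[i, shared] != m[j, shared]) / ns else NA_real_
    }
  }
  if (anyNA(d)) {
    mx <- max(d, na.rm = TRUE)
    d[is.na(d)] <- mx + 0.1
  }
  d
}
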