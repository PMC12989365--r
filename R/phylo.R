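# Distance-based phylogeny: raw hamming distances over alignment rows,
# Saitou-Nei neighbor joining with deterministic tie-breaking, midpoint
# rooting, and a square-root branch transform used for display only.
# Trees are ape "phylo" objects throughout, serialized as Newick.

#' Hamming distance matrix from a protein alignment
#'
#' Raw count of differing columns per pair of rows; gap-vs-residue counts as
#' a difference, gap-vs-gap does not. Distances are not normalized by
#' alignment length. Partial-coverage and null alleles can be excluded by
#' name.
#'
#' @param aln a `protein_alignment`.
#' @param exclude character vector of row names to drop (e.g. null alleles).
#' @return symmetric integer matrix with zero diagonal, labeled by allele.
#' @export
hamming_matrix <- function(aln, exclude = NULL) {
  stopifnot(inherits(aln, "protein_alignment"))
  mat <- aln$matrix
  if (!is.null(exclude)) mat <- mat[setdiff(rownames(mat), exclude), ,
                                    drop = FALSE]
  n <- nrow(mat)
  d <- matrix(0L, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        h <- sum(mat[i, ] != mat[j, ])
        d[i, j] <- h
        d[j, i] <- h
      }
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in the
#' Q-matrix minimum are broken toward the lowest `(i, j)` index pair, so the
#' output is deterministic. Negative branch lengths are clamped to 0 and the
#' total clamped deficit is recorded in the `"clamped_deficit"` attribute.
#' The result is exact (reproduces all path distances) whenever `d` is
#' additive.
#'
#' @param d symmetric distance matrix with labels as row/column names (or a
#'   `dist` object).
#' @return an unrooted `ape::phylo` tree (trifurcating root node). With
#'   fewer than 3 taxa a degenerate two-leaf tree is returned with a
#'   warning.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  if (max(abs(d - t(d))) > 0) stop("distance matrix is not symmetric")
  labels <- rownames(d)
  n <- length(labels)
  deficit <- 0
  clamp <- function(x) {
    neg <- x < 0
    if (any(neg)) deficit <<- deficit + sum(-x[neg])
    pmax(x, 0)
  }
  if (n < 3L) {
    warning("fewer than 3 taxa: returning degenerate tree")
    if (n == 1L) stop("cannot build a tree from a single taxon")
    len <- clamp(rep(d[1L, 2L] / 2, 2L))
    txt <- sprintf("(%s:%.12g,%s:%.12g);", labels[1L], len[1L],
                   labels[2L], len[2L])
    tree <- ape::read.tree(text = txt)
    attr(tree, "clamped_deficit") <- deficit
    return(tree)
  }
  # each active node holds a Newick fragment; joins nest the fragments
  frag <- labels
  D <- d
  storage.mode(D) <- "double"
  while (length(frag) > 3L) {
    m <- length(frag)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # lowest (i, j), i < j, among minima
    qmin <- min(Q)
    idx <- which(Q - qmin <= 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    b <- clamp(c(bi, bj))
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], b[1L], frag[j], b[2L])
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D_new <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                   c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    D <- D_new
  }
  b <- clamp(c(
    (D[1, 2] + D[1, 3] - D[2, 3]) / 2,
    (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
    (D[1, 3] + D[2, 3] - D[1, 2]) / 2))
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[1L], b[1L], frag[2L], b[2L], frag[3L], b[3L])
  tree <- ape::read.tree(text = txt)
  attr(tree, "clamped_deficit") <- deficit
  tree
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, so the
#' two farthest leaves are equidistant from the root. Rooting always uses
#' the raw branch lengths (never the square-root display transform). If all
#' branch lengths are zero the root is placed on an arbitrary (first) edge
#' and the result is flagged via the `"arbitrary_root"` attribute.
#'
#' @param tree an unrooted `ape::phylo` with branch lengths.
#' @return a rooted `ape::phylo`; the new root node splits the edge
#'   containing the midpoint.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  n_tip <- length(tree$tip.label)
  if (n_tip < 2L) stop("cannot root a tree with fewer than 2 leaves")
  dn <- ape::dist.nodes(tree)
  dleaf <- dn[seq_len(n_tip), seq_len(n_tip), drop = FALSE]
  arbitrary <- FALSE
  if (max(dleaf) == 0) {
    warning("all leaf-to-leaf distances are zero; root placed arbitrarily")
    arbitrary <- TRUE
    pair <- c(1L, 2L)
  } else {
    hit <- which(dleaf == max(dleaf), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    pair <- as.integer(hit[1L, ])
  }
  half <- dleaf[pair[1L], pair[2L]] / 2
  path <- ape::nodepath(tree, pair[1L], pair[2L])

  # adjacency list over undirected edges
  elen <- tree$edge.length
  edges <- tree$edge
  edge_id <- function(a, b) {
    which((edges[, 1] == a & edges[, 2] == b) |
            (edges[, 1] == b & edges[, 2] == a))[1L]
  }
  cum <- 0
  split_edge <- c(path[1L], path[2L])
  x <- half
  for (k in seq_len(length(path) - 1L)) {
    eid <- edge_id(path[k], path[k + 1L])
    len <- elen[eid]
    if (cum + len >= half - 1e-12) {
      split_edge <- c(path[k], path[k + 1L])
      x <- half - cum
      break
    }
    cum <- cum + len
  }
  x <- min(max(x, 0), elen[edge_id(split_edge[1L], split_edge[2L])])

  # rebuild the tree from adjacency with a new root node on split_edge
  adj <- vector("list", max(edges) + 1L)
  add_edge <- function(a, b, len) {
    adj[[a]] <<- rbind(adj[[a]], c(b, len))
    adj[[b]] <<- rbind(adj[[b]], c(a, len))
  }
  seid <- edge_id(split_edge[1L], split_edge[2L])
  for (e in seq_len(nrow(edges))) {
    if (e == seid) next
    add_edge(edges[e, 1L], edges[e, 2L], elen[e])
  }
  root_id <- max(edges) + 1L
  add_edge(root_id, split_edge[1L], x)
  add_edge(root_id, split_edge[2L], elen[seid] - x)

  # orient away from the root and renumber in ape convention
  new_id <- integer(root_id)
  new_id[seq_len(n_tip)] <- seq_len(n_tip)
  next_internal <- n_tip + 1L
  parent <- integer(0); child <- integer(0); blen <- numeric(0)
  visited <- logical(root_id)
  # iterative DFS assigning internal numbers in discovery order
  dfs <- function() {
    stk <- c(root_id)
    from <- c(NA_integer_)
    lens <- c(NA_real_)
    while (length(stk)) {
      v <- stk[[length(stk)]]; f <- from[[length(from)]]
      l <- lens[[length(lens)]]
      stk <- stk[-length(stk)]; from <- from[-length(from)]
      lens <- lens[-length(lens)]
      if (visited[[v]]) next
      visited[[v]] <<- TRUE
      if (v > n_tip) {
        new_id[[v]] <<- next_internal
        next_internal <<- next_internal + 1L
      }
      if (!is.na(f)) {
        parent <<- c(parent, f)
        child <<- c(child, v)
        blen <<- c(blen, l)
      }
      nb <- adj[[v]]
      if (!is.null(nb)) {
        for (r in rev(seq_len(nrow(nb)))) {
          w <- as.integer(nb[r, 1L])
          if (!visited[[w]]) {
            stk <- c(stk, w)
            from <- c(from, v)
            lens <- c(lens, nb[r, 2L])
          }
        }
      }
    }
  }
  dfs()
  edge_mat <- cbind(new_id[parent], new_id[child])
  out <- list(edge = edge_mat, edge.length = blen,
              tip.label = tree$tip.label,
              Nnode = next_internal - 1L - n_tip)
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  attr(out, "arbitrary_root") <- arbitrary
  attr(out, "midpoint_depth") <- half
  out
}

#' Square-root branch-length transform
#'
#' Replaces every branch length by its square root. This is a display-only
#' transform (it compresses long branches for plotting); the result is
#' flagged with the `"sqrt_transformed"` attribute and must not be used for
#' rooting or distance computations.
#'
#' @param tree an `ape::phylo` with non-negative branch lengths.
#' @return the tree with transformed branch lengths, topology unchanged.
#' @export
sqrt_branch_transform <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0))
  tree$edge.length <- sqrt(tree$edge.length)
  attr(tree, "sqrt_transformed") <- TRUE
  tree
}

#' Write a tree as Newick
#'
#' @param tree an `ape::phylo`.
#' @param path output file, or `NULL` to return the Newick string.
#' @param digits significant digits for branch lengths (default 6). A
#'   write-parse-write cycle on the returned string is byte-stable.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a Newick tree
#'
#' @param path file path or a literal Newick string.
#' @return an `ape::phylo`.
#' @export
read_newick <- function(path) {
  if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
}
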