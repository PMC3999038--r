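# Poisson-corrected distances with pairwise deletion, neighbor-joining,
# bootstrap clade support and Newick serialization.
#
# Conventions (stated because the method descriptions leave them open):
# Q-criterion ties are broken by the lowest index pair, negative estimated
# branch lengths are clamped to 0, and saturated distances (p >= 0.99,
# where -ln(1-p) explodes) are flagged undefined and rejected with a clear
# error rather than silently capped.

.msa_matrix <- function(msa) {
  stopifnot(length(msa) >= 2L)
  if (is.null(names(msa))) names(msa) <- paste0("seq", seq_along(msa))
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) stop("MSA rows differ in length")
  m <- do.call(rbind, strsplit(unname(unclass(msa)), ""))
  rownames(m) <- names(msa)
  m
}

#' Observed proportion of differing sites (pairwise deletion)
#'
#' Columns where either row has a gap are excluded for that pair only.
#'
#' @param msa Named character vector of equal-length aligned rows.
#' @param i,j Row indices or names.
#' @return Proportion in \\[0, 1\\], or NA when the pair shares no
#'   gap-free column.
#' @export
p_distance <- function(msa, i, j) {
  m <- .msa_matrix(msa)
  a <- m[i, ]
  b <- m[j, ]
  comp <- a != "-" & b != "-"
  if (!any(comp)) return(NA_real_)
  mean(a[comp] != b[comp])
}

#' Poisson correction for amino-acid distances
#'
#' d = -ln(1 - p), the expected number of substitutions per site under a
#' Poisson model with uniform rates; always >= p and monotone in p.
#'
#' @param p Proportion(s) of differing sites, 0 <= p < 1.
#' @return Distance(s) in substitutions per site.
#' @examples
#' poisson_correct(0.5)  # 0.6931472
#' @export
poisson_correct <- function(p) {
  if (any(is.na(p))) stop("p contains NA")
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 1)) stop("saturated distance: p >= 1 has no Poisson correction")
  -log1p(-p)
}

#' Poisson-corrected distance matrix from an MSA
#'
#' Pairwise-deletion p-distances corrected with [poisson_correct()].
#' Pairs with no shared gap-free column, or with p at or beyond the
#' saturation guard, are set to NA and flagged in the `"undefined"`
#' attribute; [nj_tree()] refuses such matrices.
#'
#' @param msa Named character vector of aligned rows.
#' @param saturation p at or above this value is treated as saturated
#'   (default 0.99).
#' @return Symmetric numeric matrix (substitutions per site) with zero
#'   diagonal; attribute `undefined` is a logical matrix.
#' @export
poisson_dist <- function(msa, saturation = 0.99) {
  m <- .msa_matrix(msa)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  undef <- matrix(FALSE, n, n, dimnames = dimnames(D))
  gap <- m == "-"
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- !gap[i, ] & !gap[j, ]
    if (!any(comp)) {
      D[i, j] <- D[j, i] <- NA_real_
      undef[i, j] <- undef[j, i] <- TRUE
      next
    }
    p <- mean(m[i, comp] != m[j, comp])
    if (p >= saturation) {
      D[i, j] <- D[j, i] <- NA_real_
      undef[i, j] <- undef[j, i] <- TRUE
    } else {
      D[i, j] <- D[j, i] <- poisson_correct(p)
    }
  }
  attr(D, "undefined") <- undef
  D
}

# Saitou-Nei agglomeration schedule. Returns the join list used by both
# nj_tree() and the progressive aligner's guide tree: elements
# list(a, b, la, lb) in join order (node k > n refers to join k - n),
# the final element a trifurcation list(a, b, c, la, lb, lc).
.nj_joins <- function(D) {
  n <- nrow(D)
  stopifnot(n >= 3L, isTRUE(all.equal(D, t(D))), !any(is.na(D)))
  active <- seq_len(n)                 # node ids of current rows
  W <- D
  joins <- list()
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(W)
    best <- NULL
    bestQ <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      q <- (m - 2) * W[i, j] - r[i] - r[j]
      if (q < bestQ - 1e-12) {         # strict improvement keeps lowest pair
        bestQ <- q
        best <- c(i, j)
      }
    }
    i <- best[1]
    j <- best[2]
    la <- 0.5 * W[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    lb <- W[i, j] - la
    joins[[length(joins) + 1L]] <- list(a = active[i], b = active[j],
                                        la = max(la, 0), lb = max(lb, 0))
    dnew <- 0.5 * (W[i, ] + W[j, ] - W[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    W2 <- rbind(cbind(W[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    W <- W2
    active <- c(active[keep], n + length(joins))
  }
  # resolve the remaining three nodes around a central vertex
  d12 <- W[1, 2]; d13 <- W[1, 3]; d23 <- W[2, 3]
  joins[[length(joins) + 1L]] <- list(
    a = active[1], b = active[2], c = active[3],
    la = max((d12 + d13 - d23) / 2, 0),
    lb = max((d12 + d23 - d13) / 2, 0),
    lc = max((d13 + d23 - d12) / 2, 0))
  list(joins = joins, n = n)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei Q-criterion agglomeration with deterministic tie-breaking
#' (lowest index pair) and negative branch-length estimates clamped to 0.
#' For an additive matrix the generating topology and path lengths are
#' recovered exactly. Returns an unrooted `ape::phylo` tree (the root is
#' the central trifurcation).
#'
#' @param D Symmetric distance matrix with zero diagonal, no NA entries
#'   (see [poisson_dist()] for the undefined-entry flagging).
#' @return An object of class `phylo`.
#' @export
nj_tree <- function(D) {
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  if (any(is.na(D))) {
    stop("distance matrix contains undefined entries (saturated or ",
         "non-overlapping pairs); cannot build a tree")
  }
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  js <- .nj_joins(D)
  joins <- js$joins
  n <- js$n
  J <- length(joins)
  # children per internal node (temporary ids n+1 .. n+J; n+J = center)
  kids <- vector("list", J)
  for (k in seq_len(J)) {
    jn <- joins[[k]]
    ch <- c(jn$a, jn$b, jn$c)
    ln <- c(jn$la, jn$lb, jn$lc)
    kids[[k]] <- list(ids = ch, lens = ln)
  }
  # relabel internals in preorder from the center (ape convention:
  # tips 1..n, root n+1, internals consecutive)
  new_id <- integer(n + J)
  new_id[seq_len(n)] <- seq_len(n)
  next_internal <- n + 1L
  edge <- matrix(0L, 0L, 2L)
  edge_len <- numeric(0)
  visit <- function(tmp_id) {
    new_id[tmp_id] <<- next_internal
    next_internal <<- next_internal + 1L
    node <- kids[[tmp_id - n]]
    for (idx in seq_along(node$ids)) {
      ch <- node$ids[idx]
      if (ch <= n) {
        edge <<- rbind(edge, c(new_id[tmp_id], ch))
        edge_len <<- c(edge_len, node$lens[idx])
      } else {
        edge <<- rbind(edge, c(new_id[tmp_id], NA))  # placeholder
        at <- nrow(edge)
        edge_len <<- c(edge_len, node$lens[idx])
        visit(ch)
        edge[at, 2L] <<- new_id[ch]
      }
    }
  }
  visit(n + J)
  tree <- list(edge = edge, edge.length = edge_len,
               tip.label = rownames(D), Nnode = J)
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' One row per internal edge; `key` is a canonical encoding of the split
#' (the sorted tip set on the side not containing the first tip label),
#' `node` is the child node of the edge in `tree$edge`.
#'
#' @param tree A `phylo` object.
#' @return `data.frame` with columns `node`, `key`, `size`.
#' @export
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]
    ch <- post$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(n))
  anchor <- min(tree$tip.label)   # canonical side: the one without it
  out <- lapply(internal, function(nd) {
    tips <- sort(below[[nd]])
    if (length(tips) < 2L || length(tips) > n - 2L) return(NULL)
    side <- if (anchor %in% tree$tip.label[tips]) {
      setdiff(seq_len(n), tips)
    } else {
      tips
    }
    data.frame(node = nd,
               key = paste(sort(tree$tip.label[side]), collapse = "|"),
               size = length(side))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(node = integer(0), key = character(0),
                      size = integer(0))
  }
  out
}

#' Bootstrap clade support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson/pairwise-deletion NJ tree per replicate, and reports, for each
#' internal edge of the original tree, the percentage of replicates whose
#' tree contains the same bipartition. Supports are attached to the
#' original tree's bipartitions (not a consensus). Replicates whose
#' resampled matrix has undefined distances are dropped from the
#' denominator (counted in attribute `dropped_replicates`).
#'
#' @param msa Named character vector of aligned rows.
#' @param replicates Number of bootstrap replicates (the conventional
#'   choice for these surveys is 1000).
#' @param seed Integer seed; identical seed and input give identical
#'   supports.
#' @return The original NJ `phylo` tree with integer percentage supports
#'   in `node.label` (empty for the root trifurcation and trivial edges).
#' @export
bootstrap_support <- function(msa, replicates = 1000L, seed = 1L) {
  stopifnot(replicates >= 1L)
  m <- .msa_matrix(msa)
  D0 <- poisson_dist(msa)
  tree <- nj_tree(D0)
  sp0 <- tree_splits(tree)
  counts <- setNames(integer(nrow(sp0)), sp0$key)
  L <- ncol(m)
  set.seed(as.integer(seed))
  dropped <- 0L
  valid <- 0L
  for (r in seq_len(replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    rep_msa <- setNames(apply(m[, idx, drop = FALSE], 1L, paste,
                              collapse = ""), rownames(m))
    Dr <- poisson_dist(rep_msa)
    if (any(is.na(Dr))) {
      dropped <- dropped + 1L
      next
    }
    valid <- valid + 1L
    if (nrow(sp0) == 0L) next
    keys <- tree_splits(nj_tree(Dr))$key
    hit <- names(counts) %in% keys
    counts[hit] <- counts[hit] + 1L
  }
  if (valid == 0L) stop("all bootstrap replicates were degenerate")
  labs <- rep("", tree$Nnode)
  if (nrow(sp0) > 0L) {
    supp <- round(100 * counts / valid)
    labs[sp0$node - length(tree$tip.label)] <- as.character(supp)
  }
  tree$node.label <- labs
  attr(tree, "dropped_replicates") <- dropped
  attr(tree, "replicates") <- valid
  tree
}

#' Write a tree in Newick format
#'
#' Branch lengths are rounded to six decimals; internal-node support
#' labels below `min_support` are blanked (the conventional display
#' filter; the tree topology is untouched).
#'
#' @param tree A `phylo` object, optionally with `node.label` supports.
#' @param path Output file, or NULL to return the Newick string.
#' @param min_support Display threshold (e.g. 50), or NULL to keep all.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL, min_support = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(min_support) && !is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    tree$node.label[!is.na(sup) & sup < min_support] <- ""
  }
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, 6)
  }
  txt <- ape::write.tree(tree, digits = 8)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a Newick tree
#'
#' @param text Newick string, or NULL when reading from `path`.
#' @param path File to read when `text` is NULL.
#' @return A `phylo` object.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  res <- tryCatch({
    if (!is.null(text)) ape::read.tree(text = text)
    else ape::read.tree(path)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(res) || !inherits(res, "phylo")) {
    stop("newick parse error: input is not a well-formed tree")
  }
  res
}
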