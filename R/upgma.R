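#' UPGMA clustering of a distance matrix
#'
#' Classic unweighted pair-group average linkage: the pair of clusters at
#' minimal distance is merged at height `d_min / 2`, and the distance from
#' the merged cluster to any other is the *size-weighted* average of the
#' member distances (UPGMA proper, not WPGMA/McQuitty).  Ties are broken by
#' the smallest (row, column) index pair in the current label order, which
#' makes the output fully deterministic: identical input and label order
#' yield an identical Newick string.
#'
#' @param m Symmetric labelled distance matrix, finite entries, zero
#'   diagonal, at least 2 labels.
#' @return A rooted ultrametric tree of class `"phylo"` (ape).  Branch
#'   lengths are parent height minus child height, so the cophenetic
#'   distance between two leaves equals their merge distance.
#' @examples
#' m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(upgma(m))  # ((A:1,B:1):1,C:2);
#' @export
upgma <- function(m) {
  .check_dist_matrix(m)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 labels to cluster", call. = FALSE)
  if (any(!is.finite(m))) {
    bad <- sort(which(!is.finite(m), arr.ind = TRUE)[1L, ])
    stop(sprintf("non-finite distance between %s and %s",
                 rownames(m)[bad[1L]], colnames(m)[bad[2L]]), call. = FALSE)
  }
  labs <- rownames(m)
  newick <- labs
  height <- numeric(n)
  size <- rep(1L, n)
  members <- as.list(labs)
  clades <- vector("list", n - 1L)
  d <- m
  for (step in seq_len(n - 1L)) {
    k <- nrow(d)
    if (k == 1L) break
    work <- d
    work[lower.tri(work, diag = TRUE)] <- Inf
    cand <- which(work == min(work), arr.ind = TRUE)
    # first minimum in row-major (row, then column) order
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    h <- d[i, j] / 2
    newick[i] <- sprintf("(%s:%.12g,%s:%.12g)",
                         newick[i], h - height[i], newick[j], h - height[j])
    members[[i]] <- c(members[[i]], members[[j]])
    clades[[step]] <- sort(members[[i]])
    # size-weighted average linkage update
    dn <- (size[i] * d[i, ] + size[j] * d[j, ]) / (size[i] + size[j])
    d[i, ] <- dn; d[, i] <- dn; d[i, i] <- 0
    height[i] <- h
    size[i] <- size[i] + size[j]
    keep <- setdiff(seq_len(k), j)
    d <- d[keep, keep, drop = FALSE]
    newick <- newick[keep]; height <- height[keep]
    size <- size[keep]; members <- members[keep]
  }
  tree <- ape::read.tree(text = paste0(newick[1L], ";"))
  attr(tree, "clades") <- clades
  tree
}

#' Clades (leaf sets below each internal node) of a rooted tree
#'
#' @param tree A `"phylo"` object.
#' @return List of character vectors, one per internal node (root included),
#'   each the sorted tip labels of that clade.
#' @export
tree_clades <- function(tree) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  lapply(parts, function(p) sort(labs[p]))
}

.clade_key <- function(leaves) paste(sort(leaves), collapse = "|")

#' Cophenetic distance matrix of a rooted tree
#'
#' For an ultrametric tree the cophenetic distance between two leaves is
#' twice the height of their lowest common ancestor; UPGMA applied to an
#' ultrametric matrix returns it exactly.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return Symmetric labelled matrix of leaf-to-leaf path distances.
#' @export
cophenetic_matrix <- function(tree) {
  ape::cophenetic.phylo(tree)
}

#' Newick input/output
#'
#' Thin wrappers over ape's Newick reader/writer.  Round-trips preserve
#' topology, branch lengths (to ~1e-9, limited by decimal printing) and
#' internal-node support labels.
#'
#' @param tree A `"phylo"` object.
#' @param path File path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()`
#'   returns a `"phylo"`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  chars <- strsplit(txt, NULL)[[1L]]
  n_open <- sum(chars == "(")
  n_close <- sum(chars == ")")
  if (n_open != n_close) {
    stop(sprintf("malformed Newick in %s: %d '(' vs %d ')'",
                 path, n_open, n_close), call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick in ", path, call. = FALSE)
  }
  tree
}
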