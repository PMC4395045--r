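#' Bootstrap configuration
#'
#' @param replicates Number of bootstrap replicates (the published analysis
#'   used 1000).
#' @param threshold Majority-rule threshold as a fraction; a clade is kept
#'   only if its support is *strictly* greater than `threshold * 100`
#'   percent ("more than 50%").
#' @param seed Integer seed for the resampling stream.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(replicates = 1000L, threshold = 0.5, seed = 1L) {
  stopifnot(replicates >= 1L, threshold >= 0, threshold < 1)
  structure(list(replicates = as.integer(replicates), threshold = threshold,
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Resample loci with replacement
#'
#' One Felsenstein bootstrap draw over characters — here, the loci of the
#' frequency table.  Uses the current R random stream.
#'
#' @param loci Character vector of locus names (length >= 1).
#' @return Character vector of the same length, drawn with replacement.
#' @export
resample_loci <- function(loci) {
  stopifnot(length(loci) >= 1L)
  loci[sample.int(length(loci), length(loci), replace = TRUE)]
}

#' Locus-resampling bootstrap of the distance + UPGMA pipeline
#'
#' For each replicate the loci are resampled with replacement, the Nei
#' distance matrix is recomputed on the resampled loci, and a UPGMA tree is
#' built.  Support for a clade is the percentage of *retained* replicates
#' whose tree contains it; replicates whose matrix has a non-finite entry
#' are skipped (counted and reported with a warning).
#'
#' Because a replicate is fully determined by the multiset of resampled
#' loci, trees are computed once per distinct composition and reused; with
#' two loci only three distinct matrices can occur, so support values are
#' coarse by construction.
#'
#' @param table A [freq_table()].
#' @param ids Populations to include (default: all).
#' @param cfg A [bootstrap_config()].
#' @return List with components:
#'   \describe{
#'     \item{`support`}{data frame `clade` (sorted labels joined by `|`),
#'       `size`, `support` (percent of retained replicates);}
#'     \item{`trees`}{list of the retained replicate trees (`"phylo"`);}
#'     \item{`n_retained`, `n_skipped`}{replicate bookkeeping.}
#'   }
#' @export
bootstrap_upgma <- function(table, ids = NULL, cfg = bootstrap_config()) {
  stopifnot(inherits(cfg, "bootstrap_config"))
  loci <- freq_loci(table)
  if (is.null(ids)) ids <- table$id
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(cfg$seed)
  cache <- new.env(parent = emptyenv())
  counts <- new.env(parent = emptyenv())
  trees <- vector("list", cfg$replicates)
  n_skipped <- 0L
  n_retained <- 0L
  for (b in seq_len(cfg$replicates)) {
    idx <- sort(sample.int(length(loci), length(loci), replace = TRUE))
    key <- paste(idx, collapse = ",")
    entry <- cache[[key]]
    if (is.null(entry)) {
      m <- nei_distance_matrix(table, ids, loci[idx])
      entry <- if (any(!is.finite(m))) {
        list(ok = FALSE)
      } else {
        tree <- upgma(m)
        list(ok = TRUE, tree = tree,
             keys = vapply(attr(tree, "clades"), .clade_key, character(1)))
      }
      cache[[key]] <- entry
    }
    if (!entry$ok) {
      n_skipped <- n_skipped + 1L
      next
    }
    n_retained <- n_retained + 1L
    trees[[n_retained]] <- entry$tree
    for (k in entry$keys) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  if (n_retained == 0L) {
    stop("all bootstrap replicates produced degenerate (non-finite) distances",
         call. = FALSE)
  }
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d of %d replicates with non-finite distances",
                    n_skipped, cfg$replicates), call. = FALSE)
  }
  keys <- ls(counts)
  support <- data.frame(
    clade = keys,
    size = lengths(strsplit(keys, "|", fixed = TRUE)),
    support = vapply(keys, function(k) 100 * counts[[k]] / n_retained,
                     numeric(1)),
    row.names = NULL
  )
  # leaf singletons are in every replicate by construction
  support <- rbind(support,
                   data.frame(clade = sort(ids), size = 1L, support = 100))
  support <- support[order(-support$size, support$clade), ]
  rownames(support) <- NULL
  list(support = support, trees = trees[seq_len(n_retained)],
       n_retained = n_retained, n_skipped = n_skipped)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Majority-rule consensus tree from a clade support table
#'
#' Keeps exactly the clades supported by strictly more than
#' `threshold * 100` percent of replicates.  With a threshold of at least
#' one half such clades are pairwise compatible (majority-rule theorem);
#' compatibility is still asserted on every run.  The consensus may contain
#' polytomies, carries rounded integer support values as internal node
#' labels, and has no branch lengths.
#'
#' @param support Support data frame as returned by [bootstrap_upgma()]
#'   (`clade`, `support` columns; clade keys are sorted labels joined by
#'   `|`).
#' @param leaves Character vector of all leaf labels, in display order.
#' @param threshold Fraction in \[0, 1); default 0.5 (strict "more than
#'   50%").
#' @return A `"phylo"` tree with `node.label` support percentages.
#' @export
majority_rule_consensus <- function(support, leaves, threshold = 0.5) {
  stopifnot(is.data.frame(support), length(leaves) >= 2L)
  sel <- support[support$support > threshold * 100, , drop = FALSE]
  clades <- lapply(strsplit(sel$clade, "|", fixed = TRUE), sort)
  pct <- sel$support
  # proper subsets of the leaf set only; root is implicit
  keep <- vapply(clades, function(cl) {
    length(cl) >= 2L && length(cl) < length(leaves) && all(cl %in% leaves)
  }, logical(1))
  clades <- clades[keep]; pct <- pct[keep]
  if (length(clades) >= 2L) {
    for (a in seq_len(length(clades) - 1L)) {
      for (b in seq.int(a + 1L, length(clades))) {
        int <- intersect(clades[[a]], clades[[b]])
        if (length(int) &&
            length(int) != length(clades[[a]]) &&
            length(int) != length(clades[[b]])) {
          stop("internal error: incompatible clades passed the majority threshold",
               call. = FALSE)
        }
      }
    }
  }
  root_pct <- if (nrow(support)) {
    rp <- support$support[support$clade == .clade_key(leaves)]
    if (length(rp)) rp[1L] else 100
  } else 100
  newick <- paste0(.consensus_newick(leaves, clades, pct, leaves),
                   round(root_pct), ";")
  ape::read.tree(text = newick)
}

# recursive newick for the node spanning `set`: children are the maximal
# selected clades inside it plus any uncovered leaves, ordered by first
# appearance in `leaf_order`
.consensus_newick <- function(set, clades, pct, leaf_order) {
  inside <- which(vapply(clades, function(cl) {
    length(cl) < length(set) && all(cl %in% set)
  }, logical(1)))
  maximal <- inside[vapply(inside, function(a) {
    !any(vapply(inside, function(b) {
      b != a && length(clades[[a]]) < length(clades[[b]]) &&
        all(clades[[a]] %in% clades[[b]])
    }, logical(1)))
  }, logical(1))]
  covered <- unique(unlist(clades[maximal]))
  parts <- c(
    lapply(maximal, function(a) {
      sub <- .consensus_newick(clades[[a]], clades, pct, leaf_order)
      list(first = min(match(clades[[a]], leaf_order)),
           text = paste0(sub, round(pct[a])))
    }),
    lapply(setdiff(set, covered), function(lf) {
      list(first = match(lf, leaf_order), text = lf)
    })
  )
  parts <- parts[order(vapply(parts, `[[`, numeric(1), "first"))]
  paste0("(", paste(vapply(parts, `[[`, character(1), "text"),
                    collapse = ","), ")")
}
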