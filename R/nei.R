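#' Per-locus gene identities for a biallelic null/present locus
#'
#' With allele frequency vectors `x = (q_x, 1 - q_x)` and
#' `y = (q_y, 1 - q_y)`, the within-population identities are
#' `j_x = sum(x^2)`, `j_y = sum(y^2)` and the between-population identity is
#' `j_xy = sum(x * y)`.  These are the per-locus building blocks of Nei's
#' (1972) standard genetic distance.  By Cauchy-Schwarz,
#' `j_xy <= sqrt(j_x j_y)`, and for a biallelic locus `0.5 <= j_x <= 1`.
#'
#' @param q_x,q_y Null-allele frequencies in \[0, 1\]; vectors are treated
#'   elementwise (one entry per locus).
#' @return List with numeric components `j_x`, `j_y`, `j_xy`.
#' @examples
#' locus_identities(0.240, 0.112)
#' @export
locus_identities <- function(q_x, q_y) {
  .check_freq(q_x)
  .check_freq(q_y)
  list(j_x  = q_x^2 + (1 - q_x)^2,
       j_y  = q_y^2 + (1 - q_y)^2,
       j_xy = q_x * q_y + (1 - q_x) * (1 - q_y))
}

.check_freq <- function(q) {
  if (!is.numeric(q) || anyNA(q) || any(q < 0 | q > 1)) {
    stop("allele frequencies must be numeric in [0, 1]", call. = FALSE)
  }
  invisible(q)
}

#' Nei (1972) standard genetic distance between two populations
#'
#' `D = -ln(I)` with the normalized identity
#' `I = sum_l j_xy / sqrt(sum_l j_x * sum_l j_y)`: the ratio of *summed*
#' identities across loci (Nei's definition, as implemented in PHYLIP's
#' gendist), not the mean of per-locus ratios.  `I` marginally above 1 from
#' floating-point noise is clamped so that `D = 0`; `I = 0` (fixed opposite
#' alleles at every locus) gives `D = Inf`.
#'
#' @param q_x,q_y Null-allele frequency vectors, one entry per locus, equal
#'   length.  Repeated loci are legal (bootstrap resampling).
#' @return Non-negative numeric distance, possibly `Inf`.
#' @examples
#' # Zimbabwe vs Namibia over GSTM1/GSTT1:
#' nei_standard_distance(c(0.240, 0.260), c(0.112, 0.358))  # ~0.019641
#' @export
nei_standard_distance <- function(q_x, q_y) {
  if (length(q_x) == 0L) stop("empty locus list", call. = FALSE)
  if (length(q_x) != length(q_y)) stop("locus vectors differ in length", call. = FALSE)
  j <- locus_identities(q_x, q_y)
  i_norm <- sum(j$j_xy) / sqrt(sum(j$j_x) * sum(j$j_y))
  if (i_norm <= 0) return(Inf)
  -log(min(i_norm, 1))
}

#' Pairwise Nei distance matrix for a frequency table
#'
#' @param table A [freq_table()].
#' @param ids Populations to include, in the desired label order (default:
#'   all rows, table order).
#' @param loci Loci to use; repetitions allowed (locus-resampling bootstrap).
#'   Default: all loci of the table.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = `ids`.
#' @examples
#' tab <- load_gahp_fixture("regions20")
#' d <- nei_distance_matrix(tab)
#' round(d["sAs_Ind", "eAf_Zim"], 6)  # 0.007203
#' @export
nei_distance_matrix <- function(table, ids = NULL, loci = NULL) {
  if (is.null(loci)) loci <- freq_loci(table)
  q <- freq_matrix(table, ids, loci)
  p <- 1 - q
  # summed identities, all pairs at once
  jxy <- q %*% t(q) + p %*% t(p)
  jx <- diag(jxy)
  i_norm <- jxy / sqrt(outer(jx, jx))
  d <- -log(pmin(i_norm, 1))
  d[i_norm <= 0] <- Inf
  diag(d) <- 0
  d[] <- (d + t(d)) / 2  # enforce exact symmetry
  d
}

.check_dist_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m))) stop("distance matrix needs labels", call. = FALSE)
  if (any(m < 0, na.rm = TRUE)) stop("negative distance", call. = FALSE)
  if (any(diag(m) != 0)) stop("non-zero diagonal", call. = FALSE)
  fin <- m[is.finite(m)]
  if (max(abs(m - t(m))[is.finite(m) & is.finite(t(m))]) > 1e-12)
    stop("distance matrix not symmetric", call. = FALSE)
  invisible(m)
}

#' Write a distance matrix in PHYLIP format
#'
#' First line is the number of populations; each following line is a
#' label padded to 10 characters and the distances with 6 decimals.  The
#' `"square"` dialect writes full rows; `"lower"` writes the strict lower
#' triangle (row i holds columns 1..i-1), the layout of published triangular
#' distance tables.
#'
#' @param m Symmetric distance matrix with labels.
#' @param path Output path.
#' @param dialect `"square"` or `"lower"`.
#' @return `path`, invisibly.
#' @seealso [read_dist_phylip()]
#' @export
write_dist_phylip <- function(m, path, dialect = c("square", "lower")) {
  dialect <- match.arg(dialect)
  .check_dist_matrix(m)
  if (any(!is.finite(m))) {
    stop("matrix contains non-finite distances; cap or drop them before writing",
         call. = FALSE)
  }
  labs <- rownames(m)
  if (any(grepl("[[:space:]]", labs))) {
    stop("labels with whitespace are not representable in PHYLIP format",
         call. = FALSE)
  }
  n <- nrow(m)
  lines <- character(n + 1L)
  lines[1L] <- format(n, width = 5)
  for (i in seq_len(n)) {
    vals <- if (dialect == "square") m[i, ] else m[i, seq_len(i - 1L)]
    lines[i + 1L] <- paste0(formatC(labs[i], width = 10, flag = "-"),
                            paste(sprintf("%.6f", vals), collapse = "  "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a PHYLIP distance matrix
#'
#' Accepts both dialects written by [write_dist_phylip()].
#'
#' @param path Path to a PHYLIP distance file.
#' @return Symmetric labelled matrix.
#' @export
read_dist_phylip <- function(path) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[1L]))
  if (is.na(n) || length(ln) < n + 1L) stop("malformed PHYLIP file: ", path, call. = FALSE)
  labs <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ln[i + 1L]), "[[:space:]]+")[[1L]]
    labs[i] <- f[1L]
    vals <- as.numeric(f[-1L])
    if (length(vals) == n) {
      m[i, ] <- vals
    } else if (length(vals) == i - 1L) {
      if (i > 1L) m[i, seq_len(i - 1L)] <- vals
    } else {
      stop(sprintf("row %d of %s has %d values (expected %d or %d)",
                   i, path, length(vals), n, i - 1L), call. = FALSE)
    }
  }
  m <- pmax(m, t(m))
  dimnames(m) <- list(labs, labs)
  .check_dist_matrix(m)
  m
}
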