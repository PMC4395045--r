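# Small builders and independent oracles shared across the suite.

# minimal two-locus frequency table
make_table <- function(ids, qM1, qT1, nM1 = 100L, nT1 = 100L,
                       region = "test", aggregate = FALSE) {
  freq_table(data.frame(
    id = ids, name = ids, region = rep_len(region, length(ids)),
    is_aggregate = rep_len(aggregate, length(ids)),
    q_GSTM1 = qM1, n_GSTM1 = rep_len(nM1, length(ids)),
    q_GSTT1 = qT1, n_GSTT1 = rep_len(nT1, length(ids))
  ))
}

random_table <- function(n, seed) {
  set.seed(seed)
  make_table(sprintf("p%02d", seq_len(n)), runif(n), runif(n))
}

# independent brute-force Nei (1972) D: explicit allele vectors and loops
nei_brute <- function(qx, qy) {
  jx <- jy <- jxy <- 0
  for (l in seq_along(qx)) {
    x <- c(qx[l], 1 - qx[l])
    y <- c(qy[l], 1 - qy[l])
    for (a in 1:2) {
      jx <- jx + x[a]^2
      jy <- jy + y[a]^2
      jxy <- jxy + x[a] * y[a]
    }
  }
  -log(min(jxy / sqrt(jx * jy), 1))
}

# random valid distance matrix (Euclidean, so symmetric/non-negative/0-diag)
random_dist <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(rnorm(2 * n), n)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(sprintf("p%02d", 1:n), sprintf("p%02d", 1:n))
  m
}

# published triangular distance tables packaged as TSV (row label + the
# cells printed for the leading columns)
read_published <- function(file) {
  path <- system.file("extdata", file, package = "gstpatterns")
  ln <- readLines(path)
  cols <- strsplit(ln[1], "\t")[[1]][-1]
  cells <- list()
  for (i in seq_along(ln)[-1]) {
    f <- strsplit(ln[i], "\t")[[1]]
    vals <- as.numeric(f[-1])
    if (!length(vals)) next
    cells[[f[1]]] <- stats::setNames(vals, cols[seq_along(vals)])
  }
  structure(cells, order = cols)
}

max_abs_diff <- function(a, b) {
  stopifnot(identical(dimnames(a), dimnames(b)))
  max(abs(a - b))
}

clade_in <- function(tree, ids) {
  any(vapply(tree_clades(tree), function(x) identical(sort(x), sort(ids)),
             logical(1)))
}

smallest_clade_with <- function(tree, ids) {
  cl <- Filter(function(x) all(ids %in% x), tree_clades(tree))
  cl[[which.min(lengths(cl))]]
}
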