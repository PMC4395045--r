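#' Population x locus null-allele frequency tables
#'
#' A `freq_table` is a data frame with one row per population and, for each
#' locus, a pair of columns `q_<locus>` (null-allele frequency, in \[0, 1\])
#' and `n_<locus>` (sample size, `NA` allowed).  Fixed leading columns are
#' `id` (unique short label), `name` (display name), `region` (continental
#' region label) and `is_aggregate` (logical; marks continental-average rows
#' that summarise several member populations).  Row order is preserved by all
#' operations and drives deterministic tie-breaking downstream.
#'
#' @param x A data frame with the columns described above.
#' @return A validated `freq_table` (a data frame subclass).
#' @examples
#' tab <- freq_table(data.frame(
#'   id = "pop1", name = "Example", region = "Nowhere", is_aggregate = FALSE,
#'   q_GSTM1 = 0.2, n_GSTM1 = 100L, q_GSTT1 = 0.4, n_GSTT1 = 100L
#' ))
#' freq_loci(tab)
#' @export
freq_table <- function(x) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"is_aggregate" %in% names(x)) x$is_aggregate <- FALSE
  for (col in c("id", "name", "region")) {
    if (!col %in% names(x)) stop("missing required column: ", col, call. = FALSE)
    x[[col]] <- as.character(x[[col]])
  }
  x$is_aggregate <- as.logical(x$is_aggregate)
  loci <- .loci_from_names(names(x))
  if (length(loci) == 0L) stop("no q_<locus> columns found", call. = FALSE)
  validate_freq_table(x, loci)
  rownames(x) <- NULL
  class(x) <- c("freq_table", "data.frame")
  x
}

.loci_from_names <- function(nms) {
  q <- sub("^q_", "", grep("^q_", nms, value = TRUE))
  q[q != ""]
}

validate_freq_table <- function(x, loci = freq_loci(x)) {
  if (any(is.na(x$id) | x$id == "")) stop("empty population id", call. = FALSE)
  dup <- x$id[duplicated(x$id)]
  if (length(dup)) stop("duplicate population id: ", dup[1L], call. = FALSE)
  for (loc in loci) {
    qc <- paste0("q_", loc)
    q <- x[[qc]]
    if (!is.numeric(q)) stop("column ", qc, " is not numeric", call. = FALSE)
    bad <- which(is.na(q) | q < 0 | q > 1)
    if (length(bad)) {
      stop(sprintf("frequency out of [0,1] (or missing) at row %d (id %s), column %s",
                   bad[1L], x$id[bad[1L]], qc), call. = FALSE)
    }
    nc <- paste0("n_", loc)
    if (!nc %in% names(x)) {
      x[[nc]] <- NA_integer_
    } else {
      n <- x[[nc]]
      bad <- which(!is.na(n) & n < 0)
      if (length(bad)) {
        stop(sprintf("negative sample size at row %d, column %s", bad[1L], nc),
             call. = FALSE)
      }
    }
  }
  invisible(x)
}

#' Locus names of a frequency table
#'
#' @param table A [freq_table()].
#' @return Character vector of locus names, in column order.
#' @export
freq_loci <- function(table) .loci_from_names(names(table))

#' Extract the population x locus frequency matrix
#'
#' @param table A [freq_table()].
#' @param ids Population ids to keep (default: all), in the given order.
#' @param loci Locus names; repetitions are allowed (used by the
#'   locus-resampling bootstrap).
#' @return Numeric matrix of null-allele frequencies, rows named by `id`.
#' @export
freq_matrix <- function(table, ids = NULL, loci = freq_loci(table)) {
  if (is.null(ids)) ids <- table$id
  miss <- setdiff(ids, table$id)
  if (length(miss)) stop("unknown population id: ", miss[1L], call. = FALSE)
  miss <- setdiff(unique(loci), freq_loci(table))
  if (length(miss)) stop("unknown locus: ", miss[1L], call. = FALSE)
  rows <- match(ids, table$id)
  m <- as.matrix(table[rows, paste0("q_", loci), drop = FALSE])
  dimnames(m) <- list(ids, loci)
  m
}

#' Read a frequency table from tab-separated text
#'
#' The dialect is one header line, tab-separated, UTF-8, `NA` for missing
#' values.  Required columns: `id`, `name`, `region`, and `q_<locus>` /
#' `n_<locus>` pairs; `is_aggregate` and any extra columns (for example
#' latitude/longitude) are preserved.
#'
#' @param path Path to a TSV file.
#' @return A [freq_table()].
#' @seealso [write_frequency_table()]
#' @export
read_frequency_table <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = "NA", fileEncoding = "UTF-8")
  loci <- .loci_from_names(names(raw))
  if (length(loci) == 0L) stop("no q_<locus> columns in ", path, call. = FALSE)
  num_cols <- c(paste0("q_", loci), intersect(paste0("n_", loci), names(raw)))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop(sprintf("malformed number '%s' at row %d, column %s of %s",
                   raw[[col]][bad[1L]], bad[1L], col, path), call. = FALSE)
    }
    raw[[col]] <- v
  }
  if ("is_aggregate" %in% names(raw)) {
    raw$is_aggregate <- as.logical(as.integer(raw$is_aggregate))
  }
  freq_table(raw)
}

#' Write a frequency table as tab-separated text
#'
#' Frequencies are printed with at least three decimals and missing sample
#' sizes as `NA`, so [read_frequency_table()] round-trips the table
#' losslessly, including row order.
#'
#' @param table A [freq_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(table, path) {
  stopifnot(inherits(table, "freq_table"))
  out <- as.data.frame(table)
  out$is_aggregate <- as.integer(out$is_aggregate)
  for (loc in freq_loci(table)) {
    qc <- paste0("q_", loc)
    out[[qc]] <- vapply(out[[qc]], .format_q, character(1))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# >= 3 decimals, more if needed for losslessness
.format_q <- function(q) {
  s <- formatC(q, digits = 3, format = "f")
  if (as.numeric(s) == q) s else format(q, digits = 15)
}

#' Load the packaged population fixtures
#'
#' The package ships the compiled GST M1/T1 null-allele frequency survey of
#' 45 geographically assorted human populations (plus the seven printed
#' continental-average rows), and the latitude/longitude table of the 20
#' continental regions used in the scatter analysis.
#'
#' @param which One of:
#'   \describe{
#'     \item{`"populations45"`}{the 45 individual populations (aggregate
#'       region rows excluded);}
#'     \item{`"regions20"`}{the 20-region analysis set: 13 individual
#'       populations plus the 7 printed continental aggregates, as published
#'       (aggregates are *not* recomputed from their members);}
#'     \item{`"all"`}{every row of the survey, aggregates flagged;}
#'     \item{`"geography"`}{20 rows of `id`, `latitude`, `longitude`
#'       in signed decimal degrees (south and west negative).}
#'   }
#' @return A [freq_table()], or for `"geography"` a plain data frame.
#' @examples
#' tab <- load_gahp_fixture("populations45")
#' tab[tab$id == "Ind_Guj", ]
#' @export
load_gahp_fixture <- function(which = c("populations45", "regions20",
                                        "geography", "all")) {
  which <- match.arg(which)
  if (which == "geography") {
    geo <- utils::read.delim(.extdata("gahp_geography.tsv"))
    stopifnot(all(abs(geo$latitude) <= 90), all(abs(geo$longitude) <= 180))
    return(geo)
  }
  tab <- read_frequency_table(.extdata("gahp_frequencies.tsv"))
  switch(which,
    all = tab,
    populations45 = freq_table(tab[!tab$is_aggregate, ]),
    regions20 = {
      # the 20-region set: aggregates stand in for their member populations
      agg_regions <- unique(tab$region[tab$is_aggregate])
      keep <- tab$is_aggregate | !(tab$region %in% agg_regions)
      freq_table(tab[keep, ])
    }
  )
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "gstpatterns")
  if (path == "") stop("fixture not found: ", file, call. = FALSE)
  path
}

#' @export
print.freq_table <- function(x, ...) {
  loci <- freq_loci(x)
  cat(sprintf("<freq_table> %d populations (%d aggregate), %d loci: %s\n",
              nrow(x), sum(x$is_aggregate), length(loci),
              paste(loci, collapse = ", ")))
  print(as.data.frame(x), ...)
  invisible(x)
}
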