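#' Null-genotype frequency counting
#'
#' Estimates the null frequency at one locus from per-individual
#' presence/absence calls by direct counting: `q_hat` is the number of null
#' calls over the number of non-missing calls.  Missing calls are excluded
#' from numerator and denominator (pairwise deletion per locus, so each locus
#' has its own effective sample size).
#'
#' @param calls A genotype call table: data frame with columns `population`,
#'   `individual` and one column per locus coded `0` (band present), `1`
#'   (null) or `NA` (no call).  See [read_genotype_calls()].
#' @param locus Locus column name, e.g. `"GSTM1"`.
#' @return A `freq_estimate`: list with `q_hat`, `n_used` (non-missing
#'   calls) and `se`, the binomial standard error `sqrt(q_hat (1 - q_hat) /
#'   n_used)`.
#' @examples
#' calls <- data.frame(population = "p", individual = 1:10,
#'                     GSTM1 = c(rep(1, 2), rep(0, 8)))
#' count_null_frequency(calls, "GSTM1")
#' @export
count_null_frequency <- function(calls, locus) {
  if (!locus %in% names(calls)) stop("locus not in call table: ", locus, call. = FALSE)
  v <- calls[[locus]]
  if (!all(v %in% c(0L, 1L, NA))) stop("calls must be 0, 1 or NA", call. = FALSE)
  n_used <- sum(!is.na(v))
  if (n_used == 0L) stop("no non-missing calls for locus ", locus, call. = FALSE)
  q_hat <- sum(v, na.rm = TRUE) / n_used
  structure(list(q_hat = q_hat, n_used = n_used,
                 se = sqrt(q_hat * (1 - q_hat) / n_used)),
            class = "freq_estimate")
}

#' @export
print.freq_estimate <- function(x, ...) {
  cat(sprintf("q_hat = %.4f  (n = %d, SE = %.4f)\n", x$q_hat, x$n_used, x$se))
  invisible(x)
}

#' Sample-size-weighted regional aggregate frequency
#'
#' Combines member populations of a region into one frequency estimate using
#' the weighted mean `sum(q_i n_i) / sum(n_i)`.  Every member must have a
#' sample size at the locus; the aggregate is undefined otherwise.
#'
#' @param table A [freq_table()].
#' @param member_ids Ids of the member populations.
#' @param locus Locus name.
#' @return A `freq_estimate` with `n_used = sum(n_i)`.
#' @examples
#' tab <- freq_table(data.frame(
#'   id = c("a", "b"), name = c("A", "B"), region = "R", is_aggregate = FALSE,
#'   q_GSTM1 = c(0.2, 0.4), n_GSTM1 = c(100L, 300L)
#' ))
#' aggregate_region(tab, c("a", "b"), "GSTM1")  # 0.35
#' @export
aggregate_region <- function(table, member_ids, locus) {
  stopifnot(inherits(table, "freq_table"), length(member_ids) >= 1L)
  miss <- setdiff(member_ids, table$id)
  if (length(miss)) stop("unknown member id: ", miss[1L], call. = FALSE)
  rows <- match(member_ids, table$id)
  q <- table[[paste0("q_", locus)]][rows]
  n <- table[[paste0("n_", locus)]][rows]
  if (is.null(q)) stop("unknown locus: ", locus, call. = FALSE)
  if (anyNA(n)) {
    stop("aggregate undefined: member without sample size: ",
         member_ids[which(is.na(n))[1L]], call. = FALSE)
  }
  q_hat <- sum(q * n) / sum(n)
  structure(list(q_hat = q_hat, n_used = sum(n),
                 se = sqrt(q_hat * (1 - q_hat) / sum(n))),
            class = "freq_estimate")
}

#' Summarise a genotype call table into a frequency table
#'
#' Counts the null frequency per population and locus, giving a
#' [freq_table()] that can feed the distance/tree pipeline directly.
#'
#' @param calls A genotype call table covering one or more populations.
#' @param region Optional named character vector mapping population id to
#'   region label (default `"unknown"`).
#' @return A [freq_table()] with one row per population, in first-appearance
#'   order.
#' @export
calls_to_freq_table <- function(calls, region = NULL) {
  loci <- setdiff(names(calls), c("population", "individual"))
  pops <- unique(calls$population)
  rows <- lapply(pops, function(p) {
    sub <- calls[calls$population == p, , drop = FALSE]
    row <- list(id = p, name = p,
                region = if (!is.null(region) && p %in% names(region))
                  region[[p]] else "unknown",
                is_aggregate = FALSE)
    for (loc in loci) {
      est <- count_null_frequency(sub, loc)
      row[[paste0("q_", loc)]] <- est$q_hat
      row[[paste0("n_", loc)]] <- est$n_used
    }
    as.data.frame(row)
  })
  freq_table(do.call(rbind, rows))
}

#' Read / write genotype call tables
#'
#' TSV dialect: columns `population`, `individual`, then one column per locus
#' with values `0` (present), `1` (null) or `NA`.
#'
#' @param path File path.
#' @return `read_genotype_calls()` returns the call table as a data frame;
#'   `write_genotype_calls()` returns `path` invisibly.
#' @export
read_genotype_calls <- function(path) {
  calls <- utils::read.delim(path, na.strings = "NA")
  need <- c("population", "individual")
  if (!all(need %in% names(calls))) {
    stop("call table needs 'population' and 'individual' columns", call. = FALSE)
  }
  calls
}

#' @rdname read_genotype_calls
#' @param calls A genotype call table.
#' @export
write_genotype_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}
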