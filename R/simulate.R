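#' Define a genotype-sampling scenario with known ground truth
#'
#' A scenario fixes, per population, the true null-allele frequency at each
#' locus and the number of sampled individuals, plus a no-call rate and a
#' seed.  Individuals are independent Bernoulli draws per locus; no linkage
#' between loci is modelled (the distance computation treats loci
#' independently).
#'
#' @param ids Population ids.
#' @param q Numeric matrix of true null frequencies, one row per population,
#'   one column per locus (column names are the locus names).
#' @param n Integer vector of individuals per population (`n >= 1`).
#' @param missing_rate Probability that any single call is missing, in
#'   \[0, 1).
#' @param seed Integer seed; the simulation is fully determined by it.
#' @return A `sim_scenario` list.
#' @export
simulation_scenario <- function(ids, q, n, missing_rate = 0, seed = 1L) {
  q <- as.matrix(q)
  stopifnot(length(ids) == nrow(q), length(n) == nrow(q),
            all(q >= 0 & q <= 1), all(n >= 1),
            missing_rate >= 0, missing_rate < 1,
            !is.null(colnames(q)))
  rownames(q) <- ids
  structure(list(ids = as.character(ids), q = q, n = as.integer(n),
                 loci = colnames(q), missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate per-individual genotype call tables
#'
#' Each individual's call at each locus is null (`1`) with the population's
#' true frequency, otherwise present (`0`), independently across individuals
#' and loci; calls are knocked out to `NA` with the scenario's missing rate.
#'
#' @param scenario A [simulation_scenario()].
#' @return Genotype call table: data frame with `population`, `individual`
#'   and one 0/1/`NA` column per locus, suitable for
#'   [count_null_frequency()] and [calls_to_freq_table()].
#' @export
simulate_calls <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(scenario$seed)
  blocks <- lapply(seq_along(scenario$ids), function(i) {
    n <- scenario$n[i]
    block <- data.frame(population = scenario$ids[i], individual = seq_len(n))
    for (loc in scenario$loci) {
      call <- stats::rbinom(n, 1L, scenario$q[i, loc])
      if (scenario$missing_rate > 0) {
        call[stats::runif(n) < scenario$missing_rate] <- NA_integer_
      }
      block[[loc]] <- call
    }
    block
  })
  do.call(rbind, blocks)
}

#' Build a scenario whose truth is a frequency table
#'
#' Uses the table's printed frequencies and sample sizes as simulation
#' ground truth, so the whole pipeline can be checked for parameter
#' recovery.  Populations without a sample size get `default_n` individuals
#' (reported with a message).
#'
#' @param table A [freq_table()].
#' @param default_n Sample size substituted where the table has none.
#' @param n_scale Multiplier applied to all sample sizes (larger samples
#'   tighten recovery).
#' @param missing_rate,seed Passed to [simulation_scenario()].
#' @return A `sim_scenario`; empty table gives a scenario with no
#'   populations.
#' @export
scenario_from_fixture <- function(table, default_n = 100L, n_scale = 1,
                                  missing_rate = 0, seed = 1L) {
  stopifnot(inherits(table, "freq_table"))
  loci <- freq_loci(table)
  if (nrow(table) == 0L) {
    q <- matrix(numeric(0), 0, length(loci), dimnames = list(NULL, loci))
    return(structure(list(ids = character(0), q = q, n = integer(0),
                          loci = loci, missing_rate = missing_rate,
                          seed = as.integer(seed)),
                     class = "sim_scenario"))
  }
  n_cols <- as.matrix(table[, paste0("n_", loci), drop = FALSE])
  n <- apply(n_cols, 1L, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
  if (anyNA(n)) {
    message("no sample size for ", paste(table$id[is.na(n)], collapse = ", "),
            "; using default n = ", default_n)
    n[is.na(n)] <- default_n
  }
  simulation_scenario(table$id, freq_matrix(table, loci = loci),
                      pmax(1L, as.integer(round(n * n_scale))),
                      missing_rate = missing_rate, seed = seed)
}
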