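#' Run the full frequency-to-patterns analysis
#'
#' Chains the stages end-to-end: load (or read) a frequency table, compute
#' the pairwise Nei (1972) distance matrix, build the UPGMA tree, run the
#' locus-resampling bootstrap with majority-rule consensus, assign
#' least-distance patterns and geographic splits, and write every result to
#' `outdir`:
#'
#' \describe{
#'   \item{`distances.phy`, `distances_lower.phy`}{PHYLIP square and
#'     lower-triangular distance matrices (6 decimals);}
#'   \item{`distances.csv`}{full-precision distance matrix;}
#'   \item{`upgma.nwk`}{UPGMA tree with branch lengths;}
#'   \item{`consensus.nwk`}{majority-rule consensus with integer support
#'     labels;}
#'   \item{`clade_support.csv`}{per-clade bootstrap support;}
#'   \item{`patterns.csv`}{per-population pattern/split assignment;}
#'   \item{`scatter.csv`}{assignments joined to coordinates (only for
#'     populations with coordinates);}
#'   \item{`manifest.json`}{inputs, seed, and package/R versions.}
#' }
#'
#' @param analysis `"regions20"`, `"populations45"`, or `"custom"` (then
#'   `input` must point to a frequency TSV).
#' @param input Optional path to a frequency table TSV (forces
#'   `analysis = "custom"` semantics for the input, fixture keys otherwise).
#' @param outdir Output directory, created if needed.
#' @param replicates,threshold,seed Bootstrap settings, see
#'   [bootstrap_config()].
#' @param anchors Anchor table for [assign_patterns()]; set `NULL` to skip
#'   pattern assignment (e.g. custom tables without the anchor populations).
#' @param geo Coordinate table for [scatter_export()]; defaults to the
#'   packaged geography for fixture analyses.
#' @return Invisible list with the computed objects (`table`, `dist`,
#'   `tree`, `bootstrap`, `consensus`, `patterns`, `scatter`) and `paths`.
#' @examples
#' \donttest{
#' out <- run_analysis("regions20", outdir = tempfile(), replicates = 100)
#' round(out$dist["eAf_Zim", "sAf_Nam"], 6)  # 0.019641
#' }
#' @export
run_analysis <- function(analysis = c("regions20", "populations45", "custom"),
                         input = NULL, outdir, replicates = 1000L,
                         threshold = 0.5, seed = 1L,
                         anchors = pattern_anchors(), geo = NULL) {
  analysis <- match.arg(analysis)
  if (analysis == "custom" && is.null(input)) {
    stop("analysis = 'custom' needs an input table path", call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- if (!is.null(input)) read_frequency_table(input)
         else load_gahp_fixture(analysis)
  if (is.null(geo) && analysis != "custom") {
    geo <- load_gahp_fixture("geography")
  }
  paths <- list()
  p <- function(f) file.path(outdir, f)

  d <- nei_distance_matrix(tab)
  write_dist_phylip(d, paths$phylip <- p("distances.phy"), "square")
  write_dist_phylip(d, paths$phylip_lower <- p("distances_lower.phy"), "lower")
  utils::write.csv(d, paths$dist_csv <- p("distances.csv"))

  tree <- upgma(d)
  write_newick(tree, paths$tree <- p("upgma.nwk"))

  cfg <- bootstrap_config(replicates, threshold, seed)
  boot <- bootstrap_upgma(tab, cfg = cfg)
  utils::write.csv(boot$support, paths$support <- p("clade_support.csv"),
                   row.names = FALSE)
  cons <- majority_rule_consensus(boot$support, tab$id, threshold)
  write_newick(cons, paths$consensus <- p("consensus.nwk"))

  pat <- scat <- NULL
  if (!is.null(anchors)) {
    # the 20-region analysis carries six of the seven anchors (the Andhra
    # Pradesh pattern only emerges among the 45 individual populations)
    if (analysis != "custom" && !all(anchors$id %in% tab$id)) {
      dropped <- setdiff(anchors$id, tab$id)
      message("anchor(s) not in this analysis set, dropped: ",
              paste(dropped, collapse = ", "))
      anchors <- anchors[anchors$id %in% tab$id, ]
    }
    pat <- assign_patterns(d, anchors)
    utils::write.csv(pat, paths$patterns <- p("patterns.csv"),
                     row.names = FALSE)
    if (!is.null(geo)) {
      scat <- suppressWarnings(
        scatter_export(pat, geo, paths$scatter <- p("scatter.csv")))
    }
  }

  manifest <- list(
    analysis = analysis,
    input = if (is.null(input)) paste0("fixture:", analysis) else input,
    populations = tab$id, loci = freq_loci(tab),
    replicates = cfg$replicates, threshold = cfg$threshold, seed = cfg$seed,
    bootstrap_retained = boot$n_retained, bootstrap_skipped = boot$n_skipped,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("gstpatterns"))
  )
  jsonlite::write_json(manifest, paths$manifest <- p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(table = tab, dist = d, tree = tree, bootstrap = boot,
                 consensus = cons, patterns = pat, scatter = scat,
                 paths = paths))
}
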