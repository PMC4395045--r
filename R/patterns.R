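#' The seven anchor populations and their geographic splits
#'
#' The published analysis reads seven recurring frequency clusters
#' ("patterns") off the consensus trees, each identified with an anchor
#' population, and groups the patterns into three geographic splits:
#' pattern I (Xhosa) is the "Africa" split, patterns II-IV (Zimbabwe,
#' Ethiopia, Egypt) the "out of Africa" split, and patterns V-VII
#' (Afghanistan, Caucasian, Andhra Pradesh) the "other than Africa" split.
#'
#' @return Data frame with columns `pattern` (`"I"`..`"VII"`, in tie-break
#'   priority order), `id` (anchor population) and `split`.
#' @export
pattern_anchors <- function() {
  data.frame(
    pattern = c("I", "II", "III", "IV", "V", "VI", "VII"),
    id = c("sAf_Xho", "eAf_Zim", "eAf_Eth", "nAf_Egt",
           "sAs_Afg", "wAs_Cau", "Ind_Ap"),
    split = c("Africa", "out_of_Africa", "out_of_Africa", "out_of_Africa",
              "other_than_Africa", "other_than_Africa", "other_than_Africa")
  )
}

#' Nearest neighbour of every population in a distance matrix
#'
#' @param m Symmetric labelled distance matrix with finite entries and at
#'   least 2 populations.
#' @return Data frame `id`, `nearest_id`, `distance`: for each population
#'   the other population at minimal distance, ties broken by matrix label
#'   order.
#' @export
nearest_neighbors <- function(m) {
  .check_dist_matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 populations", call. = FALSE)
  labs <- rownames(m)
  res <- lapply(seq_along(labs), function(i) {
    d <- m[i, ]
    d[i] <- Inf
    j <- which.min(d)  # first minimum = label-order tie-break
    data.frame(id = labs[i], nearest_id = labs[j], distance = d[j])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assign populations to frequency patterns and geographic splits
#'
#' Operationalizes the cluster reading of the published trees as a
#' least-distance rule: every non-anchor population receives the pattern of
#' the anchor at minimal Nei distance (ties broken by anchor order I-VII);
#' anchors label themselves at distance 0.  The split follows from the fixed
#' pattern-to-split mapping.  Assignments whose winning anchor is the
#' Caucasian aggregate are flagged (`flagged = TRUE`) because its published
#' frequencies do not reproduce the published distances involving it.
#'
#' @param m Symmetric labelled distance matrix containing all anchors.
#' @param anchors Anchor table as [pattern_anchors()] (columns `pattern`,
#'   `id`, `split`, in priority order).
#' @return Data frame: `id`, `nearest_id`, `nearest_distance` (overall
#'   nearest neighbour), `anchor_id`, `anchor_distance`, `pattern`, `split`,
#'   `flagged`.
#' @export
assign_patterns <- function(m, anchors = pattern_anchors()) {
  .check_dist_matrix(m)
  missing_anchor <- setdiff(anchors$id, rownames(m))
  if (length(missing_anchor)) {
    stop("anchor not in distance matrix: ", missing_anchor[1L], call. = FALSE)
  }
  nn <- nearest_neighbors(m)
  labs <- rownames(m)
  res <- lapply(seq_along(labs), function(i) {
    id <- labs[i]
    a <- match(id, anchors$id)
    if (is.na(a)) {
      d <- m[id, anchors$id]
      a <- which.min(d)  # first minimum = anchor-order (I-VII) tie-break
      ad <- d[a]
    } else {
      ad <- 0
    }
    data.frame(id = id,
               nearest_id = nn$nearest_id[i],
               nearest_distance = nn$distance[i],
               anchor_id = anchors$id[a],
               anchor_distance = unname(ad),
               pattern = anchors$pattern[a],
               split = anchors$split[a],
               flagged = anchors$id[a] == "wAs_Cau")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export pattern assignments with coordinates for the scatter plot
#'
#' Joins assignments to geographic coordinates and writes a CSV with
#' columns `id`, `longitude`, `latitude`, `pattern`, `split` — the data
#' behind the longitude/latitude scatter of patterns.  Populations without
#' coordinates are dropped with a warning naming them.
#'
#' @param assignments Output of [assign_patterns()].
#' @param geo Data frame `id`, `latitude`, `longitude` (signed decimal
#'   degrees, south/west negative), e.g. `load_gahp_fixture("geography")`.
#' @param path Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
scatter_export <- function(assignments, geo, path) {
  out <- merge(assignments[, c("id", "pattern", "split")], geo, by = "id",
               sort = FALSE)
  missing <- setdiff(assignments$id, geo$id)
  if (length(missing)) {
    warning("no coordinates for: ", paste(missing, collapse = ", "),
            call. = FALSE)
  }
  out <- out[match(setdiff(assignments$id, missing), out$id),
             c("id", "longitude", "latitude", "pattern", "split")]
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Plot the geographic scatter of patterns
#'
#' Longitude on the x axis, latitude on the y axis, points coloured by
#' geographic split and labelled with the pattern number.
#'
#' @param scatter Data frame as returned by [scatter_export()].
#' @param ... Passed to [graphics::plot()].
#' @return `scatter`, invisibly.
#' @export
plot_pattern_map <- function(scatter, ...) {
  splits <- c(Africa = "#1b9e77", out_of_Africa = "#d95f02",
              other_than_Africa = "#7570b3")
  graphics::plot(scatter$longitude, scatter$latitude,
                 col = splits[scatter$split], pch = 19,
                 xlab = "Longitude (deg)", ylab = "Latitude (deg)", ...)
  graphics::text(scatter$longitude, scatter$latitude, scatter$pattern,
                 pos = 3, cex = 0.7)
  graphics::legend("bottomleft", legend = names(splits), col = splits,
                   pch = 19, cex = 0.8, bty = "n")
  invisible(scatter)
}
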