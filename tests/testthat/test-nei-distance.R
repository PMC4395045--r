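test_that("per-locus gene identities expand the quadratic forms", {
  j <- locus_identities(0.240, 0.112)
  expect_equal(j$j_x, 0.6352)
  expect_equal(j$j_y, 0.801088)
  expect_equal(j$j_xy, 0.70176)

  j <- locus_identities(0.5, 0.5)
  expect_equal(unlist(j), c(j_x = 0.5, j_y = 0.5, j_xy = 0.5))

  # fixed opposite alleles share nothing
  expect_equal(locus_identities(0, 1)$j_xy, 0)

  expect_error(locus_identities(1.2, 0.5), "\\[0, 1\\]")
  expect_error(locus_identities(0.5, -0.1), "\\[0, 1\\]")
})

test_that("Nei distance matches hand-computable cases", {
  # Zimbabwe vs Namibia over both loci: the published 0.019641
  expect_equal(round(nei_standard_distance(c(0.240, 0.260), c(0.112, 0.358)), 6),
               0.019641)
  # self-distance: I = 1
  expect_equal(nei_standard_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  # single locus closed form: I = 0.5 / sqrt(0.5 * 1), D = -ln I
  expect_equal(nei_standard_distance(0.5, 1.0), -log(0.5 / sqrt(0.5)))
  # disjoint alleles at the only locus: I = 0 -> infinite distance
  expect_identical(nei_standard_distance(0, 1), Inf)

  expect_error(nei_standard_distance(numeric(0), numeric(0)), "empty locus")
  expect_error(nei_standard_distance(c(0.1, 0.2), 0.1), "length")
})

test_that("distance matrix is symmetric, non-negative, zero-diagonal and matches the brute-force oracle", {
  for (seed in 1:10) {
    tab <- random_table(6, seed)
    m <- nei_distance_matrix(tab)
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0))
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(m[i, j],
                   nei_brute(c(tab$q_GSTM1[i], tab$q_GSTT1[i]),
                             c(tab$q_GSTM1[j], tab$q_GSTT1[j])),
                   tolerance = 1e-12)
    }
  }
  # identical rows are at distance zero
  twin <- make_table(c("a", "b"), c(0.3, 0.3), c(0.6, 0.6))
  expect_equal(nei_distance_matrix(twin)["a", "b"], 0)
})

test_that("every reproducible printed cell of both published matrices is matched", {
  tab <- load_gahp_fixture("all")
  d20 <- nei_distance_matrix(load_gahp_fixture("regions20"))
  d45 <- nei_distance_matrix(load_gahp_fixture("populations45"))

  check <- function(published, d) {
    n_checked <- 0L
    for (rid in names(published)) {
      for (cid in names(published[[rid]])) {
        if (rid == "wAs_Cau" || cid == "wAs_Cau") next
        expect_lt(abs(round(d[rid, cid], 6) - published[[rid]][[cid]]),
                  2e-6, label = sprintf("|D(%s,%s) - printed|", rid, cid))
        n_checked <- n_checked + 1L
      }
    }
    n_checked
  }
  expect_equal(check(read_published("published_dst_20regions.tsv"), d20), 171)
  expect_equal(check(read_published("published_dst_45gahp.tsv"), d45), 511)

  # headline cells quoted in the published text
  expect_equal(round(d20["sAs_Ind", "eAf_Zim"], 6), 0.007203)
  expect_equal(round(d20["sAs_Iran", "eAf_Eth"], 6), 0.000882)
  expect_equal(round(d45["Ind_Kar", "Ind_Tn"], 6), 0.000355)
  expect_equal(round(d45["Ind_Guj", "sAf_Xho"], 6), 0.002144)
})

test_that("published cells involving the Caucasian aggregate are NOT reproducible", {
  # the Caucasian frequencies of the survey (0.529 / 0.197) do not yield the
  # published distances involving wAs_Cau; the package reports what the
  # frequencies imply instead of fitting the printed values
  d20 <- nei_distance_matrix(load_gahp_fixture("regions20"))
  published <- read_published("published_dst_20regions.tsv")
  errs <- c(
    abs(d20["wAs_Cau", names(published$wAs_Cau)] - published$wAs_Cau),
    vapply(setdiff(names(published), "wAs_Cau"), function(rid) {
      v <- published[[rid]]
      if ("wAs_Cau" %in% names(v)) abs(d20[rid, "wAs_Cau"] - v[["wAs_Cau"]])
      else NA_real_
    }, numeric(1))
  )
  errs <- errs[!is.na(errs)]
  expect_length(errs, 19)
  expect_true(all(errs > 2e-6))
  expect_gt(max(errs), 0.01)
})

test_that("PHYLIP matrix output round-trips in both dialects", {
  m <- random_dist(5, 1)
  for (dialect in c("square", "lower")) {
    path <- withr::local_tempfile(fileext = ".phy")
    write_dist_phylip(m, path, dialect)
    back <- read_dist_phylip(path)
    expect_lt(max_abs_diff(back, m), 1e-6)
  }

  # zero matrix round-trips to zeros
  z <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  path <- withr::local_tempfile(fileext = ".phy")
  write_dist_phylip(z, path)
  expect_true(all(read_dist_phylip(path) == 0))

  # the lower dialect prints the published layout: with rows in the
  # published order, the first value of the Namibia row is its distance to
  # Zimbabwe
  d20 <- nei_distance_matrix(load_gahp_fixture("regions20"))
  pub_order <- attr(read_published("published_dst_20regions.tsv"), "order")
  d20 <- d20[pub_order, pub_order]
  write_dist_phylip(d20, path, "lower")
  nam <- strsplit(trimws(readLines(path)[3]), "[[:space:]]+")[[1]]
  expect_equal(nam[1], "sAf_Nam")
  expect_equal(nam[2], "0.019641")

  inf <- z; inf["a", "b"] <- inf["b", "a"] <- Inf
  expect_error(write_dist_phylip(inf, path), "cap or drop")
  ws <- m; rownames(ws)[1] <- colnames(ws)[1] <- "bad label"
  expect_error(write_dist_phylip(ws, path), "whitespace")
})
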