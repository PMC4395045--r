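test_that("locus resampling has exact multinomial composition frequencies", {
  # with 2 loci the draw is {both}, {first twice}, {second twice} with
  # probabilities 0.5 / 0.25 / 0.25
  set.seed(11)
  B <- 10000
  comp <- replicate(B, paste(sort(resample_loci(c("GSTM1", "GSTT1"))),
                             collapse = "+"))
  p_obs <- c(both = mean(comp == "GSTM1+GSTT1"),
             m1 = mean(comp == "GSTM1+GSTM1"),
             t1 = mean(comp == "GSTT1+GSTT1"))
  p_true <- c(both = 0.5, m1 = 0.25, t1 = 0.25)
  expect_true(all(abs(p_obs - p_true) <
                    3 * sqrt(p_true * (1 - p_true) / B)))

  # a single locus can only resample to itself
  expect_equal(resample_loci("GSTM1"), "GSTM1")

  set.seed(5); a <- replicate(20, resample_loci(letters[1:3]))
  set.seed(5); b <- replicate(20, resample_loci(letters[1:3]))
  expect_identical(a, b)
})

test_that("bootstrap support is computed over replicate UPGMA trees", {
  # two populations with identical frequencies always form a clade
  tab <- make_table(c("a", "b", "c"), c(0.3, 0.3, 0.9), c(0.6, 0.6, 0.1))
  boot <- bootstrap_upgma(tab, cfg = bootstrap_config(50, seed = 3))
  expect_equal(boot$support$support[boot$support$clade == "a|b"], 100)
  expect_equal(boot$n_retained, 50)

  # singletons and the full set carry support 100
  expect_equal(boot$support$support[boot$support$size == 1], rep(100, 3))
  expect_equal(boot$support$support[boot$support$clade == "a|b|c"], 100)

  # a single replicate gives all-or-nothing support
  b1 <- bootstrap_upgma(tab, cfg = bootstrap_config(1, seed = 9))
  expect_true(all(b1$support$support %in% c(0, 100)))

  # identical seed, identical outcome
  s1 <- bootstrap_upgma(tab, cfg = bootstrap_config(200, seed = 42))$support
  s2 <- bootstrap_upgma(tab, cfg = bootstrap_config(200, seed = 42))$support
  expect_identical(s1, s2)
})

test_that("replicates with non-finite distances are skipped and reported", {
  # fixed opposite alleles at the first locus: the {GSTM1, GSTM1}
  # composition (probability 1/4) has I = 0 between a and b
  tab <- make_table(c("a", "b", "c"), c(0, 1, 0.5), c(0.5, 0.5, 0.5))
  expect_warning(
    boot <- bootstrap_upgma(tab, cfg = bootstrap_config(200, seed = 2)),
    "skipped"
  )
  expect_gt(boot$n_skipped, 0)
  expect_equal(boot$n_retained + boot$n_skipped, 200)

  # all replicates degenerate: single locus with fixed opposite alleles
  tab1 <- freq_table(data.frame(id = c("a", "b"), name = c("a", "b"),
                                region = "r", q_GSTM1 = c(0, 1),
                                n_GSTM1 = 10L))
  expect_error(suppressWarnings(
    bootstrap_upgma(tab1, cfg = bootstrap_config(5, seed = 1))
  ), "degenerate")
})

test_that("two-locus supports equal the exact composition mixture", {
  # a replicate tree depends only on which composition was drawn, so each
  # clade's support must equal the summed frequency of the compositions
  # whose tree contains it
  tab <- load_gahp_fixture("regions20")
  tab <- freq_table(tab[tab$id %in% c("eAf_Zim", "sAf_Nam", "sAf_Xho",
                                      "mAf_Cam", "wAf_Nig", "sAs_Ind",
                                      "sAm_Brz", "eAf_Som"), ])
  cfg <- bootstrap_config(400, seed = 13)
  boot <- bootstrap_upgma(tab, cfg = cfg)

  # replay the seeded composition draws
  set.seed(cfg$seed)
  comps <- replicate(cfg$replicates,
                     paste(sort(sample.int(2, 2, replace = TRUE)),
                           collapse = ","))
  comp_freq <- table(comps) / cfg$replicates

  loci <- freq_loci(tab)
  comp_clades <- lapply(names(comp_freq), function(key) {
    idx <- as.integer(strsplit(key, ",")[[1]])
    tree <- upgma(nei_distance_matrix(tab, loci = loci[idx]))
    vapply(tree_clades(tree), paste, character(1), collapse = "|")
  })
  names(comp_clades) <- names(comp_freq)

  internal <- boot$support[boot$support$size > 1, ]
  for (i in seq_len(nrow(internal))) {
    expected <- 100 * sum(unlist(comp_freq[vapply(
      comp_clades, function(cl) internal$clade[i] %in% cl, logical(1))]))
    expect_equal(internal$support[i], expected,
                 label = paste("support of", internal$clade[i]))
  }
})

test_that("majority-rule consensus keeps exactly the >threshold clades", {
  # direct enumeration: {A,B} in 60% of replicates, {B,C} in 40%
  sup <- data.frame(clade = c("A|B", "B|C"), size = 2L, support = c(60, 40))
  cons <- majority_rule_consensus(sup, c("A", "B", "C"))
  expect_true(clade_in(cons, c("A", "B")))
  expect_false(clade_in(cons, c("B", "C")))

  # a clade at exactly 50.0 is excluded: strictly "more than 50%"
  sup$support <- c(50, 40)
  cons <- majority_rule_consensus(sup, c("A", "B", "C"))
  expect_equal(length(tree_clades(cons)), 1)  # root only: a star tree

  # all replicates identical: consensus is that topology at support 100
  tab <- make_table(letters[1:4], c(0.1, 0.15, 0.6, 0.9),
                    c(0.2, 0.25, 0.7, 0.95))
  boot <- bootstrap_upgma(tab, cfg = bootstrap_config(25, seed = 8))
  if (all(boot$support$support %in% c(0, 100))) {
    cons <- majority_rule_consensus(boot$support, tab$id)
    ref <- upgma(nei_distance_matrix(tab))
    for (cl in tree_clades(ref)) expect_true(clade_in(cons, cl))
    expect_true(all(as.numeric(cons$node.label) == 100))
  }

  # retained clades are pairwise compatible on a full-size run
  t45 <- load_gahp_fixture("populations45")
  boot45 <- bootstrap_upgma(t45, cfg = bootstrap_config(1000, seed = 1))
  expect_silent(cons45 <- majority_rule_consensus(boot45$support, t45$id))
  keys <- vapply(tree_clades(cons45), paste, character(1), collapse = "|")
  kept <- boot45$support[boot45$support$support > 50 &
                           boot45$support$size > 1 &
                           boot45$support$size < 45, ]
  expect_setequal(setdiff(keys, paste(sort(t45$id), collapse = "|")),
                  kept$clade)
})
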