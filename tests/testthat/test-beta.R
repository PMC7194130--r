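test_that("pair counts are exact set arithmetic", {
  pc <- pair_counts(rep(1, 5), rep(1, 5))
  expect_equal(unclass(pc)[c("a", "b", "c")], list(a = 5, b = 0, c = 0))
  pc2 <- pair_counts(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  expect_equal(c(pc2$a, pc2$b, pc2$c), c(0, 3, 3))
  # site1 = {X,Y,Z}, site2 = {Y,Z,W,V}
  pc3 <- pair_counts(c(1, 1, 1, 0, 0), c(0, 1, 1, 1, 1))
  expect_equal(c(pc3$a, pc3$b, pc3$c), c(2, 1, 2))
  expect_error(pair_counts(c(0, 0), c(0, 0)), "empty")
  expect_error(pair_counts(c(1, 0), c(1, 0, 0)), "species list")
})

test_that("pairwise partition matches direct evaluation of the formulas", {
  bp0 <- pairwise_partition(list(a = 5, b = 0, c = 0))
  expect_equal(c(bp0$bsor, bp0$bsim, bp0$bsne), c(0, 0, 0))
  bp1 <- pairwise_partition(list(a = 0, b = 3, c = 3))
  expect_equal(c(bp1$bsor, bp1$bsim, bp1$bsne), c(1, 1, 0))
  bp2 <- pairwise_partition(list(a = 3, b = 4, c = 0))
  expect_equal(c(bp2$bsor, bp2$bsim, bp2$bsne), c(0.4, 0, 0.4))
  bp3 <- pairwise_partition(list(a = 2, b = 2, c = 1))
  expect_equal(c(bp3$bsor, bp3$bsim, bp3$bsne), c(3 / 7, 1 / 3, 2 / 21))
  # one empty side is undefined, not bsor = 1
  expect_error(pairwise_partition(list(a = 0, b = 2, c = 0)), "empty")
})

test_that("pairwise partition agrees with the set-arithmetic oracle on all
           small incidence pairs", {
  # exhaustive over all non-degenerate pairs on 6 species
  vecs <- as.matrix(expand.grid(rep(list(0:1), 6)))
  for (i in seq_len(nrow(vecs))) {
    if (sum(vecs[i, ]) == 0) next
    for (j in seq_len(nrow(vecs))) {
      if (sum(vecs[j, ]) == 0) next
      o <- oracle_pair(vecs[i, ], vecs[j, ])
      bp <- pairwise_partition(pair_counts(vecs[i, ], vecs[j, ]))
      expect_equal(c(bp$bsor, bp$bsim, bp$bsne),
                   unname(o[c("bsor", "bsim", "bsne")]),
                   tolerance = 1e-14)
    }
  }
})

test_that("additivity, bounds, and symmetry hold on random pairs", {
  set.seed(17)
  for (r in 1:2000) {
    v1 <- rbinom(12, 1, runif(1, 0.2, 0.8))
    v2 <- rbinom(12, 1, runif(1, 0.2, 0.8))
    if (sum(v1) == 0 || sum(v2) == 0) next
    bp <- pairwise_partition(pair_counts(v1, v2))
    expect_lt(abs(bp$bsor - bp$bsim - bp$bsne), 1e-12)
    expect_true(bp$bsim >= 0 && bp$bsne >= -1e-15 && bp$bsor <= 1)
    rev <- pairwise_partition(pair_counts(v2, v1))
    expect_equal(unclass(bp), unclass(rev))
  }
})

test_that("nestedness and turnover degeneracies", {
  # nested pairs: min(b, c) = 0 forces bsim = 0
  for (a in 1:6) for (b in 0:6) {
    bp <- pairwise_partition(list(a = a, b = b, c = 0))
    expect_equal(bp$bsim, 0)
    expect_equal(bp$bsne, bp$bsor)
  }
  # equal-richness pairs: b = c forces bsne = 0
  for (a in 0:6) for (b in 1:6) {
    bp <- pairwise_partition(list(a = a, b = b, c = b))
    expect_equal(bp$bsne, 0)
  }
})

test_that("multi-site partition equals the pairwise form for two sites", {
  set.seed(4)
  for (r in 1:200) {
    m <- rand_incidence(2, 8)
    ms <- multisite_partition(m)
    pw <- pairwise_partition(pair_counts(m[1, ], m[2, ]))
    expect_equal(c(ms$bsor, ms$bsim, ms$bsne),
                 c(pw$bsor, pw$bsim, pw$bsne), tolerance = 1e-12)
  }
})

test_that("multi-site partition matches the brute-force oracle", {
  # identical sites
  m0 <- matrix(1, 4, 5)
  ms0 <- multisite_partition(m0)
  expect_equal(c(ms0$bsor, ms0$bsim, ms0$bsne), c(0, 0, 0))
  # perfectly nested chain with richness 8, 6, 4, 2
  chain <- rbind(c(rep(1, 8)), c(rep(1, 6), 0, 0),
                 c(rep(1, 4), rep(0, 4)), c(1, 1, rep(0, 6)))
  msc <- multisite_partition(chain)
  expect_equal(msc$bsim, 0)
  expect_equal(msc$bsne, msc$bsor)
  expect_equal(unname(oracle_multisite(chain)),
               c(msc$bsor, msc$bsim, msc$bsne), tolerance = 1e-14)
  # random matrices against the oracle
  set.seed(8)
  for (r in 1:300) {
    m <- rand_incidence(sample(2:5, 1), sample(4:9, 1), runif(1, 0.3, 0.7))
    ms <- multisite_partition(m)
    expect_equal(c(ms$bsor, ms$bsim, ms$bsne),
                 unname(oracle_multisite(m)), tolerance = 1e-12)
  }
  expect_error(multisite_partition(rbind(c(1, 1), c(0, 0))), "empty")
})

test_that("multi-site partition agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  set.seed(12)
  for (r in 1:100) {
    m <- rand_incidence(4, 10)
    ms <- multisite_partition(m)
    vg <- vegan::nestedbetasor(m)
    expect_equal(c(ms$bsim, ms$bsne, ms$bsor),
                 unname(vg[c("turnover", "nestedness", "sorensen")]),
                 tolerance = 1e-10)
  }
})

test_that("temporal partition matches sites and classifies change modes", {
  mk <- function(vals, sites, species) {
    matrix(vals, nrow = length(sites), byrow = TRUE,
           dimnames = list(sites, species))
  }
  sp <- paste0("s", 1:6)
  m1 <- mk(c(1, 1, 1, 1, 1, 1,
             1, 1, 1, 1, 0, 0), c("GUL1.N", "GUL1.S"), sp)
  # GUL1.N loses 2 of 6 species, no gains: pure nestedness through time
  # GUL1.S swaps 2 species for 2 others: pure turnover
  m2 <- mk(c(1, 1, 1, 1, 0, 0,
             1, 1, 0, 0, 1, 1), c("GUL1.N", "GUL1.S"), sp)
  tp <- temporal_partition(m1, m2)
  n_row <- tp[tp$site == "GUL1.N", ]
  expect_equal(n_row$bsim, 0)
  expect_gt(n_row$bsne, 0)
  s_row <- tp[tp$site == "GUL1.S", ]
  expect_equal(s_row$bsne, 0)
  expect_gt(s_row$bsim, 0)
  # identical years: all zero
  tp0 <- temporal_partition(m1, m1)
  expect_true(all(tp0$bsor == 0))
  # unmatched site is an error naming the orphan
  m3 <- m2[1, , drop = FALSE]
  expect_error(temporal_partition(m1, m3), "GUL1.S")
})

test_that("temporal partition works on community matrices from records", {
  sv <- generate_survey(survey_design(seed = 31))
  m1 <- build_matrix(sv$observations, "aspect", year = 2014,
                     mode = "incidence")
  m2 <- build_matrix(sv$observations, "aspect", year = 2018,
                     mode = "incidence")
  tp <- temporal_partition(m1, m2)
  expect_equal(nrow(tp), 16)
  expect_true(all(abs(tp$bsor - tp$bsim - tp$bsne) < 1e-12))
})

test_that("component distance matrices are symmetric with zero diagonal", {
  m0 <- rbind(a = c(1, 1, 0), b = c(1, 1, 0))
  expect_true(all(component_distance_matrix(m0, "bsor") == 0))
  md <- rbind(a = c(1, 1, 0, 0, 0, 0), b = c(0, 0, 1, 1, 0, 0),
              c = c(0, 0, 0, 0, 1, 1))
  dm <- component_distance_matrix(md, "bsim")
  expect_true(all(dm[upper.tri(dm)] == 1))
  # nested chain: bsim distances all zero
  chain <- rbind(s1 = rep(1, 8), s2 = c(rep(1, 6), 0, 0),
                 s3 = c(rep(1, 4), rep(0, 4)), s4 = c(1, 1, rep(0, 6)))
  dchain <- component_distance_matrix(chain, "bsim")
  expect_true(all(dchain == 0))
  dsne <- component_distance_matrix(chain, "bsne")
  expect_equal(dsne, t(dsne))
  expect_true(all(diag(dsne) == 0))
})

test_that("UPGMA clustering merges at average dissimilarity", {
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  hc2 <- average_linkage_cluster(d2)
  expect_equal(hc2$height, 0.3)

  d3 <- matrix(c(0, 0.1, 0.5,
                 0.1, 0, 0.5,
                 0.5, 0.5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc3 <- average_linkage_cluster(d3)
  expect_equal(hc3$height, c(0.1, 0.5))

  # ultrametric input is a fixed point: cophenetic distances reproduce it
  expect_equal(as.matrix(stats::cophenetic(hc3))[rownames(d3), rownames(d3)],
               d3)
  expect_error(average_linkage_cluster(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
})

test_that("dendrograms survive a Newick round trip", {
  sv <- generate_survey(survey_design(seed = 23))
  m <- build_matrix(sv$observations, "aspect", year = 2014,
                    mode = "incidence")
  dm <- component_distance_matrix(m, "bsne")
  hc <- average_linkage_cluster(dm)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(hc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(dm))
})
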