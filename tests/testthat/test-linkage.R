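test_that("Kosambi function matches closed forms and inverts exactly", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.25), 25 * log(3))
  expect_equal(kosambi_cm(0.25), 27.47, tolerance = 1e-3)
  # small-r limit d ~ 100 r
  expect_equal(kosambi_cm(0.01), 1.0, tolerance = 1e-3)
  r_grid <- seq(0, 0.49, by = 0.007)
  expect_equal(kosambi_r(kosambi_cm(r_grid)), r_grid, tolerance = 1e-10)
  expect_true(all(diff(kosambi_cm(r_grid)) > 0))
  expect_error(kosambi_cm(0.5), "0.5")
  expect_error(kosambi_cm(-0.1))
  expect_error(kosambi_r(-1), "non-negative")
})

test_that("marker-trait recombination counts recombinant alleles", {
  est0 <- estimate_r_trait(rep("B", 40))
  expect_equal(est0$r_hat, 0)
  expect_gt(est0$lod, 4)
  expect_equal(est0$cm, 0)
  # 3 A (6 rec alleles) + 4 H (4 rec) in 50 plants -> 10/100
  g <- c(rep("B", 43), rep("A", 3), rep("H", 4))
  est <- estimate_r_trait(g)
  expect_equal(est$r_hat, 0.10)
  expect_equal(est$k, 10L)
  # LOD from the per-allele binomial likelihood
  lod_manual <- 10 * log10(.1) + 90 * log10(.9) - 100 * log10(.5)
  expect_equal(est$lod, lod_manual)
  expect_error(estimate_r_trait(character(0)), "no mutant-class")
  expect_error(estimate_r_trait(c("B", "Q")), "invalid genotype")
})

test_that("an unlinked marker gives r near 0.5 and LOD near 0", {
  set.seed(21)
  r_hats <- replicate(50, {
    g <- c("A", "H", "B")[rbinom(60, 1, .5) + rbinom(60, 1, .5) + 1]
    estimate_r_trait(g)$r_hat
  })
  # the MLE is truncated at 0.5, so its mean sits just below it
  expect_gt(mean(r_hats), 0.44)
  expect_lte(max(r_hats), 0.5)
  g <- c("A", "H", "B")[rbinom(200, 1, .5) + rbinom(200, 1, .5) + 1]
  expect_lt(estimate_r_trait(g)$lod, 2)
})

test_that("marker-marker EM recovers the simulated recombination", {
  set.seed(33)
  for (r_true in c(0.05, 0.2)) {
    r_hats <- replicate(60, {
      gam1 <- matrix(rbinom(400, 1, 0.5), ncol = 2)
      flip <- matrix(rbinom(400, 1, r_true), ncol = 2)
      gam2 <- (gam1 + flip) %% 2
      g1 <- c("A", "H", "B")[rowSums(gam1) + 1]
      g2 <- c("A", "H", "B")[rowSums(gam2) + 1]
      estimate_r_markers(g1, g2)$r_hat
    })
    expect_lt(abs(mean(r_hats) - r_true), 0.02)
  }
})

test_that("BSA bulk screening passes fully linked markers", {
  cfg <- tiny_config(seed = 3, n_f2 = 120L)
  map <- data.frame(marker = c("M_0", "M_25", "U_a"),
                    group = c(1L, 1L, 2L), cm = c(0, 25, 0))
  mk <- simulate_marker_table(cfg, map)
  mutants <- mk$id[mk$phenotype == "mutant"]
  normals <- mk$id[mk$phenotype == "normal"]
  res <- bsa_screen(mk, wt_bulk = normals[1:5], mutant_bulk = mutants[1:5])
  # a 0 cM marker is fixed in the mutant bulk and must pass
  expect_true(res$pass[res$marker == "M_0"])
  expect_equal(res$scp_alleles[res$marker == "M_0"], "B")
  expect_error(bsa_screen(mk, wt_bulk = c(99999),
                          mutant_bulk = mutants[1:5]),
               "not in table")
})

test_that("monomorphic markers always fail the bulk screen", {
  tab <- data.frame(id = 1:10, phenotype = rep(c("mutant", "normal"), 5),
                    mono = rep("H", 10), stringsAsFactors = FALSE)
  res <- bsa_screen(tab, wt_bulk = c(2, 4, 6, 8, 10),
                    mutant_bulk = c(1, 3, 5, 7, 9))
  expect_false(res$pass)
})

test_that("unlinked markers rarely pass the 5+5 bulk screen", {
  set.seed(9)
  passes <- 0L
  for (rep in 1:100) {
    g <- c("A", "H", "B")[rbinom(10, 1, .5) + rbinom(10, 1, .5) + 1]
    tab <- data.frame(id = 1:10, phenotype = rep(c("mutant", "normal"), 5),
                      m = g, stringsAsFactors = FALSE)
    passes <- passes +
      bsa_screen(tab, wt_bulk = seq(2, 10, 2),
                 mutant_bulk = seq(1, 9, 2))$pass
  }
  # the mutant bulk must be fixed AND differ from the WT bulk:
  # P(fixed) = 2 (1/4)^5 so passes should stay in the low single digits
  expect_lte(passes, 4L)
})

test_that("LOD grouping separates chromosomes and orders markers", {
  cfg <- sim_config(seed = 13, n_f2 = 400L)
  map <- data.frame(marker = c("a", "b", "c", "x", "y", "z"),
                    group = c(1, 1, 1, 2, 2, 2),
                    cm = c(5, 15, 30, 0, 12, 22))
  mk <- simulate_marker_table(cfg, map)
  est <- pairwise_linkage(mk)
  groups <- group_markers(est, lod_threshold = 4)
  expect_equal(length(groups), 2L)
  members <- lapply(groups, function(g) sort(g$marker))
  expect_true(list(c("a", "b", "c")) %in% members ||
                identical(members[[1]], c("a", "b", "c")) ||
                identical(members[[2]], c("a", "b", "c")))
  ord1 <- groups[[which(vapply(members, function(m)
    "a" %in% m, logical(1)))]]$marker
  expect_true(identical(ord1, c("a", "b", "c")) ||
                identical(ord1, c("c", "b", "a")))
  # grouping is invariant to input order
  est_shuf <- est[sample(nrow(est)), ]
  groups2 <- group_markers(est_shuf, lod_threshold = 4)
  expect_equal(lapply(groups, function(g) g$marker),
               lapply(groups2, function(g) g$marker))
})

test_that("an infinite LOD threshold isolates every marker", {
  est <- data.frame(a = c("m1", "m1", "m2"), b = c("m2", "m3", "m3"),
                    r_hat = c(.1, .2, .1), lod = c(10, 8, 12))
  groups <- group_markers(est, lod_threshold = Inf)
  expect_equal(length(groups), 3L)
})

test_that("known 8-marker order is recovered up to reversal", {
  cfg <- sim_config(seed = 29, n_f2 = 500L)
  pos <- c(2, 10, 18, 25, 33, 40, 48, 55)
  map <- data.frame(marker = sprintf("s%02d", seq_along(pos)),
                    group = 1, cm = pos)
  mk <- simulate_marker_table(cfg, map)
  est <- pairwise_linkage(mk)
  groups <- group_markers(est, lod_threshold = 3)
  big <- groups[[which.max(vapply(groups, nrow, integer(1)))]]
  expect_gte(nrow(big), 7L)
  ord <- big$marker
  idx <- match(sprintf("s%02d", seq_along(pos)), ord)
  idx <- idx[!is.na(idx)]
  expect_true(all(diff(idx) > 0) || all(diff(idx) < 0))
})
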