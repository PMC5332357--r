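make_sites <- function(chrom, pos, index, depth = 30L) {
  alt <- as.integer(round(index * depth))
  data.frame(chrom = chrom, pos = pos, ref = "G", alt = "A",
             ref_depth = depth - alt, alt_depth = alt,
             snp_index = alt / depth, stringsAsFactors = FALSE)
}

test_that("SNP index is the alt read fraction and NA at zero depth", {
  expect_equal(compute_snp_index(0, 20), 1)
  expect_equal(compute_snp_index(10, 10), 0.5)
  expect_equal(compute_snp_index(3, 9), 0.75)
  expect_message(idx <- compute_snp_index(c(0, 5), c(0, 5)), "zero depth")
  expect_true(is.na(idx[1]) && idx[2] == 0.5)
  expect_error(compute_snp_index(-1, 5))
})

test_that("mutant-specific derivation removes shared parental variants", {
  ems <- data.frame(chrom = "chr1", pos = seq(1000, 30000, by = 1000),
                    ref = "G", alt = "A", ref_depth = 0L, alt_depth = 25L,
                    stringsAsFactors = FALSE)
  shared <- data.frame(chrom = "chr1", pos = seq(50000, 69000, by = 1000),
                       ref = "C", alt = "T", ref_depth = 0L,
                       alt_depth = 25L, stringsAsFactors = FALSE)
  mutant <- rbind(ems, shared)
  wt <- rbind(
    transform(ems, ref_depth = 25L, alt_depth = 0L),
    transform(shared, ref_depth = 0L, alt_depth = 25L))
  out <- derive_mutant_specific_sites(mutant, wt)
  expect_equal(nrow(out), 30L)
  expect_true(all(out$pos %in% ems$pos))
  expect_true(all(out$wt_state == "ref"))
  expect_true(!is.unsorted(out$pos))
})

test_that("heterozygous or uncovered parent sites are not mutant-specific", {
  mutant <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                       ref = "G", alt = "A",
                       ref_depth = 0L, alt_depth = 20L,
                       stringsAsFactors = FALSE)
  wt <- data.frame(chrom = "chr1", pos = c(100L, 200L),
                   ref = "G", alt = "A",
                   ref_depth = c(20L, 10L), alt_depth = c(0L, 10L),
                   stringsAsFactors = FALSE)
  out <- derive_mutant_specific_sites(mutant, wt)
  # pos 200 het in parent, pos 300 absent from the parent table
  expect_equal(out$pos, 100L)
})

test_that("table mismatches are rejected", {
  a <- data.frame(chrom = "chr1", pos = c(1L, 1L), ref = "G", alt = "A",
                  ref_depth = 0L, alt_depth = 9L)
  b <- data.frame(chrom = "chr1", pos = 5L, ref = "G", alt = "A",
                  ref_depth = 9L, alt_depth = 0L)
  expect_error(derive_mutant_specific_sites(a, b), "duplicate")
  a2 <- data.frame(chrom = "chrX", pos = 1L, ref = "G", alt = "A",
                   ref_depth = 0L, alt_depth = 9L)
  expect_error(derive_mutant_specific_sites(a2, b), "shared chromosome")
  a3 <- a[1L, ]
  attr(a3, "reference") <- "buildA"
  b3 <- b
  attr(b3, "reference") <- "buildB"
  expect_error(derive_mutant_specific_sites(a3, b3),
               "different references")
})

test_that("five-SNP windows average indices at member midpoints", {
  s <- make_sites("chr1", seq(100, 500, by = 100), c(.2, .4, .6, .8, 1),
                  depth = 10L)
  w <- sliding_window(s, k = 5L)
  expect_equal(nrow(w), 1L)
  expect_equal(w$mean_index, 0.6)
  expect_equal(w$x, 300)
  expect_equal(w$start_pos, 100)
  expect_equal(w$end_pos, 500)
})

test_that("windows shift one SNP at a time and never span chromosomes", {
  s <- rbind(make_sites("chr1", seq(100, 1000, by = 100), rep(1, 10)),
             make_sites("chr2", seq(100, 400, by = 100), rep(0.5, 4)))
  w <- sliding_window(s, k = 5L)
  expect_equal(sum(w$chrom == "chr1"), 6L)   # n - k + 1
  expect_equal(sum(w$chrom == "chr2"), 0L)   # fewer than k sites
  expect_true(all(w$mean_index[w$chrom == "chr1"] == 1))
  expect_true(all(w$x > w$start_pos & w$x < w$end_pos))
})

test_that("window means are permutation-invariant and bounded", {
  set.seed(11)
  for (rep in 1:20) {
    idx <- runif(9)
    s <- make_sites("chr1", seq(100, 900, by = 100), idx, depth = 1000L)
    w <- sliding_window(s, k = 5L)
    for (i in seq_len(nrow(w))) {
      members <- s$snp_index[s$pos >= w$start_pos[i] &
                               s$pos <= w$end_pos[i]]
      expect_equal(w$mean_index[i], mean(members))
      expect_gte(w$mean_index[i], min(members))
      expect_lte(w$mean_index[i], max(members))
    }
  }
})

test_that("candidate regions are maximal runs above the threshold", {
  idx <- c(.4, .4, .4, .4, .4, 1, 1, 1, 1, 1, 1, 1, .4, .4, .4, .4, .4)
  s <- make_sites("chr1", seq(1000, by = 1000,
                              length.out = length(idx)), idx, depth = 40L)
  w <- sliding_window(s, k = 5L)
  r <- call_candidate_region(w, threshold = 0.9)
  expect_equal(nrow(r), 1L)
  # the only all-high run is windows 6..8 (sites 6-10 .. 8-12)
  expect_equal(r$start, 6000)
  expect_equal(r$end, 12000)
  expect_equal(r$peak_index, 1)
  expect_equal(r$n_sites, 7L)
})

test_that("threshold 0 spans every window; nothing passing warns", {
  s <- rbind(make_sites("chr1", seq(1000, 9000, 1000), rep(.5, 9)),
             make_sites("chr2", seq(1000, 9000, 1000), rep(.4, 9)))
  w <- sliding_window(s, k = 5L)
  r0 <- call_candidate_region(w, threshold = 0)
  expect_equal(nrow(r0), 2L)
  expect_equal(sort(r0$chrom), c("chr1", "chr2"))
  expect_equal(r0$start, c(1000, 1000))
  expect_equal(r0$end, c(9000, 9000))
  expect_warning(rE <- call_candidate_region(w, threshold = 0.9),
                 "no window")
  expect_equal(nrow(rE), 0L)
})

test_that("unlinked binomial noise at depth 30 yields no candidate region", {
  set.seed(5)
  false_pos <- 0L
  for (rep in 1:20) {
    depth <- rpois(300, 30)
    depth[depth == 0] <- 1L
    alt <- rbinom(300, depth, 0.5)
    s <- data.frame(chrom = "chr1", pos = seq_len(300) * 1000,
                    ref = "G", alt = "A", ref_depth = depth - alt,
                    alt_depth = alt, snp_index = alt / depth)
    w <- sliding_window(s, k = 5L)
    r <- suppressWarnings(call_candidate_region(w, threshold = 0.9))
    false_pos <- false_pos + (nrow(r) > 0L)
  }
  expect_equal(false_pos, 0L)
})
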