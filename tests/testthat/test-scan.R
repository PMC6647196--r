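fake_sites <- function(pos, fz, fl, depth = 60, chrom = "chr01") {
  n <- length(pos)
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
             var_class = "SNP",
             parent_wt_ref = depth, parent_wt_alt = 0,
             parent_mut_ref = 0, parent_mut_alt = depth,
             fuzzy_ref = round(depth * (1 - fz)), fuzzy_alt = round(depth * fz),
             fuzzless_ref = round(depth * (1 - fl)),
             fuzzless_alt = round(depth * fl),
             stringsAsFactors = FALSE)
}

test_that("SNP-index and delta SNP-index are the stated read fractions", {
  s <- data.frame(fuzzy_ref = c(20, 60, 0), fuzzy_alt = c(40, 0, 35))
  expect_equal(snp_index(s, "fuzzy"), c(2 / 3, 0, 1))
  s2 <- fake_sites(1:2, fz = c(0, 0.5), fl = c(2 / 3, 0.5), depth = 60)
  expect_equal(delta_snp_index(s2), c(2 / 3, 0))
  expect_error(snp_index(s, "nope"), "unknown pool")
})

test_that("Euclidean distance has its biallelic closed form", {
  s <- fake_sites(1:3, fz = c(0, 0.5, 0), fl = c(1, 0.5, 2 / 3))
  expect_equal(euclidean_distance(s), c(sqrt(2), 0, sqrt(2) * 2 / 3),
               tolerance = 1e-12)
  # brute-force allele-frequency-vector check of the third case
  f_less <- c(1 / 3, 2 / 3); f_fuzzy <- c(1, 0)
  expect_equal(sqrt(sum((f_less - f_fuzzy)^2)), sqrt(2) * 2 / 3)
  expect_equal(euclidean_distance(s, power = 4), euclidean_distance(s)^4)
  # range invariant over random biallelic sites
  set.seed(1)
  r <- fake_sites(1:50, fz = runif(50), fl = runif(50), depth = 1000)
  expect_true(all(euclidean_distance(r) >= 0 &
                    euclidean_distance(r) <= sqrt(2) + 1e-9))
  expect_true(all(abs(delta_snp_index(r)) <= 1))
})

test_that("informativeness filters drop low-depth and discordant parents", {
  s <- fake_sites(1:4, fz = rep(0.1, 4), fl = rep(0.6, 4))
  s$fuzzy_ref[1] <- 3; s$fuzzy_alt[1] <- 0          # pool depth 3 < 10
  s$parent_mut_alt[2] <- 30; s$parent_mut_ref[2] <- 30  # parent not homozygous
  s$parent_wt_ref[3] <- 4; s$parent_wt_alt[3] <- 0  # parent depth < 10
  kept <- filter_informative_sites(s, min_depth = 10, min_parent_depth = 10)
  expect_equal(kept$pos, 4)

  # simulator truth: retained set equals sites passing the depth rules,
  # since simulated parents are exact opposite homozygotes
  cfg <- sim_config(n_individuals = 400, n_sites = 200, n_bg_chrom = 0,
                    seq_error = 0, seed = 31)
  pop <- simulate_population(cfg)
  sites <- simulate_pool_depths(pop, make_pools(pop))
  kept <- filter_informative_sites(sites)
  manual <- sites[sites$parent_wt_ref + sites$parent_wt_alt >= 10 &
                    sites$parent_mut_ref + sites$parent_mut_alt >= 10 &
                    sites$fuzzy_ref + sites$fuzzy_alt >= 10 &
                    sites$fuzzless_ref + sites$fuzzless_alt >= 10, ]
  expect_equal(kept$pos, manual$pos)
})

test_that("track fitting is an exact local weighted mean", {
  s <- fake_sites(seq(1e5, 1e6, by = 1e5), fz = rep(0, 10), fl = rep(0.5, 10))
  tr <- make_track(s, "delta_snp_index")
  # constant raw -> fitted identical
  fit <- fit_track(tr, window = 4e5)
  expect_equal(fit$fitted, fit$raw)
  # window below the inter-site gap -> fitted equals raw
  s2 <- fake_sites(seq(1e5, 1e6, by = 1e5), fz = rep(0, 10),
                   fl = seq(0, 0.9, by = 0.1))
  fit2 <- fit_track(make_track(s2, "delta_snp_index"), window = 1e5)
  expect_equal(fit2$fitted, fit2$raw)
  # step signal: fitted is monotone non-decreasing across the step and
  # stays within the raw range
  s3 <- fake_sites(seq(1e4, 1e6, by = 1e4), fz = rep(0, 100),
                   fl = rep(c(0, 0.6), each = 50))
  fit3 <- fit_track(make_track(s3, "delta_snp_index"), window = 2e5)
  expect_true(all(diff(fit3$fitted) >= -1e-12))
  expect_true(all(fit3$fitted >= min(fit3$raw) - 1e-12 &
                    fit3$fitted <= max(fit3$raw) + 1e-12))
  # direct evaluation of the tricube mean at one step-adjacent site
  i <- 50
  h <- 1e5
  w <- pmax(0, 1 - (abs(fit3$pos - fit3$pos[i]) / h)^3)^3
  expect_equal(fit3$fitted[i], sum(w * fit3$raw) / sum(w))
})

test_that("median + 3SD threshold matches hand computation", {
  tr <- structure(data.frame(chrom = "c", pos = 1:4, raw = 0,
                             fitted = c(0, 0.1, 0.2, 0.9)),
                  class = c("bsa_track", "data.frame"))
  expect_equal(threshold_median_3sd(tr), 0.15 + 3 * sd(c(0, 0.1, 0.2, 0.9)))
  tr$fitted <- rep(0.1, 4)
  expect_equal(threshold_median_3sd(tr), 0.1)
  tr$fitted <- rep(0, 4)
  expect_equal(threshold_median_3sd(tr), 0)
})

test_that("region calling finds maximal runs and merges across gaps", {
  tr <- structure(data.frame(chrom = "c", pos = (1:5) * 1e5, raw = 0,
                             fitted = c(0.1, 0.4, 0.5, 0.2, 0.6)),
                  class = c("bsa_track", "data.frame"))
  reg <- call_regions(tr, 0.35, merge_gap = 0)
  expect_equal(reg$start, c(2e5, 5e5))
  expect_equal(reg$end, c(3e5, 5e5))
  expect_equal(nrow(call_regions(tr, 0.99)), 0)
  # generous merge gap bridges the dip
  reg2 <- call_regions(tr, 0.35, merge_gap = 3e5)
  expect_equal(reg2$start, 2e5)
  expect_equal(reg2$end, 5e5)
})

test_that("region calling agrees with brute-force run enumeration", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(2:50, 1)
    pos <- sort(sample(1e6, n))
    fitted <- round(runif(n), 2)
    thr <- round(runif(1), 2)
    gap <- sample(c(0, 1e4, 1e5, 5e5), 1)
    tr <- structure(data.frame(chrom = "c", pos = pos, raw = 0,
                               fitted = fitted),
                    class = c("bsa_track", "data.frame"))
    got <- call_regions(tr, thr, gap)
    want <- call_regions_oracle(pos, fitted, thr, gap)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(cbind(got$start, got$end), want)
    }
  }
})

test_that("a simulated scan localises the causal position", {
  cfg <- sim_config(n_individuals = 1000, n_sites = 1000, seed = 13)
  pop <- simulate_population(cfg)
  sites <- simulate_pool_depths(pop, make_pools(pop))
  scan <- run_scan(sites)
  hit <- any(scan$candidate$chrom == "chr01" &
               scan$candidate$start <= cfg$causal_pos &
               scan$candidate$end >= cfg$causal_pos)
  expect_true(hit)
  # thresholds are positive and below the track maxima on the focal
  # chromosome (otherwise nothing could be called)
  expect_true(all(scan$thresholds > 0))
})

test_that("called region width does not grow with sequencing depth", {
  # at this map density the scan is recombination-limited, so widths
  # saturate near the focal chromosome span rather than shrinking; they
  # must at least never widen as depth increases 20x -> 50x -> 100x
  median_width <- vapply(c(20, 50, 100), function(depth) {
    widths <- vapply(1:8, function(s) {
      cfg <- sim_config(n_individuals = 1000, n_sites = 800,
                        mean_depth = depth, seed = 700 + s)
      pop <- simulate_population(cfg)
      sites <- simulate_pool_depths(pop, make_pools(pop))
      scan <- run_scan(sites)
      focal <- scan$candidate[scan$candidate$chrom == "chr01", ]
      if (nrow(focal) == 0) return(NA_real_)
      sum(interval_length(focal))
    }, numeric(1))
    median(widths, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(median_width) <= 1e6))  # no systematic widening
  expect_true(all(median_width <= 1e7))        # within the chromosome
})
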