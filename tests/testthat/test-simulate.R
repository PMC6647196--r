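test_that("phenotype ratios match Mendelian expectations", {
  # 99% binomial bounds at the simulated sizes
  pop <- simulate_population(sim_config(n_individuals = 4000, n_sites = 10,
                                        seed = 3))
  n_less <- sum(pop$phenotype == "fuzzless")
  bounds <- qbinom(c(0.005, 0.995), 4000, 0.75)
  expect_gte(n_less, bounds[1])
  expect_lte(n_less, bounds[2])

  bc1 <- simulate_population(sim_config(n_individuals = 2000,
                                        cross_type = "BC1", n_sites = 10,
                                        seed = 4))
  n_less <- sum(bc1$phenotype == "fuzzless")
  bounds <- qbinom(c(0.005, 0.995), 2000, 0.5)
  expect_gte(n_less, bounds[1])
  expect_lte(n_less, bounds[2])
  # BC1 to the wild parent never produces mutant homozygotes
  expect_true(all(bc1$causal_dosage <= 1))
})

test_that("no recombination means constant dosage along the chromosome", {
  cfg <- sim_config(n_individuals = 100, n_sites = 20, cm_per_mb = 0,
                    pool_size = 10, seed = 5)
  pop <- simulate_population(cfg)
  dos <- dosage_at(pop, seq(1e5, 1e7, length.out = 25))
  expect_true(all(apply(dos, 1, function(r) length(unique(r)) == 1)))
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- small_sim(seed = 9)
  a <- simulate_population(cfg); b <- simulate_population(cfg)
  expect_identical(a, b)
  sa <- simulate_pool_depths(a, make_pools(a))
  sb <- simulate_pool_depths(b, make_pools(b))
  expect_identical(sa, sb)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(causal_pos = 2e7), "causal_pos")
  expect_error(sim_config(seq_error = 0.7), "seq_error")
  expect_error(sim_config(n_individuals = 100, pool_size = 30), "pool_size")
  # fillability: expected minority class below pool_size
  cfg <- sim_config(n_individuals = 130, pool_size = 32)
  expect_error(simulate_population(cfg), "pool-unfillable")
})

test_that("pools are disjoint within-class samples of the right size", {
  pop <- simulate_population(small_sim(seed = 2))
  pools <- make_pools(pop, 30)
  expect_length(pools$fuzzy, 30)
  expect_length(pools$fuzzless, 30)
  expect_length(intersect(pools$fuzzy, pools$fuzzless), 0)
  expect_true(all(pop$phenotype[pools$fuzzy] == "fuzzy"))
  expect_true(all(pop$phenotype[pools$fuzzless] == "fuzzless"))
  empty <- make_pools(pop, 0)
  expect_length(empty$fuzzy, 0)
  expect_length(empty$fuzzless, 0)
  expect_error(make_pools(pop, 1e4), "fewer than pool_size")
})

test_that("selected-pool allele frequencies match the enumeration oracle", {
  # dominant F2: fuzzy pool fixed wild (0), fuzzless pool at 2/3
  expect_equal(f2_pool_freq_oracle("fuzzy"), 0)
  expect_equal(f2_pool_freq_oracle("fuzzless"), 2 / 3)
  freqs <- vapply(1:40, function(s) {
    pop <- simulate_population(small_sim(seed = s))
    pools <- make_pools(pop, 30, seed = s + 1000)
    dos <- dosage_at(pop, pop$config$causal_pos,
                     c(pools$fuzzy, pools$fuzzless))
    c(mean(dos[1:30, ]) / 2, mean(dos[31:60, ]) / 2)
  }, numeric(2))
  expect_equal(mean(freqs[1, ]), 0)
  # Monte-Carlo 3-sigma check against the 2/3 oracle
  se <- sd(freqs[2, ]) / sqrt(ncol(freqs))
  expect_lt(abs(mean(freqs[2, ]) - 2 / 3), 3 * se)
})

test_that("pooled depths follow the stated sampling model", {
  cfg <- sim_config(n_individuals = 400, n_sites = 300, n_bg_chrom = 0,
                    seq_error = 0, mean_depth = 50, seed = 6)
  pop <- simulate_population(cfg)
  pools <- make_pools(pop)
  sites <- simulate_pool_depths(pop, pools)
  expect_true(cfg$causal_pos %in% sites$pos)
  # zero pooled frequency + zero error -> zero alt reads (fuzzy pool is
  # fixed wild at the causal site under dominance)
  causal <- sites[sites$pos == cfg$causal_pos, ]
  expect_equal(causal$fuzzy_alt, 0)
  expect_equal(causal$parent_wt_alt, 0)
  expect_equal(causal$parent_mut_ref, 0)
  # Poisson depth mean
  depth <- sites$fuzzless_ref + sites$fuzzless_alt
  expect_lt(abs(mean(depth) - 50), 3 * sd(depth) / sqrt(length(depth)))
  # positions strictly increasing within each chromosome
  expect_true(all(tapply(sites$pos, sites$chrom,
                         function(p) all(diff(p) > 0))))
})

test_that("causal-site fuzzless alt fraction converges to 2/3 at depth", {
  cfg <- sim_config(n_individuals = 4000, n_sites = 50, mean_depth = 5000,
                    n_bg_chrom = 0, seq_error = 0, seed = 8)
  pop <- simulate_population(cfg)
  sites <- simulate_pool_depths(pop, make_pools(pop))
  causal <- sites[sites$pos == cfg$causal_pos, ]
  f <- causal$fuzzless_alt / (causal$fuzzless_ref + causal$fuzzless_alt)
  # pool of 30: dominated by pool-composition noise, sd ~ sqrt(f(1-f)/60)
  expect_lt(abs(f - 2 / 3), 3 * sqrt(2 / 9 / 60))
})

test_that("background chromosomes are unlinked to the phenotype", {
  deltas <- vapply(1:30, function(s) {
    cfg <- sim_config(n_individuals = 400, n_sites = 50, n_bg_chrom = 1,
                      seed = 100 + s)
    pop <- simulate_population(cfg)
    sites <- simulate_pool_depths(pop, make_pools(pop))
    bg <- sites[sites$chrom != "chr01", ]
    mean(delta_snp_index(bg))
  }, numeric(1))
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se + 1e-3)
})

test_that("expression simulator honours its null and separation limits", {
  # null: no gene passes the FDR 0.01 + |lfc| >= 1 rule beyond the
  # nominal level
  e0 <- simulate_expression(n_genes = 2000, n_true_deg = 0, lfc = 0, seed = 21)
  d0 <- run_differential(e0$counts, e0$lengths, e0$design)
  expect_lte(sum(d0$significant) / nrow(d0), 0.01)

  # separation limit: no overdispersion, strong induction of
  # well-expressed genes -> complete recovery of stage-specific truth
  e1 <- simulate_expression(n_genes = 1000, n_true_deg = 50, lfc = 4,
                            dispersion = 0, mean_log_expr = log(2e4),
                            sd_log_expr = 0.2,
                            deg_stage_weights = c(1, 0, 0), seed = 22)
  d1 <- run_differential(e1$counts, e1$lengths, e1$design)
  truth <- e1$truth[e1$truth$deg, ]
  hit <- mapply(function(g, st) {
    any(d1$significant & d1$gene_id == g & d1$stage == st)
  }, truth$gene_id, truth$stage)
  expect_true(all(hit))

  # moderate regime: recovery measured against truth labels is a
  # proportion, and discoveries stay within the truth set
  e2 <- simulate_expression(n_genes = 2000, n_true_deg = 50, lfc = 2,
                            seed = 23)
  d2 <- run_differential(e2$counts, e2$lengths, e2$design)
  sig <- d2[d2$significant, ]
  truth_keys <- paste(e2$truth$gene_id[e2$truth$deg],
                      e2$truth$stage[e2$truth$deg])
  recovery <- mean(truth_keys %in% paste(sig$gene_id, sig$stage))
  expect_gte(recovery, 0)
  expect_lte(recovery, 1)
})

test_that("expression design matrix matches its column naming scheme", {
  e <- simulate_expression(n_genes = 20, n_true_deg = 2, seed = 1)
  expect_equal(ncol(e$counts), 12)  # 2 genotypes x 3 stages x 2 reps
  expect_equal(colnames(e$counts), e$design$library)
  expect_match(colnames(e$counts)[1], "^(wild|mutant)_[135]DPA_rep[12]$")
})
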