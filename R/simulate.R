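#' Configuration for the pooled-sequencing simulator
#'
#' Defines the cross design and sequencing model for a synthetic mapping
#' experiment: a biparental F2 or BC1 population segregating a single
#' dominant (or recessive) causal locus, phenotype-selected pools, and
#' pooled short-read depths at informative sites.
#'
#' The simulated genome is a miniature of a diploid cotton genome: one focal
#' chromosome of `chrom_length` bp carrying the causal locus, plus
#' `n_bg_chrom` background chromosomes of the same length and site density
#' that segregate independently of it. The genome-wide fitted-value
#' threshold used by the scan (median + 3*SD) presumes that most of the
#' genome is unlinked to the trait; the background chromosomes supply that
#' null background, and with `n_bg_chrom = 12` the focal chromosome is 1 of
#' 13, as in *Gossypium arboreum*.
#'
#' @param n_individuals population size (the reference F2 had 4,010).
#' @param cross_type `"F2"` or `"BC1"` (backcross to the wild parent).
#' @param chrom_length focal chromosome length in bp.
#' @param n_sites number of informative sites per chromosome.
#' @param causal_pos position (bp) of the causal locus on the focal
#'   chromosome.
#' @param dominance `"dominant"` (mutant phenotype needs >= 1 mutant allele)
#'   or `"recessive"`.
#' @param pool_size individuals per phenotype pool (30 + 30 in the
#'   reference design).
#' @param mean_depth mean sequencing depth per site and pool (reads).
#' @param seq_error per-read error probability (allele flip), in `[0, 0.5)`.
#' @param cm_per_mb genetic map density, centimorgans per megabase.
#' @param n_bg_chrom background (unlinked) chromosomes.
#' @param prop_indel fraction of emitted sites that are small InDels rather
#'   than SNPs (the reference scan used roughly 51,244 InDels to 353,611
#'   SNPs, i.e. ~0.13).
#' @param seed integer seed; all simulator randomness flows from it.
#' @return a `sim_config` list.
#' @examples
#' cfg <- sim_config(n_individuals = 400, n_sites = 500, seed = 1)
#' @export
sim_config <- function(n_individuals = 4010,
                       cross_type = c("F2", "BC1"),
                       chrom_length = 10e6,
                       n_sites = 5000,
                       causal_pos = 5e6,
                       dominance = c("dominant", "recessive"),
                       pool_size = 30,
                       mean_depth = 50,
                       seq_error = 0.001,
                       cm_per_mb = 1,
                       n_bg_chrom = 12,
                       prop_indel = 0.13,
                       seed = 1L) {
  cross_type <- match.arg(cross_type)
  dominance <- match.arg(dominance)
  stopifnot(n_individuals >= 4, chrom_length > 0, n_sites >= 2,
            mean_depth > 0, cm_per_mb >= 0, n_bg_chrom >= 0,
            prop_indel >= 0, prop_indel <= 1)
  if (!(causal_pos > 0 && causal_pos <= chrom_length))
    stop("causal_pos must lie in (0, chrom_length]")
  if (!(seq_error >= 0 && seq_error < 0.5))
    stop("seq_error must lie in [0, 0.5)")
  if (pool_size > n_individuals / 4)
    stop("pool_size must not exceed n_individuals/4 ",
         "(pools must be fillable from the minority phenotype class)")
  structure(list(n_individuals = as.integer(n_individuals),
                 cross_type = cross_type, chrom_length = chrom_length,
                 n_sites = as.integer(n_sites), causal_pos = causal_pos,
                 dominance = dominance, pool_size = as.integer(pool_size),
                 mean_depth = mean_depth, seq_error = seq_error,
                 cm_per_mb = cm_per_mb, n_bg_chrom = as.integer(n_bg_chrom),
                 prop_indel = prop_indel, seed = as.integer(seed)),
            class = "sim_config")
}

# One meiotic gamete per row: crossover count ~ Poisson(len_morgans)
# (Haldane, no interference), breakpoints uniform, starting chromatid
# chosen at random. Returned as start alleles + per-gamete breakpoint lists.
r_gametes <- function(n, chrom_length, len_morgans) {
  nb <- stats::rpois(n, len_morgans)
  start <- sample(c(0L, 1L), n, replace = TRUE)
  breaks <- vector("list", n)
  tot <- sum(nb)
  if (tot > 0) {
    u <- stats::runif(tot) * chrom_length
    idx <- rep.int(seq_len(n), nb)
    pieces <- split(u, factor(idx, levels = seq_len(n)))
    breaks <- lapply(pieces, sort)
  } else {
    breaks[] <- list(numeric(0))
  }
  list(start = start, breaks = breaks)
}

# Alleles carried by a set of gametes at given positions (0/1 matrix,
# gametes x positions). A gamete's allele flips at each breakpoint.
gamete_alleles <- function(gam, positions) {
  np <- length(positions)
  out <- matrix(0L, nrow = length(gam$start), ncol = np)
  for (i in seq_along(gam$start)) {
    b <- gam$breaks[[i]]
    if (length(b) == 0L) {
      out[i, ] <- gam$start[i]
    } else {
      out[i, ] <- bitwXor(gam$start[i], findInterval(positions, b) %% 2L)
    }
  }
  out
}

constant_gametes <- function(n, allele = 0L) {
  list(start = rep.int(as.integer(allele), n),
       breaks = rep(list(numeric(0)), n))
}

#' Simulate a segregating mapping population
#'
#' Draws a population of F2 or BC1 individuals on the focal chromosome.
#' Each individual is formed from parental gametes: crossover counts per
#' gamete are Poisson with rate `chrom_length * cm_per_mb / 100` Morgans
#' (Haldane model, no interference) and breakpoints are uniform. An F2
#' individual receives two F1 gametes; a BC1 individual one F1 gamete and
#' one (non-recombinant) wild-parent gamete. Phenotype follows from the
#' dosage of the mutant allele at `causal_pos` under the dominance mode.
#'
#' Background chromosomes are not materialised here: being unlinked to the
#' causal locus they are independent of phenotype, so
#' [simulate_pool_depths()] draws them only for the individuals that enter
#' a pool.
#'
#' @param config a [sim_config()].
#' @return a `bsa_population` list: `config`, gamete pairs, `causal_dosage`
#'   (0/1/2 mutant-allele count per individual) and `phenotype`
#'   (`"fuzzy"`/`"fuzzless"`).
#' @examples
#' pop <- simulate_population(sim_config(n_individuals = 400, seed = 1))
#' table(pop$phenotype)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  # pools must be fillable from the minority class with high probability:
  # require the expected class size minus 3 binomial SDs to cover the pool
  p_min <- if (config$cross_type == "F2") 0.25 else 0.5
  n <- config$n_individuals
  lower <- n * p_min - 3 * sqrt(n * p_min * (1 - p_min))
  if (lower < config$pool_size)
    stop("config is pool-unfillable: minority phenotype class (expected ",
         n * p_min, ", lower bound ", round(lower, 1),
         ") cannot reliably fill pools of ", config$pool_size)
  set.seed(config$seed)
  n <- config$n_individuals
  lm <- config$chrom_length * config$cm_per_mb / 100 / 1e6
  g1 <- r_gametes(n, config$chrom_length, lm)
  g2 <- if (config$cross_type == "F2") r_gametes(n, config$chrom_length, lm)
        else constant_gametes(n, 0L)
  dos <- as.integer(gamete_alleles(g1, config$causal_pos) +
                    gamete_alleles(g2, config$causal_pos))
  mutant_like <- if (config$dominance == "dominant") dos >= 1L else dos == 2L
  structure(list(config = config, g1 = g1, g2 = g2,
                 causal_dosage = dos,
                 phenotype = ifelse(mutant_like, "fuzzless", "fuzzy")),
            class = "bsa_population")
}

#' @export
print.bsa_population <- function(x, ...) {
  cat(sprintf("%s population of %d individuals (%s causal locus at %s bp)\n",
              x$config$cross_type, x$config$n_individuals,
              x$config$dominance,
              format(x$config$causal_pos, big.mark = ",")))
  print(table(x$phenotype))
  invisible(x)
}

#' Mutant-allele dosage at focal-chromosome positions
#'
#' @param pop a `bsa_population`.
#' @param positions bp positions on the focal chromosome.
#' @param individuals indices (default: all).
#' @return integer matrix, individuals x positions, entries 0/1/2.
#' @export
dosage_at <- function(pop, positions, individuals = NULL) {
  stopifnot(inherits(pop, "bsa_population"))
  if (is.null(individuals)) individuals <- seq_len(pop$config$n_individuals)
  sub <- function(g) list(start = g$start[individuals],
                          breaks = g$breaks[individuals])
  gamete_alleles(sub(pop$g1), positions) + gamete_alleles(sub(pop$g2), positions)
}

#' Select phenotype-extreme pools
#'
#' Samples `pool_size` individuals without replacement from each phenotype
#' class. For a binary trait "extremely fuzzy / extremely fuzzless" reduces
#' to random sampling within class; the two pools are disjoint by
#' construction.
#'
#' @param pop a `bsa_population`.
#' @param pool_size individuals per pool; `0` gives empty pools.
#' @param seed integer seed.
#' @return list with integer index vectors `fuzzy` and `fuzzless`.
#' @export
make_pools <- function(pop, pool_size = pop$config$pool_size,
                       seed = pop$config$seed + 1L) {
  stopifnot(inherits(pop, "bsa_population"), pool_size >= 0)
  set.seed(seed)
  idx_fuzzy <- which(pop$phenotype == "fuzzy")
  idx_fless <- which(pop$phenotype == "fuzzless")
  if (length(idx_fuzzy) < pool_size || length(idx_fless) < pool_size)
    stop("a phenotype class has fewer than pool_size members (",
         length(idx_fless), " fuzzless, ", length(idx_fuzzy), " fuzzy)")
  list(fuzzy = sort(sample(idx_fuzzy, pool_size)),
       fuzzless = sort(sample(idx_fless, pool_size)))
}

chrom_names <- function(config) {
  c("chr01", if (config$n_bg_chrom > 0)
    sprintf("chrBG%02d", seq_len(config$n_bg_chrom)))
}

site_grid <- function(config, focal = TRUE) {
  pos <- round(seq(config$chrom_length / config$n_sites, config$chrom_length,
                   length.out = config$n_sites))
  pos <- sort(unique(pos))
  if (focal) {
    # causal_pos must itself be a site: replace the nearest grid point
    nearest <- which.min(abs(pos - config$causal_pos))
    pos[nearest] <- config$causal_pos
    pos <- sort(unique(pos))
  }
  pos
}

random_alleles <- function(n, var_class) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- character(n)
  snp <- var_class == "SNP"
  if (any(snp)) {
    shift <- sample(1:3, sum(snp), replace = TRUE)
    alt[snp] <- bases[(match(ref[snp], bases) - 1L + shift) %% 4L + 1L]
  }
  if (any(!snp)) {
    ins <- sample(c(TRUE, FALSE), sum(!snp), replace = TRUE)
    extra <- vapply(sample(1:3, sum(!snp), replace = TRUE), function(k)
      paste(sample(bases, k, replace = TRUE), collapse = ""), "")
    alt[!snp] <- ifelse(ins, paste0(ref[!snp], extra), ref[!snp])
    ref[!snp] <- ifelse(ins, ref[!snp], paste0(alt[!snp], extra))
  }
  list(ref = ref, alt = alt)
}

pool_depths_for_freq <- function(f, mean_depth, seq_error) {
  n <- length(f)
  depth <- stats::rpois(n, mean_depth)
  f_obs <- f * (1 - seq_error) + (1 - f) * seq_error
  alt <- stats::rbinom(n, depth, f_obs)
  list(ref = depth - alt, alt = alt)
}

#' Simulate pooled sequencing depths at informative sites
#'
#' Emits one biallelic site per grid position on every chromosome, with
#' per-pool read depths for the two parents and the two phenotype pools.
#' Total depth per site and pool is Poisson(`mean_depth`); alt-allele reads
#' are Binomial(depth, f') where f is the pooled mutant-allele frequency
#' (mean dosage / 2) and f' = f(1-e) + (1-f)e absorbs the sequencing error
#' e. Parents are fixed opposite homozygotes at every emitted site (only
#' informative sites are emitted), so the alt allele is by construction the
#' mutant-parent allele. The causal position is always included as a site.
#'
#' @param pop a `bsa_population`.
#' @param pools pool index list from [make_pools()].
#' @param config the [sim_config()] used to build `pop`.
#' @param seed integer seed.
#' @return data.frame of sites: `chrom`, `pos`, `ref`, `alt`, `var_class`,
#'   and `<pool>_ref`/`<pool>_alt` depth columns for pools `parent_wt`,
#'   `parent_mut`, `fuzzy`, `fuzzless`; sorted by chromosome then position.
#' @export
simulate_pool_depths <- function(pop, pools, config = pop$config,
                                 seed = config$seed + 2L) {
  stopifnot(inherits(pop, "bsa_population"))
  set.seed(seed)
  chroms <- chrom_names(config)
  members <- c(pools$fuzzy, pools$fuzzless)
  n_f <- length(pools$fuzzy)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    focal <- ci == 1L
    pos <- site_grid(config, focal = focal)
    if (focal) {
      if (length(members)) {
        dos <- dosage_at(pop, pos, members)
        f_fuzzy <- colMeans(dos[seq_len(n_f), , drop = FALSE]) / 2
        f_fless <- colMeans(dos[n_f + seq_along(pools$fuzzless), , drop = FALSE]) / 2
      } else f_fuzzy <- f_fless <- rep(0, length(pos))
    } else {
      # unlinked chromosome: segregation independent of phenotype, so it is
      # drawn only for pooled individuals
      lm <- config$chrom_length * config$cm_per_mb / 100 / 1e6
      m <- length(members)
      if (m) {
        a1 <- gamete_alleles(r_gametes(m, config$chrom_length, lm), pos)
        a2 <- if (config$cross_type == "F2")
          gamete_alleles(r_gametes(m, config$chrom_length, lm), pos)
        else matrix(0L, m, length(pos))
        dos <- a1 + a2
        f_fuzzy <- colMeans(dos[seq_len(n_f), , drop = FALSE]) / 2
        f_fless <- colMeans(dos[n_f + seq_along(pools$fuzzless), , drop = FALSE]) / 2
      } else f_fuzzy <- f_fless <- rep(0, length(pos))
    }
    n <- length(pos)
    var_class <- ifelse(stats::runif(n) < config$prop_indel, "InDel", "SNP")
    al <- random_alleles(n, var_class)
    pw <- pool_depths_for_freq(rep(0, n), config$mean_depth, config$seq_error)
    pm <- pool_depths_for_freq(rep(1, n), config$mean_depth, config$seq_error)
    fz <- pool_depths_for_freq(f_fuzzy, config$mean_depth, config$seq_error)
    fl <- pool_depths_for_freq(f_fless, config$mean_depth, config$seq_error)
    out[[ci]] <- data.frame(chrom = chroms[ci], pos = pos,
                            ref = al$ref, alt = al$alt, var_class = var_class,
                            parent_wt_ref = pw$ref, parent_wt_alt = pw$alt,
                            parent_mut_ref = pm$ref, parent_mut_alt = pm$alt,
                            fuzzy_ref = fz$ref, fuzzy_alt = fz$alt,
                            fuzzless_ref = fl$ref, fuzzless_alt = fl$alt,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a two-genotype, multi-stage RNA-seq count experiment
#'
#' Negative-binomial fragment counts for `n_genes` genes across a
#' 2-genotype x stages x replicates design (the reference design was
#' wild/mutant x 1, 3, 5 days post anthesis x 2 replicates). A set of
#' `n_true_deg` genes receives a genotype effect of `lfc` log2 units
#' (random sign) at one designated stage each; all other gene/stage
#' combinations are null. Each true DEG's stage is drawn with probabilities
#' `deg_stage_weights`, whose default mirrors the 370:13:22 split of
#' stage-specific differential genes in the reference experiment. Gene
#' lengths are attached for FPKM computation and the truth labels are
#' returned for recovery testing.
#'
#' @param n_genes,n_true_deg number of genes and of true DEGs
#'   (`n_true_deg <= n_genes`).
#' @param lfc genotype effect for true DEGs, log2 units (`0` for a null
#'   simulation).
#' @param stages integer stages (days post anthesis).
#' @param reps biological replicates per genotype and stage.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param deg_stage_weights unnormalised probabilities over `stages` for
#'   assigning each true DEG its differential stage.
#' @param mean_log_expr,sd_log_expr log-scale mean and SD of baseline
#'   per-gene expected counts.
#' @param seed integer seed.
#' @return list with `counts` (genes x libraries, columns
#'   `<genotype>_<stage>DPA_rep<k>`), `lengths` (bp), `design` data.frame
#'   (library, genotype, stage, replicate) and `truth` data.frame
#'   (gene_id, deg flag, stage, true_lfc).
#' @export
simulate_expression <- function(n_genes = 2000, n_true_deg = 50, lfc = 2,
                                stages = c(1, 3, 5), reps = 2,
                                dispersion = 0.05,
                                deg_stage_weights = c(370, 13, 22),
                                mean_log_expr = log(100), sd_log_expr = 1,
                                seed = 1L) {
  stopifnot(n_true_deg <= n_genes, reps >= 1, dispersion >= 0,
            length(deg_stage_weights) == length(stages))
  set.seed(seed)
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  lengths <- sample(500:5000, n_genes, replace = TRUE)
  base_mu <- stats::rlnorm(n_genes, mean_log_expr, sd_log_expr)
  deg_idx <- if (n_true_deg > 0) sort(sample(n_genes, n_true_deg)) else integer(0)
  deg_stage <- rep(NA_integer_, n_genes)
  true_lfc <- rep(0, n_genes)
  if (n_true_deg > 0) {
    deg_stage[deg_idx] <- sample(stages, n_true_deg, replace = TRUE,
                                 prob = deg_stage_weights / sum(deg_stage_weights))
    true_lfc[deg_idx] <- lfc * sample(c(-1, 1), n_true_deg, replace = TRUE)
  }
  design <- expand.grid(replicate = seq_len(reps), stage = stages,
                        genotype = c("wild", "mutant"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$library <- sprintf("%s_%dDPA_rep%d", design$genotype, design$stage,
                            design$replicate)
  design <- design[, c("library", "genotype", "stage", "replicate")]
  counts <- matrix(0L, n_genes, nrow(design),
                   dimnames = list(gene_id, design$library))
  for (j in seq_len(nrow(design))) {
    mu <- base_mu
    hit <- design$genotype[j] == "mutant" & !is.na(deg_stage) &
      deg_stage == design$stage[j]
    mu[hit] <- mu[hit] * 2^true_lfc[hit]
    counts[, j] <- if (dispersion > 0)
      stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    else stats::rpois(n_genes, mu)
  }
  truth <- data.frame(gene_id = gene_id, deg = !is.na(deg_stage),
                      stage = deg_stage, true_lfc = true_lfc,
                      stringsAsFactors = FALSE)
  list(counts = counts, lengths = stats::setNames(lengths, gene_id),
       design = design, truth = truth)
}
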