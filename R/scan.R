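#' Filter sites to those informative between the pools
#'
#' Keeps sites whose parents behave as consistent opposite homozygotes
#' (alt-allele read fraction >= 0.9 in the mutant parent and <= 0.1 in the
#' wild parent, each at depth >= `min_parent_depth`) and whose two
#' phenotype pools both reach a total depth of `min_depth` reads. Sites
#' failing the filter are dropped, not imputed.
#'
#' @param sites site data.frame as produced by [simulate_pool_depths()] or
#'   [read_pool_vcf()] (sorted by chromosome and position).
#' @param min_depth minimum total depth per phenotype pool.
#' @param min_parent_depth minimum total depth per parent.
#' @return the filtered site data.frame.
#' @export
filter_informative_sites <- function(sites, min_depth = 10,
                                     min_parent_depth = 10) {
  wt_d <- sites$parent_wt_ref + sites$parent_wt_alt
  mu_d <- sites$parent_mut_ref + sites$parent_mut_alt
  fz_d <- sites$fuzzy_ref + sites$fuzzy_alt
  fl_d <- sites$fuzzless_ref + sites$fuzzless_alt
  keep <- wt_d >= min_parent_depth & mu_d >= min_parent_depth &
    fz_d >= min_depth & fl_d >= min_depth &
    sites$parent_mut_alt / mu_d >= 0.9 &
    sites$parent_wt_alt / wt_d <= 0.1
  keep[is.na(keep)] <- FALSE
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-pool SNP-index
#'
#' Fraction of reads carrying the alternative (mutant-parent) allele:
#' `alt / (ref + alt)`.
#'
#' @param sites site data.frame.
#' @param pool one of `"parent_wt"`, `"parent_mut"`, `"fuzzy"`,
#'   `"fuzzless"`.
#' @return numeric vector in `[0, 1]`; `NA` where the pool has zero depth.
#' @examples
#' s <- data.frame(fuzzy_ref = 20, fuzzy_alt = 40)
#' snp_index(s, "fuzzy")  # 2/3
#' @export
snp_index <- function(sites, pool) {
  ref <- sites[[paste0(pool, "_ref")]]
  alt <- sites[[paste0(pool, "_alt")]]
  if (is.null(ref) || is.null(alt)) stop("unknown pool: ", pool)
  d <- ref + alt
  ifelse(d > 0, alt / d, NA_real_)
}

#' Delta SNP-index between phenotype pools
#'
#' `snp_index(fuzzless) - snp_index(fuzzy)`. With the alt allele anchored
#' to the mutant parent, the causal peak is positive: phenotype selection
#' drives the fuzzless pool's mutant-allele frequency towards 2/3 (dominant
#' F2 pools; the selection ceiling for a dominant trait) and the fuzzy
#' pool's to 0.
#'
#' @param sites site data.frame.
#' @return numeric vector in `[-1, 1]`.
#' @export
delta_snp_index <- function(sites) {
  snp_index(sites, "fuzzless") - snp_index(sites, "fuzzy")
}

#' Euclidean distance between pool allele-frequency vectors
#'
#' Per-site distance `sqrt(sum_a (f_fuzzless(a) - f_fuzzy(a))^2)` over the
#' site's alleles, optionally raised to a power. For a biallelic site this
#' is `sqrt(2) * |delta f|`, so it lies in `[0, sqrt(2)]` at power 1.
#' Common practice sometimes raises ED to the 4th or 5th power to sharpen
#' peaks; the default power of 1 matches a threshold scale of ~0.35 on
#' pools of this size.
#'
#' @param sites site data.frame.
#' @param power positive integer exponent applied to the distance.
#' @return numeric vector `>= 0`.
#' @export
euclidean_distance <- function(sites, power = 1) {
  stopifnot(power >= 1)
  f1 <- snp_index(sites, "fuzzless")
  f2 <- snp_index(sites, "fuzzy")
  # both alleles of a biallelic site contribute: (df)^2 + (-df)^2
  (sqrt(2) * abs(f1 - f2))^power
}

#' Build a scan track
#'
#' Assembles positions and raw per-site statistic values into an index
#' track ready for fitting.
#'
#' @param sites filtered site data.frame.
#' @param statistic `"ED"` or `"delta_snp_index"`.
#' @param power ED power (ignored for the delta SNP-index).
#' @return a `bsa_track` data.frame with columns `chrom`, `pos`, `raw` and
#'   (after [fit_track()]) `fitted`; attribute `statistic`.
#' @export
make_track <- function(sites, statistic = c("ED", "delta_snp_index"),
                       power = 1) {
  statistic <- match.arg(statistic)
  raw <- switch(statistic,
                ED = euclidean_distance(sites, power),
                delta_snp_index = delta_snp_index(sites))
  tr <- data.frame(chrom = sites$chrom, pos = sites$pos, raw = raw,
                   stringsAsFactors = FALSE)
  tr <- tr[!is.na(tr$raw), , drop = FALSE]
  tr <- tr[order(tr$chrom, tr$pos), , drop = FALSE]
  if (anyDuplicated(tr[c("chrom", "pos")]))
    stop("duplicate positions within a chromosome")
  rownames(tr) <- NULL
  structure(tr, statistic = statistic, class = c("bsa_track", "data.frame"))
}

#' Fit a track by tricube-weighted local averaging
#'
#' Smooths the raw statistic with a tricube-distance-weighted mean over a
#' window of `window` bp centred on each site (local regression of degree
#' 0), per chromosome. Windows truncate at chromosome ends; each fitted
#' value is a convex combination of raw values inside its window, so it
#' lies within their range.
#'
#' @param track a `bsa_track`.
#' @param window full window width in bp (default 1 Mb).
#' @return the track with a `fitted` column.
#' @export
fit_track <- function(track, window = 1e6) {
  if (nrow(track) == 0) stop("empty track")
  stopifnot(window >= 0)
  fitted <- numeric(nrow(track))
  for (ch in unique(track$chrom)) {
    i <- which(track$chrom == ch)
    fitted[i] <- tricube_window_mean(track$pos[i], track$raw[i], window / 2)
  }
  track$fitted <- fitted
  track
}

#' Genome-wide median + 3 SD threshold
#'
#' The region-calling threshold used by the reference analysis: the median
#' of all fitted values plus three sample standard deviations, computed
#' genome-wide over every fitted point of the track.
#'
#' @param track a fitted `bsa_track`.
#' @return numeric threshold.
#' @export
threshold_median_3sd <- function(track) {
  if (is.null(track$fitted)) stop("track has no fitted values; run fit_track()")
  if (nrow(track) < 2) stop("need at least 2 fitted points")
  stats::median(track$fitted) + 3 * stats::sd(track$fitted)
}

#' Call candidate regions above a threshold
#'
#' Maximal runs of consecutive sites with `fitted >= threshold`, per
#' chromosome. Runs whose bounding sites are separated by less than
#' `merge_gap` bp are merged (bridging isolated low-coverage sites without
#' joining distinct peaks). Each interval spans the first to the last site
#' position of its run.
#'
#' @param track a fitted `bsa_track`.
#' @param threshold calling threshold (e.g. [threshold_median_3sd()]).
#' @param merge_gap bp; runs closer than this are merged (default 100 kb).
#' @return interval data.frame (possibly empty).
#' @export
call_regions <- function(track, threshold, merge_gap = 1e5) {
  if (is.null(track$fitted)) stop("track has no fitted values; run fit_track()")
  out <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    above <- sub$fitted >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = sub$pos[starts[r$values]],
                       end = sub$pos[ends[r$values]])
    # merge runs separated by < merge_gap
    keep_s <- runs$start[1]; keep_e <- runs$end[1]
    merged <- list()
    if (nrow(runs) > 1) for (k in 2:nrow(runs)) {
      if (runs$start[k] - keep_e < merge_gap) {
        keep_e <- runs$end[k]
      } else {
        merged[[length(merged) + 1L]] <- c(keep_s, keep_e)
        keep_s <- runs$start[k]; keep_e <- runs$end[k]
      }
    }
    merged[[length(merged) + 1L]] <- c(keep_s, keep_e)
    m <- do.call(rbind, merged)
    out[[length(out) + 1L]] <- genomic_interval(ch, m[, 1], m[, 2])
  }
  if (!length(out))
    return(genomic_interval(character(0), numeric(0), numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

merge_intervals <- function(x, gap = 0) {
  if (nrow(x) < 2) return(x)
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  out <- x[1, , drop = FALSE]
  for (i in 2:nrow(x)) {
    j <- nrow(out)
    if (x$chrom[i] == out$chrom[j] && x$start[i] <= out$end[j] + gap) {
      out$end[j] <- max(out$end[j], x$end[i])
    } else out <- rbind(out, x[i, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Run a full BSA-Seq scan
#'
#' The complete scan pipeline on a set of sites: depth/parent filtering,
#' then for each statistic (ED and delta SNP-index) and each variant class
#' (SNPs and InDels are scanned as separate tracks, mirroring the practice
#' of plotting them separately) a fitted track, a genome-wide
#' median + 3*SD threshold and its called regions. Per statistic the
#' class-wise regions are merged (union); the final candidate region is the
#' intersection of the ED and delta SNP-index regions.
#'
#' @param sites site data.frame.
#' @param window smoothing window, bp.
#' @param ed_power ED exponent.
#' @param merge_gap run-merging gap, bp.
#' @param min_depth,min_parent_depth depth filters
#'   (see [filter_informative_sites()]).
#' @param by_class scan SNPs and InDels as separate tracks (default) or
#'   jointly.
#' @return a `bsa_scan` list: `tracks` (per statistic/class, each with its
#'   `threshold` attribute), `thresholds`, `regions` (per statistic) and
#'   `candidate` (intersected interval set).
#' @export
run_scan <- function(sites, window = 1e6, ed_power = 1, merge_gap = 1e5,
                     min_depth = 10, min_parent_depth = 10, by_class = TRUE) {
  flt <- filter_informative_sites(sites, min_depth, min_parent_depth)
  if (nrow(flt) == 0) stop("no sites pass the informativeness filters")
  classes <- if (by_class) unique(flt$var_class) else "all"
  tracks <- list(); thresholds <- list(); regions <- list()
  for (stat in c("ED", "delta_snp_index")) {
    stat_regions <- NULL
    for (cl in classes) {
      sub <- if (identical(cl, "all")) flt
             else flt[flt$var_class == cl, , drop = FALSE]
      if (nrow(sub) < 2) next
      tr <- fit_track(make_track(sub, stat, power = ed_power), window)
      thr <- threshold_median_3sd(tr)
      attr(tr, "threshold") <- thr
      key <- paste(stat, cl, sep = ".")
      tracks[[key]] <- tr
      thresholds[[key]] <- thr
      reg <- call_regions(tr, thr, merge_gap)
      stat_regions <- if (is.null(stat_regions)) reg else rbind(stat_regions, reg)
    }
    regions[[stat]] <- merge_intervals(stat_regions, gap = merge_gap)
  }
  structure(list(tracks = tracks,
                 thresholds = unlist(thresholds),
                 regions = regions,
                 candidate = intersect_regions(regions[["ED"]],
                                               regions[["delta_snp_index"]])),
            class = "bsa_scan")
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat("BSA-Seq scan\n")
  for (k in names(x$thresholds))
    cat(sprintf("  threshold[%s] = %.4f\n", k, x$thresholds[k]))
  cat("candidate region(s):\n")
  print(x$candidate)
  invisible(x)
}
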