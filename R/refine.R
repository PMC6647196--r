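#' Interval spanned by two markers
#'
#' @param a,b single-row marker data.frames (columns `name`, `chrom`,
#'   `position`) or rows of a marker table.
#' @return a one-row interval data.frame; its length is the difference of
#'   the marker positions.
#' @examples
#' m <- data.frame(name = c("SSR82", "InDel9"), chrom = "A08",
#'                 position = c(580404, 650514))
#' interval_length(marker_interval(m[1, ], m[2, ]))  # 70110 bp, ~70 kb
#' @export
marker_interval <- function(a, b) {
  if (a$chrom != b$chrom) stop("markers lie on different chromosomes")
  genomic_interval(a$chrom, min(a$position, b$position),
                   max(a$position, b$position))
}

# Infer the causal genotype an individual implies for a causal locus lying
# in slot j (between markers j and j+1), from the nearest non-missing
# flanking marker calls under the <= 1 crossover-per-interval assumption.
# Returns the dosage (0/1/2) or NA when the flanks disagree or are absent
# (no constraint).
implied_causal_genotype <- function(geno_row, slot) {
  left <- geno_row[seq_len(slot)]
  right <- geno_row[-seq_len(slot)]
  l <- if (any(!is.na(left))) left[max(which(!is.na(left)))] else NA
  r <- if (any(!is.na(right))) right[min(which(!is.na(right)))] else NA
  if (is.na(l) || is.na(r)) return(NA_integer_)
  if (l == r) return(as.integer(l))
  NA_integer_  # recombinant across the slot: locus could sit either side
}

phenotype_consistent <- function(dosage, phenotype, dominance = "dominant") {
  mutant_like <- if (dominance == "dominant") dosage >= 1L else dosage == 2L
  (phenotype == "fuzzless") == mutant_like
}

#' Narrow a candidate region with recombinant marker genotypes
#'
#' Standard map-based cloning logic: the causal locus is placed in every
#' inter-marker slot in turn, each individual's genotype at that placement
#' is inferred from its nearest non-missing flanking markers (assuming at
#' most one crossover between adjacent markers; individuals recombinant
#' across a slot impose no constraint there), and a slot is consistent when
#' every inferred genotype explains the individual's phenotype under
#' single-locus dominance. The returned interval is bounded by the tightest
#' flanking-marker pair enclosing all consistent slots, which must be
#' contiguous.
#'
#' @param markers marker data.frame (`name`, `chrom`, `position`), sorted
#'   by position.
#' @param genotypes integer matrix individuals x markers with mutant-allele
#'   dosages 0/1/2 (`NA` = missing), or characters `A` (wild hom), `H`
#'   (het), `B` (mutant hom), `-` (missing).
#' @param phenotypes character vector, `"fuzzy"`/`"fuzzless"`.
#' @param dominance `"dominant"` or `"recessive"`.
#' @return a one-row interval data.frame with attributes `left_marker` and
#'   `right_marker`.
#' @export
narrow_by_recombinants <- function(markers, genotypes, phenotypes,
                                   dominance = "dominant") {
  stopifnot(nrow(markers) >= 2, is.matrix(genotypes),
            ncol(genotypes) == nrow(markers),
            nrow(genotypes) == length(phenotypes))
  if (is.unsorted(markers$position))
    stop("markers must be sorted by position")
  if (is.character(genotypes)) {
    conv <- c(A = 0L, H = 1L, B = 2L, `-` = NA_integer_)
    genotypes <- matrix(conv[genotypes], nrow = nrow(genotypes))
  }
  storage.mode(genotypes) <- "integer"
  if (any(rowSums(!is.na(genotypes)) == 0))
    stop("each individual needs at least one non-missing marker call")
  m <- nrow(markers)
  consistent <- logical(m - 1L)
  for (slot in seq_len(m - 1L)) {
    ok <- TRUE
    for (i in seq_len(nrow(genotypes))) {
      g <- implied_causal_genotype(genotypes[i, ], slot)
      if (!is.na(g) && !phenotype_consistent(g, phenotypes[i], dominance)) {
        ok <- FALSE
        break
      }
    }
    consistent[slot] <- ok
  }
  if (!any(consistent))
    stop("no causal placement is consistent with the phenotypes; ",
         "suspect genotyping/phenotyping error or a multi-locus trait")
  idx <- which(consistent)
  if (any(diff(idx) != 1L))
    stop("consistent placements are not contiguous; suspect genotyping error")
  left <- min(idx); right <- max(idx) + 1L
  out <- marker_interval(markers[left, ], markers[right, ])
  attr(out, "left_marker") <- markers$name[left]
  attr(out, "right_marker") <- markers$name[right]
  out
}

#' Genes fully contained in an interval
#'
#' Full containment (`start >= interval$start` and `end <= interval$end`),
#' the rule under which the reference marker interval holds exactly its
#' seven annotated ORFs; genes straddling a boundary are excluded. Input
#' order is preserved.
#'
#' @param genes gene-model data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   ...).
#' @param interval a one-row interval data.frame.
#' @return the contained subset of `genes`.
#' @export
genes_in_interval <- function(genes, interval) {
  stopifnot(nrow(interval) == 1)
  keep <- genes$chrom == interval$chrom &
    genes$start >= interval$start & genes$end <= interval$end
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank candidate genes by differential expression and variant evidence
#'
#' Tiering: tier 1 = differentially expressed with a coding or promoter
#' variant; tier 2 = differentially expressed only; tier 3 = variant only;
#' tier 4 = neither. Within a tier, genes are ordered by start position.
#'
#' @param genes gene-model data.frame (`gene_id`, `start`, ...).
#' @param deg_flags named logical, differential status per gene_id.
#' @param variant_evidence named list of consequence data.frames per
#'   gene_id (as produced by the variant-consequence functions); a gene
#'   counts as having variant evidence when any entry is a CDS
#'   (non-`none` frame effect) or promoter consequence.
#' @return `genes` with `deg`, `has_variant` and `tier` columns, ordered by
#'   tier then start.
#' @export
rank_candidates <- function(genes, deg_flags, variant_evidence = list()) {
  unknown <- setdiff(c(names(deg_flags), names(variant_evidence)),
                     genes$gene_id)
  if (length(unknown))
    stop("evidence for unknown gene ids: ", paste(unknown, collapse = ", "))
  deg <- genes$gene_id %in% names(deg_flags)[as.logical(deg_flags)]
  has_var <- vapply(genes$gene_id, function(g) {
    ev <- variant_evidence[[g]]
    if (is.null(ev) || nrow(ev) == 0) return(FALSE)
    any((ev$location_class == "CDS" & ev$frame_effect != "none") |
          ev$location_class == "promoter")
  }, logical(1))
  tier <- ifelse(deg & has_var, 1L, ifelse(deg, 2L, ifelse(has_var, 3L, 4L)))
  out <- genes
  out$deg <- deg
  out$has_variant <- unname(has_var)
  out$tier <- tier
  out <- out[order(out$tier, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
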