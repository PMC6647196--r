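#' Fragments per kilobase per million mapped fragments
#'
#' `fragments * 1e9 / (library_total * gene_length)`.
#'
#' @param fragments fragment count(s) for the gene.
#' @param gene_length transcript length in bp (> 0).
#' @param library_total total mapped fragments in the library (> 0).
#' @return FPKM value(s).
#' @examples
#' fpkm(100, 1000, 1e7)  # 10
#' @export
fpkm <- function(fragments, gene_length, library_total) {
  if (any(gene_length <= 0)) stop("gene_length must be positive")
  if (any(library_total <= 0)) stop("library_total must be positive")
  fragments * 1e9 / (library_total * gene_length)
}

#' FPKM matrix from a count matrix
#'
#' @param counts genes x libraries count matrix.
#' @param lengths gene lengths (bp), recycled across libraries.
#' @param library_totals per-library totals; defaults to column sums of
#'   `counts`.
#' @return FPKM matrix with the same dimnames.
#' @export
fpkm_matrix <- function(counts, lengths, library_totals = colSums(counts)) {
  stopifnot(length(lengths) == nrow(counts),
            length(library_totals) == ncol(counts))
  sweep(counts * 1e9 / lengths, 2, library_totals, "/")
}

#' Two-group differential test on FPKM replicates
#'
#' Log2 ratio of pseudo-count-stabilised group means,
#' `log2((mean_b + pseudo) / (mean_a + pseudo))`, with a pooled-variance
#' two-sample t-test (Student's t, df = n_a + n_b - 2) on
#' `log2(FPKM + pseudo)`; with two replicates per group a Welch correction
#' would push the degrees of freedom towards 1 and destroy what little
#' power the design has. Genes with zero variance in both groups are
#' handled deterministically: equal means give p = 1 (non-significant by
#' definition), unequal means p = 0 (perfect separation).
#'
#' @param group_a,group_b replicate FPKM vectors (>= 2 replicates each).
#' @param pseudo pseudo-count offset (default 1, for log-ratio stability
#'   with two replicates).
#' @return list with `log2_ratio` and `p`.
#' @export
differential_test <- function(group_a, group_b, pseudo = 1) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2, pseudo >= 0)
  if (pseudo == 0 && all(group_a == 0) && all(group_b == 0))
    stop("all-zero groups with pseudo = 0: log-ratio undefined")
  lr <- log2((mean(group_b) + pseudo) / (mean(group_a) + pseudo))
  la <- log2(group_a + pseudo); lb <- log2(group_b + pseudo)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
    p <- if (mean(la) == mean(lb)) 1 else 0
  } else {
    p <- stats::t.test(la, lb, var.equal = TRUE)$p.value
  }
  list(log2_ratio = lr, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values; monotone in rank and capped at 1.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Stage-wise differential expression of a two-genotype design
#'
#' For each stage, computes per-gene FPKM in the wild and mutant replicate
#' groups, a log2 ratio (mutant over wild) and t-test p-value via
#' [differential_test()], then a BH FDR adjustment across genes within the
#' stage, and flags significance with the reference decision rule
#' FDR < 0.01 and |log2 ratio| >= 1.
#'
#' @param counts genes x libraries count matrix.
#' @param lengths gene lengths, bp.
#' @param design data.frame with `library`, `genotype` (`wild`/`mutant`),
#'   `stage` columns matching `colnames(counts)`.
#' @param pseudo pseudo-count for [differential_test()].
#' @param fdr_cutoff,lfc_cutoff significance thresholds (defaults 0.01 and
#'   1, as in the reference analysis).
#' @return data.frame with `gene_id`, `stage`, `log2_ratio`, `p`, `fdr`,
#'   `significant`.
#' @export
run_differential <- function(counts, lengths, design, pseudo = 1,
                             fdr_cutoff = 0.01, lfc_cutoff = 1) {
  stopifnot(all(design$library %in% colnames(counts)))
  fk <- fpkm_matrix(counts[, design$library, drop = FALSE], lengths)
  out <- list()
  for (st in unique(design$stage)) {
    a <- design$library[design$stage == st & design$genotype == "wild"]
    b <- design$library[design$stage == st & design$genotype == "mutant"]
    res <- vapply(seq_len(nrow(fk)), function(i) {
      d <- differential_test(fk[i, a], fk[i, b], pseudo)
      c(d$log2_ratio, d$p)
    }, numeric(2))
    df <- data.frame(gene_id = rownames(fk), stage = st,
                     log2_ratio = res[1, ], p = res[2, ],
                     stringsAsFactors = FALSE)
    df$fdr <- bh_fdr(df$p)
    out[[as.character(st)]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  filter_degs(res, fdr_cutoff, lfc_cutoff)
}

#' Flag significant differential results
#'
#' A gene/stage result is significant iff `fdr < fdr_cutoff` and
#' `|log2_ratio| >= lfc_cutoff`; the boundary `|log2_ratio| = lfc_cutoff`
#' is included (the published decision rule uses ">=").
#'
#' @param results data.frame with `log2_ratio` and `fdr` columns.
#' @param fdr_cutoff,lfc_cutoff thresholds.
#' @return `results` with a logical `significant` column.
#' @export
filter_degs <- function(results, fdr_cutoff = 0.01, lfc_cutoff = 1) {
  results$significant <- results$fdr < fdr_cutoff &
    abs(results$log2_ratio) >= lfc_cutoff
  results
}

#' Venn partition of per-stage DEG sets
#'
#' Counts every non-empty membership region of up to four sets.
#'
#' @param deg_sets named list of character vectors (<= 4 sets).
#' @return named integer vector over all `2^k - 1` membership regions
#'   (names join member sets with `&`); the counts sum to the size of the
#'   union.
#' @examples
#' venn_partition(list(`1` = c("a", "b"), `3` = "b", `5` = c("b", "c")))
#' @export
venn_partition <- function(deg_sets) {
  k <- length(deg_sets)
  stopifnot(k >= 1, k <= 4)
  if (is.null(names(deg_sets))) names(deg_sets) <- seq_len(k)
  universe <- unique(unlist(deg_sets, use.names = FALSE))
  member <- vapply(deg_sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  out <- integer(nrow(combos))
  labs <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    pattern <- as.logical(combos[i, ])
    labs[i] <- paste(names(deg_sets)[pattern], collapse = "&")
    out[i] <- if (length(universe) == 0) 0L else
      sum(apply(member, 1, function(r) all(r == pattern)))
  }
  stats::setNames(out, labs)
}

#' Relative expression by the 2^-ddCt method
#'
#' Target cycle thresholds are normalised to a reference gene within each
#' sample, then to a calibrator sample:
#' `2^-((target_s - ref_s) - (target_c - ref_c))`.
#'
#' @param target_ct,reference_ct sample cycle thresholds (finite, > 0).
#' @param calibrator_target_ct,calibrator_reference_ct calibrator cycle
#'   thresholds.
#' @return fold change relative to the calibrator.
#' @examples
#' relative_expression(20, 18, 22, 18)  # ddCt = -2 -> 4
#' @export
relative_expression <- function(target_ct, reference_ct,
                                calibrator_target_ct,
                                calibrator_reference_ct) {
  cts <- c(target_ct, reference_ct, calibrator_target_ct,
           calibrator_reference_ct)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("cycle thresholds must be finite and positive")
  ddct <- (target_ct - reference_ct) -
    (calibrator_target_ct - calibrator_reference_ct)
  2^(-ddct)
}
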