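#' Pipeline configuration
#'
#' Bundles per-stage parameters for [run_pipeline()]. Defaults reproduce
#' the reference study conditions end to end on synthetic data.
#'
#' @param sim a [sim_config()].
#' @param stages character subset of
#'   `c("simulate", "scan", "refine", "express", "consequence", "rank")`,
#'   executed in pipeline order. Later stages require the earlier ones.
#' @param window,ed_power,merge_gap,min_depth,min_parent_depth scan
#'   parameters (see [run_scan()]).
#' @param n_markers markers genotyped for recombinant narrowing.
#' @param n_genes,n_true_deg,lfc,reps,dispersion,mean_log_expr
#'   expression-simulation parameters (see [simulate_expression()]). With
#'   only two replicates a per-gene t-test reaches FDR < 0.01 only for
#'   strongly expressed, low-dispersion, large-effect genes, so the
#'   pipeline demonstration parameterises its true DEGs accordingly
#'   (16-fold-plus induction of well-measured regulators, as the reference
#'   candidates showed by qPCR); see the methods vignette for the power
#'   analysis.
#' @param promoter_window promoter extent, bp upstream of the gene start.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("simulate", "scan", "refine",
                                       "express", "consequence", "rank"),
                            window = 1e6, ed_power = 1, merge_gap = 1e5,
                            min_depth = 10, min_parent_depth = 10,
                            n_markers = 17,
                            n_genes = 2000, n_true_deg = 100, lfc = 4,
                            reps = 2, dispersion = 5e-4,
                            mean_log_expr = log(4000),
                            promoter_window = 2000) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(sim = sim, stages = stages, window = window,
                 ed_power = ed_power, merge_gap = merge_gap,
                 min_depth = min_depth, min_parent_depth = min_parent_depth,
                 n_markers = n_markers, n_genes = n_genes,
                 n_true_deg = n_true_deg, lfc = lfc, reps = reps,
                 dispersion = dispersion, mean_log_expr = mean_log_expr,
                 promoter_window = promoter_window),
            class = "pipeline_config")
}

# Evenly spaced markers across an interval of the focal chromosome.
synth_marker_set <- function(config, interval, n_markers) {
  pos <- round(seq(interval$start, interval$end, length.out = n_markers))
  pos <- sort(unique(pos))
  data.frame(name = sprintf("M%02d", seq_along(pos)),
             chrom = interval$chrom, position = pos,
             marker_type = rep(c("SSR", "InDel"), length.out = length(pos)),
             stringsAsFactors = FALSE)
}

# Seven synthetic gene models tiled over the refined interval; the gene
# whose body overlaps (or lies nearest) the causal position carries the
# causal variants: a TTG coding insertion and two promoter substitutions.
synth_candidate_genes <- function(config, interval, seed) {
  set.seed(seed)
  n <- 7L
  span <- interval$end - interval$start
  width <- max(300, round(span / (3 * n)))
  gap <- max(1, round((span - n * width) / (n + 1)))
  start <- interval$start + gap + (seq_len(n) - 1L) * (width + gap)
  genes <- data.frame(gene_id = sprintf("ORF%d", seq_len(n)),
                      chrom = interval$chrom, start = start,
                      end = start + width - 1L,
                      strand = rep(c("+", "-"), length.out = n),
                      stringsAsFactors = FALSE)
  causal_gene <- which.min(pmin(abs(genes$start - config$causal_pos),
                                abs(genes$end - config$causal_pos)))
  inside <- genes$start <= config$causal_pos & genes$end >= config$causal_pos
  if (any(inside)) causal_gene <- which(inside)[1]
  # random stop-free CDS plus terminal stop codon
  codons <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T")), 1, paste,
                          collapse = ""), c("TAA", "TAG", "TGA"))
  cds <- vapply(seq_len(n), function(i)
    paste0("ATG", paste(sample(codons, 60, replace = TRUE), collapse = ""),
           "TAA"), "")
  names(cds) <- genes$gene_id
  cg <- genes[causal_gene, ]
  prom_off <- c(500, 1200)
  prom_pos <- if (cg$strand == "+") cg$start - prom_off else cg$end + prom_off
  variants <- data.frame(chrom = cg$chrom, pos = prom_pos,
                         ref = c("G", "C"), alt = c("A", "A"),
                         stringsAsFactors = FALSE)
  list(genes = genes, cds = cds, causal_gene = genes$gene_id[causal_gene],
       coding_insertion = list(gene_id = genes$gene_id[causal_gene],
                               insert_pos = 3 * 10 + 1, inserted = "TTG"),
       promoter_snvs = variants)
}

#' Run the fine-mapping pipeline on synthetic data
#'
#' Executes the enabled stages in workflow order — pooled-sequencing
#' simulation, BSA-Seq scan, recombinant-marker narrowing, differential
#' expression, variant consequence and candidate ranking — writing each
#' stage's outputs under `out_dir` and a JSON run manifest (parameters,
#' seeds, output digests). Reruns with the same configuration reproduce
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly; also written to
#'   `out_dir/report/manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  need <- function(s, prereq) {
    if (s %in% stages && !all(prereq %in% stages))
      stop("stage '", s, "' requires stage(s): ",
           paste(setdiff(prereq, stages), collapse = ", "))
  }
  need("scan", "simulate"); need("refine", c("simulate", "scan"))
  need("express", "simulate"); need("consequence", c("simulate", "scan", "refine"))
  need("rank", c("simulate", "scan", "refine", "express", "consequence"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  summaries <- list()
  stage_dir <- function(s) {
    d <- file.path(out_dir, s)
    dir.create(d, showWarnings = FALSE)
    d
  }
  fail <- function(s, e) stop("pipeline stage '", s, "' failed: ",
                              conditionMessage(e), call. = FALSE)

  sim <- config$sim
  pop <- pools <- sites <- scan <- refined <- genes <- NULL
  deg_flags <- evidence <- NULL

  if ("simulate" %in% stages) tryCatch({
    d <- stage_dir("simulate")
    pop <- simulate_population(sim)
    pools <- make_pools(pop)
    sites <- simulate_pool_depths(pop, pools)
    p <- file.path(d, "pools.vcf")
    write_pool_vcf(sites, p, stats::setNames(rep(sim$chrom_length,
                                                 sim$n_bg_chrom + 1),
                                             chrom_names(sim)))
    paths <- c(paths, p)
    summaries$simulate <- list(n_individuals = sim$n_individuals,
                               phenotype = as.list(table(pop$phenotype)),
                               n_sites = nrow(sites))
  }, error = function(e) fail("simulate", e))

  if ("scan" %in% stages) tryCatch({
    d <- stage_dir("scan")
    scan <- run_scan(sites, window = config$window,
                     ed_power = config$ed_power,
                     merge_gap = config$merge_gap,
                     min_depth = config$min_depth,
                     min_parent_depth = config$min_parent_depth)
    for (k in names(scan$tracks)) {
      p <- file.path(d, paste0("track_", k, ".tsv"))
      utils::write.table(as.data.frame(scan$tracks[[k]]), p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
    p <- file.path(d, "candidate_regions.bed")
    write_bed(scan$candidate, p)
    paths <- c(paths, p)
    summaries$scan <- list(thresholds = as.list(scan$thresholds),
                           candidate = scan$candidate)
  }, error = function(e) fail("scan", e))

  if ("refine" %in% stages) tryCatch({
    d <- stage_dir("refine")
    focal <- scan$candidate[scan$candidate$chrom == chrom_names(sim)[1], ,
                            drop = FALSE]
    if (nrow(focal) == 0) stop("no candidate region on the focal chromosome")
    # follow the scan peak: take the candidate interval holding the highest
    # fitted value across tracks
    peak_score <- vapply(seq_len(nrow(focal)), function(i) {
      max(vapply(scan$tracks, function(tr) {
        inside <- tr$chrom == focal$chrom[i] & tr$pos >= focal$start[i] &
          tr$pos <= focal$end[i]
        if (any(inside)) max(tr$fitted[inside]) else -Inf
      }, numeric(1)))
    }, numeric(1))
    region <- focal[which.max(peak_score), ]
    markers <- synth_marker_set(sim, region, config$n_markers)
    geno <- dosage_at(pop, markers$position)
    refined <- narrow_by_recombinants(markers, geno, pop$phenotype,
                                      sim$dominance)
    p <- file.path(d, "refined_interval.bed")
    write_bed(refined, p)
    pm <- file.path(d, "markers.tsv")
    utils::write.table(markers, pm, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p, pm)
    summaries$refine <- list(interval = refined,
                             left_marker = attr(refined, "left_marker"),
                             right_marker = attr(refined, "right_marker"),
                             length_bp = interval_length(refined))
  }, error = function(e) fail("refine", e))

  cand <- NULL
  if ("consequence" %in% stages || "rank" %in% stages) tryCatch({
    cand <- synth_candidate_genes(sim, refined, seed = sim$seed + 3L)
    genes <- cand$genes
  }, error = function(e) fail("consequence", e))

  expr <- degs <- NULL
  if ("express" %in% stages) tryCatch({
    d <- stage_dir("express")
    expr <- simulate_expression(n_genes = config$n_genes,
                                n_true_deg = config$n_true_deg,
                                lfc = config$lfc, reps = config$reps,
                                dispersion = config$dispersion,
                                mean_log_expr = config$mean_log_expr,
                                seed = sim$seed + 4L)
    if (!is.null(genes)) {
      # embed the interval genes in the expression universe: the causal
      # gene and its neighbour are true stage-1 DEGs (the promoter/coding
      # lesions act early), the other five are null genes
      # the causal gene and its neighbour were up-regulated in the mutant;
      # embed them on up-regulated stage-1 true DEGs
      stage1 <- which(expr$truth$deg & expr$truth$stage == 1 &
                        expr$truth$true_lfc > 0)
      if (length(stage1) < 2)
        stage1 <- c(stage1, setdiff(which(expr$truth$deg), stage1))
      nulls <- which(!expr$truth$deg)
      ci <- match(cand$causal_gene, genes$gene_id)
      neighbour <- if (ci < nrow(genes)) ci + 1L else ci - 1L
      ids <- rownames(expr$counts)
      ids[stage1[1]] <- genes$gene_id[ci]
      ids[stage1[2]] <- genes$gene_id[neighbour]
      other <- setdiff(seq_len(nrow(genes)), c(ci, neighbour))
      ids[nulls[seq_along(other)]] <- genes$gene_id[other]
      rownames(expr$counts) <- ids
      names(expr$lengths) <- ids
      expr$truth$gene_id <- ids
    }
    p <- file.path(d, "expression.tsv")
    write_expression_tsv(expr, p)
    degs <- run_differential(expr$counts, expr$lengths, expr$design)
    pd <- file.path(d, "differential.tsv")
    utils::write.table(degs, pd, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p, pd)
    sig <- degs[degs$significant, ]
    deg_flags <- stats::setNames(rep(TRUE, length(unique(sig$gene_id))),
                                 unique(sig$gene_id))
    venn <- if (nrow(sig)) as.list(venn_partition(split(sig$gene_id, sig$stage)))
            else list()
    summaries$express <- list(n_significant = nrow(sig), venn = venn)
  }, error = function(e) fail("express", e))

  if ("consequence" %in% stages) tryCatch({
    d <- stage_dir("consequence")
    ins <- cand$coding_insertion
    cc <- classify_coding_insertion(cand$cds[[ins$gene_id]],
                                    ins$insert_pos, ins$inserted)
    coding <- data.frame(gene_id = ins$gene_id,
                         location_class = cc$location_class,
                         frame_effect = cc$frame_effect,
                         protein_change = cc$protein_change,
                         dna_change = cc$dna_change, pos = NA_real_,
                         stringsAsFactors = FALSE)
    ci <- match(ins$gene_id, genes$gene_id)
    prom <- promoter_variants(cand$promoter_snvs, genes[ci, ],
                              config$promoter_window)
    evidence <- split(rbind(coding, prom),
                      rbind(coding, prom)$gene_id)
    p <- file.path(d, "consequences.tsv")
    utils::write.table(rbind(coding, prom), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
    summaries$consequence <- list(causal_gene = cand$causal_gene,
                                  frame_effect = cc$frame_effect,
                                  protein_change = cc$protein_change,
                                  n_promoter = nrow(prom))
  }, error = function(e) fail("consequence", e))

  if ("rank" %in% stages) tryCatch({
    d <- stage_dir("report")
    contained <- genes_in_interval(genes, refined)
    flags <- deg_flags[names(deg_flags) %in% contained$gene_id]
    ranked <- rank_candidates(contained, flags, evidence)
    p <- file.path(d, "candidates.tsv")
    utils::write.table(ranked, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    summaries$rank <- list(tier1 = ranked$gene_id[ranked$tier == 1L],
                           n_candidates = nrow(ranked))
  }, error = function(e) fail("rank", e))

  manifest <- list(package = "bsamapr",
                   version = as.character(utils::packageVersion("bsamapr")),
                   seed = sim$seed,
                   stages = stages,
                   parameters = unclass(config)[setdiff(names(config), "sim")],
                   sim = unclass(sim),
                   outputs = {
                     dg <- tools::md5sum(paths)
                     names(dg) <- substring(paths, nchar(out_dir) + 2)
                     as.list(dg)
                   },
                   summaries = summaries)
  d <- stage_dir("report")
  jsonlite::write_json(manifest, file.path(d, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
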