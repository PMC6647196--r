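POOL_NAMES <- c("parent_wt", "parent_mut", "fuzzy", "fuzzless")

#' Write pooled allele depths as VCF 4.2
#'
#' One sample column per pool with per-sample `AD` (ref,alt) fields and a
#' `contig` header line per chromosome.
#'
#' @param sites site data.frame (see [simulate_pool_depths()]).
#' @param path output file.
#' @param contig_lengths named vector of chromosome lengths; defaults to
#'   the maximum site position per chromosome.
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(sites, path, contig_lengths = NULL) {
  chroms <- unique(sites$chrom)
  if (is.null(contig_lengths))
    contig_lengths <- vapply(chroms, function(ch)
      max(sites$pos[sites$chrom == ch]), numeric(1))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bsamapr",
           sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                   as.integer(contig_lengths)),
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths (ref,alt)\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", POOL_NAMES), collapse = "\t"))
  ad <- vapply(POOL_NAMES, function(p)
    paste0(sites[[paste0(p, "_ref")]], ",", sites[[paste0(p, "_alt")]]),
    character(nrow(sites)))
  body <- paste(sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE),
                ".", sites$ref, sites$alt, ".", "PASS",
                paste0("VC=", sites$var_class), "AD",
                ad[, 1], ad[, 2], ad[, 3], ad[, 4], sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read pooled allele depths from a VCF
#'
#' Parses a VCF 4.2 with per-sample `AD` fields into the site data.frame
#' used by the scan functions. Multi-allelic records are not supported.
#'
#' @param path VCF file.
#' @param sample_map named character vector mapping the pool roles
#'   `parent_wt`, `parent_mut`, `fuzzy`, `fuzzless` to VCF sample names;
#'   defaults to identically named samples.
#' @return site data.frame (`chrom`, `pos`, `ref`, `alt`, `var_class`,
#'   depth columns).
#' @export
read_pool_vcf <- function(path, sample_map = stats::setNames(POOL_NAMES,
                                                             POOL_NAMES)) {
  stopifnot(all(POOL_NAMES %in% names(sample_map)))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multi-allelic records are not supported")
  ad <- vcfR::extract.gt(v, element = "AD")
  info <- fix[, "INFO"]
  var_class <- ifelse(grepl("VC=InDel", info), "InDel",
                      ifelse(grepl("VC=SNP", info), "SNP",
                             ifelse(nchar(fix[, "REF"]) == nchar(fix[, "ALT"]),
                                    "SNP", "InDel")))
  out <- data.frame(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    var_class = var_class, stringsAsFactors = FALSE)
  for (p in POOL_NAMES) {
    col <- ad[, sample_map[[p]]]
    parts <- do.call(rbind, strsplit(col, ",", fixed = TRUE))
    out[[paste0(p, "_ref")]] <- as.integer(parts[, 1])
    out[[paste0(p, "_alt")]] <- as.integer(parts[, 2])
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an expression count matrix as TSV
#'
#' Columns: `gene_id`, `length_bp`, then one column per library named
#' `<genotype>_<stage>DPA_rep<k>`.
#'
#' @param sim list with `counts` and `lengths` (see
#'   [simulate_expression()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(sim, path) {
  df <- data.frame(gene_id = rownames(sim$counts),
                   length_bp = unname(sim$lengths[rownames(sim$counts)]),
                   sim$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' @param path TSV written by [write_expression_tsv()].
#' @return list with `counts`, `lengths` and a `design` data.frame parsed
#'   from the library column names.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  libs <- setdiff(names(df), c("gene_id", "length_bp"))
  counts <- as.matrix(df[, libs, drop = FALSE])
  rownames(counts) <- df$gene_id
  m <- regmatches(libs, regexec("^([a-z]+)_([0-9]+)DPA_rep([0-9]+)$", libs))
  if (any(vapply(m, length, 1L) != 4))
    stop("library columns must be named <genotype>_<stage>DPA_rep<k>")
  design <- data.frame(library = libs,
                       genotype = vapply(m, `[`, "", 2),
                       stage = as.integer(vapply(m, `[`, "", 3)),
                       replicate = as.integer(vapply(m, `[`, "", 4)),
                       stringsAsFactors = FALSE)
  list(counts = counts, lengths = stats::setNames(df$length_bp, df$gene_id),
       design = design)
}

#' Read a marker table
#'
#' TSV with columns `name`, `chrom`, `position` and optionally
#' `marker_type`, `forward_primer`, `reverse_primer`, `product_length`.
#'
#' @param path TSV file.
#' @return marker data.frame sorted by position.
#' @export
read_marker_table <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "chrom", "position") %in% names(m)))
  m <- m[order(m$chrom, m$position), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Read gene models from GFF3 or TSV
#'
#' GFF3 files are parsed with `rtracklayer` (features of type `gene`, with
#' `ID` as the gene id); TSV files need columns `gene_id`, `chrom`,
#' `start`, `end`, `strand` and optionally `cds_length`, `annotation`.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or TSV file.
#' @return gene-model data.frame sorted by start.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    g <- data.frame(gene_id = gr$ID,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
    if (!is.null(gr$annotation)) g$annotation <- gr$annotation
  } else {
    g <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(g)))
  }
  g <- g[order(g$chrom, g$start), , drop = FALSE]
  rownames(g) <- NULL
  g
}
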