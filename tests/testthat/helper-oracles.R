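# Independent oracles used to freeze expected values. These deliberately do
# not share code with the package implementation.

# Expected mutant-allele frequency in a phenotype-selected F2 pool, by
# enumeration of the 1:2:1 genotype classes restricted to the phenotype.
f2_pool_freq_oracle <- function(phenotype, dominance = "dominant") {
  dosage <- c(0, 1, 2)
  weight <- c(1, 2, 1)
  mutant_like <- if (dominance == "dominant") dosage >= 1 else dosage == 2
  keep <- if (phenotype == "fuzzless") mutant_like else !mutant_like
  sum(weight[keep] * dosage[keep] / 2) / sum(weight[keep])
}

# Brute-force enumeration of maximal above-threshold runs with gap merging.
call_regions_oracle <- function(pos, fitted, threshold, merge_gap) {
  above <- which(fitted >= threshold)
  if (!length(above)) return(NULL)
  runs <- split(above, cumsum(c(1, diff(above) != 1)))
  iv <- t(vapply(runs, function(r) c(pos[min(r)], pos[max(r)]), numeric(2)))
  merged <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv[k, 1] - merged[nrow(merged), 2] < merge_gap) {
      merged[nrow(merged), 2] <- iv[k, 2]
    } else merged <- rbind(merged, iv[k, ])
  }
  unname(merged)
}

# Step-up Benjamini-Hochberg, written out longhand.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# Minimal standard-code translator independent of Biostrings.
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

translate_oracle <- function(dna) {
  codons <- substring(dna, seq(1, nchar(dna) - 2, 3), seq(3, nchar(dna), 3))
  paste(CODON_TABLE[codons], collapse = "")
}

# Random stop-free CDS of n_codons codons plus a terminal stop.
random_cds <- function(n_codons) {
  codons <- names(CODON_TABLE)[CODON_TABLE != "*"]
  paste0(paste(sample(codons, n_codons, replace = TRUE), collapse = ""), "TAA")
}

# Exhaustive causal-placement oracle for recombinant narrowing: a slot is
# consistent when no individual's flanking-marker-implied genotype
# contradicts its phenotype.
narrow_oracle <- function(positions, geno, phen, dominance = "dominant") {
  m <- length(positions)
  ok <- logical(m - 1)
  for (slot in seq_len(m - 1)) {
    good <- TRUE
    for (i in seq_len(nrow(geno))) {
      lft <- geno[i, seq_len(slot)]
      rgt <- geno[i, (slot + 1):m]
      lft <- lft[!is.na(lft)]; rgt <- rgt[!is.na(rgt)]
      if (!length(lft) || !length(rgt)) next
      l <- lft[length(lft)]; r <- rgt[1]
      if (l != r) next
      mut <- if (dominance == "dominant") l >= 1 else l == 2
      if ((phen[i] == "fuzzless") != mut) { good <- FALSE; break }
    }
    ok[slot] <- good
  }
  ok
}

table2_markers <- function() {
  read_marker_table(system.file("extdata", "markers_a08.tsv",
                                package = "bsamapr"))
}

table3_orfs <- function() {
  read_gene_models(system.file("extdata", "orfs_candidate_region.tsv",
                               package = "bsamapr"))
}

small_sim <- function(seed = 1, n = 400, n_sites = 400, n_bg = 2) {
  sim_config(n_individuals = n, n_sites = n_sites, n_bg_chrom = n_bg,
             seed = seed)
}
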