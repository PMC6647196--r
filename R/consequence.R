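#' Classify a coding-sequence insertion
#'
#' An insertion into a CDS is a frameshift unless its length is a multiple
#' of 3. For in-frame insertions at a codon boundary the inserted residues
#' are named via the standard nuclear genetic code (the reference case: a
#' TTG insertion adding a leucine rather than shifting the frame);
#' codon-internal in-frame insertions are reported as a composite codon
#' replacement. The mutated CDS is translated to detect a premature stop
#' (nonsense) introduced by an otherwise in-frame insertion.
#'
#' @param cds_sequence CDS as a character string of A/C/G/T, length
#'   divisible by 3.
#' @param insert_pos 1-based offset in the CDS *before* which the insertion
#'   occurs (`1` to `nchar(cds) + 1`; a codon boundary is
#'   `(insert_pos - 1) %% 3 == 0`).
#' @param inserted inserted sequence (non-empty A/C/G/T).
#' @return list with `location_class` (`"CDS"`), `frame_effect`
#'   (`"in_frame_insertion"` or `"frameshift"`), `protein_change`,
#'   `dna_change`, `nonsense` flag and the mutated `cds`.
#' @examples
#' classify_coding_insertion("ATGAAATAG", 4, "TTG")  # in-frame, inserts Leu
#' @export
classify_coding_insertion <- function(cds_sequence, insert_pos, inserted) {
  check_dna <- function(x, what) {
    if (nchar(x) == 0) stop(what, " must be non-empty")
    if (grepl("[^ACGTacgt]", x)) stop(what, " contains non-ACGT characters")
    toupper(x)
  }
  cds_sequence <- check_dna(cds_sequence, "cds_sequence")
  inserted <- check_dna(inserted, "inserted")
  n <- nchar(cds_sequence)
  if (n %% 3 != 0) stop("CDS length must be divisible by 3")
  if (insert_pos < 1 || insert_pos > n + 1)
    stop("insert_pos out of range")
  mutated <- paste0(substr(cds_sequence, 1, insert_pos - 1), inserted,
                    substr(cds_sequence, insert_pos, n))
  dna_change <- sprintf("c.%d_%dins%s", insert_pos - 1, insert_pos, inserted)
  if (nchar(inserted) %% 3 != 0) {
    return(list(location_class = "CDS", frame_effect = "frameshift",
                protein_change = sprintf("frameshift at codon %d",
                                         (insert_pos - 1) %/% 3 + 1),
                dna_change = dna_change, nonsense = FALSE, cds = mutated))
  }
  at_boundary <- (insert_pos - 1) %% 3 == 0
  aa_mut <- as.character(Biostrings::translate(
    Biostrings::DNAString(mutated), no.init.codon = TRUE))
  # premature stop: a '*' before the final codon of the mutated translation
  body <- substr(aa_mut, 1, nchar(aa_mut) - 1)
  nonsense <- grepl("*", body, fixed = TRUE)
  if (at_boundary) {
    ins_aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(inserted), no.init.codon = TRUE))
    codon <- (insert_pos - 1) %/% 3 + 1
    change <- sprintf("in-frame insertion of %s at residue %d", ins_aa, codon)
  } else {
    codon <- (insert_pos - 1) %/% 3 + 1
    k <- nchar(inserted) / 3
    change <- sprintf("in-frame insertion within codon %d (%d codon(s) replaced by %d)",
                      codon, 1, k + 1)
  }
  if (nonsense) change <- paste0(change, "; introduces premature stop")
  list(location_class = "CDS", frame_effect = "in_frame_insertion",
       protein_change = change, dna_change = dna_change,
       nonsense = nonsense, cds = mutated)
}

#' Variants in a gene's promoter window
#'
#' Classifies variants lying within `upstream_window` bp upstream of the
#' transcription start (positions `[start - window, start - 1]` for a +
#' strand gene; mirrored to `[end + 1, end + window]` on the - strand) as
#' promoter variants. The reference analysis never defines the promoter
#' extent; 2 kb upstream of the annotated gene start is the package
#' default.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param gene one-row gene-model data.frame (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param upstream_window promoter window, bp.
#' @return data.frame of consequences (`gene_id`, `location_class`,
#'   `frame_effect`, `protein_change`, `dna_change`, `pos`); zero rows when
#'   none qualify.
#' @export
promoter_variants <- function(variants, gene, upstream_window = 2000) {
  stopifnot(nrow(gene) == 1, upstream_window >= 0)
  v <- variants[variants$chrom == gene$chrom, , drop = FALSE]
  inwin <- if (gene$strand == "+") {
    v$pos >= gene$start - upstream_window & v$pos <= gene$start - 1
  } else {
    v$pos >= gene$end + 1 & v$pos <= gene$end + upstream_window
  }
  v <- v[inwin, , drop = FALSE]
  if (nrow(v) == 0)
    return(data.frame(gene_id = character(0), location_class = character(0),
                      frame_effect = character(0), protein_change = character(0),
                      dna_change = character(0), pos = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(gene_id = gene$gene_id, location_class = "promoter",
             frame_effect = ifelse(nchar(v$ref) == nchar(v$alt),
                                   "substitution", "none"),
             protein_change = "promoter variant",
             dna_change = sprintf("%s>%s at %d", v$ref, v$alt, as.integer(v$pos)),
             pos = v$pos, stringsAsFactors = FALSE)
}

#' Simple variants between two sequences
#'
#' Globally aligns two sequences (match 1, mismatch -1, gap opening -2,
#' gap extension -1) and converts the alignment to substitution, insertion
#' and deletion records in coordinates of `seq_a`. Identical inputs give an
#' empty record list. [apply_variants()] re-applies the records to
#' reconstruct `seq_b`.
#'
#' @param seq_a,seq_b character strings (non-empty, comparable length).
#' @return data.frame with `pos` (1-based in `seq_a`; for an insertion, the
#'   base after which the insertion occurs, 0 allowed), `type`
#'   (`substitution`/`insertion`/`deletion`), `ref` and `alt`.
#' @examples
#' diff_sequences("ACGT", "ACTTGGT")  # one 3-bp insertion
#' @export
diff_sequences <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) stop("empty sequence")
  if (identical(toupper(seq_a), toupper(seq_b)))
    return(data.frame(pos = integer(0), type = character(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(toupper(seq_a)),
                                       Biostrings::DNAString(toupper(seq_b)),
                                       type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  recs <- list()
  i_a <- 0L
  k <- 1L
  L <- length(pa)
  while (k <= L) {
    if (pa[k] != "-" && sa[k] != "-") {
      i_a <- i_a + 1L
      if (pa[k] != sa[k])
        recs[[length(recs) + 1L]] <- data.frame(pos = i_a,
                                                type = "substitution",
                                                ref = pa[k], alt = sa[k],
                                                stringsAsFactors = FALSE)
      k <- k + 1L
    } else if (pa[k] == "-") {   # insertion relative to seq_a
      j <- k
      while (j <= L && pa[j] == "-") j <- j + 1L
      recs[[length(recs) + 1L]] <- data.frame(pos = i_a, type = "insertion",
                                              ref = "",
                                              alt = paste(sa[k:(j - 1L)], collapse = ""),
                                              stringsAsFactors = FALSE)
      k <- j
    } else {                     # deletion from seq_a
      j <- k
      while (j <= L && sa[j] == "-") j <- j + 1L
      recs[[length(recs) + 1L]] <- data.frame(pos = i_a + 1L, type = "deletion",
                                              ref = paste(pa[k:(j - 1L)], collapse = ""),
                                              alt = "",
                                              stringsAsFactors = FALSE)
      i_a <- i_a + (j - k)
      k <- j
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Re-apply variant records to a sequence
#'
#' Inverse of [diff_sequences()]: applying its records to `seq_a`
#' reconstructs `seq_b` exactly.
#'
#' @param seq_a original sequence.
#' @param records data.frame from [diff_sequences()].
#' @return the edited sequence.
#' @export
apply_variants <- function(seq_a, records) {
  chars <- strsplit(toupper(seq_a), "")[[1]]
  pieces <- as.list(chars)       # pieces[[i]] replaces/extends base i
  lead <- ""                     # insertions before position 1
  if (!is.null(records) && nrow(records)) {
    for (r in seq_len(nrow(records))) {
      p <- records$pos[r]
      switch(records$type[r],
             substitution = { pieces[[p]] <- records$alt[r] },
             insertion = {
               if (p == 0) lead <- paste0(lead, records$alt[r])
               else pieces[[p]] <- paste0(pieces[[p]], records$alt[r])
             },
             deletion = {
               span <- p:(p + nchar(records$ref[r]) - 1L)
               for (q in span) pieces[[q]] <- ""
             })
    }
  }
  paste0(lead, paste(unlist(pieces), collapse = ""))
}
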