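#' Genomic intervals
#'
#' A genomic interval is a plain `data.frame` with columns `chrom`, `start`
#' and `end` (1-based inclusive coordinates, VCF convention). Interval length
#' is reported as `end - start`, the convention under which the endpoints
#' 76,294 and 2,305,623 bp span 2.23 Mb; BED export converts to 0-based
#' half-open coordinates.
#'
#' @param chrom chromosome identifier(s).
#' @param start,end 1-based endpoint(s), `start <= end`.
#' @return `genomic_interval()` returns a `data.frame` with columns
#'   `chrom`, `start`, `end`; one row per interval.
#' @examples
#' r <- genomic_interval("A08", 76294, 2305623)
#' interval_length(r)        # 2229329 bp
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(length(start) == length(end), length(chrom) %in% c(1L, length(start)))
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start) | is.na(end)) || any(start > end))
    stop("interval endpoints must satisfy start <= end")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' @rdname genomic_interval
#' @param interval interval data.frame as returned by [genomic_interval()].
#' @export
interval_length <- function(interval) {
  interval$end - interval$start
}

#' Intersect two sets of genomic intervals
#'
#' Pairwise intersections of overlapping intervals on matching chromosomes.
#' Commutative; the result has at most `min(nrow(a), nrow(b))` rows when each
#' input is non-overlapping within itself.
#'
#' @param a,b interval data.frames (`chrom`, `start`, `end`).
#' @return interval data.frame of all non-empty pairwise intersections,
#'   sorted by chromosome and start.
#' @examples
#' ed    <- genomic_interval("A08", 76294, 2305623)
#' dsnp  <- genomic_interval("A08", 68670, 2195304)
#' intersect_regions(ed, dsnp)   # 76,294 - 2,195,304
#' @export
intersect_regions <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (s <= e) out[[length(out) + 1L]] <- genomic_interval(a$chrom[i], s, e)
  }
  if (!length(out))
    return(genomic_interval(character(0), numeric(0), numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write intervals as a BED file
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param intervals interval data.frame.
#' @param path output file.
#' @param names optional feature names (4th BED column).
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, names = NULL) {
  bed <- data.frame(chrom = intervals$chrom,
                    start = format(intervals$start - 1, scientific = FALSE, trim = TRUE),
                    end   = format(intervals$end, scientific = FALSE, trim = TRUE))
  if (!is.null(names)) bed$name <- names
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
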