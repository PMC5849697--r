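#' Genomic intervals (0-based, half-open)
#'
#' Plain data.frame representation of genomic intervals in BED-native
#' coordinates: `start` is 0-based inclusive, `end` exclusive. Used both
#' for methylated regions and annotation tracks.
#'
#' @param chrom character chromosome names.
#' @param start,end integer coordinates, `0 <= start < end`.
#' @param name optional interval names.
#' @param strand optional strand (`"+"`, `"-"`, `"."`).
#' @return a `genomic_intervals` data.frame.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, strand = NULL) {
  chrom <- as.character(chrom)
  start <- as.integer(start); end <- as.integer(end)
  if (any(!nzchar(chrom))) stop("empty chromosome name")
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop("malformed interval at record ", bad[1],
         ": need 0 <= start < end (got start=", start[bad[1]],
         ", end=", end[bad[1]], ")")
  out <- data.frame(chrom = chrom, start = start, end = end,
                    name = if (is.null(name)) paste0("iv", seq_along(chrom))
                           else as.character(name),
                    strand = if (is.null(strand)) "." else as.character(strand),
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

as_granges <- function(iv) {
  # internal 0-based half-open -> GRanges 1-based closed
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end),
    name = iv$name)
}

#' Build methylated regions around probe positions
#'
#' Extends each methylation site by `flank` bp upstream and downstream:
#' with the default flank of 25 bp each region is 51 bp long. Probe
#' coordinates are supplied 1-based (the array-manifest convention) and
#' converted internally to 0-based half-open: a probe at 1-based position
#' `p` becomes the interval `[p - 1 - flank, p + flank)`. Regions running
#' off the chromosome start are clipped at 0 with a warning.
#'
#' @param probes data.frame with columns `probe_id`, `chrom`, `pos_1based`.
#' @param flank bp added on each side (default 25).
#' @return a `genomic_intervals` data.frame with extra columns `probe_id`
#'   and `probe_pos` (the 0-based probe base).
#' @export
make_regions <- function(probes, flank = 25L) {
  stopifnot(all(c("probe_id", "chrom", "pos_1based") %in% colnames(probes)))
  flank <- as.integer(flank)
  if (flank < 0) stop("`flank` must be non-negative")
  pos0 <- as.integer(probes$pos_1based) - 1L
  if (any(pos0 < 0)) stop("probe positions must be >= 1 (1-based)")
  start <- pos0 - flank
  clipped <- start < 0L
  if (any(clipped)) {
    warning(sum(clipped), " region(s) clipped at chromosome start")
    start[clipped] <- 0L
  }
  out <- genomic_intervals(probes$chrom, start, pos0 + flank + 1L,
                           name = probes$probe_id)
  out$probe_id <- as.character(probes$probe_id)
  out$probe_pos <- pos0
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Intersect regions with annotation intervals
#'
#' All pairs with at least 1 bp overlap on the same chromosome, via
#' [GenomicRanges::findOverlaps()]. Strand is ignored (CpG methylation is
#' strand-symmetric); a region may hit any number of annotations.
#'
#' @param regions,annotations `genomic_intervals` data.frames.
#' @return data.frame with `region`, `annotation`, the two coordinate
#'   pairs, and `overlap_bp`.
#' @export
intersect_regions <- function(regions, annotations) {
  regions <- validate_intervals(regions)
  annotations <- validate_intervals(annotations)
  if (nrow(regions) == 0 || nrow(annotations) == 0)
    return(data.frame(region = character(0), annotation = character(0),
                      overlap_bp = integer(0)))
  gr_r <- as_granges(regions)
  gr_a <- as_granges(annotations)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_r, gr_a, minoverlap = 1L,
                                ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- pmin(regions$end[qi], annotations$end[si]) -
        pmax(regions$start[qi], annotations$start[si])
  data.frame(region = regions$name[qi], annotation = annotations$name[si],
             region_start = regions$start[qi], region_end = regions$end[qi],
             annotation_start = annotations$start[si],
             annotation_end = annotations$end[si],
             overlap_bp = as.integer(ov), stringsAsFactors = FALSE)
}

validate_intervals <- function(iv) {
  if (!inherits(iv, "genomic_intervals"))
    iv <- genomic_intervals(iv$chrom, iv$start, iv$end, iv$name,
                            if ("strand" %in% colnames(iv)) iv$strand)
  bad <- which(iv$start < 0 | iv$start >= iv$end)
  if (length(bad))
    stop("malformed interval in record '", iv$name[bad[1]], "' (",
         iv$chrom[bad[1]], ":", iv$start[bad[1]], "-", iv$end[bad[1]], ")")
  iv
}

#' Read / write BED files
#'
#' BED3+ input via `rtracklayer::import()` (chrom, start, end, then
#' optional name/score/strand), preserving BED's 0-based half-open
#' convention in the returned `genomic_intervals`. A pre-scan reports
#' malformed records (negative start, start >= end) with their line
#' numbers before parsing.
#'
#' @param path BED file path.
#' @return a `genomic_intervals` data.frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("line ", i, " of ", path, ": fewer than 3 BED columns")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop("line ", i, " of ", path, ": non-numeric coordinates")
    if (s < 0) stop("line ", i, " of ", path, ": negative start ", s)
    if (s >= e) stop("line ", i, " of ", path, ": start >= end (", s, " >= ", e, ")")
  }
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || all(is.na(nm))) nm <- paste0("iv", seq_along(gr))
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to BED 0-based
    end = GenomicRanges::end(gr),
    name = nm,
    strand = as.character(GenomicRanges::strand(gr)))
}

#' @rdname read_bed
#' @param intervals a `genomic_intervals` data.frame.
#' @export
write_bed <- function(intervals, path) {
  intervals <- validate_intervals(intervals)
  df <- data.frame(chrom = intervals$chrom, start = intervals$start,
                   end = intervals$end, name = intervals$name,
                   score = 0L,
                   strand = ifelse(intervals$strand %in% c("+", "-"),
                                   intervals$strand, "."))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
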