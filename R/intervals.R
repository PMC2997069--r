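#' Genomic interval in 0-based half-open coordinates
#'
#' A minimal value type for a single interval.  Coordinates are 0-based and
#' half-open: `end` is exclusive, so the interval covers `end - start` bp and
#' `[100, 200)` abuts (does not overlap) `[200, 300)`.
#'
#' @param chrom Chromosome name (exact string; no "chr" normalization).
#' @param start 0-based inclusive start (non-negative integer).
#' @param end 0-based exclusive end; must satisfy `end > start`.
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval("chr1", 100, 200)
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || end <= start) {
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  }
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:[%d,%d) %d bp>\n", x$chrom, x$start, x$end, x$end - x$start))
  invisible(x)
}

interval_length <- function(x) x$end - x$start
interval_mid <- function(x) (x$start + x$end) / 2

# Internal: 0-based half-open coordinates -> GRanges (1-based closed).
gr_from_0based <- function(chrom, start, end) {
  GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end))
  )
}

gr_starts0 <- function(gr) GenomicRanges::start(gr) - 1L
gr_ends0 <- function(gr) GenomicRanges::end(gr)

#' Domain set for one chromatin feature
#'
#' Holds the called domains (peak intervals) of a single chromatin feature,
#' e.g. one histone mark.  Domains are kept in 0-based half-open coordinates.
#' Most scoring functions require a merged set (see [merge_domains()]) so
#' that any locus is contained in at most one domain.
#'
#' @param chrom,start,end Parallel vectors of interval coordinates
#'   (0-based half-open).
#' @param feature_name Identifier for the feature.
#' @param merged Logical; set by [merge_domains()], rarely by hand.
#' @return An object of class `domain_set` with fields `feature_name`,
#'   `gr` (a `GRanges`), and `merged`.
#' @seealso [read_bed()], [merge_domains()]
#' @export
domain_set <- function(chrom = character(), start = integer(),
                       end = integer(), feature_name = "feature",
                       merged = FALSE) {
  if (length(chrom) == 1L && length(start) > 1L) {
    chrom <- rep(chrom, length(start))
  }
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(start)) {
    bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | end <= start)
    if (length(bad)) {
      stop("invalid interval(s) at position(s) ", paste(bad, collapse = ", "),
           ": need 0 <= start < end")
    }
  }
  gr <- gr_from_0based(chrom, start, end)
  structure(list(feature_name = as.character(feature_name)[1L],
                 gr = gr, merged = isTRUE(merged)),
            class = "domain_set")
}

#' @export
print.domain_set <- function(x, ...) {
  cat(sprintf("domain_set '%s': %d interval(s)%s\n", x$feature_name,
              length(x$gr), if (x$merged) ", merged" else ""))
  invisible(x)
}

#' @export
length.domain_set <- function(x) length(x$gr)

#' Read a BED3 file into a domain set
#'
#' Parses a tab-separated file with at least three columns
#' (chrom, start, end) in 0-based half-open coordinates.  Lines are kept in
#' file order and the returned set is unmerged.
#'
#' @param path Path to the BED3 file.
#' @param feature_name Feature identifier; defaults to the file name without
#'   extension.
#' @return An unmerged [domain_set()].
#' @export
read_bed <- function(path, feature_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(feature_name)) {
    feature_name <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(domain_set(feature_name = feature_name))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- vapply(fields, length, integer(1))
  if (any(n_col < 3L)) {
    stop("line ", which(n_col < 3L)[1L], ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad)) {
    stop("line ", bad[1L], ": non-integer coordinates")
  }
  bad <- which(end <= start | start < 0)
  if (length(bad)) {
    stop("line ", bad[1L], ": invalid interval (end <= start or start < 0)")
  }
  domain_set(chrom, start, end, feature_name = feature_name)
}

#' Write a domain set as BED3
#'
#' @param d A [domain_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(d, path) {
  stopifnot(inherits(d, "domain_set"))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(d$gr)),
                   start = gr_starts0(d$gr), end = gr_ends0(d$gr))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge overlapping domains of a feature
#'
#' Any two intervals on the same chromosome sharing at least 1 bp are
#' replaced by their union; abutting half-open intervals share 0 bp and are
#' left separate.  Total covered bp is preserved and the result is sorted.
#' The operation is idempotent.
#'
#' @param d A [domain_set()].
#' @return A merged, sorted [domain_set()] with `merged = TRUE`.
#' @export
merge_domains <- function(d) {
  stopifnot(inherits(d, "domain_set"))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(d$gr), min.gapwidth = 0L)
  structure(list(feature_name = d$feature_name, gr = gr, merged = TRUE),
            class = "domain_set")
}

#' Read a CpG locus table
#'
#' Reads a TSV with header columns `locus_id`, `chrom`, `start`, `end`,
#' `methylation` (0-based half-open coordinates; methylation level in
#' \[0,1\]).  Loci are returned in file order; duplicate ids and methylation
#' values outside \[0,1\] are rejected.
#'
#' @param path Path to the loci TSV.
#' @return A `data.frame` of class `cpg_loci`.
#' @export
read_loci <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("locus_id", "chrom", "start", "end", "methylation")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("loci table missing column(s): ", paste(miss, collapse = ", "))
  }
  as_cpg_loci(df[, need])
}

#' Validate a CpG locus table
#'
#' @param df Data frame with columns `locus_id`, `chrom`, `start`, `end`,
#'   `methylation`.
#' @return `df` with class `cpg_loci` prepended.
#' @export
as_cpg_loci <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("locus_id", "chrom", "start", "end", "methylation")
  stopifnot(all(need %in% names(df)))
  df$locus_id <- as.character(df$locus_id)
  if (anyDuplicated(df$locus_id)) {
    stop("duplicate locus_id: ",
         df$locus_id[anyDuplicated(df$locus_id)][1L])
  }
  if (nrow(df)) {
    if (any(df$end <= df$start | df$start < 0)) {
      stop("invalid locus interval(s): need 0 <= start < end")
    }
    bad <- which(!is.finite(df$methylation) | df$methylation < 0 |
                   df$methylation > 1)
    if (length(bad)) {
      stop("methylation outside [0,1] for locus ", df$locus_id[bad[1L]])
    }
  }
  class(df) <- unique(c("cpg_loci", class(df)))
  df
}

#' Write a CpG locus table
#'
#' @param loci A `cpg_loci` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path) {
  write.table(as.data.frame(loci), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

loci_gr <- function(loci) gr_from_0based(loci$chrom, loci$start, loci$end)

#' Overlap between two intervals in base pairs
#'
#' Returns `max(0, min(a$end, b$end) - max(a$start, b$start))` when the two
#' intervals are on the same chromosome, 0 otherwise.  Under the half-open
#' convention, abutting intervals overlap by 0 bp.
#'
#' @param a,b [genomic_interval()] objects.
#' @return Non-negative integer overlap in bp.
#' @export
overlap_bp <- function(a, b) {
  stopifnot(inherits(a, "genomic_interval"), inherits(b, "genomic_interval"))
  if (a$chrom != b$chrom) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

#' Find the merged domain containing a locus
#'
#' Returns the unique merged interval overlapping the locus by at least
#' 1 bp, or `NULL` when the locus falls outside every domain.  Requires a
#' merged set: merged intervals are pairwise disjoint, so at most one can
#' overlap any locus.
#'
#' @param locus A one-row `cpg_loci` data frame or a [genomic_interval()].
#' @param d A merged [domain_set()].
#' @return A [genomic_interval()] or `NULL`.
#' @export
containing_domain <- function(locus, d) {
  stopifnot(inherits(d, "domain_set"))
  if (!d$merged) stop("containing_domain() requires a merged domain_set; ",
                      "call merge_domains() first")
  li <- as_interval(locus)
  q <- gr_from_0based(li$chrom, li$start, li$end)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, d$gr, minoverlap = 1L))
  idx <- S4Vectors::subjectHits(hits)
  if (!length(idx)) return(NULL)
  stopifnot(length(idx) == 1L)  # merged => disjoint => unique container
  genomic_interval(as.character(GenomicRanges::seqnames(d$gr)[idx]),
                   gr_starts0(d$gr)[idx], gr_ends0(d$gr)[idx])
}

as_interval <- function(x) {
  if (inherits(x, "genomic_interval")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    return(genomic_interval(x$chrom, x$start, x$end))
  }
  stop("cannot interpret object of class ", class(x)[1L], " as an interval")
}
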