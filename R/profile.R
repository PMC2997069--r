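#' Closeness measure of a CpG locus to a chromatin feature
#'
#' Scores how centrally a locus sits inside its containing merged domain.
#' With `m` the domain length, `c` the domain midpoint and `x` the locus
#' midpoint, the score is
#' \deqn{CM = \max(0, \min(1, 1 - 2|x - c| / m))}
#' for a locus overlapping the domain by at least 1 bp, and 0 for a locus
#' outside every domain of the feature.  The score is 1 exactly when the
#' locus midpoint coincides with the domain centre, decreases linearly with
#' midpoint distance, and reaches 0 at the domain edge; the factor 2 rescales
#' the raw half-length range \[0, 0.5\] to \[0, 1\] so the score is
#' comparable to a methylation level.  A locus straddling the domain edge
#' (overlap >= 1 bp but midpoint beyond the half-length) is clamped to 0.
#'
#' @param locus A one-row `cpg_loci` data frame or [genomic_interval()].
#' @param d A merged [domain_set()].
#' @return A single closeness value in \[0,1\].
#' @seealso [closeness_all()] for the vectorized form, [encode_element()]
#'   for binary genomic elements.
#' @examples
#' d <- merge_domains(domain_set("chr1", 100, 200))
#' closeness(genomic_interval("chr1", 149, 151), d)  # at centre: 1
#' closeness(genomic_interval("chr1", 500, 502), d)  # outside: 0
#' @export
closeness <- function(locus, d) {
  li <- as_interval(locus)
  loci <- data.frame(locus_id = "q", chrom = li$chrom,
                     start = li$start, end = li$end, methylation = 0)
  closeness_all(loci, d)[1L]
}

#' Closeness measure for every locus against one feature
#'
#' Vectorized form of [closeness()].
#'
#' @param loci A `cpg_loci` data frame (the methylation column is ignored).
#' @param d A merged [domain_set()].
#' @return Numeric vector of closeness values, one per locus, in loci order.
#' @export
closeness_all <- function(loci, d) {
  stopifnot(inherits(d, "domain_set"))
  if (!d$merged) stop("closeness requires a merged domain_set; ",
                      "call merge_domains() first")
  n <- nrow(loci)
  out <- numeric(n)
  if (!n || !length(d$gr)) return(out)
  q <- loci_gr(loci)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, d$gr, minoverlap = 1L))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (length(qi)) {
    ds <- gr_starts0(d$gr)[si]
    de <- gr_ends0(d$gr)[si]
    m <- de - ds
    ctr <- (ds + de) / 2
    x <- (loci$start[qi] + loci$end[qi]) / 2
    out[qi] <- pmax(0, pmin(1, 1 - 2 * abs(x - ctr) / m))
  }
  out
}

#' Binary overlap encoding of a genomic element
#'
#' Encodes genomic elements (promoters, CpG islands, repeats) as indicator
#' variables: 1 when the locus overlaps any interval of the element set by
#' at least 1 bp, else 0.
#'
#' @param locus A one-row `cpg_loci` data frame or [genomic_interval()].
#' @param element A [domain_set()]; merging is optional since only overlap
#'   is tested.
#' @return 0 or 1.
#' @export
encode_element <- function(locus, element) {
  li <- as_interval(locus)
  loci <- data.frame(locus_id = "q", chrom = li$chrom,
                     start = li$start, end = li$end, methylation = 0)
  encode_element_all(loci, element)[1L]
}

#' Binary overlap encoding for every locus against one element set
#'
#' @param loci A `cpg_loci` data frame.
#' @param element A [domain_set()].
#' @return Integer vector of 0/1, one per locus.
#' @export
encode_element_all <- function(loci, element) {
  stopifnot(inherits(element, "domain_set"))
  n <- nrow(loci)
  if (!n || !length(element$gr)) return(integer(n))
  q <- loci_gr(loci)
  as.integer(suppressWarnings(
    GenomicRanges::countOverlaps(q, element$gr, minoverlap = 1L)) > 0L)
}

#' Construct a CM profile
#'
#' Low-level constructor; most users call [build_profile()].
#'
#' @param values N x f numeric matrix with feature names as column names.
#' @param methylation Length-N methylation vector in \[0,1\].
#' @param locus_ids Length-N locus identifiers.
#' @param binary_features Character subset of column names flagged as binary
#'   genomic elements.
#' @return An object of class `cm_profile`.
#' @export
cm_profile <- function(values, methylation, locus_ids,
                       binary_features = character()) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(methylation),
            nrow(values) == length(locus_ids),
            !is.null(colnames(values)))
  p <- structure(list(locus_ids = as.character(locus_ids),
                      feature_names = colnames(values),
                      binary_features = as.character(binary_features),
                      values = values,
                      methylation = as.numeric(methylation)),
                 class = "cm_profile")
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  stopifnot(inherits(p, "cm_profile"))
  if (anyDuplicated(p$feature_names)) stop("duplicate feature names")
  if (anyDuplicated(p$locus_ids)) stop("duplicate locus ids")
  if (length(p$values) && (min(p$values) < 0 || max(p$values) > 1)) {
    stop("profile values outside [0,1]")
  }
  if (length(p$methylation) &&
      (min(p$methylation) < 0 || max(p$methylation) > 1)) {
    stop("methylation outside [0,1]")
  }
  bad <- setdiff(p$binary_features, p$feature_names)
  if (length(bad)) stop("unknown binary feature(s): ",
                        paste(bad, collapse = ", "))
  for (b in p$binary_features) {
    if (nrow(p$values) && !all(p$values[, b] %in% c(0, 1))) {
      stop("binary column '", b, "' contains non-binary values")
    }
  }
  invisible(p)
}

#' @export
print.cm_profile <- function(x, ...) {
  cat(sprintf("cm_profile: %d loci x %d features (+ methylation)\n",
              length(x$locus_ids), length(x$feature_names)))
  if (length(x$binary_features)) {
    cat("  binary elements:", paste(x$binary_features, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.cm_profile <- function(x) c(length(x$locus_ids), length(x$feature_names))

#' Assemble the N x (f+1) CM profile matrix
#'
#' Scores every locus against every feature: chromatin features via the
#' closeness measure ([closeness_all()]), genomic elements via the binary
#' overlap indicator ([encode_element_all()]).  Together with the
#' methylation column this yields the N x (f+1) profile on a 0-1 scale that
#' all downstream stages consume.
#'
#' @param loci A `cpg_loci` data frame.
#' @param cm_features Named list of merged [domain_set()]s scored by
#'   closeness.  Unnamed lists fall back to each set's `feature_name`.
#' @param element_features Named list of [domain_set()]s encoded as binary
#'   indicators (may be empty).
#' @return A [cm_profile()].
#' @export
build_profile <- function(loci, cm_features, element_features = list()) {
  loci <- as_cpg_loci(as.data.frame(loci))
  cm_features <- name_feature_list(cm_features)
  element_features <- name_feature_list(element_features)
  all_names <- c(names(cm_features), names(element_features))
  if (anyDuplicated(all_names)) {
    stop("feature name collision: ",
         paste(all_names[duplicated(all_names)], collapse = ", "))
  }
  for (nm in names(cm_features)) {
    if (!cm_features[[nm]]$merged) {
      stop("CM feature '", nm, "' is not merged; call merge_domains()")
    }
  }
  n <- nrow(loci)
  vals <- matrix(0, nrow = n, ncol = length(all_names),
                 dimnames = list(NULL, all_names))
  for (nm in names(cm_features)) {
    vals[, nm] <- closeness_all(loci, cm_features[[nm]])
  }
  for (nm in names(element_features)) {
    vals[, nm] <- encode_element_all(loci, element_features[[nm]])
  }
  cm_profile(vals, loci$methylation, loci$locus_id,
             binary_features = names(element_features))
}

name_feature_list <- function(fl) {
  if (!length(fl)) return(setNames(list(), character()))
  stopifnot(all(vapply(fl, inherits, logical(1), "domain_set")))
  nms <- names(fl)
  if (is.null(nms)) nms <- rep("", length(fl))
  auto <- vapply(fl, function(d) d$feature_name, character(1))
  nms[!nzchar(nms)] <- auto[!nzchar(nms)]
  setNames(fl, nms)
}

#' Write a CM profile to TSV
#'
#' Layout: a comment line naming the binary-element columns, then a header
#' `locus_id <feature...> methylation`, then one row per locus with values
#' at 10 decimal places.  The round-trip through [read_profile()] is
#' lossless to 1e-10.
#'
#' @param p A [cm_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path) {
  validate_profile(p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#binary_features=",
                    paste(p$binary_features, collapse = ",")), con)
  writeLines(paste(c("locus_id", p$feature_names, "methylation"),
                   collapse = "\t"), con)
  if (length(p$locus_ids)) {
    body <- cbind(p$locus_ids,
                  format(round(cbind(p$values, p$methylation), 10),
                         trim = TRUE, scientific = FALSE, nsmall = 10))
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a CM profile from TSV
#'
#' @param path Path written by [write_profile()].
#' @return A [cm_profile()].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 2L)
  if (!length(lines) || !startsWith(lines[1L], "#binary_features=")) {
    stop("format error: missing #binary_features comment line")
  }
  bin <- sub("^#binary_features=", "", lines[1L])
  bin <- if (nzchar(bin)) strsplit(bin, ",", fixed = TRUE)[[1L]] else character()
  hdr <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  if (hdr[1L] != "locus_id" || hdr[length(hdr)] != "methylation") {
    stop("format error: header must be locus_id ... methylation")
  }
  df <- read.table(path, header = TRUE, sep = "\t", skip = 1L,
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = c("character", rep("numeric",
                                                   length(hdr) - 1L)))
  feats <- hdr[-c(1L, length(hdr))]
  vals <- as.matrix(df[, feats, drop = FALSE])
  cm_profile(vals, df$methylation, df$locus_id, binary_features = bin)
}

#' Extract the feature submatrix of a profile
#'
#' @param p A [cm_profile()].
#' @param features Optional character vector restricting the columns.
#' @return Numeric matrix of feature values (no methylation column).
#' @export
profile_matrix <- function(p, features = NULL) {
  validate_profile(p)
  if (is.null(features)) return(p$values)
  miss <- setdiff(features, p$feature_names)
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  p$values[, features, drop = FALSE]
}

#' Restrict a profile to a subset of features and/or loci
#'
#' @param p A [cm_profile()].
#' @param features Character vector of features to keep (default all).
#' @param loci Indices or locus ids to keep (default all).
#' @return A [cm_profile()].
#' @export
subset_profile <- function(p, features = NULL, loci = NULL) {
  validate_profile(p)
  features <- features %||% p$feature_names
  idx <- seq_along(p$locus_ids)
  if (!is.null(loci)) {
    idx <- if (is.character(loci)) match(loci, p$locus_ids) else loci
    if (anyNA(idx)) stop("unknown locus id(s)")
  }
  cm_profile(p$values[idx, features, drop = FALSE],
             p$methylation[idx], p$locus_ids[idx],
             binary_features = intersect(p$binary_features, features))
}
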