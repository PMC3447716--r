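#' Specify a genomic training region
#'
#' A region is the interval of the genome whose aligned bases are used to
#' train the error model. Coordinates are 1-based and inclusive, following
#' the samtools `chrom:start-end` convention.
#'
#' @param chrom Reference sequence name.
#' @param start,end 1-based inclusive genomic coordinates, `end >= start`.
#' @param max_train Optional cap on the number of aligned bases collected
#'   from the region (counted before any filtering).
#' @return An object of class `region_spec`.
#' @seealso [parse_region()] for the string syntax.
#' @export
region_spec <- function(chrom, start, end, max_train = NULL) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || start < 1) stop("region start must be >= 1")
  if (is.na(end) || end < start) stop("region end must be >= start")
  if (!is.null(max_train)) {
    max_train <- as.numeric(max_train)
    if (is.na(max_train) || max_train <= 0) stop("max_train must be > 0")
  }
  structure(list(chrom = chrom, start = start, end = end,
                 max_train = max_train),
            class = "region_spec")
}

#' Parse a region string
#'
#' Accepts `"chrom:start-end"` or a bare `"chrom"`. A bare chromosome name
#' spans the full reference sequence, so `ref` (a FASTA path or
#' [Rsamtools::FaFile]) must be supplied to resolve its length.
#'
#' @param x Region string, or an existing `region_spec` (returned unchanged).
#' @param ref Reference FASTA path or `FaFile`; required for bare names.
#' @param max_train Optional cap on collected bases, attached to the result.
#' @return A `region_spec`.
#' @export
parse_region <- function(x, ref = NULL, max_train = NULL) {
  if (inherits(x, "region_spec")) {
    if (!is.null(max_train)) x$max_train <- max_train
    return(x)
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl(":", x, fixed = TRUE)) {
    chrom <- sub(":.*$", "", x)
    coords <- sub("^[^:]*:", "", x)
    parts <- strsplit(coords, "-", fixed = TRUE)[[1]]
    # strip thousands separators samtools-style
    parts <- gsub(",", "", parts, fixed = TRUE)
    if (length(parts) != 2L) stop("malformed region string: ", x)
    region_spec(chrom, as.numeric(parts[1]), as.numeric(parts[2]), max_train)
  } else {
    if (is.null(ref)) stop("a bare chromosome region needs `ref` to resolve its length")
    fa <- .as_fafile(ref)
    idx <- as.data.frame(Rsamtools::scanFaIndex(fa))
    hit <- match(x, as.character(idx$seqnames))
    if (is.na(hit)) stop("chromosome '", x, "' not found in reference index")
    region_spec(x, 1, idx$end[hit], max_train)
  }
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region %s:%s-%s%s>\n", x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              if (is.null(x$max_train)) "" else
                sprintf(", max_train=%s", format(x$max_train, big.mark = ","))))
  invisible(x)
}

# FaFile with a guaranteed .fai; builds the index on first use.
.as_fafile <- function(ref) {
  if (inherits(ref, "FaFile")) return(ref)
  stopifnot(is.character(ref), length(ref) == 1L)
  if (!file.exists(ref)) stop("reference FASTA not found: ", ref)
  if (!file.exists(paste0(ref, ".fai"))) Rsamtools::indexFa(ref)
  Rsamtools::FaFile(ref)
}
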