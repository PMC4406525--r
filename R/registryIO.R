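#' @include syntheticPopulation.R
NULL

## fixed locus order of the six-locus haplotype strings
.HLA_LOCI <- c("A", "C", "B", "DRBX", "DRB1", "DQB1")

#' Parse six-locus haplotype strings
#'
#' Splits `~`-joined haplotype strings into their six allele fields in the
#' fixed locus order A, C, B, DRBX, DRB1, DQB1 (DRBX standing for
#' DRB3/4/5).  Strings must have exactly six nonempty fields and
#' round-trip byte-identically through [haplotypeString()].
#'
#' @param x Character vector of haplotype strings.
#' @return Character matrix with one row per haplotype and the six loci as
#'   columns.
#' @examples
#' parseHaplotype("A*01:01~C*07:01~B*08:01~DRB3*01:01~DRB1*03:01~DQB1*02:01")
#' @export
parseHaplotype <- function(x) {
  parts <- strsplit(x, "~", fixed = TRUE)
  bad <- vapply(parts, function(p)
    length(p) != 6L || any(!nzchar(p)), logical(1))
  if (any(bad))
    stop("malformed haplotype string (need 6 nonempty '~'-joined fields): ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  m <- do.call(rbind, parts)
  colnames(m) <- .HLA_LOCI
  rownames(m) <- NULL
  m
}

#' @rdname parseHaplotype
#' @param fields Character matrix as produced by [parseHaplotype()].
#' @return For `haplotypeString`: the serialized `~`-joined strings.
#' @export
haplotypeString <- function(fields) {
  apply(fields, 1L, paste, collapse = "~")
}

## sniff the delimiter from the header line: tab wins over comma
.sniffDelim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a population frequency table
#'
#' Reads a delimited text table with a header naming a `category` column
#' and a `frequency` and/or `count` column.  The delimiter is
#' auto-detected (tab or comma) unless forced.  Frequencies summing to 1
#' within \eqn{\pm 0.01} are renormalized (with a message); sums outside
#' that band are rejected.  When only counts are present, frequencies are
#' derived as `count / sum(count)`.
#'
#' @param path Path to the delimited file.
#' @param delim Forced delimiter, or `NULL` (default) to auto-detect.
#' @param kind `"haplotype"` or `"allele"`.
#' @param population Population label (defaults to the file name).
#' @param locus Locus label for allele tables.
#' @return A [FrequencyTable].
#' @export
readFrequencyTable <- function(path, delim = NULL, kind = "haplotype",
                               population = NULL, locus = NA_character_) {
  if (is.null(delim)) delim <- .sniffDelim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          colClasses = "character", check.names = TRUE,
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!"category" %in% names(df))
    stop("'", path, "': no 'category' column in header")
  if (!any(c("frequency", "count") %in% names(df)))
    stop("'", path, "': need a 'frequency' and/or 'count' column")
  dup <- which(duplicated(df$category))
  if (length(dup))
    stop("'", path, "': duplicate category '", df$category[dup[1]],
         "' at line ", dup[1] + 1L)
  counts <- NULL
  if ("count" %in% names(df)) {
    counts <- suppressWarnings(as.numeric(df$count))
    bad <- which(!is.finite(counts))
    if (length(bad))
      stop("'", path, "': non-numeric count at line ", bad[1] + 1L)
  }
  if ("frequency" %in% names(df)) {
    freq <- suppressWarnings(as.numeric(df$frequency))
    bad <- which(!is.finite(freq))
    if (length(bad))
      stop("'", path, "': non-numeric frequency at line ", bad[1] + 1L)
  } else {
    freq <- counts / sum(counts)
  }
  s <- sum(freq)
  if (abs(s - 1) > 1e-6) {
    if (s < 0.99 || s > 1.01)
      stop("'", path, "': frequencies sum to ", signif(s, 6),
           ", outside the renormalization band [0.99, 1.01]")
    message("frequencies sum to ", signif(s, 6), "; renormalizing")
    freq <- freq / s
  }
  rec <- data.frame(category = df$category, frequency = freq)
  if (!is.null(counts)) rec$count <- counts
  if (is.null(population))
    population <- sub("\\.[^.]*$", "", basename(path))
  FrequencyTable(rec, population = population, kind = kind, locus = locus)
}

#' Write a population frequency table
#'
#' Writes the table as tab-delimited text with header columns `category`,
#' `frequency` (and `count` when present), rows ordered by descending
#' frequency with ties broken by label, so that a read-write-read cycle is
#' byte-stable.
#'
#' @param table A [FrequencyTable].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFrequencyTable <- function(table, path) {
  stopifnot(is(table, "FrequencyTable"))
  rec <- tableRecords(table)
  if (all(is.na(rec$count))) rec$count <- NULL
  utils::write.table(rec, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Marginal allele tables from a haplotype table
#'
#' Derives the six per-locus allele frequency tables as marginal sums of
#' the haplotype frequencies: each allele's frequency is the sum of the
#' frequencies of the haplotypes carrying it, so each locus table conserves
#' total probability mass exactly.
#'
#' @param table A haplotype-kind [FrequencyTable] whose categories are
#'   parseable six-locus strings.
#' @return Named list of six allele-kind [FrequencyTable]s (A, C, B,
#'   DRBX, DRB1, DQB1).
#' @export
allelesFromHaplotypes <- function(table) {
  stopifnot(is(table, "FrequencyTable"))
  if (table@kind != "haplotype")
    stop("allele marginalization needs a haplotype-kind table")
  rec <- tableRecords(table)
  fields <- parseHaplotype(rec$category)
  out <- lapply(.HLA_LOCI, function(loc) {
    m <- rowsum(rec$frequency, fields[, loc])
    FrequencyTable(data.frame(category = rownames(m), frequency = m[, 1]),
                   population = table@population, kind = "allele",
                   locus = loc)
  })
  names(out) <- .HLA_LOCI
  out
}

#' Integer counts from a frequency table
#'
#' Bridges frequency-typed registry tables to the count-based estimators:
#' counts are `round(frequency * r)`; categories rounding to zero are
#' dropped (with a message) and the total draw count is recomputed from
#' the rounded counts.  When the table carries explicit counts they are
#' used directly and `r` is ignored.
#'
#' @param table A [FrequencyTable].
#' @param r Nominal sample size used to scale frequencies.
#' @return An [ObservedSample].
#' @export
countsFromFrequencies <- function(table, r) {
  stopifnot(is(table, "FrequencyTable"))
  rec <- tableRecords(table)
  if (!all(is.na(rec$count))) {
    y <- rec$count
  } else {
    if (r < 1) stop("'r' must be >= 1")
    y <- round(rec$frequency * r)
  }
  keep <- y >= 1
  if (!any(keep))
    stop("all categories round to zero counts; increase 'r'")
  if (any(!keep))
    message(sum(!keep), " categories rounded to zero and were dropped")
  ObservedSample(stats::setNames(y[keep], rec$category[keep]))
}
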