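#' Read a barcode or sgRNA count table
#'
#' Count tables are delimited text (tab or comma, auto-detected) with a header
#' row. The `barcode` schema expects a `barcode` identifier column followed by
#' one integer count column per sample. The `sgrna` schema expects
#' `sgrna_id`, `gene`, `tss` and `targeting` annotation columns followed by
#' count columns; non-targeting control sgRNAs carry `targeting = FALSE` (or
#' 0) and their `gene` field is ignored.
#'
#' @param path path to a delimited text file.
#' @param schema `"barcode"` or `"sgrna"`.
#' @return a data frame of class `barcode_counts` or `screen_counts`; count
#'   columns are integer, identifiers unique.
#' @export
read_count_table <- function(path, schema = c("barcode", "sgrna")) {
  schema <- match.arg(schema)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  id_cols <- if (schema == "barcode") "barcode" else
    c("sgrna_id", "gene", "tss", "targeting")
  missing <- setdiff(id_cols, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  count_cols <- setdiff(names(df), id_cols)
  if (length(count_cols) == 0) stop("no sample count columns found")
  for (cc in count_cols) {
    v <- df[[cc]]
    if (is.character(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("malformed numeric cell at row %d, column '%s': '%s'",
                     bad[1], cc, v[bad[1]]))
      v <- vn
    }
    if (anyNA(v)) stop(sprintf("missing count in column '%s' (row %d)",
                               cc, which(is.na(v))[1]))
    if (any(v < 0)) stop(sprintf("negative count in column '%s' (row %d)",
                                 cc, which(v < 0)[1]))
    if (any(v != round(v)))
      stop(sprintf("non-integer count in column '%s' (row %d)",
                   cc, which(v != round(v))[1]))
    df[[cc]] <- as.integer(round(v))
  }
  key <- df[[id_cols[1]]]
  if (anyDuplicated(key))
    stop("duplicate identifiers: ", paste(utils::head(key[duplicated(key)], 3),
                                          collapse = ", "))
  if (schema == "sgrna") df$targeting <- as.logical(df$targeting)
  class(df) <- c(if (schema == "barcode") "barcode_counts" else "screen_counts",
                 "data.frame")
  df
}

#' Write a count table
#'
#' Output is always tab-delimited with a header row, so that
#' `read_count_table(write_count_table(x))` round-trips.
#'
#' @param x a `barcode_counts` or `screen_counts` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count clone-tracing barcodes in raw reads
#'
#' Clone-tracing barcodes are 30 nt sequences alternating weak (A/T) and
#' strong (G/C) bases, starting weak; this fixed composition removes PCR
#' amplification bias and doubles as a quality filter. Reads must already be
#' trimmed to start at the barcode. A read is counted only when its first
#' `pattern_length` bases strictly follow the weak/strong alternation; all
#' other reads are discarded.
#'
#' @param reads character vector of read sequences, or a path to a FASTQ file
#'   (read via the Biostrings package).
#' @param pattern_length barcode length in bases (default 30).
#' @param sample_name column name for the resulting counts.
#' @return a `barcode_counts` data frame with one count column, sorted by
#'   decreasing count; attribute `n_discarded` holds the number of
#'   pattern-failing reads.
#' @export
extract_barcodes <- function(reads, pattern_length = 30L,
                             sample_name = "sample") {
  if (length(reads) == 1 && file.exists(reads) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTQ files requires the Biostrings package")
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  reads <- as.character(reads)
  if (length(reads) == 0) {
    warning("zero reads supplied; returning empty table")
    out <- data.frame(barcode = character(0), x = integer(0))
    names(out)[2] <- sample_name
    class(out) <- c("barcode_counts", "data.frame")
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  bc <- substr(reads, 1L, pattern_length)
  ok <- nchar(bc) == pattern_length & barcode_pattern_ok(bc, pattern_length)
  counts <- sort(table(bc[ok]), decreasing = TRUE)
  out <- data.frame(barcode = as.character(names(counts)),
                    x = as.integer(counts), stringsAsFactors = FALSE)
  names(out)[2] <- sample_name
  class(out) <- c("barcode_counts", "data.frame")
  attr(out, "n_discarded") <- sum(!ok)
  out
}

# vectorized weak/strong alternation check: odd positions A/T, even G/C
barcode_pattern_ok <- function(seqs, pattern_length) {
  n <- length(seqs)
  if (n == 0) return(logical(0))
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = pattern_length)
  odd <- seq(1L, pattern_length, by = 2L)
  even <- seq(2L, pattern_length, by = 2L)
  okw <- m[odd, , drop = FALSE] == "A" | m[odd, , drop = FALSE] == "T"
  oks <- m[even, , drop = FALSE] == "G" | m[even, , drop = FALSE] == "C"
  colSums(okw) == length(odd) & colSums(oks) == length(even)
}

# Hamming distances from one sequence to many (equal length)
hamming_to <- function(seq, others) {
  a <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- matrix(unlist(strsplit(others, "", fixed = TRUE), use.names = FALSE),
              nrow = length(a))
  colSums(m != a)
}

#' Merge sequencing-error barcodes into their parent barcode
#'
#' Barcode reads containing one or two sequencing errors appear as
#' low-abundance barcodes one or two substitutions away from a genuine
#' high-abundance barcode. Each barcode whose count is at least `min_ratio`
#' times lower than that of a barcode within `max_hamming` substitutions is
#' merged into the nearest such parent (counts summed across all sample
#' columns); merging iterates to a fixed point. A child with two candidate
#' parents at the same distance is left unmerged and reported.
#'
#' @param table a `barcode_counts` data frame with equal-length barcodes.
#' @param max_hamming maximum substitution distance to a parent (default 2).
#' @param min_ratio minimum parent:child total-count ratio (default 8).
#' @return the collapsed `barcode_counts` table; attribute `merges` is a data
#'   frame of (child, parent, distance), attribute `ambiguous` the barcodes
#'   left unmerged for lack of a unique parent.
#' @export
collapse_sequencing_errors <- function(table, max_hamming = 2L, min_ratio = 8) {
  stopifnot(inherits(table, "barcode_counts"))
  bl <- nchar(table$barcode)
  if (length(unique(bl)) > 1) stop("barcodes must be equal length")
  count_cols <- setdiff(names(table), "barcode")
  merges <- list()
  ambiguous <- character(0)
  repeat {
    tot <- rowSums(as.matrix(table[count_cols]))
    ord <- order(tot)            # try to merge rarest first
    merged_any <- FALSE
    drop <- rep(FALSE, nrow(table))
    for (i in ord) {
      if (drop[i]) next
      cand <- which(!drop & tot >= min_ratio * tot[i])
      cand <- setdiff(cand, i)
      if (!length(cand)) next
      d <- hamming_to(table$barcode[i], table$barcode[cand])
      cand <- cand[d <= max_hamming]
      d <- d[d <= max_hamming]
      if (!length(cand)) next
      nearest <- cand[d == min(d)]
      if (length(nearest) > 1) {
        ambiguous <- c(ambiguous, table$barcode[i])
        next
      }
      p <- nearest
      table[p, count_cols] <- table[p, count_cols] + table[i, count_cols]
      tot[p] <- tot[p] + tot[i]
      merges[[length(merges) + 1L]] <-
        data.frame(child = table$barcode[i], parent = table$barcode[p],
                   distance = min(d), stringsAsFactors = FALSE)
      drop[i] <- TRUE
      merged_any <- TRUE
    }
    table <- table[!drop, , drop = FALSE]
    if (!merged_any) break
  }
  rownames(table) <- NULL
  attr(table, "merges") <- if (length(merges)) do.call(rbind, merges) else
    data.frame(child = character(0), parent = character(0),
               distance = integer(0))
  attr(table, "ambiguous") <- unique(ambiguous)
  table
}
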