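# Sequence and interval I/O plus ligation-junction-anchored window extraction.

#' Read a FASTQ file
#'
#' Reads 4-line FASTQ (plain or gzip, detected by magic bytes) into a data
#' frame of records. Sequences are uppercased on input. Malformed input stops
#' with an error naming the offending record; a well-formed file (uppercase
#' bases, bare `+` separator) round-trips byte-identically through
#' [write_fastq()].
#'
#' @param path Path to a FASTQ file, optionally gzip-compressed.
#' @return A data frame with columns `id`, `seq`, `qual` (one row per read).
#' @export
read_fastq <- function(path) {
  if (!is.character(path) || length(path) != 1L) stop_arg("path must be a single file path")
  if (!file.exists(path)) stop_arg("input file not found: ", path)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(id = character(0), seq = character(0), qual = character(0),
                      stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    stop_data(sprintf("truncated FASTQ: record %d is incomplete in '%s'", n %/% 4L + 1L, path))
  }
  m <- matrix(lines, nrow = 4L)
  heads <- m[1L, ]; seqs <- m[2L, ]; seps <- m[3L, ]; quals <- m[4L, ]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad)) stop_data(sprintf("FASTQ parse error at record %d: header does not start with '@'", bad[1L]))
  bad <- which(!startsWith(seps, "+"))
  if (length(bad)) stop_data(sprintf("FASTQ parse error at record %d: missing '+' separator line", bad[1L]))
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad)) stop_data(sprintf("FASTQ parse error at record %d: quality length differs from sequence length", bad[1L]))
  data.frame(id = sub("^@", "", heads), seq = toupper(seqs), qual = quals,
             stringsAsFactors = FALSE)
}

#' Write records to a FASTQ file
#'
#' @param records Data frame with columns `id`, `seq`, `qual` as returned by
#'   [read_fastq()].
#' @param path Output path (plain text).
#' @return The path, invisibly.
#' @export
write_fastq <- function(records, path) {
  if (!all(c("id", "seq", "qual") %in% names(records))) {
    stop_arg("records must have columns id, seq, qual")
  }
  n <- nrow(records)
  lines <- character(4L * n)
  if (n > 0L) {
    lines[seq(1L, 4L * n, 4L)] <- paste0("@", records$id)
    lines[seq(2L, 4L * n, 4L)] <- records$seq
    lines[seq(3L, 4L * n, 4L)] <- "+"
    lines[seq(4L, 4L * n, 4L)] <- records$qual
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' Wrapped or unwrapped FASTA via Biostrings; sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `seq`, `qual` (`qual` all `NA`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_arg("input file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  data.frame(id = names(x), seq = toupper(as.character(x)),
             qual = NA_character_, stringsAsFactors = FALSE)
}

#' Read a BED6 file of stranded intervals
#'
#' BED is 0-based half-open; the returned `GRanges` is 1-based closed, so a
#' BED line `chr1 0 50 . 0 +` becomes `chr1:1-50:+`. Records with strand
#' outside `+`/`-` or with `start >= end` are rejected with an error naming
#' the record.
#'
#' @param path Path to a 6-column BED file.
#' @return A [GenomicRanges::GRanges] with `name` and `score` metadata columns.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_arg("input file not found: ", path)
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               comment.char = "", quote = ""),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL else stop_data("failed to read BED: ", conditionMessage(e))
    })
  if (is.null(df)) return(GenomicRanges::GRanges())
  if (ncol(df) < 6L) stop_data("BED6 required (6 columns), got ", ncol(df))
  start0 <- df[[2L]]; end0 <- df[[3L]]; strand <- as.character(df[[6L]])
  bad <- which(!(strand %in% c("+", "-")))
  if (length(bad)) {
    stop_data(sprintf("BED record %d: strand must be '+' or '-', got '%s'", bad[1L], strand[bad[1L]]))
  }
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad)) {
    stop_data(sprintf("BED record %d: need 0 <= start < end, got start=%s end=%s",
                      bad[1L], start0[bad[1L]], end0[bad[1L]]))
  }
  GenomicRanges::GRanges(
    seqnames = as.character(df[[1L]]),
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand,
    name = as.character(df[[4L]]),
    score = df[[5L]])
}

#' Write stranded intervals as BED6
#'
#' @param gr A `GRanges`; `name`/`score` metadata columns are used if present.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(gr, path) {
  n <- length(gr)
  mc <- S4Vectors::mcols(gr)
  nm <- if ("name" %in% names(mc)) as.character(mc$name) else rep(".", n)
  sc <- if ("score" %in% names(mc)) mc$score else rep(0L, n)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   name = nm, score = sc,
                   strand = as.character(BiocGenerics::strand(gr)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chromosome-sizes TSV
#'
#' Two columns: chromosome name and length in bp.
#'
#' @param path Path to the TSV.
#' @return A named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop_arg("input file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_data("chrom sizes file needs 2 columns (name, length)")
  setNames(as.integer(df[[2L]]), as.character(df[[1L]]))
}

#' Extract ligation-junction-anchored windows from assay reads
#'
#' Locates the fixed adaptor (`anchor`) in each read by Hamming-distance scan
#' (no indels; best hit wins, ties are ambiguous and dropped) and emits the
#' `window` bases on the junction side of the anchor. Window positions are
#' numbered 1..W outward from the ligation junction regardless of side:
#' position 1 is the junction-adjacent base and position W the most distal.
#' For `side = "donor5"` the window is the read segment following the anchor
#' (in read order); for `side = "acceptor3"` it is the segment preceding the
#' anchor, reversed so position 1 is again junction-adjacent.
#'
#' Reads are uppercased; reads containing characters outside A/C/G/T/N are
#' dropped and tallied as `n_bad_char`. N never matches the anchor.
#'
#' @param reads Data frame from [read_fastq()] or a character vector of reads.
#' @param anchor Adaptor sequence over A/C/G/T, at least 8 nt.
#' @param side `"donor5"` (junction at the window's 5' end) or `"acceptor3"`.
#' @param window Window length W (default 40, the N40 assay).
#' @param max_mismatch Maximum Hamming mismatches allowed for an anchor hit.
#' @param revcomp Reverse-complement reads before anchoring (set when the
#'   sequencer reports the strand complementary to the assay layout).
#' @return A list with `windows` (data frame: `source_id`, `side`, `bases`,
#'   `insert_len` = bases available on the junction side before trimming to W)
#'   and `report` (named integer vector: `n_total`, `n_anchored`,
#'   `n_no_anchor`, `n_ambiguous`, `n_short`, `n_bad_char`; the last five sum
#'   to `n_total`).
#' @export
anchor_and_extract <- function(reads, anchor, side = c("donor5", "acceptor3"),
                               window = 40L, max_mismatch = 1L, revcomp = FALSE) {
  side <- match.arg(side)
  if (!is.character(anchor) || length(anchor) != 1L || !grepl("^[ACGT]+$", anchor)) {
    stop_arg("anchor must be a single non-empty string over A/C/G/T")
  }
  if (nchar(anchor) < 8L) stop_arg("anchor must be at least 8 nt, got ", nchar(anchor))
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop_arg("window must be a positive integer")
  if (max_mismatch < 0L) stop_arg("max_mismatch must be >= 0")

  if (is.data.frame(reads)) {
    ids <- reads$id; seqs <- reads$seq
  } else {
    seqs <- as.character(reads)
    ids <- names(reads) %||% paste0("read", seq_along(seqs))
  }
  seqs <- toupper(seqs)
  n_total <- length(seqs)

  empty_windows <- data.frame(source_id = character(0), side = character(0),
                              bases = character(0), insert_len = integer(0),
                              stringsAsFactors = FALSE)
  report <- c(n_total = n_total, n_anchored = 0L, n_no_anchor = 0L,
              n_ambiguous = 0L, n_short = 0L, n_bad_char = 0L)
  if (n_total == 0L) return(list(windows = empty_windows, report = report))

  ok <- !grepl("[^ACGTN]", seqs)
  report[["n_bad_char"]] <- sum(!ok)
  seqs <- seqs[ok]; ids <- ids[ok]
  if (length(seqs) == 0L) return(list(windows = empty_windows, report = report))
  if (revcomp) {
    seqs <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  }

  k <- nchar(anchor)
  mi <- Biostrings::vmatchPattern(anchor, Biostrings::DNAStringSet(seqs),
                                  max.mismatch = max_mismatch, fixed = TRUE)
  starts <- Biostrings::startIndex(mi)
  nh <- vapply(starts, function(s) length(s %||% integer(0)), integer(1))

  best_start <- rep(NA_integer_, length(seqs))
  ambiguous <- logical(length(seqs))
  single <- which(nh == 1L)
  best_start[single] <- vapply(starts[single], `[`, integer(1), 1L)
  for (i in which(nh > 1L)) {
    st <- starts[[i]]
    mm <- vapply(st, function(s) hamming(substr(seqs[i], s, s + k - 1L), anchor), numeric(1))
    m0 <- min(mm)
    if (sum(mm == m0) > 1L) ambiguous[i] <- TRUE else best_start[i] <- st[which.min(mm)]
  }
  report[["n_no_anchor"]] <- sum(nh == 0L)
  report[["n_ambiguous"]] <- sum(ambiguous)

  idx <- which(nh >= 1L & !ambiguous)
  if (length(idx) == 0L) return(list(windows = empty_windows, report = report))
  st <- best_start[idx]
  if (side == "donor5") {
    avail <- nchar(seqs[idx]) - (st + k - 1L)
    from <- st + k
    to <- from + window - 1L
  } else {
    avail <- st - 1L
    from <- st - window
    to <- st - 1L
  }
  short <- avail < window
  report[["n_short"]] <- sum(short)
  keep <- !short
  report[["n_anchored"]] <- sum(keep)
  bases <- substring(seqs[idx][keep], from[keep], to[keep])
  if (side == "acceptor3") bases <- reverse_strings(bases)
  windows <- data.frame(source_id = ids[idx][keep], side = side, bases = bases,
                        insert_len = avail[keep], stringsAsFactors = FALSE)
  list(windows = windows, report = report)
}
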