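# Internal helpers: error classes, seeded evaluation, string reversal.

stop_arg <- function(...) {
  stop(structure(class = c("ligbias_argument_error", "ligbias_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("ligbias_data_error", "ligbias_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a seed without disturbing the caller's RNG stream;
# seed = NULL uses the current stream.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# Text connection with gzip auto-detection by magic bytes (not extension).
open_text <- function(path) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = 2L)
  close(con)
  if (length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)) {
    gzfile(path, "rt")
  } else {
    file(path, "rt")
  }
}

BASES <- c("A", "C", "G", "T")

# Per-sequence string reversal (keeps the alphabet, incl. N).
reverse_strings <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# 6-significant-digit TSV writer used by all table outputs.
write_tsv6 <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
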