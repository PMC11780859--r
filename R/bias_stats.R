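# Positional nucleotide composition, distal-baseline enrichment and the
# degree-of-bias (DB) statistic.

window_bases <- function(windows) {
  if (is.data.frame(windows)) return(windows$bases)
  if (is.list(windows) && !is.null(windows$windows)) return(windows$windows$bases)
  as.character(windows)
}

#' Per-position nucleotide composition of junction-anchored windows
#'
#' Counts A/C/G/T at each window position 1..W (proximal to distal from the
#' ligation junction). An N at position p removes the window from position p's
#' counts only (tallied in `n_excluded_N`); the window still contributes at
#' its other positions.
#'
#' @param windows Windows as returned by [anchor_and_extract()] (the list or
#'   its `windows` data frame), or a character vector of equal-length strings.
#' @param window Required window length when `windows` is empty; otherwise
#'   checked against the observed length.
#' @return An object of class `nt_composition`: list with `counts` (W x 4
#'   integer matrix), `n_excluded_N` (length-W integer) and `n_windows`.
#' @export
nt_composition <- function(windows, window = NULL) {
  bases <- window_bases(windows)
  if (length(bases) == 0L) {
    if (is.null(window)) stop_arg("window length required for empty input")
    W <- as.integer(window)
    return(structure(list(counts = matrix(0L, W, 4L, dimnames = list(NULL, BASES)),
                          n_excluded_N = integer(W), n_windows = 0L),
                     class = "nt_composition"))
  }
  lens <- unique(nchar(bases))
  if (length(lens) != 1L) {
    stop_data("windows of mixed lengths: ", paste(sort(head(lens, 5L)), collapse = ", "))
  }
  W <- lens
  if (!is.null(window) && as.integer(window) != W) {
    stop_data("windows have length ", W, " but window=", window, " was requested")
  }
  counts <- matrix(0L, W, 4L, dimnames = list(NULL, BASES))
  nN <- integer(W)
  for (p in seq_len(W)) {
    idx <- match(substring(bases, p, p), c(BASES, "N"))
    if (anyNA(idx)) stop_data("unexpected character in window at position ", p)
    tab <- tabulate(idx, 5L)
    counts[p, ] <- tab[1:4]
    nN[p] <- tab[5L]
  }
  structure(list(counts = counts, n_excluded_N = nN, n_windows = length(bases)),
            class = "nt_composition")
}

#' @export
print.nt_composition <- function(x, ...) {
  cat(sprintf("nt_composition: %d windows x %d positions (%d N exclusions)\n",
              x$n_windows, nrow(x$counts), sum(x$n_excluded_N)))
  invisible(x)
}

#' Per-position base frequencies of a composition matrix
#'
#' Frequencies use the windows counted at that position (N exclusions removed
#' from the denominator). An optional pseudocount is added to every cell.
#'
#' @param comp An `nt_composition`.
#' @param pseudocount Added to every count cell before normalization.
#' @return A W x 4 matrix of frequencies (rows sum to 1 where defined).
#' @export
position_frequencies <- function(comp, pseudocount = 0) {
  cc <- comp$counts + pseudocount
  tot <- rowSums(cc)
  fr <- cc / tot
  fr[tot == 0, ] <- NaN
  fr
}

#' Distal baseline composition
#'
#' Mean base composition over the `distal_n` most distal window positions
#' (positions W-distal_n+1 .. W): the unweighted mean of per-position
#' frequency vectors, renormalized to sum 1. This is the normalizer that
#' absorbs batch-dependent base-composition skew of the synthesized oligo
#' pool.
#'
#' @inheritParams position_frequencies
#' @param distal_n Number of distal positions averaged (default 30).
#' @return A named numeric vector of 4 frequencies (A, C, G, T) summing to 1.
#' @export
distal_baseline <- function(comp, distal_n = 30L, pseudocount = 0) {
  W <- nrow(comp$counts)
  if (W < distal_n + 1L) {
    stop_arg("window length ", W, " too short for distal_n=", distal_n,
             " (need at least distal_n+1 positions)")
  }
  pos <- (W - distal_n + 1L):W
  cc <- comp$counts[pos, , drop = FALSE] + pseudocount
  tot <- rowSums(cc)
  if (any(tot == 0)) {
    stop_data("no counted windows at distal position ", pos[which(tot == 0)[1L]])
  }
  b <- colMeans(cc / tot)
  b / sum(b)
}

#' Proximal enrichment and per-position degree of bias
#'
#' Enrichment at proximal position p for base b is the position-p frequency of
#' b divided by the baseline frequency of b. The per-position degree of bias
#' (DB) is the ratio of the most- to the least-enriched base's enrichment;
#' the headline DB is DB at position 1, the junction-adjacent base.
#'
#' @inheritParams distal_baseline
#' @param baseline Baseline frequencies from [distal_baseline()]; computed
#'   from `comp` (with `distal_n`) when `NULL`.
#' @param proximal_n Number of junction-proximal positions (default 10).
#' @return An object of class `bias_profile`: `enrichment` (P x 4 matrix),
#'   `db_per_position`, `zero_cell` (flags positions where an enrichment of 0
#'   forced DB to `Inf`), `headline_db`, `baseline`, and the `composition`.
#' @export
proximal_enrichment <- function(comp, baseline = NULL, proximal_n = 10L,
                                distal_n = 30L, pseudocount = 0) {
  W <- nrow(comp$counts)
  if (W < proximal_n) stop_arg("window length ", W, " shorter than proximal_n=", proximal_n)
  if (is.null(baseline)) baseline <- distal_baseline(comp, distal_n, pseudocount)
  if (any(baseline <= 0)) {
    stop_data("baseline frequency is zero for base ",
              BASES[which(baseline <= 0)[1L]],
              "; consider a pseudocount (pseudocount > 0)")
  }
  pos <- seq_len(proximal_n)
  cc <- comp$counts[pos, , drop = FALSE] + pseudocount
  tot <- rowSums(cc)
  if (any(tot == 0)) {
    stop_data("no counted windows at proximal position ", pos[which(tot == 0)[1L]])
  }
  enr <- sweep(cc / tot, 2L, baseline, "/")
  zero_cell <- apply(enr, 1L, function(e) min(e) == 0)
  db <- vapply(seq_len(nrow(enr)), function(p) {
    e <- enr[p, ]
    if (min(e) == 0) Inf else max(e) / min(e)
  }, numeric(1))
  structure(list(enrichment = enr, db_per_position = db, zero_cell = zero_cell,
                 headline_db = db[1L], baseline = baseline,
                 proximal_n = proximal_n, composition = comp),
            class = "bias_profile")
}

#' @export
print.bias_profile <- function(x, ...) {
  cat(sprintf("bias_profile: %d proximal positions, headline DB (position 1) = %.4g%s\n",
              x$proximal_n, x$headline_db,
              if (x$zero_cell[1L]) " [zero enrichment cell]" else ""))
  invisible(x)
}

#' Degree of bias at one proximal position
#'
#' Ratio of the most- to the least-enriched base's enrichment at the given
#' position; `Inf` (with attribute `zero_cell = TRUE`) when the least-enriched
#' base has enrichment 0.
#'
#' @param profile A `bias_profile`.
#' @param position Proximal position index (default 1, the junction-adjacent
#'   base, which is the headline DB).
#' @return A single numeric value with attribute `zero_cell`.
#' @export
degree_of_bias <- function(profile, position = 1L) {
  if (position < 1L || position > nrow(profile$enrichment)) {
    stop_arg("position must be in 1..", nrow(profile$enrichment))
  }
  structure(profile$db_per_position[[position]],
            zero_cell = profile$zero_cell[[position]])
}

#' Full bias profile from windows
#'
#' Convenience wrapper: composition, distal baseline, proximal enrichment and
#' per-position DB in one call.
#'
#' @inheritParams nt_composition
#' @inheritParams proximal_enrichment
#' @return A `bias_profile` (see [proximal_enrichment()]).
#' @export
bias_profile <- function(windows, proximal_n = 10L, distal_n = 30L,
                         pseudocount = 0, window = NULL) {
  comp <- nt_composition(windows, window = window)
  proximal_enrichment(comp, proximal_n = proximal_n, distal_n = distal_n,
                      pseudocount = pseudocount)
}

#' Insert-length histogram
#'
#' @param x Integer lengths, a windows data frame (uses `insert_len`), or a
#'   reads data frame (uses `nchar(seq)`).
#' @return A data frame `length`, `count`; total count equals the input size.
#' @export
insert_length_histogram <- function(x) {
  lens <- if (is.numeric(x)) {
    as.integer(x)
  } else if (is.data.frame(x) && "insert_len" %in% names(x)) {
    x$insert_len
  } else if (is.list(x) && !is.null(x$windows)) {
    x$windows$insert_len
  } else if (is.data.frame(x) && "seq" %in% names(x)) {
    nchar(x$seq)
  } else {
    stop_arg("cannot derive lengths from input")
  }
  if (any(lens < 0)) stop_arg("lengths must be >= 0")
  if (length(lens) == 0L) {
    return(data.frame(length = integer(0), count = integer(0)))
  }
  tab <- table(lens)
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}

#' Per-cycle base composition of reads
#'
#' For each sequencing cycle 1..`max_pos`, the fraction of A/C/G/T/N among
#' reads at least that long (characters outside A/C/G/T are counted under N).
#' Fractions sum to 1 at every cycle.
#'
#' @param reads Reads data frame (uses `seq`) or character vector.
#' @param max_pos Last cycle to profile; defaults to the longest read.
#' @return A data frame: `cycle`, `A`, `C`, `G`, `T`, `N`, `n_reads`.
#' @export
read_composition_profile <- function(reads, max_pos = NULL) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  if (length(seqs) == 0L) stop_arg("reads must be non-empty")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  max_pos <- as.integer(max_pos %||% max(lens))
  out <- matrix(0, max_pos, 5L, dimnames = list(NULL, c(BASES, "N")))
  n_reads <- integer(max_pos)
  for (p in seq_len(max_pos)) {
    ch <- substring(seqs[lens >= p], p, p)
    n <- length(ch)
    n_reads[p] <- n
    if (n == 0L) { out[p, ] <- NA_real_; next }
    idx <- match(ch, BASES)
    tab <- tabulate(idx[!is.na(idx)], 4L)
    out[p, ] <- c(tab, sum(is.na(idx))) / n
  }
  data.frame(cycle = seq_len(max_pos), out, n_reads = n_reads)
}

#' Write bias-statistic TSV tables
#'
#' Emits `<prefix>.composition.tsv`, `<prefix>.enrichment.tsv` (long form),
#' `<prefix>.db.tsv`, and optionally `<prefix>.lengths.tsv`,
#' `<prefix>.cycles.tsv`, `<prefix>.report.tsv`. Floats are printed with 6
#' significant digits.
#'
#' @param prefix Output path prefix.
#' @param profile A `bias_profile`.
#' @param lengths Optional data frame from [insert_length_histogram()].
#' @param cycles Optional data frame from [read_composition_profile()].
#' @param report Optional named counts vector from [anchor_and_extract()].
#' @return Character vector of written paths, invisibly.
#' @export
write_bias_tables <- function(prefix, profile, lengths = NULL, cycles = NULL,
                              report = NULL) {
  comp <- profile$composition
  paths <- character(0)
  p <- paste0(prefix, ".composition.tsv")
  write_tsv6(data.frame(position = seq_len(nrow(comp$counts)), comp$counts,
                        N_excluded = comp$n_excluded_N), p)
  paths <- c(paths, p)
  enr <- profile$enrichment
  long <- data.frame(position = rep(seq_len(nrow(enr)), each = 4L),
                     base = rep(BASES, nrow(enr)),
                     enrichment = as.vector(t(enr)))
  p <- paste0(prefix, ".enrichment.tsv")
  write_tsv6(long, p); paths <- c(paths, p)
  p <- paste0(prefix, ".db.tsv")
  write_tsv6(data.frame(position = seq_along(profile$db_per_position),
                        db = profile$db_per_position,
                        zero_cell_flag = profile$zero_cell), p)
  paths <- c(paths, p)
  if (!is.null(lengths)) {
    p <- paste0(prefix, ".lengths.tsv"); write_tsv6(lengths, p); paths <- c(paths, p)
  }
  if (!is.null(cycles)) {
    p <- paste0(prefix, ".cycles.tsv"); write_tsv6(cycles, p); paths <- c(paths, p)
  }
  if (!is.null(report)) {
    p <- paste0(prefix, ".report.tsv")
    write_tsv6(data.frame(metric = names(report), count = as.integer(report)), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
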