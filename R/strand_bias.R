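# Binned per-strand read depth, strand-bias score, origin-candidate
# transition calling, and GC-content coverage bias.

#' Binned per-strand read depth
#'
#' Each read is assigned to the bin containing its midpoint (midpoint
#' binning: the fragments are short, so spreading coverage adds nothing);
#' plus and minus reads are tallied separately. The per-bin strand-bias
#' score is `(plus - minus) / (plus + minus)`, `NA` where both are 0
#' (undefined bins are never imputed).
#'
#' @param gr Stranded reads as a `GRanges` (e.g. from [read_bed()]).
#' @param chrom_sizes Named vector of chromosome lengths (bp), e.g. from
#'   [read_chrom_sizes()].
#' @param bin_size Bin width in bp (default 100, the yeast-scale default).
#' @return A named list (one entry per chromosome in `chrom_sizes`) of
#'   `strand_depth_track` objects: `chrom`, `chrom_len`, `bin_size`, `plus`,
#'   `minus`, `score`.
#' @export
binned_strand_depth <- function(gr, chrom_sizes, bin_size = 100L) {
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 1L) stop_arg("bin_size must be >= 1")
  if (is.null(names(chrom_sizes))) stop_arg("chrom_sizes must be a named vector")
  chroms <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chroms), names(chrom_sizes))
  if (length(unknown)) stop_data("chromosome not in chrom sizes: ", unknown[1L])
  s_all <- BiocGenerics::start(gr)
  e_all <- BiocGenerics::end(gr)
  st_all <- as.character(BiocGenerics::strand(gr))
  tracks <- list()
  for (ch in names(chrom_sizes)) {
    size <- chrom_sizes[[ch]]
    sel <- which(chroms == ch)
    s <- s_all[sel]; e <- e_all[sel]; st <- st_all[sel]
    bad <- which(e > size | s < 1L)
    if (length(bad)) {
      stop_data(sprintf("read %d (%s:%d-%d) extends beyond chromosome end %d",
                        sel[bad[1L]], ch, s[bad[1L]], e[bad[1L]], size))
    }
    nb <- as.integer(ceiling(size / bin_size))
    mid <- (s + e) %/% 2L
    bin <- (mid - 1L) %/% bin_size + 1L
    plus <- tabulate(bin[st == "+"], nb)
    minus <- tabulate(bin[st == "-"], nb)
    tot <- plus + minus
    score <- ifelse(tot > 0L, (plus - minus) / tot, NA_real_)
    tracks[[ch]] <- structure(list(chrom = ch, chrom_len = size, bin_size = bin_size,
                                   plus = plus, minus = minus, score = score),
                              class = "strand_depth_track")
  }
  tracks
}

#' @export
print.strand_depth_track <- function(x, ...) {
  cat(sprintf("strand_depth_track %s: %d bins x %d bp, %d reads (+%d/-%d)\n",
              x$chrom, length(x$plus), x$bin_size, sum(x$plus) + sum(x$minus),
              sum(x$plus), sum(x$minus)))
  invisible(x)
}

#' Smooth the strand-bias score
#'
#' Centered moving average over defined bins only: undefined (`NA`) bins are
#' excluded from the average and remain undefined in the output rather than
#' being imputed. `window_bins = 1` is the identity.
#'
#' @param track A `strand_depth_track`.
#' @param window_bins Odd window width in bins (default 15).
#' @return The track with `score` smoothed and the original kept as
#'   `score_raw`.
#' @export
smooth_score <- function(track, window_bins = 15L) {
  window_bins <- as.integer(window_bins)
  if (is.na(window_bins) || window_bins < 1L || window_bins %% 2L != 1L) {
    stop_arg("window_bins must be odd and >= 1")
  }
  s <- track$score
  n <- length(s)
  def <- !is.na(s)
  x <- ifelse(def, s, 0)
  k <- (window_bins - 1L) %/% 2L
  cpx <- c(0, cumsum(x))
  cpw <- c(0, cumsum(as.numeric(def)))
  i <- seq_len(n)
  lo <- pmax(1L, i - k)
  hi <- pmin(n, i + k)
  num <- cpx[hi + 1L] - cpx[lo]
  den <- cpw[hi + 1L] - cpw[lo]
  sm <- ifelse(den > 0, num / den, NA_real_)
  sm[!def] <- NA_real_
  track$score_raw <- track$score
  track$score <- sm
  track$window_bins <- window_bins
  track
}

#' Call strand-switch transitions (origin candidates)
#'
#' Scans the (smoothed) score for sign changes flanked by at least
#' `min_run_bins` defined bins of consistent sign on each side. The call's
#' amplitude is the difference between the mean score over the
#' `min_run_bins` flanking bins right and left of the change; calls below
#' `min_amp` are discarded. The position is the midpoint between the two
#' flanking bin centers. Direction `"up"` is a minus-to-plus switch,
#' `"down"` the reverse; around an origin one direction marks the origin and
#' the opposite direction marks fork-convergence (termination) zones between
#' origins. Undefined and exactly-zero bins are skipped.
#'
#' @param track A `strand_depth_track`, normally after [smooth_score()].
#' @param min_amp Minimum amplitude in (0, 2] (default 0.5).
#' @param min_run_bins Minimum run of consistent sign on each side (default 5).
#' @return Data frame: `chrom`, `position` (bp), `amplitude`, `direction`,
#'   `bin_left`, `bin_right`.
#' @export
call_transitions <- function(track, min_amp = 0.5, min_run_bins = 5L) {
  if (min_amp <= 0 || min_amp > 2) stop_arg("min_amp must be in (0, 2]")
  min_run_bins <- as.integer(min_run_bins)
  if (is.na(min_run_bins) || min_run_bins < 1L) stop_arg("min_run_bins must be >= 1")
  empty <- data.frame(chrom = character(0), position = numeric(0),
                      amplitude = numeric(0), direction = character(0),
                      bin_left = integer(0), bin_right = integer(0),
                      stringsAsFactors = FALSE)
  s <- track$score
  d <- which(!is.na(s) & s != 0)
  if (length(d) < 2L * min_run_bins) return(empty)
  ss <- s[d]
  sg <- sign(ss)
  r <- rle(sg)
  if (length(r$lengths) < 2L) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  calls <- list()
  for (j in seq_len(length(r$lengths) - 1L)) {
    if (r$lengths[j] < min_run_bins || r$lengths[j + 1L] < min_run_bins) next
    i <- ends[j]
    jn <- starts[j + 1L]
    left_mean <- mean(ss[(i - min_run_bins + 1L):i])
    right_mean <- mean(ss[jn:(jn + min_run_bins - 1L)])
    amp <- abs(right_mean - left_mean)
    if (amp < min_amp) next
    pos <- ((d[i] - 0.5) + (d[jn] - 0.5)) / 2 * track$bin_size
    calls[[length(calls) + 1L]] <- data.frame(
      chrom = track$chrom, position = pos, amplitude = amp,
      direction = if (r$values[j] < 0) "up" else "down",
      bin_left = d[i], bin_right = d[jn], stringsAsFactors = FALSE)
  }
  if (length(calls) == 0L) return(empty)
  do.call(rbind, calls)
}

#' GC-content-dependent coverage bias profile
#'
#' Bins the genome, computes each bin's GC fraction (over A/C/G/T; other
#' letters excluded from the denominator) and midpoint read depth, groups
#' bins by GC deciles (quantile breaks; collapsed when the GC distribution
#' is degenerate) and reports each group's mean depth divided by the global
#' mean depth. Groups with fewer than `min_group_bins` bins are flagged, as
#' is everything when there are no reads.
#'
#' @param gr Reads as a `GRanges`.
#' @param genome A `DNAStringSet` or path to a genome FASTA.
#' @param bin_size Bin width in bp.
#' @param n_gc_bins Number of GC groups (default 10, deciles).
#' @param min_group_bins Flag threshold for thin groups (default 10).
#' @return Data frame: `gc_bin`, `gc_lo`, `gc_hi`, `n_bins`, `mean_depth`,
#'   `norm_depth`, `flagged`.
#' @export
gc_bias_profile <- function(gr, genome, bin_size = 100L, n_gc_bins = 10L,
                            min_group_bins = 10L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  missing_ch <- setdiff(chroms, names(genome))
  if (length(missing_ch)) stop_data("chromosome absent from genome FASTA: ", missing_ch[1L])
  gc_all <- depth_all <- numeric(0)
  s_all <- BiocGenerics::start(gr)
  e_all <- BiocGenerics::end(gr)
  ch_all <- as.character(GenomicRanges::seqnames(gr))
  for (ch in names(genome)) {
    L <- length(genome[[ch]])
    nb <- as.integer(ceiling(L / bin_size))
    starts <- (seq_len(nb) - 1L) * bin_size + 1L
    ends <- pmin(L, starts + bin_size - 1L)
    v <- Biostrings::Views(genome[[ch]], starts, ends)
    lf <- Biostrings::letterFrequency(v, BASES)
    tot <- rowSums(lf)
    gc <- ifelse(tot > 0, (lf[, "C"] + lf[, "G"]) / tot, NA_real_)
    sel <- ch_all == ch
    mid <- (s_all[sel] + e_all[sel]) %/% 2L
    mid <- pmin(pmax(mid, 1L), L)
    dep <- tabulate((mid - 1L) %/% bin_size + 1L, nb)
    gc_all <- c(gc_all, gc)
    depth_all <- c(depth_all, dep)
  }
  ok <- !is.na(gc_all)
  gc_ok <- gc_all[ok]
  dep_ok <- depth_all[ok]
  gmean <- mean(dep_ok)
  qs <- quantile(gc_ok, probs = seq(0, 1, length.out = n_gc_bins + 1L), names = FALSE)
  brk <- unique(qs)
  grp <- if (length(brk) >= 2L) {
    cut(gc_ok, breaks = brk, include.lowest = TRUE)
  } else {
    factor(rep(sprintf("[%g,%g]", brk, brk), length(gc_ok)))
  }
  lv <- levels(grp)
  n_bins <- as.integer(table(grp))
  mean_depth <- vapply(lv, function(l) mean(dep_ok[grp == l]), numeric(1))
  lo <- vapply(split(gc_ok, grp), function(x) if (length(x)) min(x) else NA_real_, numeric(1))
  hi <- vapply(split(gc_ok, grp), function(x) if (length(x)) max(x) else NA_real_, numeric(1))
  data.frame(gc_bin = lv,
             gc_lo = unname(lo), gc_hi = unname(hi), n_bins = n_bins,
             mean_depth = unname(mean_depth),
             norm_depth = if (gmean > 0) unname(mean_depth) / gmean else NaN,
             flagged = n_bins < min_group_bins | gmean == 0,
             stringsAsFactors = FALSE)
}

#' Write one track channel as bedGraph
#'
#' bedGraph is 0-based half-open; `NA` score bins are skipped.
#'
#' @param track A `strand_depth_track`.
#' @param what `"plus"`, `"minus"` or `"score"`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, what = c("plus", "minus", "score"), path) {
  what <- match.arg(what)
  v <- track[[what]]
  nb <- length(v)
  start0 <- (seq_len(nb) - 1L) * track$bin_size
  end0 <- pmin(seq_len(nb) * track$bin_size, track$chrom_len)
  keep <- !is.na(v)
  df <- data.frame(chrom = track$chrom, start = start0[keep], end = end0[keep],
                   value = signif(as.numeric(v[keep]), 6L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
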