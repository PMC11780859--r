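# Synthetic-data generators: bias-assay reads under a terminal-nucleotide
# ligation-weight model with pool depletion, and strand-switching reads
# around planted replication origins.

#' Terminal-nucleotide ligation-weight model
#'
#' A molecule's ligation weight is the product of per-position weights over
#' its junction-proximal bases: by default only position 1 (the
#' junction-adjacent base) is weighted, which generates the single-position
#' 5'-donor pattern; extra positions via `w_proximal` generate multi-position
#' patterns such as the acceptor-side 3'-terminal enrichment. `theta` is the
#' base composition of the synthesized oligo pool and models batch-dependent
#' composition skew.
#'
#' @param w_terminal Named positive weights (A, C, G, T) at position 1.
#' @param w_proximal Optional named list: names are positions (`"2"`, `"3"`,
#'   ...), values are 4-vectors of positive weights.
#' @param theta Pool base composition; 4 probabilities summing to 1.
#' @return An object of class `bias_model`.
#' @export
bias_model <- function(w_terminal = c(A = 1, C = 1, G = 1, T = 1),
                       w_proximal = NULL,
                       theta = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  norm4 <- function(x, what, prob = FALSE) {
    if (length(x) != 4L) stop_arg(what, " must have 4 entries (A, C, G, T)")
    if (is.null(names(x))) names(x) <- BASES
    if (!setequal(names(x), BASES)) stop_arg(what, " must be named A, C, G, T")
    x <- x[BASES]
    if (prob) {
      if (any(x < 0)) stop_arg(what, " must be non-negative")
      if (abs(sum(x) - 1) > 1e-9) stop_arg(what, " must sum to 1")
    } else if (any(x <= 0)) stop_arg(what, " must be strictly positive")
    x
  }
  w_terminal <- norm4(w_terminal, "w_terminal")
  theta <- norm4(theta, "theta", prob = TRUE)
  if (!is.null(w_proximal)) {
    if (is.null(names(w_proximal)) || anyNA(suppressWarnings(as.integer(names(w_proximal))))) {
      stop_arg("w_proximal must be a list named by position (\"2\", \"3\", ...)")
    }
    w_proximal <- lapply(w_proximal, norm4, what = "w_proximal entry")
  }
  structure(list(w_terminal = w_terminal, w_proximal = w_proximal, theta = theta),
            class = "bias_model")
}

#' Generate a randomized-insert pool
#'
#' i.i.d. bases from `theta`; deterministic given `seed`. The returned vector
#' is the generator's ledger: element i is molecule i.
#'
#' @param n_pool Number of molecules.
#' @param insert_len Single length (default 40, the N40 assay) or a 2-vector
#'   `c(min, max)` for uniform integer lengths.
#' @param theta Pool base composition (4 probabilities summing to 1).
#' @param seed Optional integer seed.
#' @return Character vector of inserts, written junction-proximal first
#'   (position 1 = junction-adjacent base).
#' @export
generate_pool <- function(n_pool, insert_len = 40L,
                          theta = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                          seed = NULL) {
  if (n_pool < 1L) stop_arg("n_pool must be >= 1")
  theta <- bias_model(theta = theta)$theta
  if (!length(insert_len) %in% c(1L, 2L) || any(insert_len < 1L)) {
    stop_arg("insert_len must be one positive length or c(min, max)")
  }
  with_seed_opt(seed, {
    lens <- if (length(insert_len) == 1L) {
      rep.int(as.integer(insert_len), n_pool)
    } else {
      sample(seq.int(insert_len[1L], insert_len[2L]), n_pool, replace = TRUE)
    }
    b <- sample(BASES, sum(lens), replace = TRUE, prob = theta)
    long <- paste(b, collapse = "")
    ends <- cumsum(lens)
    substring(long, ends - lens + 1L, ends)
  })
}

insert_weights <- function(inserts, model) {
  if (any(grepl("[^ACGT]", inserts))) stop_data("inserts must be over A/C/G/T")
  w <- unname(model$w_terminal[substring(inserts, 1L, 1L)])
  for (p in names(model$w_proximal)) {
    pi <- as.integer(p)
    w <- w * unname(model$w_proximal[[p]][substring(inserts, pi, pi)])
  }
  w
}

#' Ligate a fraction of the pool under the bias model
#'
#' Weighted sampling without replacement (exponential-key method, equivalent
#' in distribution to sequential weighted draws) of `ceiling(f * n_pool)`
#' molecules; the weight of a molecule is the product of the model's
#' positional weights over its junction-proximal bases. Sampling without
#' replacement is the depletion mechanism: as `f` grows (longer incubation),
#' preferred molecules run out and the realized bias dilutes; `f = 1` returns
#' the whole pool and downstream DB is 1 up to counting noise.
#'
#' @param pool Character vector from [generate_pool()].
#' @param model A [bias_model()].
#' @param f Ligated fraction in (0, 1].
#' @param seed Optional integer seed.
#' @return List with `inserts` (selected molecules, pool order) and `index`
#'   (their positions in the pool).
#' @export
simulate_ligation <- function(pool, model, f, seed = NULL) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1) stop_arg("f must be in (0, 1]")
  n <- length(pool)
  n_sel <- ceiling(f * n)
  if (n_sel >= n) return(list(inserts = pool, index = seq_len(n)))
  w <- insert_weights(pool, model)
  idx <- with_seed_opt(seed, {
    keys <- rexp(n) / w
    sort(order(keys)[seq_len(n_sel)])
  })
  list(inserts = pool[idx], index = idx)
}

#' Assemble selected inserts into assay reads and write FASTQ
#'
#' Each read is the fixed adaptor followed by the insert (`donor5`) or the
#' reversed insert followed by the adaptor (`acceptor3`), so that the
#' insert's position 1 always sits adjacent to the ligation junction in the
#' read; [anchor_and_extract()] on the output recovers the inserts exactly.
#' Read ids carry the ledger index (`sim<index>`).
#'
#' @param inserts Selected inserts (junction-proximal first).
#' @param anchor Adaptor sequence over A/C/G/T.
#' @param side `"donor5"` or `"acceptor3"`.
#' @param path Output FASTQ path, or `NULL` to return the records only.
#' @param qual_char Constant quality character (default `"I"`).
#' @param index Ledger indices for the read ids.
#' @return The records data frame (invisibly when `path` is given).
#' @export
emit_fastq <- function(inserts, anchor, side = c("donor5", "acceptor3"),
                       path = NULL, qual_char = "I", index = seq_along(inserts)) {
  side <- match.arg(side)
  if (!grepl("^[ACGT]+$", anchor)) stop_arg("anchor must be over A/C/G/T")
  seqs <- if (length(inserts) == 0L) {
    character(0)  # paste0() would promote a zero-length operand to ""
  } else if (side == "donor5") {
    paste0(anchor, inserts)
  } else {
    paste0(reverse_strings(inserts), anchor)
  }
  rec <- data.frame(id = if (length(seqs)) paste0("sim", index) else character(0),
                    seq = seqs,
                    qual = strrep(qual_char, nchar(seqs)),
                    stringsAsFactors = FALSE)
  if (is.null(path)) return(rec)
  write_fastq(rec, path)
  invisible(rec)
}

#' Strand-switching read scenario around planted replication origins
#'
#' Models the unsealed lagging-strand fragments of ligase-deficient cells:
#' each read's strand of origin switches at the nearest replication origin.
#'
#' @param genome_len Genome length in bp (single chromosome).
#' @param origins Planted origin positions (bp, within the genome).
#' @param n_reads Number of reads.
#' @param frag_mean,frag_sd Fragment length distribution (normal, bp).
#' @param noise_frac Probability that a read's strand is random instead of
#'   the origin-determined one, in `[0, 1]`.
#' @param polarity `"left_plus"`: reads left of their nearest origin map to
#'   `+`, reads to the right to `-`; `"left_minus"` is the mirror. The
#'   convention linking lagging-strand reads to Watson/Crick is
#'   dataset-dependent, hence a configuration, not a constant.
#' @param chrom Chromosome name.
#' @param seed Optional integer seed.
#' @return An object of class `origin_scenario`.
#' @export
origin_scenario <- function(genome_len, origins, n_reads, frag_mean = 150,
                            frag_sd = 30, noise_frac = 0,
                            polarity = c("left_plus", "left_minus"),
                            chrom = "chrSim", seed = NULL) {
  polarity <- match.arg(polarity)
  if (genome_len < 1) stop_arg("genome_len must be >= 1")
  if (length(origins) == 0L || any(origins < 1 | origins > genome_len)) {
    stop_arg("origins must lie within 1..genome_len")
  }
  if (noise_frac < 0 || noise_frac > 1) stop_arg("noise_frac must be in [0, 1]")
  structure(list(genome_len = as.integer(genome_len), origins = sort(as.integer(origins)),
                 n_reads = as.integer(n_reads), frag_mean = frag_mean,
                 frag_sd = frag_sd, noise_frac = noise_frac, polarity = polarity,
                 chrom = chrom, seed = seed),
            class = "origin_scenario")
}

#' Generate strand-biased reads around planted origins
#'
#' Read midpoints are uniform over the genome; each read's strand follows the
#' replication polarity of its nearest origin (ties go to the right-hand
#' side) and is replaced by a fair coin with probability `noise_frac`.
#'
#' @param scenario An [origin_scenario()].
#' @param bed_path Optional path: write the reads as BED6.
#' @param truth_path Optional path: write the planted origins as a TSV with
#'   column `origin_pos`.
#' @return A `GRanges` of reads with seqlengths set.
#' @export
generate_strand_reads <- function(scenario, bed_path = NULL, truth_path = NULL) {
  sc <- scenario
  gr <- with_seed_opt(sc$seed, {
    mid <- sample.int(sc$genome_len, sc$n_reads, replace = TRUE)
    len <- pmax(1L, as.integer(round(rnorm(sc$n_reads, sc$frag_mean, sc$frag_sd))))
    ori <- sc$origins
    iv <- findInterval(mid, ori)
    cl <- pmax(iv, 1L)
    cr <- pmin(iv + 1L, length(ori))
    nearest <- ifelse(abs(mid - ori[cl]) <= abs(ori[cr] - mid), ori[cl], ori[cr])
    is_left <- mid < nearest
    base_strand <- if (sc$polarity == "left_plus") {
      ifelse(is_left, "+", "-")
    } else {
      ifelse(is_left, "-", "+")
    }
    flip <- runif(sc$n_reads) < sc$noise_frac
    rnd <- sample(c("+", "-"), sc$n_reads, replace = TRUE)
    strand <- ifelse(flip, rnd, base_strand)
    start1 <- pmax(1L, mid - len %/% 2L)
    end1 <- pmin(sc$genome_len, start1 + len - 1L)
    g <- GenomicRanges::GRanges(sc$chrom, IRanges::IRanges(start1, end1), strand = strand,
                                name = paste0("frag", seq_len(sc$n_reads)), score = 0L)
    GenomeInfoDb::seqlengths(g) <- setNames(sc$genome_len, sc$chrom)
    g
  })
  if (!is.null(bed_path)) write_bed(gr, bed_path)
  if (!is.null(truth_path)) {
    write.table(data.frame(origin_pos = sc$origins), truth_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  gr
}
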