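test_that("composition counts match a hand count and apply the N rule", {
  comp <- nt_composition(c("GA", "GC", "AT", "GG"))
  expect_equal(comp$counts[1, ], c(A = 1L, C = 0L, G = 3L, T = 0L))
  expect_equal(comp$counts[2, ], c(A = 1L, C = 1L, G = 1L, T = 1L))
  expect_equal(comp$n_excluded_N, c(0L, 0L))

  zero <- nt_composition(character(0), window = 5)
  expect_true(all(zero$counts == 0L))
  expect_equal(nrow(zero$counts), 5L)

  # N at position 1 excludes the window there only; position 2 still counted
  compN <- nt_composition("NA")
  expect_equal(compN$n_excluded_N, c(1L, 0L))
  expect_equal(sum(compN$counts[1, ]), 0L)
  expect_equal(unname(compN$counts[2, "A"]), 1L)

  expect_error(nt_composition(c("ACG", "AC")), "mixed", class = "ligbias_data_error")
})

test_that("per-position frequencies sum to 1 over counted windows", {
  pool <- generate_pool(500, 12, theta = c(A = .4, C = .1, G = .3, T = .2), seed = 21)
  pool[1:30] <- paste0("N", substring(pool[1:30], 2))  # inject Ns at position 1
  comp <- nt_composition(pool)
  fr <- position_frequencies(comp)
  expect_equal(unname(rowSums(fr)), rep(1, 12), tolerance = 1e-12)
  expect_equal(rowSums(comp$counts) + comp$n_excluded_N, rep(500L, 12),
               ignore_attr = TRUE)
})

test_that("distal baseline averages distal positions and demands coverage", {
  uniform <- nt_composition(generate_pool(200, 8, seed = 5))
  b <- distal_baseline(uniform, distal_n = 4)
  expect_equal(sum(b), 1, tolerance = 1e-12)

  # two distal positions with mirrored skew average to uniform
  comp <- nt_composition(c("AAAC", "AAGT", "CCAG", "CCGT"))
  # positions 3/4 counts: p3 {A:2,G:2}, p4 {C:1,T:2,G:1}; use symmetric fixture instead
  comp2 <- nt_composition(c("TTAG", "TTCT", "GGAG", "GGCT"))
  b2 <- distal_baseline(comp2, distal_n = 2)
  # p3 freqs (.5,.5,0,0), p4 (0,0,.5,.5) -> mean (.25,.25,.25,.25)
  expect_equal(unname(b2), rep(0.25, 4))

  # baseline recovers the generating composition within binomial tolerance
  theta <- c(A = .3, C = .2, G = .3, T = .2)
  pool <- generate_pool(10000, 40, theta = theta, seed = 11)
  b3 <- distal_baseline(nt_composition(pool), distal_n = 30)
  oracle <- colMeans(t(vapply(11:40, function(p) oracle_base_freq(pool, p), numeric(4))))
  expect_equal(unname(b3), unname(oracle / sum(oracle)), tolerance = 1e-9)
  expect_lt(max(abs(b3 - theta)), 0.01)

  # a distal position with zero counted windows is an error naming the position
  allN <- c("AAN", "CCN")
  expect_error(distal_baseline(nt_composition(allN), distal_n = 1),
               "position 3", class = "ligbias_data_error")
  expect_error(distal_baseline(uniform, distal_n = 8), class = "ligbias_argument_error")
})

test_that("enrichment divides by the baseline and its weighted mean is 1", {
  # identical proximal and distal composition -> all enrichments 1
  pool <- generate_pool(4000, 40, theta = c(A = .4, C = .2, G = .2, T = .2), seed = 8)
  prof <- bias_profile(pool)
  expect_equal(dim(prof$enrichment), c(10L, 4L))
  # baseline-weighted mean of enrichments is exactly 1 at every position
  wm <- as.vector(prof$enrichment %*% prof$baseline)
  expect_equal(wm, rep(1, 10), tolerance = 1e-9)

  # direct-division example: position-1 freqs (.5,.125,.25,.125), uniform baseline
  comp <- nt_composition(c(rep("AA", 4), "CA", rep("GA", 2), "TA"))
  baseline <- c(A = .25, C = .25, G = .25, T = .25)
  prof2 <- proximal_enrichment(comp, baseline = baseline, proximal_n = 1)
  expect_equal(unname(prof2$enrichment[1, ]), c(2, 0.5, 1, 0.5))
  expect_equal(prof2$headline_db, 4)  # 2.0 / 0.5

  # zero baseline frequency errors and points at the pseudocount escape
  noT <- nt_composition(c("AAA", "CCC", "GGG"))
  expect_error(proximal_enrichment(noT, proximal_n = 1, distal_n = 2),
               "pseudocount", class = "ligbias_data_error")
  withpc <- proximal_enrichment(noT, proximal_n = 1, distal_n = 2, pseudocount = 1)
  expect_true(all(is.finite(withpc$enrichment)))
})

test_that("degree of bias is max/min enrichment with an infinity flag", {
  comp <- nt_composition(c(rep("AA", 4), "CA", rep("GA", 2), "TA"))
  prof <- proximal_enrichment(comp, baseline = c(A = .25, C = .25, G = .25, T = .25),
                              proximal_n = 1)
  expect_equal(as.numeric(degree_of_bias(prof, 1)), 4)
  expect_false(attr(degree_of_bias(prof, 1), "zero_cell"))

  # all enrichments equal -> DB 1
  even <- nt_composition(c("AA", "CC", "GG", "TT"))
  prof1 <- proximal_enrichment(even, baseline = c(A = .25, C = .25, G = .25, T = .25),
                               proximal_n = 1)
  expect_equal(as.numeric(degree_of_bias(prof1)), 1)

  # an enrichment of zero forces +Inf with the zero-cell flag
  noT1 <- nt_composition(c("AA", "CC", "GA"))
  profz <- proximal_enrichment(noT1, baseline = c(A = .25, C = .25, G = .25, T = .25),
                               proximal_n = 1)
  expect_identical(as.numeric(degree_of_bias(profz)), Inf)
  expect_true(attr(degree_of_bias(profz), "zero_cell"))
  expect_error(degree_of_bias(profz, 5), class = "ligbias_argument_error")
})

test_that("DB is at least 1 and invariant under duplicating every window", {
  pool <- generate_pool(2000, 40, theta = c(A = .35, C = .15, G = .25, T = .25), seed = 13)
  model <- bias_model(w_terminal = c(A = 2, C = 1, G = 3, T = 1))
  sel <- simulate_ligation(pool, model, f = 0.1, seed = 14)
  prof <- bias_profile(sel$inserts)
  expect_true(all(prof$db_per_position >= 1))
  prof3x <- bias_profile(rep(sel$inserts, 3L))
  expect_equal(prof3x$db_per_position, prof$db_per_position, tolerance = 1e-12)
  expect_equal(prof3x$enrichment, prof$enrichment, tolerance = 1e-12)
})

test_that("insert-length histogram is an exact tally", {
  h <- insert_length_histogram(c(40, 40, 50))
  expect_equal(h, data.frame(length = c(40L, 50L), count = c(2L, 1L)))
  expect_equal(nrow(insert_length_histogram(integer(0))), 0L)

  lens_pool <- generate_pool(10000, c(30L, 60L), seed = 5)
  h2 <- insert_length_histogram(nchar(lens_pool))
  expect_true(all(h2$length >= 30 & h2$length <= 60))
  expect_equal(sum(h2$count), 10000L)
  expect_equal(h2$count[h2$length == 40],
               sum(nchar(lens_pool) == 40))  # oracle: direct tally
})

test_that("per-cycle composition profiles sum to 1 and expose bisulfite conversion", {
  prof <- read_composition_profile(rep("ACGT", 3))
  expect_equal(prof$A[1], 1)
  expect_equal(prof$C[2], 1)
  expect_equal(prof$G[3], 1)
  expect_equal(prof$T[4], 1)

  reads <- generate_pool(4000, 40, seed = 9)
  pr <- read_composition_profile(reads)
  expect_equal(rowSums(pr[, c("A", "C", "G", "T", "N")]), rep(1, 40),
               ignore_attr = TRUE)
  # binomial tolerance for the max over 160 cells at n = 4000
  expect_lt(max(abs(as.matrix(pr[, c("A", "C", "G", "T")]) - 0.25)), 0.05)
  # exact agreement with an independent per-cycle tally
  expect_equal(unname(as.matrix(pr[3, c("A", "C", "G", "T")])[1, ]),
               unname(oracle_base_freq(reads, 3)))

  # in-silico bisulfite: every C -> T on the read strand
  bs <- chartr("C", "T", reads)
  prbs <- read_composition_profile(bs)
  expect_equal(prbs$C, rep(0, 40))
  expect_true(all(prbs$T > prbs$A - 0.1))
})

test_that("bias tables are written with headers and 6 significant digits", {
  pool <- generate_pool(300, 40, seed = 2)
  prof <- bias_profile(pool)
  prefix <- file.path(tempdir(), "tabtest")
  paths <- write_bias_tables(prefix, prof,
                             lengths = insert_length_histogram(nchar(pool)))
  expect_true(all(file.exists(paths)))
  db <- read.delim(paste0(prefix, ".db.tsv"))
  expect_named(db, c("position", "db", "zero_cell_flag"))
  expect_equal(nrow(db), 10L)
  enr <- read.delim(paste0(prefix, ".enrichment.tsv"))
  expect_equal(nrow(enr), 40L)
  expect_equal(enr$enrichment[enr$position == 1 & enr$base == "A"],
               unname(signif(prof$enrichment[1, "A"], 6)))
})
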