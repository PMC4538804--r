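test_that("allele states reproduce bulk exactly when epimutation rates are zero", {
  amp <- toy_amplicon(3, 2)
  bulk <- uniform_bulk_profile("toy", 3, "METHYLATED")
  cfg <- simulation_config(n_cells = 10, rate_demethylating = 0,
                           rate_methylating = 0, seed = 1)
  set.seed(cfg$seed)
  st <- simulate_cell_allele_states(bulk, cfg, amplicon = amp)
  expect_true(all(st$states))
  expect_identical(nrow(st$ledger), 0L)

  bulk_u <- uniform_bulk_profile("toy", 3, "UNMETHYLATED")
  set.seed(cfg$seed)
  st_u <- simulate_cell_allele_states(bulk_u, cfg, amplicon = amp)
  expect_false(any(st_u$states))
})

test_that("rate one flips every allele and logs every event", {
  amp <- toy_amplicon(2, 1)
  bulk <- uniform_bulk_profile("toy", 2, "METHYLATED")
  cfg <- simulation_config(n_cells = 5, ploidy = 2,
                           rate_demethylating = 1, seed = 3)
  set.seed(cfg$seed)
  st <- simulate_cell_allele_states(bulk, cfg, amplicon = amp)
  expect_false(any(st$states))
  expect_identical(nrow(st$ledger), 5L * 2L * 2L)
  expect_true(all(st$ledger$event_kind == "DEMETHYLATING_EPIMUTATION"))
  expect_true(all(st$ledger$position %in% amp$cpg_positions))
})

test_that("planted demethylating events follow the binomial expectation", {
  # 601 haploid cell-by-CpG units at rate 16/601: mean 16, sd ~ 4
  amp <- toy_amplicon(1, 1)
  bulk <- uniform_bulk_profile("toy", 1, "METHYLATED")
  r <- 16 / 601
  counts <- vapply(1:20, function(seed) {
    cfg <- simulation_config(n_cells = 601, ploidy = 1,
                             rate_demethylating = r, seed = seed)
    set.seed(cfg$seed)
    nrow(simulate_cell_allele_states(bulk, cfg, amplicon = amp)$ledger)
  }, 1)
  sd3 <- 3 * sqrt(601 * r * (1 - r))
  expect_true(all(abs(counts - 16) <= sd3))
  expect_gt(stats::var(counts), 0)
})

test_that("MIXED bulk CpGs are drawn at their methylated fraction, unflipped", {
  amp <- toy_amplicon(1, 0)
  bulk <- bulk_profile("toy", "MIXED", methylated_fraction = 0.3)
  cfg <- simulation_config(n_cells = 2000, ploidy = 1,
                           rate_demethylating = 1, rate_methylating = 1,
                           seed = 11)
  set.seed(cfg$seed)
  st <- simulate_cell_allele_states(bulk, cfg, amplicon = amp)
  frac <- mean(st$states)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
  expect_identical(nrow(st$ledger), 0L)  # no epimutation flip on MIXED
})

test_that("chemistry with zero error equals deterministic conversion", {
  amp <- toy_amplicon(2, 3)
  cfg <- simulation_config(n_cells = 1, conversion_failure_rate = 0,
                           overconversion_rate = 0)
  out <- apply_bisulfite_chemistry(amp, c(TRUE, FALSE), NULL, cfg)
  expect_identical(out$sequence,
                   bisulfite_convert(amp$sequence, amp$cpg_positions[1]))
  expect_identical(nrow(out$events), 0L)

  # failure rate 1 retains every unmethylated cytosine
  cfg1 <- simulation_config(n_cells = 1, conversion_failure_rate = 1,
                            overconversion_rate = 0)
  out1 <- apply_bisulfite_chemistry(amp, c(FALSE, FALSE), NULL, cfg1)
  expect_identical(out1$sequence, amp$sequence)
  expect_identical(sort(out1$events$position),
                   sort(c(amp$cpg_positions, amp$non_cpg_c_positions)))
  expect_true(all(out1$events$event_kind == "CONVERSION_FAILURE"))
})

test_that("conversion failures occur at the configured binomial rate", {
  # 3296 unmethylated cytosine draws at rate 17/3296: mean 17, 3 sd ~ 12
  amp <- toy_amplicon(0, 8)
  f <- 17 / 3296
  cfg <- simulation_config(n_cells = 412, conversion_failure_rate = f,
                           overconversion_rate = 0)
  counts <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 0
    for (i in 1:412) {
      out <- apply_bisulfite_chemistry(amp, logical(0), NULL, cfg)
      n <- n + nrow(out$events)
    }
    n
  }, 1)
  sd3 <- 3 * sqrt(3296 * f * (1 - f))
  expect_true(all(abs(counts - 17) <= sd3))
})

test_that("Sanger consensus renders agreement, C/T mixtures and other clashes", {
  expect_identical(render_sanger_consensus(c("ACGT", "ACGT")), "ACGT")
  expect_identical(render_sanger_consensus(c("ACGT", "ATGT")), "AYGT")
  expect_identical(render_sanger_consensus("ACGT"), "ACGT")
  expect_identical(render_sanger_consensus(c("ACGT", "AGGT")), "ANGT")
  expect_identical(render_sanger_consensus(c("ACGT", "ATGT", "AGGT")),
                   "ANGT")
  expect_error(render_sanger_consensus(c("ACGT", "ACG")), "same length")
})

test_that("an experiment with no noise emits the converted reference for every cell", {
  amp <- toy_amplicon(2, 2)
  bulk <- uniform_bulk_profile("toy", 2, "METHYLATED")
  cfg <- simulation_config(n_cells = 8, amplicon_success_prob = 1,
                           allelic_dropout_prob = 0,
                           conversion_failure_rate = 0,
                           overconversion_rate = 0, seed = 5)
  sim <- simulate_experiment(amp, bulk, cfg)
  expect_length(sim$reads, 8)
  ref <- bisulfite_convert(amp$sequence, amp$cpg_positions)
  expect_true(all(sim$reads == ref))
  expect_identical(nrow(sim$ledger), 0L)
})

test_that("amplicon dropout removes reads and is ledgered", {
  amp <- toy_amplicon(1, 1)
  bulk <- uniform_bulk_profile("toy", 1, "METHYLATED")
  cfg <- simulation_config(n_cells = 12, amplicon_success_prob = 0,
                           seed = 2)
  sim <- simulate_experiment(amp, bulk, cfg)
  expect_length(sim$reads, 0)
  expect_identical(nrow(sim$ledger), 12L)
  expect_true(all(sim$ledger$event_kind == "AMPLICON_DROPOUT"))

  # ~99% success emulates the 100-cell control regime; pooled over seeds
  # because a single count of 100 draws is too discrete for a 3 sd band
  counts <- vapply(1:10, function(seed) {
    cfg <- simulation_config(n_cells = 100, amplicon_success_prob = 0.99,
                             seed = seed)
    length(simulate_experiment(amp, bulk, cfg)$reads)
  }, 1)
  expect_lte(abs(sum(counts) - 990), 3 * sqrt(1000 * 0.99 * 0.01))
  expect_true(all(counts >= 94))
})

test_that("same seed and config give byte-identical FASTA and ledger", {
  amp <- toy_amplicon(2, 3)
  bulk <- uniform_bulk_profile("toy", 2, "METHYLATED")
  cfg <- simulation_config(n_cells = 30, rate_demethylating = 0.1,
                           rate_methylating = 0.05,
                           non_cpg_methylation_rate = 0.02, seed = 99)
  s1 <- simulate_experiment(amp, bulk, cfg)
  s2 <- simulate_experiment(amp, bulk, cfg)
  expect_identical(s1, s2)
  d <- withr::local_tempdir()
  write_reads_fasta(s1$reads, file.path(d, "r1.fasta"))
  write_reads_fasta(s2$reads, file.path(d, "r2.fasta"))
  expect_identical(readLines(file.path(d, "r1.fasta")),
                   readLines(file.path(d, "r2.fasta")))
  s3 <- simulate_experiment(amp, bulk,
                            simulation_config(n_cells = 30,
                                              rate_demethylating = 0.1,
                                              rate_methylating = 0.05,
                                              non_cpg_methylation_rate = 0.02,
                                              seed = 100))
  expect_false(identical(s1$reads, s3$reads))
})

test_that("ledger conversion-failure counts fit the binomial law across seeds", {
  # 120 seeds of Bin(n = 200, p = 0.05); chi-square goodness of fit on the
  # empirical count distribution, tails pooled to expected >= 5
  amp <- toy_amplicon(0, 10)
  bulk <- data.frame(locus = character(0), cpg_index = integer(0),
                     status = character(0),
                     methylated_fraction = numeric(0))
  counts <- vapply(1:120, function(seed) {
    cfg <- simulation_config(n_cells = 20, ploidy = 1,
                             amplicon_success_prob = 1,
                             allelic_dropout_prob = 0,
                             conversion_failure_rate = 0.05,
                             overconversion_rate = 0, seed = seed)
    sim <- simulate_experiment(amp, bulk, cfg)
    sum(sim$ledger$event_kind == "CONVERSION_FAILURE")
  }, 1)
  n <- 200; p <- 0.05
  probs <- stats::dbinom(0:n, n, p)
  # pool bins so every expected count is >= 5
  brk <- c(-1, 5, 7, 9, 11, 14, n)
  obs <- table(cut(counts, brk))
  expctd <- 120 * vapply(seq_len(length(brk) - 1), function(i)
    sum(probs[(0:n) > brk[i] & (0:n) <= brk[i + 1]]), 1)
  stat <- sum((as.numeric(obs) - expctd)^2 / expctd)
  pval <- stats::pchisq(stat, df = length(expctd) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("every Y in a noise-free diploid read marks a ledgered allele disagreement", {
  amp <- toy_amplicon(3, 2)
  bulk <- uniform_bulk_profile("toy", 3, "METHYLATED")
  cfg <- simulation_config(n_cells = 50, ploidy = 2,
                           rate_demethylating = 0.3,
                           amplicon_success_prob = 1,
                           allelic_dropout_prob = 0,
                           conversion_failure_rate = 0,
                           overconversion_rate = 0, seed = 8)
  sim <- simulate_experiment(amp, bulk, cfg)
  flips <- sim$ledger[sim$ledger$event_kind == "DEMETHYLATING_EPIMUTATION", ]
  single_allele_flips <- with(flips, table(cell_id, position)) == 1
  for (h in names(sim$reads)) {
    cell <- sub("^cell:([^|]+).*$", "\\1", h)
    chars <- strsplit(sim$reads[[h]], "")[[1]]
    ypos <- which(chars == "Y") - 1L
    # every Y is at a CpG where exactly one allele flipped, and conversely
    expected_y <- flips$position[flips$cell_id == cell]
    expected_y <- as.integer(names(which(
      table(factor(expected_y, levels = amp$cpg_positions)) == 1)))
    expect_setequal(ypos, expected_y)
  }
})

test_that("the 5-Aza time course demethylates with cell divisions", {
  amp <- toy_amplicon(3, 2)
  bulk <- uniform_bulk_profile("toy", 3, "METHYLATED")
  cfg <- simulation_config(n_cells = 40, ploidy = 2,
                           amplicon_success_prob = 1,
                           allelic_dropout_prob = 0,
                           conversion_failure_rate = 0,
                           overconversion_rate = 0, seed = 21)
  tc <- simulate_aza_timecourse(amp, bulk, cfg, timepoints = c(0, 24, 48),
                                per_division_block_prob = 0.5,
                                generation_time_hours = 24)
  ref_m <- bisulfite_convert(amp$sequence, amp$cpg_positions)
  expect_true(all(tc$t0$reads == ref_m))

  # (1 - 0.5)^1 = 0.5 retention at 24 h: ~half of the 240 allele-CpGs lost
  lost <- sum(tc$t24$ledger$event_kind == "DEMETHYLATING_EPIMUTATION")
  expect_lt(abs(lost - 120), 3 * sqrt(240 * 0.25))

  # full blocking demethylates everything after one division
  tc1 <- simulate_aza_timecourse(amp, bulk, cfg, timepoints = 24,
                                 per_division_block_prob = 1)
  ref_u <- bisulfite_convert(amp$sequence)
  expect_true(all(tc1$t24$reads == ref_u))
  expect_error(simulate_aza_timecourse(amp, bulk, cfg, 24, 0.5,
                                       generation_time_hours = 0), "> 0")
})
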