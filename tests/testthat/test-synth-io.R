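# Synthetic generators, file round trips and the command-line interface.

test_that("the paralog-pair generator is deterministic and hits its targets", {
  g1 <- generate_paralog_pair(seed = 33)
  g2 <- generate_paralog_pair(seed = 33)
  expect_identical(g1, g2)
  tr <- g1$truth
  id <- pairwise_identity(g1$pair$a, g1$pair$b)
  expect_lt(abs(id$percent - 95), 1.01)
  expect_equal(id$percent, tr$expected_identity_percent, tolerance = 1e-9)
  # paper-like geometry: 24 CpGs in A, 21 in the B read window
  expect_length(tr$cpg_sites_a, 24)
  win <- c(tr$head_len + 1L, tr$length - tr$tail_len)
  expect_identical(sum(tr$cpg_sites_b >= win[1] & tr$cpg_sites_b <= win[2]), 21L)
  # markers survive conversion of both pure states
  for (pat in c("all_methylated", "all_unmethylated")) {
    d <- discover_discriminating_positions(g1$pair, pat)
    expect_true(all(tr$marker_a_positions %in% d$offset))
    expect_true(all(tr$marker_b_positions %in% d$offset))
  }
})

test_that("a 100%-identity request with no features returns an identical pair", {
  g <- generate_paralog_pair(seed = 4, target_identity = 100,
                             n_markers_per_paralog = 0, n_a_specific = 0,
                             n_b_specific = 0, include_cpg_shift = FALSE,
                             engineer_rev_mismatches = FALSE)
  expect_identical(g$pair$a, g$pair$b)
  expect_identical(g$truth$n_substitutions, 0L)
  expect_error(generate_paralog_pair(seed = 1, length = 40), ">= 50")
  expect_error(generate_paralog_pair(seed = 1, n_cpgs = 3), "infeasible")
})

test_that("standard sets carry the engineered truth at every level", {
  std <- generate_standard_set(fix_assay, paralog_ratio = 0.7, seed = 5)
  pos <- std$positions
  s0 <- std$standards[["0"]]
  raw0 <- methylation_from_pyrogram(s0$pyrograms[[1]], pos)$raw
  expect_equal(raw0, rep(0, length(raw0)), tolerance = 1e-9)
  s50 <- std$standards[["50"]]
  cp <- methylation_from_pyrogram(s50$pyrograms[[1]], pos)
  expect_equal(cp$raw[cp$specificity == "shared"],
               rep(50, sum(cp$specificity == "shared")), tolerance = 1e-9)
  # melt curves sit between the pure species and shift up with methylation
  f75 <- std$standards[["75"]]$melt$fluorescence
  f25 <- std$standards[["25"]]$melt$fluorescence
  expect_true(mean(f75) > mean(f25))
  # pure-A standard set recovers a proportion of 100
  stdA <- generate_standard_set(fix_assay, levels = 100, paralog_ratio = 1,
                                seed = 6)
  est <- estimate_paralog_proportion(stdA$standards[["100"]]$pyrograms[[1]],
                                     pos)
  expect_equal(est$p_a, 100, tolerance = 1e-9)
})

test_that("FASTA, peak-table and melt-curve writers round-trip losslessly", {
  td <- withr::local_tempdir()
  set.seed(41)
  seqs <- setNames(vapply(1:10, function(i) random_dna(sample(20:80, 1)), ""),
                   paste0("s", 1:10))
  fp <- file.path(td, "x.fasta")
  write_fasta(seqs, fp)
  expect_identical(read_fasta(fp), seqs)
  # lowercase is uppercased with a warning
  writeLines(c(">lc", "acgtacgtacgt"), file.path(td, "lc.fasta"))
  expect_warning(lc <- read_fasta(file.path(td, "lc.fasta")), "uppercased")
  expect_identical(unname(lc), "ACGTACGTACGT")
  # peak tables
  pyr <- std_pyrogram(0.5, 50)
  pp <- file.path(td, "peaks.tsv")
  write_peaks_tsv(pyr, pp)
  back <- read_peaks_tsv(pp)
  expect_identical(back$dispensation, pyr$dispensation)
  expect_equal(back$heights, pyr$heights, tolerance = 1e-12)
  # negative heights are rejected with the line number
  tab <- read.delim(pp)
  tab$height[3] <- -1
  write.table(tab, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_peaks_tsv(pp), "line 4")
  # melt curves
  curves <- list(a = level_curve(0), b = level_curve(50))
  curves$a$sample_id <- "a"; curves$b$sample_id <- "b"
  mp <- file.path(td, "melt.tsv")
  write_melt_tsv(curves, mp)
  back <- read_melt_tsv(mp)
  expect_equal(back$a$fluorescence, curves$a$fluorescence, tolerance = 1e-12)
  expect_equal(back$b$temperature, curves$b$temperature, tolerance = 1e-12)
})

test_that("assay configurations and calibration models survive JSON", {
  td <- withr::local_tempdir()
  cp <- file.path(td, "assay.json")
  write_assay_config(fix_assay, cp)
  cfg <- read_assay_config(cp)
  expect_identical(cfg$primers$forward, fix_assay$primers$forward)
  expect_identical(cfg$pair$a, fix_assay$pair$a)
  expect_identical(cfg$read_windows, fix_assay$read_windows)
  expect_identical(map_dispensation_positions(cfg)$read_offset,
                   fix_positions$read_offset)
  model <- fit_calibration(level_standards())
  mp <- file.path(td, "cal.json")
  write_calibration(model, mp)
  m2 <- read_calibration(mp)
  expect_equal(m2$coefficients, model$coefficients, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(quantify_sample(level_curve(40), m2)$estimate, 40,
               tolerance = 1e-6)
})

test_that("the CLI drives the full fixture-simulate-analyze-call loop", {
  td <- withr::local_tempdir()
  expect_identical(quiet_cli(c("make-fixtures", "--seed", "5", "--out", td)), 0L)
  cfgp <- file.path(td, "assay.json")
  expect_true(file.exists(cfgp))
  expect_identical(quiet_cli(c("simulate", "--config", cfgp, "--out", td,
                              "--paralog-ratio", "0.85", "--seed", "3")), 0L)
  st <- quiet_cli(c("analyze-psq", "--config", cfgp,
                   "--peaks", file.path(td, "peaks_75_S1.tsv"),
                   "--out", file.path(td, "res.tsv"),
                   "--json", file.path(td, "res.json")))
  expect_identical(st, 0L)
  res <- jsonlite::read_json(file.path(td, "res.json"), simplifyVector = TRUE)
  expect_equal(res$proportion$p_a, 85, tolerance = 1e-6)
  tab <- read.delim(file.path(td, "res.tsv"), na.strings = "n.a.")
  expect_true(all(abs(tab$corrected[tab$specificity != "shared"] - 75) < 1e-6,
                  na.rm = TRUE))
  # assay-check exits 0 on the healthy config
  expect_identical(quiet_cli(c("assay-check", "--config", cfgp,
                              "--out", file.path(td, "report.tsv"))), 0L)
  # HRM fit/call on the simulated standards
  mm <- read.delim(file.path(td, "melt.tsv"), check.names = FALSE)
  names(mm) <- sub("^std_", "", names(mm))
  write.table(mm, file.path(td, "melt2.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_identical(quiet_cli(c("hrm-fit", "--melt", file.path(td, "melt2.tsv"),
                              "--out", file.path(td, "cal.json"))), 0L)
  expect_identical(quiet_cli(c("hrm-call", "--melt", file.path(td, "melt2.tsv"),
                              "--model", file.path(td, "cal.json"),
                              "--out", file.path(td, "calls.tsv"))), 0L)
  calls <- read.delim(file.path(td, "calls.tsv"))
  expect_equal(calls$methylation_percent[calls$sample == 50], 50,
               tolerance = 0.01)
  # bisulfite conversion round trip through FASTA
  fa <- file.path(td, "in.fasta")
  write_fasta(c(x = "ACGTCCGT"), fa)
  expect_identical(quiet_cli(c("bisconvert", "--in", fa, "--out",
                              file.path(td, "conv.fasta"), "--methylated")), 0L)
  expect_identical(unname(read_fasta(file.path(td, "conv.fasta"))), "ACGTTCGT")
  # unknown subcommands and errors exit non-zero
  expect_identical(quiet_cli("frobnicate"), 1L)
  expect_identical(quiet_cli(c("analyze-psq", "--config", "/nonexistent.json",
                              "--peaks", "x")), 1L)
})
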