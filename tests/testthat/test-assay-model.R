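# Assay model: discriminating-position discovery, dispensation position
# mapping, and configuration validation.

test_that("identical paralogs have no discriminating positions", {
  p <- paralog_pair("AATCGATTACGA", "AATCGATTACGA")
  expect_identical(nrow(discover_discriminating_positions(p)), 0L)
})

test_that("a single differing column is found and classified", {
  p <- paralog_pair("AATAGATT", "AATCGATT")  # A vs C at column 4
  d <- discover_discriminating_positions(p, "all_methylated")
  expect_identical(d$offset, 4L)
  expect_identical(d$base_a, "A")
  expect_identical(d$classification, "a_specific_base")
  expect_error(discover_discriminating_positions(p, window = c(0, 8)),
               "window")
})

test_that("engineered marker and shift columns are discovered with their classes", {
  gen <- generate_paralog_pair(seed = 7, n_cpgs = 6, n_a_specific = 0,
                               n_b_specific = 0, include_cpg_shift = TRUE,
                               engineer_rev_mismatches = FALSE,
                               target_identity = 98)
  d <- discover_discriminating_positions(gen$pair, "all_methylated")
  tr <- gen$truth
  a_cols <- d$offset[d$classification == "a_specific_base"]
  b_cols <- d$offset[d$classification == "b_specific_base"]
  s_cols <- d$offset[d$classification == "cpg_shift"]
  expect_identical(a_cols, tr$marker_a_positions)
  expect_identical(b_cols, tr$marker_b_positions)
  expect_true(all(s_cols >= tr$shift_positions &
                  s_cols <= tr$shift_positions + 2L))
  expect_gte(length(s_cols), 1L)
})

test_that("position mapping is a pure function of the configuration", {
  p1 <- map_dispensation_positions(fix_assay)
  p2 <- map_dispensation_positions(fix_assay)
  expect_identical(p1, p2)
})

test_that("a toy one-CpG assay maps the C/T slots with CpG number 1/1", {
  s <- "AAGGTATTACGTATTAAGGA"
  cfg <- assay_config("toy", primers = list(forward = "AAGGT",
                                            reverse = revcomp("TAAGGA"),
                                            sequencing = "AAGGTATT"),
                      pair = paralog_pair(s, s),
                      read_windows = list(c(9L, 14L)))
  pos <- map_dispensation_positions(cfg)
  cp <- pos[pos$kind == "cpg", ]
  expect_identical(nrow(cp), 1L)
  expect_identical(cp$specificity, "shared")
  expect_identical(cp$cpg_number_a, 1L)
  expect_identical(cp$cpg_number_b, 1L)
  expect_true(cp$usable)
  disp <- attr(pos, "dispensations")[[1]]
  # the variant/reference slots dispense C and T respectively
  expect_identical(substr(disp, cp$variant_slots[[1]], cp$variant_slots[[1]]), "C")
  expect_identical(substr(disp, cp$reference_slots[[1]], cp$reference_slots[[1]]), "T")
})

test_that("a dispensation that never consumes the read reports the stall", {
  s <- "AAGGTATTACGTATTAAGGA"
  cfg <- assay_config("stall", primers = list(forward = "AAGGT",
                                              reverse = revcomp("TAAGGA"),
                                              sequencing = "AAGGTATT"),
                      pair = paralog_pair(s, s),
                      read_windows = list(c(9L, 14L)),
                      dispensations = list("ACG"))
  expect_error(map_dispensation_positions(cfg), "stalls at read position")
})

test_that("single-template exact dispensation yields no variable positions", {
  s <- "AAGTATTAGTATTAAGGA"  # no CpG: methylated and unmethylated reads equal
  cfg <- assay_config("flat", primers = list(forward = "AAGT",
                                             reverse = revcomp("TAAGGA"),
                                             sequencing = "AAGTA"),
                      region = s, read_windows = list(c(6L, 12L)))
  pos <- map_dispensation_positions(cfg)
  expect_identical(nrow(pos), 0L)
})

test_that("every sequenced discriminating column appears in the position map", {
  d_m <- discover_discriminating_positions(fix_gen$pair, "all_methylated")
  d_u <- discover_discriminating_positions(fix_gen$pair, "all_unmethylated")
  cols <- sort(unique(c(d_m$offset, d_u$offset)))
  cols <- cols[cols >= fix_window[1] & cols <= fix_window[2]]
  mapped <- sort(unique(fix_positions$read_offset + fix_window[1] - 1L))
  expect_true(all(cols %in% mapped))
})

test_that("a pair with no post-conversion differences cannot be deconvolved", {
  gen <- generate_paralog_pair(seed = 3, target_identity = 100,
                               n_markers_per_paralog = 0, n_a_specific = 0,
                               n_b_specific = 0, include_cpg_shift = FALSE,
                               engineer_rev_mismatches = FALSE)
  expect_identical(gen$pair$a, gen$pair$b)
  cfg <- make_synthetic_assay(gen)
  pos <- map_dispensation_positions(cfg)
  expect_identical(sum(pos$kind == "paralog_marker"), 0L)
  pyr <- simulate_pyrogram(
    template_mix(paralogmeth:::assay_reads(cfg, 1), rep(0.25, 4)),
    attr(pos, "dispensations")[[1]])
  expect_error(estimate_paralog_proportion(pyr, pos), "impossible")
})

test_that("validate_assay reports engineered mismatches and soft failures", {
  rep <- validate_assay(fix_assay)
  expect_false(any(rep$status == "fail"))
  lab <- fix_gen$pair$labels
  met <- rep$detail[rep$check == paste0("reverse_primer_on_", lab[2], "_methylated")]
  unm <- rep$detail[rep$check == paste0("reverse_primer_on_", lab[2], "_unmethylated")]
  expect_match(met, "3 mismatch")
  expect_match(unm, "1 mismatch")
  # missing sequencing primer is a failure entry, not an error
  broken <- fix_assay
  broken$primers$sequencing <- character(0)
  broken$read_windows <- list()
  rep2 <- validate_assay(broken)
  expect_identical(rep2$status[rep2$check == "sequencing_primer_present"], "fail")
  # single-region (promoter-style) assay skips the marker checks
  reg <- generate_single_region(21)
  rep3 <- validate_assay(make_synthetic_region_assay(reg))
  expect_identical(rep3$status[rep3$check == "paralog_markers"], "skipped")
  expect_false(any(rep3$status == "fail"))
  # primer-only built-in configurations skip sequence-dependent checks
  rep4 <- validate_assay(cdkn2a_exon2_assay())
  expect_true(any(rep4$status == "skipped"))
  expect_error(validate_assay(list()), "malformed")
})
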