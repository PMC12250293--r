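# Accession-tier validation: reproduces the published sequence-level
# characteristics of the CDKN2A/CDKN2B assays from user-supplied reference
# FASTA files (GRCh38 chr9 and RefSeq transcripts). No sequences ship with
# the package and nothing is downloaded; all checks are optional and the
# synthetic fixtures cover the same machinery desk-side.

#' Parse an NCBI-style region descriptor
#'
#' `"NC_000009.12:c21970915-21971191"`: the `c` prefix marks the minus
#' (complement) strand; coordinates are 1-based inclusive.
#'
#' @param x Region string.
#' @return List with `seqname`, `start`, `end`, `strand`.
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):(c?)(\\d+)[-–](\\d+)$", x))[[1]]
  if (length(m) != 5L) stop("cannot parse region descriptor: ", x, call. = FALSE)
  start <- as.numeric(m[4])
  end <- as.numeric(m[5])
  list(seqname = m[2], start = min(start, end), end = max(start, end),
       strand = if (m[3] == "c") "minus" else "plus")
}

#' Extract a region from reference sequences
#'
#' Returns the region's sequence 5'->3' on its own strand (minus-strand
#' regions are reverse-complemented), which for the methylation assays is
#' the strand that is bisulfite-converted and sequenced.
#'
#' @param seqs Named character vector (e.g. from [read_fasta()]); names are
#'   matched against the region's sequence name by prefix.
#' @param region Region string or [parse_region()] result.
#' @return Sequence string.
#' @export
extract_region <- function(seqs, region) {
  if (is.character(region)) region <- parse_region(region)
  hit <- which(startsWith(names(seqs), region$seqname) |
               vapply(names(seqs), function(n)
                 startsWith(region$seqname, strsplit(n, "[ ]")[[1]][1]),
                 logical(1)))
  if (length(hit) == 0L)
    stop("sequence ", region$seqname, " not found in FASTA", call. = FALSE)
  s <- substr(seqs[[hit[1]]], region$start, region$end)
  if (nchar(s) != region$end - region$start + 1L)
    stop("region ", region$seqname, ":", region$start, "-", region$end,
         " extends beyond the supplied sequence", call. = FALSE)
  if (region$strand == "minus") revcomp(s) else s
}

#' Validate the assays against reference sequences
#'
#' Recomputes the published sequence-level characteristics of the exon 2 and
#' promoter assays from user-supplied reference FASTA: target-region identity
#' of the unconverted and bisulfite-converted paralogs, predicted amplicon
#' lengths, GC content of the converted amplicons, CpG counts, and
#' reverse-primer mismatches on the B paralog. When a transcript FASTA is
#' given, additionally predicts the exon-boundary RT-PCR product of the
#' p16(INK4a) transcript.
#'
#' @param genome_fasta Path to a FASTA containing GRCh38 chromosome 9 (or at
#'   least the two target regions under the accession name `NC_000009.12`).
#' @param transcripts_fasta Optional path to a RefSeq transcript FASTA
#'   (e.g. `NM_000077.5`).
#' @return data.frame of class `accession_report` with `metric`, `value` and
#'   `expected` (the published characteristic).
#' @export
accession_validation <- function(genome_fasta, transcripts_fasta = NULL) {
  seqs <- read_fasta(genome_fasta)
  cfg <- cdkn2a_exon2_assay()
  reg_a <- extract_region(seqs, cfg$regions[["CDKN2A"]])
  reg_b <- extract_region(seqs, cfg$regions[["CDKN2B"]])

  res <- list()
  add <- function(metric, value, expected) {
    res[[length(res) + 1L]] <<- data.frame(metric = metric, value = value,
                                           expected = expected,
                                           stringsAsFactors = FALSE)
  }
  add("cpg_count_CDKN2A_region", length(find_cpg_sites(reg_a)), 35)

  # amplicons on the converted paralogs (methylation primers target the
  # converted strand); lengths are conversion-invariant
  conv_a_m <- bisulfite_convert(reg_a, "all_methylated")
  conv_a_u <- bisulfite_convert(reg_a, "all_unmethylated")
  conv_b_m <- bisulfite_convert(reg_b, "all_methylated")
  conv_b_u <- bisulfite_convert(reg_b, "all_unmethylated")
  amp_a <- predict_amplicon(cfg$primers$forward, cfg$primers$reverse,
                            conv_a_u, max_mismatch = 3L)
  add("exon2_amplicon_bp_CDKN2A",
      if (nrow(amp_a)) amp_a$length[1] else NA_real_, 230)
  if (nrow(amp_a)) {
    amp_seq_u <- amp_a$sequence[1]
    amp_am <- predict_amplicon(cfg$primers$forward, cfg$primers$reverse,
                               conv_a_m, max_mismatch = 3L)
    amp_b <- predict_amplicon(cfg$primers$forward, cfg$primers$reverse,
                              conv_b_u, max_mismatch = 3L)
    if (nrow(amp_am))
      add("gc_percent_methylated_CDKN2A_amplicon",
          gc_fraction(amp_am$sequence[1]), 48.7)
    if (nrow(amp_b)) {
      amp_bm <- predict_amplicon(cfg$primers$forward, cfg$primers$reverse,
                                 conv_b_m, max_mismatch = 3L)
      if (nrow(amp_bm))
        add("gc_percent_methylated_CDKN2B_amplicon",
            gc_fraction(amp_bm$sequence[1]), 47.8)
      # identity over the unconverted and converted target regions
      raw_a <- substr(reg_a, amp_a$start[1], amp_a$end[1])
      raw_b <- substr(reg_b, amp_b$start[1], amp_b$end[1])
      add("target_identity_percent_unconverted",
          pairwise_identity(raw_a, raw_b)$percent, 95)
      if (nrow(amp_bm) && nrow(amp_am))
        add("target_identity_percent_converted_methylated",
            pairwise_identity(amp_am$sequence[1], amp_bm$sequence[1])$percent, 98)
      add("target_identity_percent_converted_unmethylated",
          pairwise_identity(amp_seq_u, amp_b$sequence[1])$percent, 96)
    }
  }
  # reverse-primer mismatches on converted CDKN2B
  for (state in c("unmethylated", "methylated")) {
    tmpl <- if (state == "methylated") conv_b_m else conv_b_u
    hits <- match_primer(cfg$primers$reverse, tmpl, "minus", max_mismatch = 6L)
    add(paste0("rev_primer_mismatches_CDKN2B_", state),
        if (nrow(hits)) min(hits$mismatch_count) else NA_real_,
        if (state == "methylated") 3 else 1)
  }

  if (!is.null(transcripts_fasta)) {
    tr <- read_fasta(transcripts_fasta)
    hit <- grep("NM_000077", names(tr))
    if (length(hit)) {
      # exon 1alpha - exon 3 boundary primer set on the p16 transcript
      amp <- predict_amplicon("GATCCAGACATCCCCGATTG", "CCTGTAGGACCTTCGGTGA",
                              tr[[hit[1]]], max_mismatch = 0L)
      add("transcript_set3_product_bp_NM_000077",
          if (nrow(amp)) amp$length[1] else NA_real_, 95)
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("accession_report", "data.frame")
  out
}
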