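# Assay model: which pyrogram positions are CpGs, paralog markers or CpG
# shifts, and how dispensation slots map onto per-paralog CpG numbers. The
# central object is the assay configuration (primers, dispensation orders,
# target sequences); the central operation is map_dispensation_positions(),
# which simulates noiseless sequencing of the four pure templates
# (paralog x methylation state) and classifies every position where their
# expected peak patterns differ.

#' Pair of homologous paralog sequences over one assay window
#'
#' @param a,b Sequences of the two paralogs over the same assay window (the
#'   converted-and-sequenced strand, unconverted bases). Must be the same
#'   length: the pair is assumed to align without indels, as holds for
#'   substitution-derived paralogs over a short amplicon.
#' @param labels Character vector of two distinct labels, e.g.
#'   `c("CDKN2A", "CDKN2B")`.
#' @return Object of class `paralog_pair`.
#' @export
paralog_pair <- function(a, b, labels = c("A", "B")) {
  a <- check_seq(a)
  b <- check_seq(b)
  if (length(labels) != 2L || anyDuplicated(labels))
    stop("two distinct paralog labels are required", call. = FALSE)
  structure(list(a = a, b = b, labels = as.character(labels)),
            class = "paralog_pair")
}

# Columns involved in a CpG position shift: a CpG private to one paralog
# whose C sits directly next to a CpG C private to the other paralog. The
# run-length structure at such columns entangles the two paralogs (the
# paper-motivating case is one G in one paralog vs two Gs in the other), so
# they are mapped but excluded from proportion estimation.
shift_columns <- function(a, b) {
  ca <- find_cpg_sites(a)
  cb <- find_cpg_sites(b)
  only_a <- setdiff(ca, cb)
  only_b <- setdiff(cb, ca)
  out <- integer(0)
  for (p in only_a) {
    for (q in c(p - 1L, p + 1L)) {
      if (q %in% only_b) out <- c(out, min(p, q):(max(p, q) + 1L))
    }
  }
  sort(unique(out))
}

#' Discriminating positions between two converted paralogs
#'
#' Bisulfite-converts both paralogs under the given methylation patterns and
#' reports every column where the converted bases differ, classified as
#' `a_specific_base`, `b_specific_base` or `cpg_shift`. Columns inside a CpG
#' position shift are recognized from the unconverted pair; otherwise a column
#' is attributed to the paralog carrying the conversion-robust (purine) or
#' methylation-retained (C) base.
#'
#' @param pair A [paralog_pair()].
#' @param pattern_a,pattern_b Methylation patterns passed to
#'   [bisulfite_convert()] for each paralog.
#' @param window Optional `c(start, end)` restricting the comparison (1-based,
#'   inclusive); default the full pair.
#' @return data.frame with `offset` (1-based column), `base_a`, `base_b`,
#'   `classification`. Zero rows for identical converted sequences.
#' @export
discover_discriminating_positions <- function(pair,
                                              pattern_a = "all_methylated",
                                              pattern_b = pattern_a,
                                              window = NULL) {
  stopifnot(inherits(pair, "paralog_pair"))
  if (nchar(pair$a) != nchar(pair$b))
    stop("paralog sequences must have equal length (no-indel window)",
         call. = FALSE)
  ca <- bisulfite_convert(pair$a, pattern_a)
  cb <- bisulfite_convert(pair$b, pattern_b)
  win <- window %||% c(1L, nchar(ca))
  if (win[1] < 1L || win[2] > nchar(ca) || win[1] > win[2])
    stop("window outside the paralog sequences", call. = FALSE)
  ba <- seq_chars(ca)
  bb <- seq_chars(cb)
  cols <- which(ba != bb)
  cols <- cols[cols >= win[1] & cols <= win[2]]
  shift <- shift_columns(pair$a, pair$b)
  classify <- function(j) {
    x <- ba[j]
    y <- bb[j]
    if (j %in% shift) return("cpg_shift")
    pur_x <- x %in% c("A", "G")
    pur_y <- y %in% c("A", "G")
    if (pur_x && !pur_y) return("a_specific_base")
    if (pur_y && !pur_x) return("b_specific_base")
    if (pur_x && pur_y) return(if (y == "A" && x != "A") "b_specific_base" else "a_specific_base")
    # both pyrimidines and different: one of them is a retained methyl-C
    if (x == "C") "a_specific_base" else "b_specific_base"
  }
  data.frame(offset = cols,
             base_a = ba[cols],
             base_b = bb[cols],
             classification = vapply(cols, classify, ""),
             stringsAsFactors = FALSE)
}

#' Assay configuration
#'
#' Bundles the target (a [paralog_pair()] or a single region), the PCR and
#' sequencing primers, per-sequencing-primer read windows on the assay strand
#' and (optionally fixed) dispensation orders. Built-in configurations for the
#' CDKN2A(INK4a) promoter and the CDKN2A/CDKN2B exon 2 assays are provided by
#' [cdkn2a_promoter_assay()] and [cdkn2a_exon2_assay()].
#'
#' @param name Assay name.
#' @param primers List with `forward`, `reverse` (both 5'->3'; the reverse
#'   primer is the biotinylated one) and `sequencing`, a character vector of
#'   1-2 sequencing primers.
#' @param pair Optional [paralog_pair()] target.
#' @param region Optional single target sequence (promoter-style assay).
#' @param read_windows List of `c(start, end)` windows (1-based on the assay
#'   strand), one per sequencing primer: the stretch read after that primer.
#' @param dispensations Optional list of dispensation order strings, one per
#'   sequencing primer; characters outside `A,C,G,T` are stripped on ingest.
#'   `NULL` entries are auto-designed by [design_dispensation()].
#' @param regions Optional named character vector of genomic region
#'   descriptors (e.g. `"NC_000009.12:c21970915-21971191"`) for provenance.
#' @param params An [analysis_params()] object.
#' @return Object of class `assay_config`.
#' @export
assay_config <- function(name, primers, pair = NULL, region = NULL,
                         read_windows = list(), dispensations = NULL,
                         regions = NULL, params = analysis_params()) {
  if (!is.list(primers))
    stop("malformed config: 'primers' must be a list", call. = FALSE)
  if (!is.null(pair) && !inherits(pair, "paralog_pair"))
    stop("malformed config: 'pair' must be a paralog_pair", call. = FALSE)
  if (!is.null(pair) && !is.null(region))
    stop("malformed config: give either a pair or a single region", call. = FALSE)
  if (!is.null(region)) region <- check_seq(region)
  nseq <- length(primers$sequencing %||% character(0))
  if (length(read_windows) && length(read_windows) != nseq)
    stop("malformed config: one read window per sequencing primer", call. = FALSE)
  if (!is.null(dispensations)) {
    if (length(dispensations) != nseq)
      stop("malformed config: one dispensation order per sequencing primer",
           call. = FALSE)
    dispensations <- lapply(dispensations, function(d)
      if (is.null(d) || is.na(d)) NULL else clean_dispensation(d))
  } else {
    dispensations <- vector("list", nseq)
  }
  structure(list(name = name, primers = primers, pair = pair, region = region,
                 read_windows = read_windows, dispensations = dispensations,
                 regions = regions, params = params),
            class = "assay_config")
}

has_target_sequence <- function(config) {
  !is.null(config$pair) || !is.null(config$region)
}

# Converted template reads downstream of sequencing primer i, one per pure
# template (paralog x methylation state for a pair; methylation state only for
# a single region). Conversion is applied to the full assay sequence first so
# CpG context at the window edges is respected.
assay_reads <- function(config, i) {
  win <- config$read_windows[[i]]
  cut <- function(s) substr(s, win[1], win[2])
  if (!is.null(config$pair)) {
    c(aM = cut(bisulfite_convert(config$pair$a, "all_methylated")),
      aU = cut(bisulfite_convert(config$pair$a, "all_unmethylated")),
      bM = cut(bisulfite_convert(config$pair$b, "all_methylated")),
      bU = cut(bisulfite_convert(config$pair$b, "all_unmethylated")))
  } else {
    c(M = cut(bisulfite_convert(config$region, "all_methylated")),
      U = cut(bisulfite_convert(config$region, "all_unmethylated")))
  }
}

#' Map dispensation slots to variable pyrogram positions
#'
#' Simulates noiseless sequencing of each pure template (paralog x fully
#' methylated / fully unmethylated) under the assay's dispensation orders and
#' identifies every read column whose expected peak pattern differs across
#' templates. Each variable column becomes one position-to-analyze ("pos N",
#' numbered 1-based per sequencing primer in read order) and emits one or more
#' rows:
#'
#' * `kind = "cpg"`: a methylation-sensitive C/T position, with per-paralog
#'   CpG ordinals and `specificity` `"shared"`, `"a_specific"` or
#'   `"b_specific"`; `variant_slots` hold the C signal, `reference_slots` all
#'   other signal at the column (so the raw level of a paralog-specific CpG is
#'   diluted by the other paralog, as on the instrument).
#' * `kind = "paralog_marker"`: a conversion-invariant base private to one
#'   paralog (`marker_for`); its peak fraction estimates that paralog's
#'   proportion in the product pool.
#' * `kind = "cpg_shift"`: a shifted-CpG column; mapped for inspection but
#'   flagged unusable and never used for proportion estimation.
#'
#' Rows whose quantification slots also receive signal from other read
#' columns (a sequencing frameshift the dispensation order failed to absorb)
#' are flagged `usable = FALSE`.
#'
#' @param config An [assay_config()] with target sequences.
#' @return data.frame of class `variable_positions` with columns
#'   `seq_primer`, `pyrogram_index`, `read_offset`, `kind`, `marker_for`,
#'   `specificity`, `cpg_number_a`, `cpg_number_b`, list columns
#'   `variant_slots` / `reference_slots`, and `usable`; the dispensation
#'   orders actually used are in `attr(, "dispensations")`.
#' @export
map_dispensation_positions <- function(config) {
  stopifnot(inherits(config, "assay_config"))
  if (!has_target_sequence(config))
    stop("config carries no target sequences; attach a pair or region first",
         call. = FALSE)
  is_pair <- !is.null(config$pair)
  disps <- list()
  rows <- list()
  for (i in seq_along(config$read_windows)) {
    reads <- assay_reads(config, i)
    if (length(unique(nchar(reads))) != 1L)
      stop("template reads differ in length; no-indel alignment required",
           call. = FALSE)
    disp <- config$dispensations[[i]] %||% design_dispensation(reads)
    disps[[i]] <- disp
    walks <- lapply(reads, walk_template, disp = disp)
    for (nm in names(walks)) {
      if (!walks[[nm]]$consumed)
        stop("dispensation order for sequencing primer ", i,
             " stalls at read position ", walks[[nm]]$stall,
             " of template ", nm, call. = FALSE)
    }
    L <- nchar(reads[[1L]])
    basem <- do.call(rbind, strsplit(reads, "", fixed = TRUE))
    slotm <- do.call(rbind, lapply(walks, function(w) w$slot_of))
    rownames(basem) <- rownames(slotm) <- names(reads)
    varcols <- which(vapply(seq_len(L), function(j)
      length(unique(basem[, j])) > 1L, logical(1)))
    win <- config$read_windows[[i]]
    if (is_pair) {
      shift_full <- shift_columns(config$pair$a, config$pair$b)
      shift <- shift_full[shift_full >= win[1] & shift_full <= win[2]] - win[1] + 1L
      sites_a <- find_cpg_sites(config$pair$a)
      sites_b <- find_cpg_sites(config$pair$b)
    } else {
      shift <- integer(0)
      sites_r <- find_cpg_sites(config$region)
    }
    # TRUE when any template maps a read column other than j onto the slots
    collides <- function(slots, j) {
      any(vapply(seq_len(nrow(slotm)), function(t)
        any(slotm[t, -j] %in% slots), logical(1)))
    }
    posno <- 0L
    for (j in varcols) {
      posno <- posno + 1L
      j_full <- win[1] + j - 1L
      emit <- function(kind, marker_for = NA_character_,
                       specificity = NA_character_,
                       cpg_a = NA_integer_, cpg_b = NA_integer_,
                       variant = integer(0), reference = integer(0),
                       usable = TRUE) {
        rows[[length(rows) + 1L]] <<- data.frame(
          seq_primer = i, pyrogram_index = posno, read_offset = j,
          kind = kind, marker_for = marker_for, specificity = specificity,
          cpg_number_a = cpg_a, cpg_number_b = cpg_b,
          variant_slots = I(list(as.integer(variant))),
          reference_slots = I(list(as.integer(reference))),
          usable = usable, stringsAsFactors = FALSE)
      }
      if (is_pair) {
        bj <- basem[, j]
        sj <- slotm[, j]
        if (j %in% shift) {
          emit("cpg_shift", variant = unique(sj), usable = FALSE)
          next
        }
        a_idx <- c("aM", "aU")
        b_idx <- c("bM", "bU")
        # paralog markers: conversion-invariant base private to one paralog
        if (bj[["aM"]] == bj[["aU"]] && !(bj[["aM"]] %in% bj[b_idx])) {
          v <- unique(sj[a_idx])
          r <- unique(sj[b_idx])
          emit("paralog_marker", marker_for = "A", variant = v, reference = r,
               usable = !collides(c(v, r), j))
        }
        if (bj[["bM"]] == bj[["bU"]] && !(bj[["bM"]] %in% bj[a_idx])) {
          v <- unique(sj[b_idx])
          r <- unique(sj[a_idx])
          emit("paralog_marker", marker_for = "B", variant = v, reference = r,
               usable = !collides(c(v, r), j))
        }
        # CpG positions: C (methylated) vs T (unmethylated) within a paralog
        a_var <- bj[["aM"]] == "C" && bj[["aU"]] == "T"
        b_var <- bj[["bM"]] == "C" && bj[["bU"]] == "T"
        if (a_var || b_var) {
          v <- unique(sj[bj == "C"])
          r <- unique(sj[bj != "C"])
          spec <- if (a_var && b_var) "shared" else if (a_var) "a_specific" else "b_specific"
          emit("cpg", specificity = spec,
               cpg_a = if (a_var) match(j_full, sites_a) else NA_integer_,
               cpg_b = if (b_var) match(j_full, sites_b) else NA_integer_,
               variant = v, reference = r,
               usable = !collides(c(v, r), j))
        }
      } else {
        bj <- basem[, j]
        sj <- slotm[, j]
        if (bj[["M"]] == "C" && bj[["U"]] == "T") {
          v <- unique(sj[bj == "C"])
          r <- unique(sj[bj != "C"])
          emit("cpg", specificity = "single",
               cpg_a = match(j_full, sites_r),
               variant = v, reference = r,
               usable = !collides(c(v, r), j))
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_primer = integer(0), pyrogram_index = integer(0),
               read_offset = integer(0), kind = character(0),
               marker_for = character(0), specificity = character(0),
               cpg_number_a = integer(0), cpg_number_b = integer(0),
               variant_slots = I(list()), reference_slots = I(list()),
               usable = logical(0), stringsAsFactors = FALSE)
  attr(out, "dispensations") <- disps
  class(out) <- c("variable_positions", "data.frame")
  out
}

#' Validate an assay configuration
#'
#' Soft checks: primers present, primers locate on the converted templates
#' (with mismatch counts), every window CpG covered by a usable pyrogram
#' position, and at least one proportion marker per paralog. Failures are
#' reported as rows, never raised; only a malformed object errors.
#'
#' @param config An [assay_config()].
#' @param max_mismatch Mismatch budget for primer location checks.
#' @return data.frame of class `assay_report` with `check`, `status`
#'   (`"ok"`, `"fail"`, `"skipped"`) and `detail`.
#' @export
validate_assay <- function(config, max_mismatch = 3L) {
  if (!inherits(config, "assay_config"))
    stop("malformed config: not an assay_config", call. = FALSE)
  res <- list()
  add <- function(check, status, detail = "") {
    res[[length(res) + 1L]] <<- data.frame(check = check, status = status,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }
  for (p in c("forward", "reverse")) {
    if (is.null(config$primers[[p]]) || !nzchar(config$primers[[p]] %||% ""))
      add(paste0(p, "_primer_present"), "fail", "missing")
    else add(paste0(p, "_primer_present"), "ok")
  }
  nseq <- length(config$primers$sequencing %||% character(0))
  if (nseq < 1L) add("sequencing_primer_present", "fail", "missing")
  else add("sequencing_primer_present", "ok", paste(nseq, "primer(s)"))

  if (!has_target_sequence(config)) {
    add("primer_location", "skipped", "no target sequences attached")
    add("cpg_coverage", "skipped", "no target sequences attached")
    add("paralog_markers", "skipped", "no target sequences attached")
    out <- do.call(rbind, res)
    class(out) <- c("assay_report", "data.frame")
    return(out)
  }

  templates <- if (!is.null(config$pair)) {
    lab <- config$pair$labels
    setNames(list(bisulfite_convert(config$pair$a, "all_methylated"),
                  bisulfite_convert(config$pair$a, "all_unmethylated"),
                  bisulfite_convert(config$pair$b, "all_methylated"),
                  bisulfite_convert(config$pair$b, "all_unmethylated")),
             c(paste0(lab[1], "_methylated"), paste0(lab[1], "_unmethylated"),
               paste0(lab[2], "_methylated"), paste0(lab[2], "_unmethylated")))
  } else {
    list(region_methylated = bisulfite_convert(config$region, "all_methylated"),
         region_unmethylated = bisulfite_convert(config$region, "all_unmethylated"))
  }
  for (p in c("forward", "reverse")) {
    pr <- config$primers[[p]]
    if (is.null(pr) || !nzchar(pr)) next
    strand <- if (p == "forward") "plus" else "minus"
    for (tn in names(templates)) {
      hits <- match_primer(pr, templates[[tn]], strand, max_mismatch)
      if (nrow(hits) == 0L) {
        add(paste0(p, "_primer_on_", tn), "fail",
            paste("no site within", max_mismatch, "mismatches"))
      } else {
        add(paste0(p, "_primer_on_", tn), "ok",
            paste0("best site: ", min(hits$mismatch_count), " mismatch(es)"))
      }
    }
  }

  pos <- tryCatch(map_dispensation_positions(config), error = function(e) e)
  if (inherits(pos, "error")) {
    add("position_map", "fail", conditionMessage(pos))
  } else {
    add("position_map", "ok", paste(nrow(pos), "variable position rows"))
    # CpG coverage over the read windows
    covered_ok <- TRUE
    detail <- character(0)
    if (!is.null(config$pair)) {
      shift <- shift_columns(config$pair$a, config$pair$b)
      for (side in c("a", "b")) {
        sites <- find_cpg_sites(config$pair[[side]])
        in_win <- unlist(lapply(config$read_windows, function(w)
          which(sites >= w[1] & sites <= w[2])))
        # shifted CpGs are mapped as cpg_shift rows, not analyzable by design
        in_win <- setdiff(in_win, which(sites %in% shift))
        col <- paste0("cpg_number_", side)
        got <- sort(unique(pos[[col]][pos$kind == "cpg" & pos$usable]))
        missing <- setdiff(in_win, got)
        if (length(missing)) {
          covered_ok <- FALSE
          detail <- c(detail, paste0(config$pair$labels[(side == "b") + 1L],
                                     " CpG ", paste(missing, collapse = ",")))
        }
      }
    } else {
      sites <- find_cpg_sites(config$region)
      in_win <- unlist(lapply(config$read_windows, function(w)
        which(sites >= w[1] & sites <= w[2])))
      got <- sort(unique(pos$cpg_number_a[pos$kind == "cpg" & pos$usable]))
      missing <- setdiff(in_win, got)
      if (length(missing)) {
        covered_ok <- FALSE
        detail <- paste0("CpG ", paste(missing, collapse = ","))
      }
    }
    add("cpg_coverage", if (covered_ok) "ok" else "fail",
        paste(detail, collapse = "; "))
    if (!is.null(config$pair)) {
      mk <- pos[pos$kind == "paralog_marker" & pos$usable, , drop = FALSE]
      for (side in c("A", "B")) {
        n <- sum(mk$marker_for == side)
        add(paste0("marker_", side), if (n >= 1L) "ok" else "fail",
            paste(n, "marker position(s)"))
      }
    } else {
      add("paralog_markers", "skipped", "single-region assay")
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("assay_report", "data.frame")
  out
}

#' Built-in assay: CDKN2A(INK4a) promoter
#'
#' Primers, dispensation order and target-region descriptor of the
#' promoter methylation assay (7 CpGs upstream of exon 1-alpha; 75 bp
#' product). Ships without genomic sequence; attach one via the `region`
#' argument of [assay_config()] fields before sequence-dependent operations.
#'
#' @return An [assay_config()] without target sequence.
#' @export
cdkn2a_promoter_assay <- function() {
  assay_config(
    name = "CDKN2A_INK4a_promoter",
    primers = list(
      forward = "GAGGGGTTGGTTGGTTATTAG",
      reverse = "TACCTACTCTCCCCCTCTC",
      sequencing = "GGTTGGTTGGTTATTAGA"),
    read_windows = list(),
    dispensations = NULL,
    regions = c(product_bp = "75"))
}

#' Built-in assay: CDKN2A/CDKN2B exon 2
#'
#' Primers, the two sequencing primers with their dispensation orders, and
#' the genomic region descriptors of the paralog-deconvolution assay
#' (CDKN2A exon 2 CpGs 1-24 co-amplified with CDKN2B exon 2 CpGs 1-21;
#' 230 bp product). Ships without genomic sequence.
#'
#' @return An [assay_config()] without target sequence.
#' @export
cdkn2a_exon2_assay <- function() {
  cfg <- assay_config(
    name = "CDKN2A_CDKN2B_exon2",
    primers = list(
      forward = "GTTTTTTTTGGTAGGTTATGATGATGG",
      reverse = "ACCCAACTCCTCAACCAAATCC",
      sequencing = c("AGGTTATGATGATGGGTA", "GGGAGGGTTTTTTGGATA")),
    read_windows = list(),
    dispensations = NULL,
    regions = c(
      CDKN2A = "NC_000009.12:c21970915-21971191",
      CDKN2B = "NC_000009.12:c22005889-22006230",
      product_bp = "230"))
  cfg$dispensations <- list(
    clean_dispensation(paste0(
      "AGCTAGTCAGACTGTAGCTGAGCTGTGTGTTGTACTAGCTAGCTGAGTATATGCTAGTACGTATT",
      "CGTATTGTATCGTATCGTGATGACTGTACTGTAG-TCGAGTTGATGACTGTGTGTGTGTGATCAG",
      "TCGGCTAGCTGTGTACTGTAGCTAG-CTGATGTGGTCGTAGTCGTG")),
    clean_dispensation(
      "ACTGTGTGTGTGCTGTATCAGGTCGGCT-AGCTGTGTACTGTAGCTAGCTGATGTGGTCGTAGTCGTG"))
  cfg
}
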