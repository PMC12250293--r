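# File I/O: FASTA via Biostrings, peak tables and melt curves as TSV, assay
# configurations and results as JSON. Every writer/reader pair round-trips
# losslessly; malformed input errors with the offending line.

#' Read a FASTA file
#'
#' @param path FASTA file (multi-record allowed).
#' @return Named character vector of uppercase sequences. Lowercase input is
#'   uppercased with a warning.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  s <- as.character(x)
  if (any(grepl("[a-z]", s)))
    warning("lowercase bases uppercased on ingest", call. = FALSE)
  setNames(toupper(s), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a pyrogram as a peak table (TSV)
#'
#' Columns: `disp_index` (1-based), `nucleotide`, `height`.
#'
#' @param pyrogram A pyrogram.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_tsv <- function(pyrogram, path) {
  df <- data.frame(disp_index = seq_len(nchar(pyrogram$dispensation)),
                   nucleotide = seq_chars(pyrogram$dispensation),
                   height = pyrogram$heights)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak table (TSV) as a pyrogram
#'
#' @param path TSV with columns `disp_index`, `nucleotide`, `height`.
#' @return A `pyrogram` object.
#' @export
read_peaks_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("disp_index", "nucleotide", "height")
  if (!all(need %in% names(df)))
    stop("peak table must have columns disp_index, nucleotide, height",
         call. = FALSE)
  bad <- which(!is.finite(df$height) | df$height < 0)
  if (length(bad))
    stop("negative or non-numeric height at line ", bad[1] + 1L, call. = FALSE)
  if (!identical(as.integer(df$disp_index), seq_len(nrow(df))))
    stop("disp_index must run 1..n", call. = FALSE)
  bad_nt <- which(!df$nucleotide %in% c("A", "C", "G", "T"))
  if (length(bad_nt))
    stop("invalid nucleotide at line ", bad_nt[1] + 1L, call. = FALSE)
  structure(list(dispensation = paste(df$nucleotide, collapse = ""),
                 heights = as.numeric(df$height),
                 noise_sd = NA_real_, signal_decay = NA_real_,
                 seed = NA_integer_),
            class = "pyrogram")
}

#' Write melt curves as TSV
#'
#' One `temperature` column plus one fluorescence column per sample.
#'
#' @param curves A [melt_curve()] or list of them (shared grid).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_melt_tsv <- function(curves, path) {
  if (inherits(curves, "melt_curve")) curves <- list(curves)
  tt <- curves[[1]]$temperature
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$temperature, tt)))
      stop("melt curves must share one temperature grid", call. = FALSE)
  }
  ids <- vapply(seq_along(curves), function(i)
    if (is.na(curves[[i]]$sample_id)) paste0("sample", i)
    else curves[[i]]$sample_id, "")
  df <- data.frame(temperature = tt)
  for (i in seq_along(curves)) df[[ids[i]]] <- curves[[i]]$fluorescence
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read melt curves from TSV
#'
#' @param path TSV written by [write_melt_tsv()].
#' @return Named list of [melt_curve()]s.
#' @export
read_melt_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "temperature")
    stop("first column must be 'temperature'", call. = FALSE)
  if (ncol(df) < 2L) stop("no sample columns found", call. = FALSE)
  bad <- which(!is.finite(df$temperature))
  if (length(bad))
    stop("non-numeric temperature at line ", bad[1] + 1L, call. = FALSE)
  out <- lapply(names(df)[-1], function(nm)
    melt_curve(df$temperature, df[[nm]], nm))
  setNames(out, names(df)[-1])
}

#' Serialize an assay configuration to JSON
#'
#' @param config An [assay_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_config <- function(config, path) {
  stopifnot(inherits(config, "assay_config"))
  obj <- list(name = config$name,
              primers = config$primers,
              pair = if (!is.null(config$pair))
                list(a = config$pair$a, b = config$pair$b,
                     labels = config$pair$labels),
              region = config$region,
              read_windows = config$read_windows,
              dispensations = lapply(config$dispensations, function(d)
                d %||% NA_character_),
              regions = as.list(config$regions %||% list()))
  write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
             pretty = TRUE)
  invisible(path)
}

#' Read an assay configuration from JSON
#'
#' @param path JSON written by [write_assay_config()].
#' @return An [assay_config()].
#' @export
read_assay_config <- function(path) {
  obj <- read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  pair <- if (!is.null(obj$pair))
    paralog_pair(obj$pair$a, obj$pair$b, obj$pair$labels)
  disp <- if (!is.null(obj$dispensations))
    lapply(obj$dispensations, function(d) if (is.null(d) || is.na(d)) NULL else d)
  rw <- obj$read_windows
  rw <- if (is.matrix(rw)) lapply(seq_len(nrow(rw)), function(r) as.integer(rw[r, ]))
        else lapply(rw, as.integer)
  assay_config(name = obj$name,
               primers = lapply(obj$primers, unlist),
               pair = pair,
               region = obj$region,
               read_windows = rw,
               dispensations = disp,
               regions = unlist(obj$regions))
}

#' Write a methylation profile to TSV and JSON
#'
#' The TSV holds one row per CpG position (specificity, per-paralog CpG
#' numbers, raw, corrected and reported levels, reliability and quality);
#' the JSON additionally records the paralog proportion, parameters and
#' provenance.
#'
#' @param profile A [build_profile()] result.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @param provenance Optional named list merged into the JSON output.
#' @return Invisibly, the list written to JSON.
#' @export
write_results <- function(profile, tsv_path = NULL, json_path = NULL,
                          provenance = list()) {
  stopifnot(inherits(profile, "methylation_profile"))
  tab <- profile$cpgs
  tab$tier <- profile$proportion$tier
  if (!is.null(tsv_path))
    write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "n.a.")
  obj <- c(list(proportion = unclass(profile$proportion),
                cpgs = tab,
                params = unclass(profile$params)),
           provenance)
  if (!is.null(json_path))
    write_json(obj, json_path, auto_unbox = TRUE, digits = NA, null = "null",
               pretty = TRUE, force = TRUE)
  invisible(obj)
}

#' Serialize an HRM calibration model to JSON
#'
#' @param model A [fit_calibration()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- list(temperature = model$temperature,
              coefficients = asplit(model$coefficients, 2L),
              levels = model$levels,
              excluded = model$excluded)
  write_json(obj, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an HRM calibration model from JSON
#'
#' @param path JSON written by [write_calibration()].
#' @return A `calibration_model`.
#' @export
read_calibration <- function(path) {
  obj <- read_json(path, simplifyVector = TRUE)
  cf <- obj$coefficients
  cf <- if (is.matrix(cf)) t(cf) else matrix(unlist(cf), nrow = 4L)
  structure(list(temperature = obj$temperature,
                 coefficients = cf,
                 levels = obj$levels,
                 excluded = obj$excluded %||% numeric(0),
                 params = hrm_params()),
            class = "calibration_model")
}
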