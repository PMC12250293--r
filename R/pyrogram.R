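# Pyrogram engine: sequencing-by-synthesis simulation under a programmed
# dispensation order, plus quantification of nucleotide fractions at variable
# positions. Heights are in expected-incorporation units (1.0 = one base
# incorporated in every template molecule); the downstream analysis only
# consumes relative peak ratios, so no light-intensity calibration is modeled.

clean_dispensation <- function(disp) {
  disp <- toupper(disp)
  disp <- gsub("[^ACGT]", "", disp)  # strip hyphenation/line-break artifacts
  if (nchar(disp) < 1L) stop("dispensation order is empty", call. = FALSE)
  disp
}

# Walk one template read through a dispensation order. For each dispensed
# nucleotide the template incorporates the full run of that base at its
# pointer (0 if the next base differs). Returns per-slot heights, the slot
# that consumed each read position, and a stall marker when the order ends
# before the read is fully consumed.
walk_template <- function(read, disp) {
  rb <- seq_chars(read)
  db <- seq_chars(disp)
  n <- length(rb)
  heights <- numeric(length(db))
  slot_of <- rep(NA_integer_, n)
  ptr <- 1L
  for (s in seq_along(db)) {
    k <- 0L
    while (ptr + k <= n && rb[ptr + k] == db[s]) k <- k + 1L
    if (k > 0L) {
      slot_of[ptr:(ptr + k - 1L)] <- s
      heights[s] <- k
      ptr <- ptr + k
    }
  }
  list(heights = heights, slot_of = slot_of,
       consumed = ptr > n,
       stall = if (ptr <= n) ptr else NA_integer_)
}

#' Design a dispensation order for a set of template reads
#'
#' Greedy scheduler over per-template pointers: while any template has bases
#' left, dispense a base needed by the least-advanced templates, preferring a
#' base that no further-advanced template would also incorporate (this is the
#' "adapted" ordering that keeps heterogeneous templates synchronized and
#' avoids sequencing frameshifts). Deterministic.
#'
#' @param reads Character vector of template reads (the converted strand
#'   downstream of the sequencing primer).
#' @return Dispensation order string over `A,C,G,T` that fully consumes every
#'   read.
#' @export
design_dispensation <- function(reads) {
  reads <- vapply(reads, check_seq, "", arg = "reads")
  rb <- lapply(reads, seq_chars)
  len <- vapply(rb, length, 1L)
  ptr <- rep(1L, length(rb))
  disp <- character(0)
  max_len <- 4L * sum(len) + 16L
  while (any(ptr <= len)) {
    active <- which(ptr <= len)
    m <- min(ptr[active])
    lag <- active[ptr[active] == m]
    cand <- sort(unique(vapply(lag, function(i) rb[[i]][ptr[i]], "")))
    ahead <- active[ptr[active] > m]
    ahead_bases <- unique(vapply(ahead, function(i) rb[[i]][ptr[i]], ""))
    safe <- setdiff(cand, ahead_bases)
    b <- if (length(safe)) safe[1L] else cand[1L]
    disp <- c(disp, b)
    for (i in active) {
      while (ptr[i] <= len[i] && rb[[i]][ptr[i]] == b) ptr[i] <- ptr[i] + 1L
    }
    if (length(disp) > max_len)
      stop("dispensation design did not converge", call. = FALSE)
  }
  paste(disp, collapse = "")
}

#' Weighted template mixture
#'
#' @param reads Character vector of template read sequences.
#' @param weights Non-negative weights summing to 1 (tolerance 1e-9).
#' @return Object of class `template_mix`.
#' @export
template_mix <- function(reads, weights) {
  reads <- vapply(reads, check_seq, "", arg = "reads")
  if (length(weights) != length(reads))
    stop("one weight per read is required", call. = FALSE)
  if (any(weights < 0))
    stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1", call. = FALSE)
  structure(list(reads = reads, weights = as.numeric(weights)),
            class = "template_mix")
}

#' Simulate a pyrogram from a template mixture
#'
#' Each template holds a synthesis pointer; for each dispensed nucleotide a
#' template incorporates the full homopolymer run of that base at its pointer.
#' The peak height at a dispensation slot is the weight-averaged number of
#' incorporated bases, optionally degraded by a linear signal decay along the
#' dispensation index, plus i.i.d. Gaussian noise, clipped at zero.
#'
#' @param mix A [template_mix()].
#' @param disp Dispensation order string (characters outside `A,C,G,T` are
#'   stripped on ingest).
#' @param noise_sd Gaussian noise standard deviation in expected-incorporation
#'   units (default 0).
#' @param seed Optional integer seed; recorded in the output.
#' @param signal_decay Linear decay per dispensation slot: the expected height
#'   at slot s is scaled by `max(0, 1 - signal_decay * (s - 1))`. Default 0.
#' @return Object of class `pyrogram`: list with `dispensation`, `heights`,
#'   `noise_sd`, `signal_decay`, `seed`.
#' @export
#' @examples
#' m <- template_mix(c("CAG", "TAG"), c(0.5, 0.5))
#' simulate_pyrogram(m, "CTAG")$heights  # 0.5 0.5 1 1
simulate_pyrogram <- function(mix, disp, noise_sd = 0, seed = NULL,
                              signal_decay = 0) {
  stopifnot(inherits(mix, "template_mix"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  disp <- clean_dispensation(disp)
  nslot <- nchar(disp)
  expected <- numeric(nslot)
  for (i in seq_along(mix$reads)) {
    expected <- expected + mix$weights[i] * walk_template(mix$reads[i], disp)$heights
  }
  scale <- pmax(0, 1 - signal_decay * (seq_len(nslot) - 1L))
  heights <- expected * scale
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    heights <- heights + rnorm(nslot, 0, noise_sd)
  }
  structure(list(dispensation = disp, heights = pmax(0, heights),
                 noise_sd = noise_sd, signal_decay = signal_decay,
                 seed = seed %||% NA_integer_),
            class = "pyrogram")
}

#' @export
print.pyrogram <- function(x, ...) {
  cat("pyrogram:", nchar(x$dispensation), "dispensations, noise_sd =",
      x$noise_sd, "\n")
  invisible(x)
}

#' Nucleotide fraction at a variable pyrogram position
#'
#' The percentage of signal at the variant slots relative to variant plus
#' reference slots, each summed over the given dispensation indices.
#'
#' @param pyrogram A [simulate_pyrogram()] result or object with
#'   `dispensation` and `heights`.
#' @param variant_slots,reference_slots Dispensation slot indices (1-based).
#' @return Percent in \[0, 100\].
#' @export
peak_fraction <- function(pyrogram, variant_slots, reference_slots) {
  h <- pyrogram$heights
  n <- length(h)
  slots <- c(variant_slots, reference_slots)
  if (any(slots < 1L) || any(slots > n))
    stop("slot index outside the dispensation order", call. = FALSE)
  hv <- sum(h[variant_slots])
  hr <- sum(h[reference_slots])
  if (hv + hr == 0)
    stop("no signal at the requested position: fraction undefined", call. = FALSE)
  100 * hv / (hv + hr)
}

#' Raw per-CpG methylation from a pyrogram
#'
#' For every CpG row of a variable-position map, computes the C/(C + other)
#' signal fraction (converted-strand convention: a methylated CpG retains C,
#' an unmethylated one reads T). Positions flagged unusable (slot collisions,
#' CpG shifts) are excluded.
#'
#' @param pyrogram A pyrogram.
#' @param positions A variable-position map from [map_dispensation_positions()].
#' @return The CpG rows of `positions` with an added `raw` percent column.
#' @export
methylation_from_pyrogram <- function(pyrogram, positions) {
  stopifnot(inherits(positions, "variable_positions"))
  cp <- positions[positions$kind == "cpg" & positions$usable, , drop = FALSE]
  if (nrow(cp) == 0L) {
    cp$raw <- numeric(0)
    return(cp)
  }
  cp$raw <- vapply(seq_len(nrow(cp)), function(i) {
    v <- cp$variant_slots[[i]]
    r <- cp$reference_slots[[i]]
    if (length(v) == 0L || length(r) == 0L)
      stop("CpG position ", cp$pyrogram_index[i], " has no quantification slots",
           call. = FALSE)
    peak_fraction(pyrogram, v, r)
  }, numeric(1))
  cp
}

#' Signal quality at a variable position
#'
#' Classifies the total signal at a position against absolute thresholds:
#' `failed` below the floor, `check` inside the warn band, `passed` above.
#' The default thresholds (0.1 / 0.3 expected-incorporation units) are
#' declared package defaults, configurable via `thresholds`.
#'
#' @param pyrogram A pyrogram.
#' @param position One row of a variable-position map.
#' @param thresholds Named numeric vector with `failed` and `check` floors.
#' @return List of class `quality_flag` with `level` and `reason`.
#' @export
assess_quality <- function(pyrogram, position,
                           thresholds = c(failed = 0.1, check = 0.3)) {
  slots <- unique(c(position$variant_slots[[1L]], position$reference_slots[[1L]]))
  slots <- slots[!is.na(slots)]
  total <- if (length(slots)) sum(pyrogram$heights[slots]) else 0
  if (total < thresholds[["failed"]]) {
    level <- "failed"
    reason <- sprintf("total signal %.3f below floor %.3f", total,
                      thresholds[["failed"]])
  } else if (total < thresholds[["check"]]) {
    level <- "check"
    reason <- sprintf("total signal %.3f inside warn band", total)
  } else {
    level <- "passed"
    reason <- ""
  }
  structure(list(level = level, reason = reason, total_signal = total),
            class = "quality_flag")
}
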