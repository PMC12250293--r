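# Sequence-level primitives: CpG enumeration, in-silico bisulfite conversion,
# identity, GC content, primer matching and amplicon prediction. Sequences are
# plain uppercase character scalars over {A,C,G,T,N}; assay sequences are held
# as the strand that is bisulfite-converted and sequenced (for the CDKN2A/2B
# assays that is the lower genomic strand, 5'->3'). All positions are 1-based.

check_seq <- function(x, arg = deparse(substitute(x))) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("'", arg, "' must be a single DNA sequence string", call. = FALSE)
  x <- toupper(x)
  if (nchar(x) < 1L)
    stop("'", arg, "' must have length >= 1", call. = FALSE)
  if (grepl("[^ACGTN]", x))
    stop("'", arg, "' contains characters outside {A,C,G,T,N}", call. = FALSE)
  x
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Reverse complement of a DNA sequence
#'
#' @param seq DNA sequence (character scalar over `A,C,G,T,N`).
#' @return The reverse complement as a character scalar.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(seq) {
  seq <- check_seq(seq)
  chartr("ACGTN", "TGCAN", paste(rev(seq_chars(seq)), collapse = ""))
}

#' Find CpG sites in a sequence
#'
#' Returns the 1-based positions of the C of every CpG dinucleotide, in
#' increasing order. CpG sites are the methylatable positions interrogated by
#' bisulfite assays; site ordinals (CpG 1, CpG 2, ...) used elsewhere in the
#' package are ranks into this vector.
#'
#' @inheritParams revcomp
#' @return Integer vector of C positions (possibly empty).
#' @export
#' @examples
#' find_cpg_sites("ACGCGT")  # c(2, 4)
find_cpg_sites <- function(seq) {
  seq <- check_seq(seq)
  b <- seq_chars(seq)
  n <- length(b)
  if (n < 2L) return(integer(0))
  which(b[-n] == "C" & b[-1L] == "G")
}

#' In-silico bisulfite conversion
#'
#' Converts every cytosine outside a CpG context to thymine (complete
#' conversion is assumed). A CpG-site cytosine is retained as C when the site
#' is methylated and converted to T otherwise.
#'
#' @inheritParams revcomp
#' @param pattern Methylation pattern: `"all_unmethylated"` (default),
#'   `"all_methylated"`, a logical vector with one state per CpG site of
#'   `seq`, or an integer vector of CpG site ordinals to mark methylated.
#' @return Converted sequence, same length as the input.
#' @export
#' @examples
#' bisulfite_convert("ACGT", "all_methylated")    # "ACGT"
#' bisulfite_convert("ACGT", "all_unmethylated")  # "ATGT"
#' bisulfite_convert("CCGG", "all_methylated")    # "TCGG"
bisulfite_convert <- function(seq, pattern = "all_unmethylated") {
  seq <- check_seq(seq)
  sites <- find_cpg_sites(seq)
  n <- length(sites)
  met <- rep(FALSE, n)
  if (is.character(pattern)) {
    pattern <- match.arg(pattern, c("all_unmethylated", "all_methylated"))
    if (pattern == "all_methylated") met[] <- TRUE
  } else if (is.logical(pattern)) {
    if (length(pattern) != n || anyNA(pattern))
      stop("per-site pattern has ", length(pattern), " states but the sequence has ",
           n, " CpG sites", call. = FALSE)
    met <- pattern
  } else if (is.numeric(pattern)) {
    if (length(pattern) && (any(pattern != trunc(pattern)) ||
                            any(pattern < 1) || any(pattern > n)))
      stop("methylation pattern refers to a non-CpG site index (sequence has ",
           n, " CpG sites)", call. = FALSE)
    met[as.integer(pattern)] <- TRUE
  } else {
    stop("unsupported methylation pattern", call. = FALSE)
  }
  b <- seq_chars(seq)
  cs <- which(b == "C")
  keep <- sites[met]
  b[setdiff(cs, keep)] <- "T"
  paste(b, collapse = "")
}

#' Global pairwise identity between two sequences
#'
#' Needleman-Wunsch global alignment (end gaps penalized) with match +1,
#' mismatch -1, gap opening 2 and gap extension 0.5; identity is the number
#' of matching columns over the total number of alignment columns.
#'
#' @param a,b DNA sequences.
#' @param gap_opening,gap_extension Gap penalties (positive costs).
#' @return An object of class `identity_result`: list with `matches`,
#'   `alignment_length` and `percent`.
#' @export
#' @examples
#' pairwise_identity("ACGT", "AGGT")$percent  # 75
pairwise_identity <- function(a, b, gap_opening = 2, gap_extension = 0.5) {
  a <- check_seq(a)
  b <- check_seq(b)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = gap_opening,
                                       gapExtension = gap_extension)
  len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  m <- Biostrings::nmatch(aln)
  structure(list(matches = m, alignment_length = len,
                 percent = 100 * m / len),
            class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("identity: %d/%d columns (%.1f%%)\n",
              x$matches, x$alignment_length, x$percent))
  invisible(x)
}

#' GC content of a sequence
#'
#' @inheritParams revcomp
#' @return Percent of G+C bases.
#' @export
#' @examples
#' gc_fraction("GGCC")  # 100
gc_fraction <- function(seq) {
  seq <- check_seq(seq)
  b <- seq_chars(seq)
  100 * sum(b %in% c("G", "C")) / length(b)
}

#' Match a primer against a template by Hamming scan
#'
#' Slides the primer (no indels) along the template and reports every offset
#' with at most `max_mismatch` mismatches. For `strand = "minus"` the primer
#' is reverse-complemented before scanning, i.e. hits are sites where the
#' primer anneals to the displayed strand as a reverse primer. The ambiguity
#' base N matches only N.
#'
#' @param primer,template DNA sequences; the primer must be shorter.
#' @param strand `"plus"` (forward primer) or `"minus"` (reverse primer).
#' @param max_mismatch Maximum Hamming mismatches (default 3).
#' @return data.frame with one row per hit: `start` (1-based on template),
#'   `end`, `strand`, `mismatch_count` and a list column `mismatch_positions`
#'   (1-based within the scanned primer sequence). Zero rows when no site.
#' @export
match_primer <- function(primer, template, strand = c("plus", "minus"),
                         max_mismatch = 3L) {
  strand <- match.arg(strand)
  primer <- check_seq(primer)
  template <- check_seq(template)
  query <- if (strand == "minus") revcomp(primer) else primer
  pb <- seq_chars(query)
  tb <- seq_chars(template)
  k <- length(pb)
  n <- length(tb)
  if (k >= n) stop("primer must be shorter than template", call. = FALSE)
  starts <- integer(0)
  counts <- integer(0)
  poss <- list()
  for (off in 0:(n - k)) {
    mm <- which(tb[(off + 1L):(off + k)] != pb)
    if (length(mm) <= max_mismatch) {
      starts <- c(starts, off + 1L)
      counts <- c(counts, length(mm))
      poss[[length(poss) + 1L]] <- mm
    }
  }
  data.frame(start = starts, end = starts + k - 1L,
             strand = rep(strand, length(starts)),
             mismatch_count = counts,
             mismatch_positions = I(poss),
             stringsAsFactors = FALSE)
}

#' Predict PCR products for a primer pair on a template
#'
#' Locates the forward primer on the displayed strand and the reverse primer
#' on the opposite strand (scanned as its reverse complement), then enumerates
#' all products spanning from the 5' end of a forward site to the 5' end of a
#' reverse site. Product length includes both primers.
#'
#' @param fwd,rev Forward and reverse primer sequences (each written 5'->3').
#' @param template Template sequence (the strand the forward primer matches).
#' @param max_mismatch Maximum mismatches allowed per primer site.
#' @return data.frame with `start`, `end`, `length`, `fwd_mismatches`,
#'   `rev_mismatches` and `sequence`; zero rows when no product forms.
#' @export
predict_amplicon <- function(fwd, rev, template, max_mismatch = 3L) {
  template <- check_seq(template)
  fh <- match_primer(fwd, template, "plus", max_mismatch)
  rh <- match_primer(rev, template, "minus", max_mismatch)
  out <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                    fwd_mismatches = integer(0), rev_mismatches = integer(0),
                    sequence = character(0), stringsAsFactors = FALSE)
  if (nrow(fh) == 0L || nrow(rh) == 0L) return(out)
  for (i in seq_len(nrow(fh))) {
    for (j in seq_len(nrow(rh))) {
      if (rh$end[j] > fh$start[i]) {
        out <- rbind(out, data.frame(
          start = fh$start[i], end = rh$end[j],
          length = rh$end[j] - fh$start[i] + 1L,
          fwd_mismatches = fh$mismatch_count[i],
          rev_mismatches = rh$mismatch_count[j],
          sequence = substr(template, fh$start[i], rh$end[j]),
          stringsAsFactors = FALSE))
      }
    }
  }
  out[order(out$start, out$end), , drop = FALSE]
}

#' Splice exons into a cDNA sequence
#'
#' Concatenates exon sequences in the given order and records the exon
#' boundaries on the product, so that transcript-variant amplicons (including
#' exon-skipping isoforms) can be predicted with [predict_amplicon()].
#'
#' @param exons Character vector (optionally named) of exon sequences, 5'->3'
#'   in transcript order.
#' @return List of class `spliced_transcript` with `sequence` and an `exons`
#'   data.frame (`exon`, `start`, `end` on the cDNA).
#' @export
splice_transcript <- function(exons) {
  if (length(exons) < 1L) stop("at least one exon is required", call. = FALSE)
  exons <- vapply(exons, check_seq, "", arg = "exons")
  lens <- nchar(exons)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  nm <- names(exons) %||% paste0("exon", seq_along(exons))
  if (is.null(names(exons))) names(exons) <- nm
  structure(list(sequence = paste(exons, collapse = ""),
                 exons = data.frame(exon = names(exons), start = starts,
                                    end = ends, stringsAsFactors = FALSE)),
            class = "spliced_transcript")
}
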