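# Seeded synthetic-data generators. The flagship generator builds a pair of
# homologous paralog amplicons that emulates the geometry of the CDKN2A /
# CDKN2B exon 2 target: ~230 bp, ~95% genomic identity, 24 vs 21 CpGs,
# paralog-private conversion-invariant marker bases (C-to-A-transversion
# style), CpGs private to one paralog (C-to-T-transition style), one shifted
# CpG, and reverse-primer mismatches on the B paralog (one for unmethylated,
# three for methylated templates). Every engineered feature is recorded in a
# truth object that fully determines the expected noiseless output of every
# downstream operation.

spread_indices <- function(n, from, to) {
  if (n == 0L) return(integer(0))
  idx <- unique(round(seq(from, to, length.out = n)))
  while (length(idx) < n) idx <- unique(c(idx, max(idx) + 1L))
  sort(idx[seq_len(n)])
}

#' Generate a synthetic paralog pair with known truth
#'
#' Paralog A is a random sequence with `n_cpgs` planted CpGs; paralog B is
#' derived from it by substitutions only, so the pair aligns without indels.
#' Substitutions are biased toward the edit types seen between real paralog
#' CpG islands: CpG-destroying C-to-T transitions (A-specific CpGs),
#' CpG-creating T-to-C edits (B-specific CpGs), C-to-A-style transversions
#' that leave one paralog with a conversion-invariant private base (the
#' proportion markers), one shifted CpG, and silent C-to-T edits at non-CpG
#' cytosines that lower the genomic identity without surviving bisulfite
#' conversion. Local contexts around every variable position are fixed so
#' that a designed dispensation order quantifies each position exactly.
#'
#' @param seed Integer seed; the output is a deterministic function of the
#'   arguments.
#' @param length Amplicon length in bp (default 230).
#' @param target_identity Target genomic (unconverted) percent identity
#'   (default 95); achieved within about 1 percentage point.
#' @param n_cpgs Number of CpGs planted in paralog A (default 24).
#' @param n_markers_per_paralog Conversion-invariant marker positions private
#'   to each paralog (default 1).
#' @param n_a_specific CpGs of A destroyed in B by C-to-T transition
#'   (default 4; together with the marker and shift edits this leaves the
#'   B paralog with 21 window CpGs against 24 in A, the real assay's ratio).
#' @param n_b_specific CpGs created in B where A has TG (default 1).
#' @param include_cpg_shift Engineer one shifted CpG (default TRUE).
#' @param engineer_rev_mismatches Engineer reverse-primer mismatches on B:
#'   two B-private CpGs inside the primer footprint (mismatch only for
#'   methylated templates) plus one invariant substitution (default TRUE).
#' @param head_len,tail_len Lengths of the substitution-free primer regions
#'   at the amplicon ends (defaults 26 / 24).
#' @param labels Paralog labels.
#' @return List with `pair` (a [paralog_pair()]) and `truth` (class
#'   `synthetic_truth`): anchor table with roles and positions, CpG site
#'   lists, engineered marker/shift/reverse-primer positions, substitution
#'   count and expected identity.
#' @export
generate_paralog_pair <- function(seed, length = 230L, target_identity = 95,
                                  n_cpgs = 24L, n_markers_per_paralog = 1L,
                                  n_a_specific = 4L, n_b_specific = 1L,
                                  include_cpg_shift = TRUE,
                                  engineer_rev_mismatches = TRUE,
                                  head_len = 26L, tail_len = 24L,
                                  labels = c("A", "B")) {
  if (length < 50L) stop("length must be >= 50", call. = FALSE)
  set.seed(seed)
  n_mk <- n_markers_per_paralog
  n_shift <- as.integer(include_cpg_shift)
  if (n_cpgs < n_mk + n_a_specific + n_shift + 2L)
    stop("infeasible: not enough CpGs for the requested special roles",
         call. = FALSE)

  a <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
              prob = c(0.3, 0.2, 0.2, 0.3))
  # remove accidental CpGs so the planted set is exactly the CpG set
  repeat {
    cg <- which(a[-length] == "C" & a[-1L] == "G")
    if (!length(cg)) break
    a[cg] <- "A"
  }

  # anchor layout: CpG anchors plus non-CpG anchors (A markers, B-specific
  # CpG sites), evenly spaced between the primer regions
  n_anchor <- n_cpgs + n_mk + n_b_specific
  zone <- c(head_len + 4L, length - tail_len - 5L)
  spacing <- (zone[2] - zone[1]) %/% max(1L, n_anchor)
  if (n_anchor > 0L && spacing < 6L)
    stop("infeasible: amplicon too short for the requested feature count",
         call. = FALSE)
  anchor_pos <- as.integer(zone[1] + spacing * (seq_len(n_anchor) - 1L))

  roles <- rep("shared", n_anchor)
  noncpg <- c(rep("marker_a", n_mk), rep("b_specific", n_b_specific))
  if (length(noncpg)) {
    idx_non <- spread_indices(length(noncpg), 2L, max(2L, n_anchor - 2L))
    roles[idx_non] <- noncpg
  }
  cpg_anchor_idx <- which(roles == "shared")
  special <- c(rep("marker_b", n_mk), rep("a_specific", n_a_specific),
               if (include_cpg_shift) "cpg_shift")
  if (length(special)) {
    pick <- cpg_anchor_idx[spread_indices(length(special), 2L,
                                          max(2L, length(cpg_anchor_idx) - 1L))]
    roles[pick] <- special
  }

  edits <- list()  # position -> base for paralog B
  add_edit <- function(pos, base) edits[[as.character(pos)]] <<- base
  for (k in seq_len(n_anchor)) {
    p <- anchor_pos[k]
    role <- roles[k]
    if (role %in% c("shared", "a_specific", "marker_b")) {
      prev <- if (role == "marker_b") "G" else "A"
      if (prev == "G" && a[p - 2L] == "C") a[p - 2L] <- "A"
      a[p - 1L] <- prev
      a[p] <- "C"; a[p + 1L] <- "G"; a[p + 2L] <- "A"
      if (role == "a_specific") add_edit(p, "T")
      if (role == "marker_b") add_edit(p, "A")
    } else if (role == "marker_a") {
      if (a[p - 2L] == "C") a[p - 2L] <- "A"
      a[p - 1L] <- "G"
      a[p] <- "A"; a[p + 1L] <- "G"; a[p + 2L] <- "A"
      add_edit(p, "C")
    } else if (role == "b_specific") {
      a[p - 1L] <- "A"
      a[p] <- "T"; a[p + 1L] <- "G"; a[p + 2L] <- "A"
      add_edit(p, "C")
    } else if (role == "cpg_shift") {
      a[p - 1L] <- "A"
      a[p] <- "C"; a[p + 1L] <- "G"; a[p + 2L] <- "T"; a[p + 3L] <- "A"
      add_edit(p, "T"); add_edit(p + 1L, "C"); add_edit(p + 2L, "G")
    }
  }

  rev_truth <- NULL
  if (engineer_rev_mismatches) {
    q <- length - tail_len + c(5L, 11L, 17L)
    for (qq in q[1:2]) {  # B-private CpG inside the reverse-primer footprint
      if (a[qq - 1L] == "C") a[qq - 1L] <- "A"
      a[qq] <- "T"; a[qq + 1L] <- "G"
      add_edit(qq, "C")
    }
    if (a[q[3] - 1L] == "C") a[q[3] - 1L] <- "A"
    a[q[3]] <- "G"
    if (a[q[3] + 1L] == "G") a[q[3] + 1L] <- "T"
    add_edit(q[3], "A")
    rev_truth <- list(positions = q,
                      mismatches_unmethylated = 1L,
                      mismatches_methylated = 3L)
  }

  # silent substitutions (invisible after conversion) to reach the identity
  n_engineered <- base::length(edits)
  n_target_subs <- round(length * (1 - target_identity / 100))
  n_neutral <- max(0L, n_target_subs - n_engineered)
  if (n_neutral > 0L) {
    foot <- unlist(lapply(anchor_pos, function(p) (p - 2L):(p + 3L)))
    cand <- setdiff(which(a == "C"), c(find_cpg_positions_chr(a), foot))
    cand <- cand[cand > head_len & cand <= length - tail_len]
    if (base::length(cand) < n_neutral) n_neutral <- base::length(cand)
    neutral <- sort(sample(cand, n_neutral))
    for (p in neutral) add_edit(p, "T")
  }

  b <- a
  for (pos in names(edits)) b[as.integer(pos)] <- edits[[pos]]
  seq_a <- paste(a, collapse = "")
  seq_b <- paste(b, collapse = "")
  pair <- paralog_pair(seq_a, seq_b, labels)

  n_subs <- base::length(edits)
  truth <- structure(list(
    seed = seed, length = length,
    head_len = head_len, tail_len = tail_len,
    anchors = data.frame(anchor = seq_len(n_anchor), position = anchor_pos,
                         role = roles, stringsAsFactors = FALSE),
    cpg_sites_a = find_cpg_sites(seq_a),
    cpg_sites_b = find_cpg_sites(seq_b),
    marker_a_positions = anchor_pos[roles == "marker_a"],
    marker_b_positions = anchor_pos[roles == "marker_b"],
    a_specific_positions = anchor_pos[roles == "a_specific"],
    b_specific_positions = anchor_pos[roles == "b_specific"],
    shift_positions = if (include_cpg_shift)
      anchor_pos[roles == "cpg_shift"] else integer(0),
    rev_primer = rev_truth,
    n_substitutions = n_subs,
    expected_identity_percent = 100 * (length - n_subs) / length),
    class = "synthetic_truth")
  list(pair = pair, truth = truth)
}

# CpG C positions on a character vector (internal; avoids re-pasting)
find_cpg_positions_chr <- function(b) {
  n <- base::length(b)
  if (n < 2L) return(integer(0))
  which(b[-n] == "C" & b[-1L] == "G")
}

#' Build an assay configuration for a synthetic paralog pair
#'
#' Derives forward, reverse and sequencing primers from the substitution-free
#' primer regions of a [generate_paralog_pair()] result (primers are written
#' against the bisulfite-converted sequence, as real methylation primers
#' are), sets the read window to the stretch between them, and leaves the
#' dispensation order to be auto-designed.
#'
#' @param x Result of [generate_paralog_pair()] (list with `pair`, `truth`).
#' @param name Assay name.
#' @param params An [analysis_params()] object.
#' @return An [assay_config()].
#' @export
make_synthetic_assay <- function(x, name = "synthetic_exon2_like",
                                 params = analysis_params()) {
  pair <- x$pair
  truth <- x$truth
  conv <- bisulfite_convert(pair$a, "all_unmethylated")
  len <- nchar(conv)
  fwd <- substr(conv, 1L, min(22L, truth$head_len))
  seqp <- substr(conv, 1L, truth$head_len)
  rev <- revcomp(substr(conv, len - truth$tail_len + 1L, len))
  assay_config(name = name,
               primers = list(forward = fwd, reverse = rev, sequencing = seqp),
               pair = pair,
               read_windows = list(c(truth$head_len + 1L, len - truth$tail_len)),
               params = params)
}

#' Generate a methylation standard set (pyrograms and melt curves)
#'
#' Emulates the standard series run alongside every assay: unmethylated (0%)
#' and methylated (100%) control DNA plus mixtures (25/50/75% by default).
#' For each level, both paralogs contribute templates at `paralog_ratio` for
#' paralog A, methylated/unmethylated within each paralog according to the
#' level. Pyrograms are simulated under the assay's dispensation orders; melt
#' curves as a two-species mixture (unmethylated and methylated amplicons,
#' the methylated one melting higher because conversion leaves it GC-richer).
#'
#' @param config An [assay_config()] with target sequences.
#' @param levels Methylation levels in percent (default 0, 25, 50, 75, 100).
#' @param paralog_ratio Fraction of paralog A templates (default 0.5).
#' @param noise_sd Pyrogram Gaussian noise SD (default 0).
#' @param melt_noise_sd Melt-curve Gaussian noise SD (default 0).
#' @param seed Integer seed; per-level seeds are derived from it.
#' @param tm_unmethylated,tm_methylated Melting temperatures of the two
#'   amplicon species (defaults 79.2 / 82.0 deg C, placing the transition
#'   inside the default calibration window).
#' @param melt_grid Temperature grid for melt curves.
#' @return List of class `standard_set`: `standards` (per level: `level`,
#'   `mix` weights, `pyrograms` list, `melt` curve), `positions` (the
#'   variable-position map, with dispensations in its attribute), `truth`.
#' @export
generate_standard_set <- function(config, levels = c(0, 25, 50, 75, 100),
                                  paralog_ratio = 0.5, noise_sd = 0,
                                  melt_noise_sd = 0, seed = 1L,
                                  tm_unmethylated = 79.2, tm_methylated = 82.0,
                                  melt_grid = seq(74, 88, by = 0.1)) {
  stopifnot(inherits(config, "assay_config"))
  positions <- map_dispensation_positions(config)
  disps <- attr(positions, "dispensations")
  is_pair <- !is.null(config$pair)
  standards <- list()
  for (li in seq_along(levels)) {
    m <- levels[li] / 100
    r <- paralog_ratio
    pyrs <- list()
    for (i in seq_along(config$read_windows)) {
      reads <- assay_reads(config, i)
      w <- if (is_pair) c(r * m, r * (1 - m), (1 - r) * m, (1 - r) * (1 - m))
           else c(m, 1 - m)
      keep <- w > 0
      mix <- template_mix(reads[keep], w[keep])
      pyrs[[i]] <- simulate_pyrogram(mix, disps[[i]], noise_sd = noise_sd,
                                     seed = seed * 1000L + 10L * li + i)
    }
    species <- data.frame(label = c("unmethylated", "methylated"),
                          tm = c(tm_unmethylated, tm_methylated),
                          gc_percent = NA_real_,
                          weight = c(1 - m, m),
                          stringsAsFactors = FALSE)
    species <- species[species$weight > 0, , drop = FALSE]
    melt <- simulate_melt(species, noise_sd = melt_noise_sd,
                          seed = seed * 1000L + 500L + li,
                          grid = melt_grid,
                          sample_id = paste0("std_", levels[li]))
    standards[[as.character(levels[li])]] <-
      list(level = levels[li], weights = if (is_pair)
             setNames(c(r * m, r * (1 - m), (1 - r) * m, (1 - r) * (1 - m)),
                      c("aM", "aU", "bM", "bU"))
           else setNames(c(m, 1 - m), c("M", "U")),
           pyrograms = pyrs, melt = melt)
  }
  structure(list(standards = standards, positions = positions,
                 truth = list(levels = levels, paralog_ratio = paralog_ratio,
                              noise_sd = noise_sd, seed = seed,
                              tm_unmethylated = tm_unmethylated,
                              tm_methylated = tm_methylated)),
            class = "standard_set")
}

#' Generate a synthetic single-region assay target (promoter-style)
#'
#' A random region with `n_cpgs` planted CpGs and substitution-free primer
#' regions, for assays that interrogate a single locus without paralog
#' interference.
#'
#' @param seed Integer seed.
#' @param length Region length (default 110).
#' @param n_cpgs CpGs to plant (default 7).
#' @param head_len,tail_len Primer region lengths.
#' @return List with `region` (sequence) and `truth` (CpG sites, layout).
#' @export
generate_single_region <- function(seed, length = 110L, n_cpgs = 7L,
                                   head_len = 20L, tail_len = 16L) {
  set.seed(seed)
  a <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
              prob = c(0.3, 0.2, 0.2, 0.3))
  repeat {
    cg <- which(a[-length] == "C" & a[-1L] == "G")
    if (!base::length(cg)) break
    a[cg] <- "A"
  }
  zone <- c(head_len + 4L, length - tail_len - 4L)
  spacing <- (zone[2] - zone[1]) %/% max(1L, n_cpgs)
  if (spacing < 5L)
    stop("infeasible: region too short for the requested CpG count",
         call. = FALSE)
  pos <- zone[1] + spacing * (seq_len(n_cpgs) - 1L)
  for (p in pos) {
    a[p - 1L] <- "A"; a[p] <- "C"; a[p + 1L] <- "G"; a[p + 2L] <- "A"
  }
  seq_r <- paste(a, collapse = "")
  list(region = seq_r,
       truth = list(seed = seed, cpg_sites = find_cpg_sites(seq_r),
                    head_len = head_len, tail_len = tail_len))
}

#' Assay configuration for a synthetic single region
#'
#' @param x Result of [generate_single_region()].
#' @param name Assay name.
#' @return An [assay_config()].
#' @export
make_synthetic_region_assay <- function(x, name = "synthetic_promoter_like") {
  conv <- bisulfite_convert(x$region, "all_unmethylated")
  len <- nchar(conv)
  assay_config(name = name,
               primers = list(forward = substr(conv, 1L, 18L),
                              reverse = revcomp(substr(conv, len - x$truth$tail_len + 1L, len)),
                              sequencing = substr(conv, 1L, x$truth$head_len)),
               region = x$region,
               read_windows = list(c(x$truth$head_len + 1L,
                                     len - x$truth$tail_len)))
}
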