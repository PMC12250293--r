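# Shared fixtures, built once per test run. All randomness is seeded.

seq_chars <- paralogmeth:::seq_chars

fix_gen <- generate_paralog_pair(seed = 101)
fix_assay <- make_synthetic_assay(fix_gen)
fix_positions <- map_dispensation_positions(fix_assay)
fix_disp <- attr(fix_positions, "dispensations")[[1]]
fix_reads <- paralogmeth:::assay_reads(fix_assay, 1)
fix_window <- c(fix_gen$truth$head_len + 1L,
                fix_gen$truth$length - fix_gen$truth$tail_len)

# standard mixture weights: paralog ratio r for A, methylation level m percent
std_weights <- function(r, m) {
  m <- m / 100
  c(aM = r * m, aU = r * (1 - m), bM = (1 - r) * m, bU = (1 - r) * (1 - m))
}

std_pyrogram <- function(r, m, noise_sd = 0, seed = NULL, disp = fix_disp,
                         reads = fix_reads) {
  w <- std_weights(r, m)
  keep <- w > 0
  simulate_pyrogram(template_mix(reads[keep], w[keep]), disp,
                    noise_sd = noise_sd, seed = seed)
}

# independent brute-force pyrogram oracle: regex run-stripping, one template
oracle_walk <- function(read, disp) {
  heights <- numeric(nchar(disp))
  rest <- read
  for (s in seq_len(nchar(disp))) {
    b <- substr(disp, s, s)
    m <- regmatches(rest, regexpr(paste0("^", b, "+"), rest))
    k <- if (length(m) == 1L) nchar(m) else 0L
    heights[s] <- k
    if (k > 0L) rest <- substr(rest, k + 1L, nchar(rest))
  }
  heights
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# melt-curve generator for a standard at m percent methylation: mixture of an
# unmethylated and a methylated amplicon species (fluorescence affine in m,
# as for physically mixed standards)
level_curve <- function(m, noise_sd = 0, seed = NULL, power = 1) {
  w <- (m / 100)^power
  sp <- data.frame(label = c("unmeth", "meth"), tm = c(79.2, 82.0),
                   gc_percent = NA_real_, weight = c(1 - w, w))
  sp <- sp[sp$weight > 0, , drop = FALSE]
  simulate_melt(sp, noise_sd = noise_sd, seed = seed,
                grid = seq(74, 88, by = 0.1), sample_id = as.character(m))
}

level_standards <- function(levels = c(0, 25, 50, 75), ...) {
  setNames(lapply(levels, level_curve, ...), as.character(levels))
}

quiet_cli <- function(args) suppressWarnings(suppressMessages(cli_main(args)))
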