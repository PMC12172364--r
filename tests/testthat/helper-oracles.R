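# Independent brute-force oracles and tiny fixture builders shared across
# the test files. These deliberately avoid the code paths they check.

# Step-up FDR oracle: q_i = min over thresholds t >= p_i of m*t/#{p <= t},
# capped at 1. Evaluated literally, element by element.
bh_oracle <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(m * ts / vapply(ts, function(t) sum(p <= t), numeric(1))))
  }, numeric(1))
}

# Position-by-position motif scan.
scan_oracle <- function(sequence, motif) {
  L <- nchar(motif)
  n <- nchar(sequence)
  if (n < L) return(integer(0))
  hits <- vapply(seq_len(n - L + 1L), function(i)
    substr(sequence, i, i + L - 1L) == motif, logical(1))
  which(hits)
}

revcomp_chr <- function(x) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")
}

# Sliding-window Hamming off-target oracle over a character vector of
# references; counts windows on both strands, optional NGG PAM.
offtarget_oracle <- function(guide, refs, k, pam = TRUE) {
  g <- strsplit(guide, "")[[1]]
  L <- length(g)
  total <- 0L
  for (ref in refs) {
    for (seqchr in c(ref, revcomp_chr(ref))) {
      r <- strsplit(seqchr, "")[[1]]
      n <- length(r)
      if (n < L) next
      for (i in seq_len(n - L + 1L)) {
        if (sum(r[i:(i + L - 1L)] != g) > k) next
        if (pam) {
          if (i + L + 2L > n) next   # PAM = positions i+L .. i+L+2 (NGG)
          if (!(r[i + L + 1L] == "G" && r[i + L + 2L] == "G")) next
        }
        total <- total + 1L
      }
    }
  }
  total
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Minimal manifest with explicit per-probe fields.
toy_manifest <- function(probe_id, gene, cgi_relation = "island",
                         isoform = "") {
  n <- length(probe_id)
  as_probe_manifest(data.frame(
    probe_id = probe_id, contig = "chr1",
    position = seq_len(n) * 100L, strand = "+",
    gene = rep_len(gene, n), isoform = rep_len(isoform, n),
    cgi_relation = rep_len(cgi_relation, n), stringsAsFactors = FALSE))
}

# Paired sheet for n pairs with columns N01..Nn, T01..Tn.
toy_sheet <- function(n) {
  data.frame(sample_id = c(sprintf("N%02d", 1:n), sprintf("T%02d", 1:n)),
             pair_id = rep(sprintf("P%02d", 1:n), 2),
             condition = rep(c("normal", "tumor"), each = n),
             stringsAsFactors = FALSE)
}

# Probe test table stub for ranking tests.
toy_results <- function(probe_id, delta_beta, q) {
  data.frame(probe_id = probe_id, mean_normal = 0.2,
             mean_tumor = 0.2 + delta_beta, delta_beta = delta_beta,
             statistic = 0, p = q, q = q, significant = FALSE,
             stringsAsFactors = FALSE)
}

# Small default-effects cohort: full programmed effects over a reduced
# null background, for fast end-to-end checks.
small_cohort <- function(seed = 1L, n_background = 200L,
                         noise_precision = 2000) {
  cfg <- cohort_config(n_background_genes = n_background,
                       noise_precision = noise_precision, seed = seed)
  eff <- default_ptccrcc_effects()
  man <- build_manifest(cfg, eff)
  ch <- simulate_cohort(man, eff, cfg)
  list(cfg = cfg, eff = eff, manifest = man, beta = ch$beta,
       sheet = ch$sheet)
}
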