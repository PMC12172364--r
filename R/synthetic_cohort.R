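#' Programmed methylation effect
#'
#' An effect specification programs one gene of a synthetic cohort: its
#' CpG-island relation, the methylation fraction of the normal (control)
#' tissue, and the signed tumor-minus-normal change in methylation
#' fraction (delta-beta; positive = hypermethylation in tumors).
#'
#' @param gene_label Unique, non-empty gene label.
#' @param region CGI relation of the gene's probes: one of `"island"`,
#'   `"shore"`, `"shelf"`, `"open_sea"`.
#' @param control_mean Methylation fraction of normal tissue, in `[0,1]`.
#' @param tumor_delta Signed methylation change in fraction units; the
#'   tumor mean is `control_mean + tumor_delta`, clipped to the open unit
#'   interval before noise is added.
#' @param isoform Optional isoform promoter label (e.g. `"A"`, `"B"`);
#'   empty when the gene has a single annotated promoter.
#' @return An object of class `effect_spec`.
#' @seealso [default_ptccrcc_effects()], [simulate_cohort()]
#' @export
effect_spec <- function(gene_label, region = "island", control_mean = 0.5,
                        tumor_delta = 0, isoform = "") {
  .assert(.is_string(gene_label), "gene_label must be a non-empty string")
  .assert(.is_string(region) && region %in% .cgi_levels,
          "region must be one of: ", paste(.cgi_levels, collapse = ", "))
  .assert(.is_number(control_mean) && control_mean >= 0 && control_mean <= 1,
          "control_mean must lie in [0,1]")
  .assert(.is_number(tumor_delta) && abs(tumor_delta) <= 1,
          "tumor_delta must lie in [-1,1]")
  .assert(is.character(isoform) && length(isoform) == 1L && !is.na(isoform),
          "isoform must be a single string (possibly empty)")
  structure(list(gene_label = gene_label, region = region,
                 control_mean = control_mean, tumor_delta = tumor_delta,
                 isoform = isoform),
            class = "effect_spec")
}

#' Default programmed effects of the paired ccRCC study design
#'
#' The four effects emulate the cohort in which the two-isoform claudin-10
#' signature was discovered: a CLDN10B-like CpG island that is nearly
#' unmethylated in normal kidney (control mean below 20%) and gains more
#' than 40 percentage points in tumors; a CLDN10A-like island that is
#' methylated in normal tissue and slightly hypomethylated in tumors; a
#' RASSF1A-like island (the classic renal-cancer positive control) gaining
#' about 30 points; and a null open-sea background gene with no change.
#'
#' @return A list of four [effect_spec()] objects.
#' @examples
#' eff <- default_ptccrcc_effects()
#' vapply(eff, `[[`, numeric(1), "tumor_delta")
#' @export
default_ptccrcc_effects <- function() {
  list(
    effect_spec("CLDN10B-like", region = "island", control_mean = 0.15,
                tumor_delta = +0.45, isoform = "B"),
    effect_spec("CLDN10A-like", region = "island", control_mean = 0.60,
                tumor_delta = -0.10, isoform = "A"),
    effect_spec("RASSF1A-like", region = "island", control_mean = 0.25,
                tumor_delta = +0.30),
    effect_spec("BACKGROUND-NULL", region = "open_sea", control_mean = 0.50,
                tumor_delta = 0)
  )
}

#' Synthetic cohort configuration
#'
#' @param n_pairs Number of tumor/normal matched pairs (default 5, the
#'   size of the paired post-transplantation ccRCC cohort the generator
#'   emulates). Must be at least 2.
#' @param n_background_genes Number of null background genes.
#' @param probes_per_gene Array reporters per gene (default 4).
#' @param noise_precision Positive dispersion parameter `s` of the
#'   beta-distributed probe noise: values are drawn from
#'   `Beta(mu*s, (1-mu)*s)`, so larger `s` means tighter spread around the
#'   programmed mean. Default 2000, corresponding to a per-probe
#'   across-sample SD of roughly 0.008-0.011 over the beta range of the
#'   programmed effects (see the methods vignette for the calibration).
#' @param seed Integer master seed; identical configurations (including
#'   the seed) produce bit-identical cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 5L, n_background_genes = 2500L,
                          probes_per_gene = 4L, noise_precision = 2000,
                          seed = 1L) {
  .assert(.is_count(n_pairs, 2L), "n_pairs must be an integer >= 2")
  .assert(.is_count(n_background_genes, 0L),
          "n_background_genes must be a non-negative integer")
  .assert(.is_count(probes_per_gene, 1L),
          "probes_per_gene must be an integer >= 1")
  .assert(.is_number(noise_precision) && noise_precision > 0,
          "noise_precision must be > 0")
  .assert(.is_count(seed, 0L) || .is_count(-seed, 0L),
          "seed must be an integer")
  structure(list(n_pairs = as.integer(n_pairs),
                 n_background_genes = as.integer(n_background_genes),
                 probes_per_gene = as.integer(probes_per_gene),
                 noise_precision = noise_precision,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Deterministic per-gene sub-stream seed from (master seed, gene label), so
# that adding or removing genes never perturbs the draws of the others.
# Polynomial string hash mod the Mersenne prime 2^31 - 1.
.gene_stream_seed <- function(seed, gene_label) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(gene_label)) h <- (h * 31 + b) %% m
  as.integer((h + (abs(seed) %% m) * 2654435) %% m)
}

#' Build a synthetic probe manifest
#'
#' Lays out one probe block per programmed effect gene plus
#' `n_background_genes` null genes, with unique probe ids, strictly
#' increasing positions per contig, and CGI relations consistent with each
#' gene's region (effect genes carry their programmed region; background
#' genes cycle through the four relation categories).
#'
#' @param config A [cohort_config()].
#' @param effects List of [effect_spec()] objects with unique gene labels.
#' @return A `probe_manifest` data frame (see [read_manifest()] for the
#'   column contract).
#' @export
build_manifest <- function(config, effects) {
  stopifnot(inherits(config, "cohort_config"))
  .assert(is.list(effects) && all(vapply(effects, inherits, logical(1),
                                         "effect_spec")),
          "effects must be a list of effect_spec objects")
  labels <- vapply(effects, `[[`, character(1), "gene_label")
  dup <- labels[duplicated(labels)]
  .assert(length(dup) == 0L,
          "duplicate gene label(s) in effects: ", paste(unique(dup),
                                                        collapse = ", "))
  nb <- config$n_background_genes
  bg_labels <- if (nb > 0) sprintf("BG%05d", seq_len(nb)) else character(0)
  genes <- c(labels, bg_labels)
  isoforms <- c(vapply(effects, `[[`, character(1), "isoform"),
                rep("", nb))
  regions <- c(vapply(effects, `[[`, character(1), "region"),
               .cgi_levels[(seq_len(nb) - 1L) %% 4L + 1L])
  ppg <- config$probes_per_gene
  n_genes <- length(genes)
  gene_idx <- rep(seq_len(n_genes), each = ppg)
  probe_in_gene <- rep(seq_len(ppg), times = n_genes)
  manifest <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(n_genes * ppg)),
    contig = "chr1",
    position = (gene_idx - 1L) * 10000L + probe_in_gene * 100L,
    strand = "+",
    gene = genes[gene_idx],
    isoform = isoforms[gene_idx],
    cgi_relation = regions[gene_idx],
    stringsAsFactors = FALSE
  )
  as_probe_manifest(manifest)
}

#' Simulate a paired tumor/normal beta-value cohort
#'
#' For every gene, normal samples are drawn around the gene's control mean
#' and tumor samples around `control_mean + tumor_delta`, both from a beta
#' distribution parameterized by mean and precision
#' (`Beta(mu*s, (1-mu)*s)`), then clipped to `[0.001, 0.999]`. Genes not
#' covered by an effect are null background genes whose control mean is
#' drawn uniformly from `[0.05, 0.95]`. Each gene consumes its own random
#' sub-stream derived from `(seed, gene_label)`.
#'
#' @inheritParams build_manifest
#' @param manifest A probe manifest covering (at least) the effect genes.
#' @return A list with elements `beta` (numeric matrix, probes x samples,
#'   probe ids as rownames) and `sheet` (sample sheet data frame with
#'   columns `sample_id`, `pair_id`, `condition`).
#' @examples
#' cfg <- cohort_config(n_background_genes = 5, seed = 7)
#' eff <- default_ptccrcc_effects()
#' cohort <- simulate_cohort(build_manifest(cfg, eff), eff, cfg)
#' dim(cohort$beta)
#' @export
simulate_cohort <- function(manifest, effects, config) {
  manifest <- as_probe_manifest(manifest)
  stopifnot(inherits(config, "cohort_config"))
  labels <- vapply(effects, `[[`, character(1), "gene_label")
  missing <- setdiff(labels, unique(manifest$gene))
  .assert(length(missing) == 0L,
          "effect gene(s) absent from manifest: ",
          paste(missing, collapse = ", "))
  eff_by_gene <- setNames(effects, labels)
  n <- config$n_pairs
  s <- config$noise_precision
  sample_id <- c(sprintf("N%02d", seq_len(n)), sprintf("T%02d", seq_len(n)))
  sheet <- data.frame(
    sample_id = sample_id,
    pair_id = rep(sprintf("P%02d", seq_len(n)), 2L),
    condition = rep(c("normal", "tumor"), each = n),
    stringsAsFactors = FALSE
  )
  beta <- matrix(NA_real_, nrow = nrow(manifest), ncol = 2L * n,
                 dimnames = list(manifest$probe_id, sample_id))
  clip <- function(x) pmin(pmax(x, 0.001), 0.999)
  for (g in unique(manifest$gene)) {
    rows <- which(manifest$gene == g)
    k <- length(rows)
    set.seed(.gene_stream_seed(config$seed, g))
    if (g %in% labels) {
      mu_n <- eff_by_gene[[g]]$control_mean
      mu_t <- mu_n + eff_by_gene[[g]]$tumor_delta
    } else {
      mu_n <- runif(1, 0.05, 0.95)
      mu_t <- mu_n
    }
    mu_n <- clip(mu_n); mu_t <- clip(mu_t)
    beta[rows, seq_len(n)] <-
      clip(rbeta(k * n, mu_n * s, (1 - mu_n) * s))
    beta[rows, n + seq_len(n)] <-
      clip(rbeta(k * n, mu_t * s, (1 - mu_t) * s))
  }
  list(beta = beta, sheet = sheet)
}

#' Generate a methylation-annotated template sequence
#'
#' Fixture generator for the in silico bisulfite assay: produces a
#' [methylated_template()] either from an explicit sequence or from a
#' random sequence of the requested length and CpG density. The template's
#' CpG position list always equals the exact set of CG dinucleotide
#' occurrences in the final sequence.
#'
#' @param sequence Explicit A/C/G/T sequence, or `NULL` to generate one.
#' @param length Sequence length when generating (ignored if `sequence`
#'   is given).
#' @param cpg_density Expected fraction of positions starting a CG
#'   dinucleotide when generating; `0` yields a CpG-free sequence.
#' @param cpg_positions Optional 1-based positions that must carry a CG.
#'   With an explicit `sequence` these are checked against it (a requested
#'   position not starting a CG is an error); with a generated sequence
#'   CGs are planted there and nowhere else.
#' @param methylation Per-CpG methylation states: `"all"`, `"none"`, a
#'   logical vector (one value per CpG), or a single numeric fraction in
#'   `[0,1]` giving the probability that each CpG is methylated.
#' @param seed Optional integer seed for the random draws.
#' @return A [methylated_template()].
#' @examples
#' generate_template(sequence = "ATCGAT", methylation = "all")
#' @export
generate_template <- function(sequence = NULL, length = 200L,
                              cpg_density = 0.05, cpg_positions = NULL,
                              methylation = "all", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sequence)) {
    .assert(.is_count(length, 1L), "length must be a positive integer")
    .assert(.is_number(cpg_density) && cpg_density >= 0 && cpg_density <= 0.5,
            "cpg_density must lie in [0, 0.5]")
    sequence <- .random_sequence(length, cpg_density, cpg_positions)
  } else {
    .assert(.is_string(sequence), "sequence must be a non-empty string")
  }
  found <- .find_cpgs(sequence)
  if (!is.null(cpg_positions)) {
    bad <- setdiff(as.integer(cpg_positions), found)
    .assert(length(bad) == 0L,
            "requested CpG at non-CG position(s): ",
            paste(bad, collapse = ", "))
  }
  states <- .resolve_states(methylation, length(found))
  methylated_template(sequence, methylation = states)
}

# random A/C/G/T sequence; CGs either planted at fixed positions (and
# nowhere else) or sprinkled at the requested density; density 0 (or an
# explicit position list) suppresses accidental CGs by never emitting a G
# right after a C.
.random_sequence <- function(len, density, cpg_positions) {
  bases <- character(len)
  planted <- logical(len)
  if (!is.null(cpg_positions)) {
    p <- sort(unique(as.integer(cpg_positions)))
    .assert(all(p >= 1 & p + 1L <= len), "cpg_positions out of range")
    .assert(all(diff(p) >= 2L), "cpg_positions must not overlap")
    bases[p] <- "C"; bases[p + 1L] <- "G"
    planted[p] <- TRUE; planted[p + 1L] <- TRUE
    density <- 0
  }
  i <- 1L
  while (i <= len) {
    if (planted[i]) { i <- i + 1L; next }
    if (density > 0 && i < len && !planted[i + 1L] &&
        runif(1) < density) {
      bases[i] <- "C"; bases[i + 1L] <- "G"
      i <- i + 2L
      next
    }
    prev_c <- i > 1L && bases[i - 1L] == "C"
    nxt_g <- i < len && planted[i + 1L] && bases[i + 1L] == "G"
    pool <- c("A", "C", "G", "T")
    if (prev_c) pool <- setdiff(pool, "G")   # no accidental CG
    if (nxt_g) pool <- setdiff(pool, "C")
    bases[i] <- sample(pool, 1L)
    i <- i + 1L
  }
  paste(bases, collapse = "")
}

.resolve_states <- function(methylation, n_cpg) {
  if (is.character(methylation) && length(methylation) == 1L) {
    .assert(methylation %in% c("all", "none"),
            "methylation must be 'all', 'none', a logical vector, ",
            "or a fraction in [0,1]")
    return(rep(methylation == "all", n_cpg))
  }
  if (is.logical(methylation)) {
    .assert(length(methylation) == n_cpg && !anyNA(methylation),
            "logical methylation vector must have one value per CpG (",
            n_cpg, ")")
    return(methylation)
  }
  .assert(.is_number(methylation) && methylation >= 0 && methylation <= 1,
          "methylation fraction must lie in [0,1]")
  runif(n_cpg) < methylation
}

#' Simulate a per-sample two-CGI signature panel
#'
#' Generates per-sample island-probe betas for two CpG islands (the A- and
#' B-isoform promoters of a claudin-10-like gene) for three classes of
#' profiles: ccRCC/pRCC-like (A hypomethylated, B strongly
#' hypermethylated), chromophobe-like (A hypomethylated only) and
#' non-renal-tumor-like (no change). Deltas are intended to be computed
#' against the fixed normal-tissue reference aggregate returned alongside,
#' as for unpaired cell-line panels.
#'
#' @param n_per_class Profiles per class.
#' @param probes_per_island Island reporters per CGI (default 24; promoter
#'   CGIs carry reporters in the tens on the 850k array).
#' @param noise_precision Beta precision of per-probe noise (default 100).
#' @param seed Integer seed.
#' @return A list with `beta` (probes x profiles matrix), `manifest`
#'   (island probes of genes `CLDN10A-like` / `CLDN10B-like`), `classes`
#'   (true class per profile) and `reference` (named vector of normal
#'   reference CGI aggregates for isoforms A and B).
#' @export
simulate_signature_panel <- function(n_per_class = 20L,
                                     probes_per_island = 24L,
                                     noise_precision = 100,
                                     seed = 1L) {
  .assert(.is_count(n_per_class, 1L), "n_per_class must be >= 1")
  .assert(.is_count(probes_per_island, 1L), "probes_per_island must be >= 1")
  ref <- c(A = 0.60, B = 0.15)
  class_delta <- list(
    ccRCC_pRCC_like = c(A = -0.10, B = +0.45),
    chrRCC_like     = c(A = -0.10, B = 0.00),
    non_RCC_like    = c(A = 0.00,  B = 0.00)
  )
  cfg <- cohort_config(n_pairs = 2L, n_background_genes = 0L,
                       probes_per_gene = probes_per_island,
                       noise_precision = noise_precision, seed = seed)
  effects <- list(
    effect_spec("CLDN10A-like", "island", ref[["A"]], 0, isoform = "A"),
    effect_spec("CLDN10B-like", "island", ref[["B"]], 0, isoform = "B")
  )
  manifest <- build_manifest(cfg, effects)
  classes <- rep(names(class_delta), each = n_per_class)
  n_prof <- length(classes)
  ids <- sprintf("S%03d", seq_len(n_prof))
  beta <- matrix(NA_real_, nrow = nrow(manifest), ncol = n_prof,
                 dimnames = list(manifest$probe_id, ids))
  s <- noise_precision
  clip <- function(x) pmin(pmax(x, 0.001), 0.999)
  set.seed(.gene_stream_seed(seed, "signature-panel"))
  for (j in seq_len(n_prof)) {
    d <- class_delta[[classes[j]]]
    for (iso in c("A", "B")) {
      rows <- which(manifest$isoform == iso)
      mu <- clip(ref[[iso]] + d[[iso]])
      beta[rows, j] <- clip(rbeta(length(rows), mu * s, (1 - mu) * s))
    }
  }
  list(beta = beta, manifest = manifest, classes = classes, reference = ref)
}
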