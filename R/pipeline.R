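#' Discovery run configuration
#'
#' Bundles every tunable of the end-to-end discovery pipeline. In
#' `"simulate"` mode the cohort comes from [simulate_cohort()]; in
#' `"load"` mode it is read from `manifest_path`, `beta_path` and
#' `sheet_path`.
#'
#' @param mode `"simulate"` or `"load"`.
#' @param effects Programmed effects for simulate mode (default
#'   [default_ptccrcc_effects()]).
#' @param cohort A [cohort_config()] for simulate mode.
#' @param manifest_path,beta_path,sheet_path Input files for load mode.
#' @param alpha Adjusted significance level (default 0.01).
#' @param min_frac Minimum fraction of significant reporters per gene
#'   (default 0.5).
#' @param delta_floor Minimum `|delta_beta|` per reporter (default 0.10).
#' @param tA,tB Signature thresholds (defaults 0.05 and 0.20, see
#'   [classify_rcc()]).
#' @param top_n Genes in the fold table (default 100).
#' @param signature_genes Either `NULL` (skip the signature stage) or a
#'   list with elements `A = c(gene, isoform)` and `B = c(gene, isoform)`
#'   naming the two isoform promoters; the default addresses the two
#'   claudin-10-like promoters of the default effects.
#' @param out_dir Output directory for result tables, or `NULL` to skip
#'   writing.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "load"),
                       effects = default_ptccrcc_effects(),
                       cohort = cohort_config(),
                       manifest_path = NULL, beta_path = NULL,
                       sheet_path = NULL,
                       alpha = 0.01, min_frac = 0.5, delta_floor = 0.10,
                       tA = 0.05, tB = 0.20, top_n = 100L,
                       signature_genes = list(A = c("CLDN10A-like", "A"),
                                              B = c("CLDN10B-like", "B")),
                       out_dir = NULL) {
  mode <- match.arg(mode)
  .assert(.is_number(alpha) && alpha > 0 && alpha <= 1,
          "alpha must lie in (0,1]")
  .assert(.is_number(min_frac) && min_frac >= 0 && min_frac <= 1,
          "min_frac must lie in [0,1]")
  .assert(.is_number(delta_floor) && delta_floor >= 0 && delta_floor <= 1,
          "delta_floor must lie in [0,1]")
  .assert(.is_number(tA) && tA > 0 && .is_number(tB) && tB > 0,
          "signature thresholds must be positive")
  .assert(.is_count(top_n, 1L), "top_n must be a positive integer")
  if (mode == "load") {
    for (p in c(manifest_path, beta_path, sheet_path)) {
      .assert(!is.null(p) && file.exists(p), "load mode needs existing ",
              "manifest_path, beta_path and sheet_path (missing: ",
              if (is.null(p)) "unset" else p, ")")
    }
  }
  structure(list(mode = mode, effects = effects, cohort = cohort,
                 manifest_path = manifest_path, beta_path = beta_path,
                 sheet_path = sheet_path, alpha = alpha,
                 min_frac = min_frac, delta_floor = delta_floor,
                 tA = tA, tB = tB, top_n = as.integer(top_n),
                 signature_genes = signature_genes, out_dir = out_dir),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the end-to-end discovery pipeline
#'
#' Simulates or loads a paired cohort, then runs probe-level testing with
#' FDR control, significance filtering, gene-level aggregation and
#' ranking, the fold table, and (when two isoform promoters are
#' configured) the CGI signature stage. All parameters, the seed and the
#' package version are recorded in the report's provenance block. When
#' `out_dir` is set, every result table is written there as TSV along
#' with a plain-text configuration echo and the run summary.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report` with elements `counts`,
#'   `probe_tests`, `significant`, `candidates`, `ranked`, `fold`,
#'   `signature` (or `NULL`), `config`, `provenance`.
#' @examples
#' cfg <- run_config(cohort = cohort_config(n_background_genes = 20,
#'                                          seed = 1))
#' rep <- run_discovery(cfg)
#' rep$ranked$gene[1]
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "simulate") {
    manifest <- .stage("simulate",
                       build_manifest(config$cohort, config$effects))
    cohort <- .stage("simulate",
                     simulate_cohort(manifest, config$effects,
                                     config$cohort))
    beta <- cohort$beta
    sheet <- cohort$sheet
  } else {
    manifest <- .stage("load", read_manifest(config$manifest_path))
    beta <- .stage("load", read_beta_matrix(config$beta_path, manifest))
    sheet <- .stage("load", read_sample_sheet(config$sheet_path))
  }
  tests <- .stage("test_probes", test_probes(beta, sheet))
  signif_tab <- .stage("filter_significant",
                       filter_significant(tests, config$alpha))
  candidates <- .stage("aggregate_by_gene",
                       aggregate_by_gene(tests, manifest,
                                         alpha = config$alpha,
                                         delta_floor = config$delta_floor))
  ranked <- .stage("rank_candidates",
                   rank_candidates(candidates, config$min_frac))
  fold <- .stage("fold_table",
                 fold_table(tests, manifest, ranked, config$top_n))
  signature <- NULL
  sg <- config$signature_genes
  if (!is.null(sg) &&
      all(c(sg$A[1], sg$B[1]) %in% manifest$gene)) {
    signature <- .stage("signature", {
      agg_A <- aggregate_cgi(beta, manifest, sg$A[1], sg$A[2])
      agg_B <- aggregate_cgi(beta, manifest, sg$B[1], sg$B[2])
      deltas <- signature_deltas(agg_A, agg_B, sheet)
      calls <- classify_rcc(deltas$pairs$delta_A, deltas$pairs$delta_B,
                            tA = config$tA, tB = config$tB)
      cohort_call <- classify_rcc(deltas$cohort[["delta_A"]],
                                  deltas$cohort[["delta_B"]],
                                  tA = config$tA, tB = config$tB)
      list(pairs = cbind(deltas$pairs, call = calls,
                         stringsAsFactors = FALSE),
           cohort = deltas$cohort, cohort_call = cohort_call)
    })
  }
  report <- structure(list(
    counts = list(
      probes_tested = nrow(tests),
      probes_significant = nrow(signif_tab),
      genes_aggregated = nrow(candidates),
      genes_ranked = nrow(ranked)
    ),
    probe_tests = tests,
    significant = signif_tab,
    candidates = candidates,
    ranked = ranked,
    fold = fold,
    signature = signature,
    config = config,
    provenance = list(
      seed = if (config$mode == "simulate") config$cohort$seed else NA,
      package_version = as.character(utils::packageVersion("methylsift")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    )
  ), class = "run_report")
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tab, file) write_results(tab, file.path(out_dir, file))
  w(report$probe_tests, "probe_tests.tsv")
  w(report$significant, "significant_probes.tsv")
  w(report$candidates, "candidates.tsv")
  w(report$ranked, "ranked_candidates.tsv")
  w(report$fold, "fold_table.tsv")
  if (!is.null(report$signature)) w(report$signature$pairs, "signature.tsv")
  cfg <- report$config
  lines <- c(
    paste0("mode = ", cfg$mode),
    paste0("alpha = ", cfg$alpha),
    paste0("min_frac = ", cfg$min_frac),
    paste0("delta_floor = ", cfg$delta_floor),
    paste0("tA = ", cfg$tA),
    paste0("tB = ", cfg$tB),
    paste0("top_n = ", cfg$top_n),
    if (cfg$mode == "simulate") c(
      paste0("n_pairs = ", cfg$cohort$n_pairs),
      paste0("n_background_genes = ", cfg$cohort$n_background_genes),
      paste0("probes_per_gene = ", cfg$cohort$probes_per_gene),
      paste0("noise_precision = ", cfg$cohort$noise_precision),
      paste0("seed = ", cfg$cohort$seed)
    ),
    paste0("package_version = ", report$provenance$package_version)
  )
  writeLines(lines, file.path(out_dir, "run_config.txt"))
  writeLines(summarize_counts(report), file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' One-line-per-stage run summary
#'
#' @param report A `run_report` from [run_discovery()].
#' @return Character vector, one line per stage.
#' @export
summarize_counts <- function(report) {
  stopifnot(inherits(report, "run_report"))
  n <- report$counts
  lines <- c(
    sprintf("probes tested:       %d", n$probes_tested),
    sprintf("probes significant:  %d (q < %g)", n$probes_significant,
            report$config$alpha),
    sprintf("genes aggregated:    %d", n$genes_aggregated),
    sprintf("genes ranked:        %d (frac_sig >= %g)", n$genes_ranked,
            report$config$min_frac)
  )
  if (!is.null(report$signature)) {
    lines <- c(lines, sprintf(
      "signature:           cohort delta_A = %+.3f, delta_B = %+.3f (%s)",
      report$signature$cohort[["delta_A"]],
      report$signature$cohort[["delta_B"]],
      report$signature$cohort_call))
  }
  if (n$genes_ranked > 0) {
    lines <- c(lines, sprintf("top candidate:       %s%s",
                              report$ranked$gene[1],
                              if (nzchar(report$ranked$isoform[1]))
                                paste0(" (isoform ",
                                       report$ranked$isoform[1], ")")
                              else ""))
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat("methylsift discovery run\n")
  cat(paste0("  ", summarize_counts(x)), sep = "\n")
  invisible(x)
}
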