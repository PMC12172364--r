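#' Aggregate probe test results into gene candidates
#'
#' Stage 2 of the discovery pipeline collapses per-probe statistics onto
#' genes. A reporter counts as differentially methylated when `q < alpha`
#' and `|delta_beta| >= delta_floor` (the floor suppresses statistically
#' significant but biologically trivial probes). Probes with an empty
#' `gene` field are intergenic reporters and are excluded. When the
#' manifest carries isoform promoter labels, aggregation is per
#' (gene, isoform) pair, so a gene with two annotated promoters (as the
#' claudin-10 locus has) yields one candidate per promoter.
#'
#' `cgi_mean_delta` is the mean delta-beta of the gene's significant
#' reporters in its most island-proximal relation class with any
#' significant reporter (priority island > shore > shelf > open sea); it
#' is 0 with `cgi_class = NA` when the gene has no significant reporter.
#'
#' @param results Probe test table from [test_probes()] (all tested
#'   probes, not only the significant subset).
#' @param manifest A `probe_manifest` covering every tested probe.
#' @param alpha Adjusted significance level defining a differentially
#'   methylated reporter (default 0.01).
#' @param delta_floor Minimum `|delta_beta|` for a reporter to count
#'   (default 0.10).
#' @return Data frame of unranked candidates: `gene`, `isoform`,
#'   `n_probes`, `n_sig`, `frac_sig`, `mean_delta` (mean delta-beta over
#'   significant reporters, 0 if none), `cgi_mean_delta`, `cgi_class`,
#'   `direction_consistency` (fraction of significant reporters sharing
#'   the majority sign; `NA` if none), `rank` (`NA` until
#'   [rank_candidates()]).
#' @export
aggregate_by_gene <- function(results, manifest, alpha = 0.01,
                              delta_floor = 0.10) {
  manifest <- as_probe_manifest(manifest)
  .assert(is.data.frame(results) &&
            all(c("probe_id", "delta_beta", "q") %in% names(results)),
          "results must be a probe test table")
  idx <- match(results$probe_id, manifest$probe_id)
  .assert(!anyNA(idx),
          "result probe(s) missing from manifest: ",
          paste(head(results$probe_id[is.na(idx)], 5L), collapse = ", "))
  dat <- data.frame(
    gene = manifest$gene[idx],
    isoform = manifest$isoform[idx],
    cgi_relation = manifest$cgi_relation[idx],
    delta_beta = results$delta_beta,
    sig = results$q < alpha & abs(results$delta_beta) >= delta_floor,
    stringsAsFactors = FALSE
  )
  dat <- dat[nzchar(dat$gene), , drop = FALSE]
  if (nrow(dat) == 0L) {
    return(data.frame(gene = character(0), isoform = character(0),
                      n_probes = integer(0), n_sig = integer(0),
                      frac_sig = numeric(0), mean_delta = numeric(0),
                      cgi_mean_delta = numeric(0), cgi_class = character(0),
                      direction_consistency = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(dat$gene, dat$isoform, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(
    gene = dat$gene[first], isoform = dat$isoform[first],
    n_probes = as.integer(tabulate(factor(key, levels = key[first]))),
    n_sig = 0L, frac_sig = 0, mean_delta = 0, cgi_mean_delta = 0,
    cgi_class = NA_character_, direction_consistency = NA_real_,
    rank = NA_integer_, stringsAsFactors = FALSE)
  # only genes with at least one significant reporter need row-wise work
  sig <- dat[dat$sig, , drop = FALSE]
  if (nrow(sig) > 0L) {
    for (g in split(sig, paste(sig$gene, sig$isoform, sep = "\r"))) {
      i <- which(out$gene == g$gene[1] & out$isoform == g$isoform[1])
      cls <- .cgi_levels[.cgi_levels %in% g$cgi_relation][1]
      out$n_sig[i] <- nrow(g)
      out$mean_delta[i] <- mean(g$delta_beta)
      out$cgi_mean_delta[i] <- mean(g$delta_beta[g$cgi_relation == cls])
      out$cgi_class[i] <- cls
      signs <- sign(g$delta_beta)
      out$direction_consistency[i] <-
        max(tabulate(factor(signs, levels = c(-1, 0, 1)))) / nrow(g)
    }
  }
  out$frac_sig <- out$n_sig / out$n_probes
  out <- out[order(out$gene, out$isoform), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank gene candidates
#'
#' Keeps candidates with at least `min_frac` of their reporters
#' differentially methylated (the "at least 50% of reporters per gene"
#' rule by default) and at least one significant reporter, then sorts by
#' number of significant reporters (descending), absolute CGI-proximal
#' mean delta-beta (descending), absolute mean delta-beta (descending),
#' and finally gene / isoform label (ascending) for a deterministic
#' tie-break. Ranks are 1-based with no gaps.
#'
#' @param candidates Output of [aggregate_by_gene()].
#' @param min_frac Minimum fraction of significant reporters (default 0.5).
#' @return The ranked subset with `rank` filled in.
#' @export
rank_candidates <- function(candidates, min_frac = 0.5) {
  .assert(is.data.frame(candidates) &&
            all(c("gene", "n_sig", "frac_sig") %in% names(candidates)),
          "candidates must come from aggregate_by_gene()")
  .assert(.is_number(min_frac) && min_frac >= 0 && min_frac <= 1,
          "min_frac must lie in [0,1]")
  keep <- candidates$frac_sig >= min_frac & candidates$n_sig >= 1L
  out <- candidates[keep, , drop = FALSE]
  ord <- order(-out$n_sig, -abs(out$cgi_mean_delta), -abs(out$mean_delta),
               out$gene, out$isoform)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Per-reporter fold table for the top-ranked genes
#'
#' Builds the table behind a fold plot of the most significantly changed
#' genes: one row per tested reporter of every candidate ranked at or
#' above `top_n`, in manifest order within each gene.
#'
#' @param results Probe test table from [test_probes()].
#' @param manifest A `probe_manifest`.
#' @param ranked Ranked candidates from [rank_candidates()].
#' @param top_n Number of top-ranked genes to include (default 100).
#' @return Data frame with columns `gene`, `isoform`, `probe_id`,
#'   `delta_beta`, `cgi_relation`, `rank`.
#' @export
fold_table <- function(results, manifest, ranked, top_n = 100L) {
  manifest <- as_probe_manifest(manifest)
  .assert(.is_count(top_n, 1L), "top_n must be a positive integer")
  .assert(is.data.frame(ranked) && all(c("gene", "isoform", "rank") %in%
                                         names(ranked)),
          "ranked must come from rank_candidates()")
  sel <- ranked[ranked$rank <= top_n, , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(data.frame(gene = character(0), isoform = character(0),
                      probe_id = character(0), delta_beta = numeric(0),
                      cgi_relation = character(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  tested <- setNames(results$delta_beta, results$probe_id)
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    m <- manifest[manifest$gene == sel$gene[i] &
                    manifest$isoform == sel$isoform[i], , drop = FALSE]
    m <- m[m$probe_id %in% names(tested), , drop = FALSE]
    data.frame(gene = m$gene, isoform = m$isoform, probe_id = m$probe_id,
               delta_beta = unname(tested[m$probe_id]),
               cgi_relation = m$cgi_relation, rank = sel$rank[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
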