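#' Aggregate CpG-island methylation per sample
#'
#' Stage 3 works at the level of whole CpG islands: for one
#' (gene, isoform) promoter it averages the island-annotated reporters'
#' beta values per sample (unweighted mean, missing probes skipped).
#' Samples with no non-missing island probe are dropped with a message.
#'
#' @param beta Probes x samples beta matrix.
#' @param manifest A `probe_manifest`.
#' @param gene,isoform Promoter to aggregate.
#' @param relations CGI relation classes to include (default `"island"`;
#'   add `"shore"`/`"shelf"` to follow hypermethylation that extends into
#'   the island flanks).
#' @return Data frame with columns `sample_id`, `gene`, `isoform`,
#'   `mean_beta`.
#' @export
aggregate_cgi <- function(beta, manifest, gene, isoform = "",
                          relations = "island") {
  manifest <- as_probe_manifest(manifest)
  .assert(is.matrix(beta) && is.numeric(beta), "beta must be a numeric matrix")
  .assert(all(relations %in% .cgi_levels),
          "relations must be drawn from: ", paste(.cgi_levels,
                                                  collapse = ", "))
  probes <- manifest$probe_id[manifest$gene == gene &
                                manifest$isoform == isoform &
                                manifest$cgi_relation %in% relations]
  probes <- intersect(probes, rownames(beta))
  .assert(length(probes) > 0L,
          "no ", paste(relations, collapse = "/"), " probes for gene ",
          gene, if (nzchar(isoform)) paste0(" isoform ", isoform))
  sub <- beta[probes, , drop = FALSE]
  mean_beta <- colMeans(sub, na.rm = TRUE)
  empty <- colSums(!is.na(sub)) == 0L
  if (any(empty)) {
    message(sum(empty), " sample(s) with no non-missing probe dropped ",
            "from CGI aggregate of ", gene)
  }
  data.frame(sample_id = colnames(sub)[!empty], gene = gene,
             isoform = isoform, mean_beta = unname(mean_beta[!empty]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-pair isoform methylation deltas
#'
#' Combines the CGI aggregates of the two isoform promoters into per-pair
#' tumor-minus-normal deltas (`delta_A`, `delta_B`) and a cohort summary
#' (mean over pairs). Pairs missing either member in either aggregate are
#' skipped with a message.
#'
#' @param agg_A,agg_B CGI aggregates from [aggregate_cgi()] for the A and
#'   B isoform promoters.
#' @param sheet Sample sheet pairing the samples.
#' @return List with `pairs` (data frame `pair_id`, `delta_A`, `delta_B`)
#'   and `cohort` (named vector of means over pairs).
#' @export
signature_deltas <- function(agg_A, agg_B, sheet) {
  sheet <- validate_sample_sheet(sheet)
  get <- function(agg, sample) {
    v <- agg$mean_beta[agg$sample_id == sample]
    if (length(v) == 1L) v else NA_real_
  }
  pairs <- unique(sheet$pair_id)
  rows <- lapply(pairs, function(p) {
    tum <- sheet$sample_id[sheet$pair_id == p & sheet$condition == "tumor"]
    nor <- sheet$sample_id[sheet$pair_id == p & sheet$condition == "normal"]
    dA <- get(agg_A, tum) - get(agg_A, nor)
    dB <- get(agg_B, tum) - get(agg_B, nor)
    data.frame(pair_id = p, delta_A = dA, delta_B = dB,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bad <- is.na(out$delta_A) | is.na(out$delta_B)
  if (any(bad)) {
    message(sum(bad), " incomplete pair(s) skipped: ",
            paste(out$pair_id[bad], collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  .assert(nrow(out) > 0L, "no complete pair covered by both aggregates")
  rownames(out) <- NULL
  list(pairs = out,
       cohort = c(delta_A = mean(out$delta_A), delta_B = mean(out$delta_B)))
}

#' Deltas of unpaired samples against a normal reference
#'
#' For panels without matched normals (cell lines, unpaired tumors), each
#' sample's CGI aggregate is compared against a user-supplied
#' normal-tissue reference aggregate for the same island.
#'
#' @param agg CGI aggregate from [aggregate_cgi()].
#' @param reference Scalar reference mean beta for that island.
#' @return Data frame `sample_id`, `delta` (sample minus reference).
#' @export
reference_deltas <- function(agg, reference) {
  .assert(.is_number(reference) && reference >= 0 && reference <= 1,
          "reference must be a beta value in [0,1]")
  data.frame(sample_id = agg$sample_id,
             delta = agg$mean_beta - reference,
             stringsAsFactors = FALSE)
}

#' Two-isoform methylation signature call
#'
#' Classifies a sample (or pair) from its two CGI deltas. The
#' ccRCC/pRCC-like pattern is A-isoform hypomethylation together with
#' strong B-isoform hypermethylation; chromophobe-like is A
#' hypomethylation without the B gain; anything else is non-RCC-like:
#' \itemize{
#'   \item `ccRCC_pRCC_like` iff `delta_A <= -tA` and `delta_B >= +tB`
#'   \item `chrRCC_like` iff `delta_A <= -tA` and `delta_B < +tB`
#'   \item `non_RCC_like` otherwise
#' }
#'
#' @param delta_A,delta_B Numeric delta-beta vectors (recycled together).
#' @param tA Hypomethylation threshold on the A isoform (default 0.05).
#' @param tB Hypermethylation threshold on the B isoform (default 0.20).
#' @return Character vector of calls.
#' @examples
#' classify_rcc(c(-0.20, -0.10, 0), c(0.45, 0.05, 0))
#' @export
classify_rcc <- function(delta_A, delta_B, tA = 0.05, tB = 0.20) {
  .assert(.is_number(tA) && tA > 0, "tA must be positive")
  .assert(.is_number(tB) && tB > 0, "tB must be positive")
  .assert(length(delta_A) == length(delta_B),
          "delta_A and delta_B must have equal length")
  ifelse(delta_A <= -tA,
         ifelse(delta_B >= tB, "ccRCC_pRCC_like", "chrRCC_like"),
         "non_RCC_like")
}
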