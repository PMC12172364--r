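#' Probe manifest validation
#'
#' A probe manifest is a data frame with columns `probe_id`, `contig`,
#' `position` (1-based), `strand` (`+`/`-`), `gene` (empty string =
#' intergenic reporter), `isoform` (e.g. `"A"`, `"B"`, empty) and
#' `cgi_relation` (`island`, `shore`, `shelf`, `open_sea`). `probe_id`
#' must be unique and `position >= 1`.
#'
#' @param x A data frame to validate.
#' @return `x` with class `probe_manifest` prepended.
#' @export
as_probe_manifest <- function(x) {
  .assert(is.data.frame(x), "manifest must be a data frame")
  required <- c("probe_id", "contig", "position", "strand", "gene",
                "isoform", "cgi_relation")
  miss <- setdiff(required, names(x))
  .assert(length(miss) == 0L,
          "manifest is missing column(s): ", paste(miss, collapse = ", "))
  x$position <- as.integer(x$position)
  for (col in setdiff(required, "position")) x[[col]] <- as.character(x[[col]])
  dup <- x$probe_id[duplicated(x$probe_id)]
  .assert(length(dup) == 0L,
          "duplicate probe_id(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(!x$cgi_relation %in% .cgi_levels)
  .assert(length(bad) == 0L,
          "unknown cgi_relation in row(s) ",
          paste(head(bad, 5L), collapse = ", "), ": ",
          paste(unique(x$cgi_relation[bad]), collapse = ", "))
  badp <- which(is.na(x$position) | x$position < 1L)
  .assert(length(badp) == 0L,
          "position must be >= 1 in row(s): ",
          paste(head(badp, 5L), collapse = ", "))
  bads <- which(!x$strand %in% c("+", "-"))
  .assert(length(bads) == 0L,
          "strand must be '+' or '-' in row(s): ",
          paste(head(bads, 5L), collapse = ", "))
  if (!inherits(x, "probe_manifest")) class(x) <- c("probe_manifest",
                                                    class(x))
  x
}

#' Read / write a probe manifest TSV
#'
#' The file is tab-separated with header
#' `probe_id contig position strand gene isoform cgi_relation`;
#' coordinates are 1-based. All manifest invariants are enforced on read.
#'
#' @param path File path.
#' @return `read_manifest()` returns a `probe_manifest`;
#'   `write_manifest()` returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  .assert(file.exists(path), "no such file: ", path)
  x <- read.delim(path, colClasses = "character", na.strings = NULL,
                  check.names = FALSE)
  as_probe_manifest(x)
}

#' @param manifest A `probe_manifest`.
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  manifest <- as_probe_manifest(manifest)
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beta-value matrix TSV
#'
#' The first column is `probe_id`; remaining columns are samples. Values
#' must lie in `[0,1]` or be `NA`. Rows are restricted to probes present
#' in the manifest (file order preserved); rows for un-manifested probes
#' are dropped with a warning giving the count.
#'
#' @param path File path.
#' @param manifest A `probe_manifest` restricting and validating the rows.
#' @return Numeric matrix with probe ids as rownames, sample ids as
#'   colnames.
#' @export
read_beta_matrix <- function(path, manifest) {
  manifest <- as_probe_manifest(manifest)
  x <- read.delim(path, check.names = FALSE)
  .assert(names(x)[1] == "probe_id", "first column must be 'probe_id'")
  probes <- as.character(x$probe_id)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probes
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("beta value outside [0,1] at probe ", probes[bad[1, 1]],
         ", sample ", colnames(m)[bad[1, 2]], " (", nrow(bad),
         " offending value(s))", call. = FALSE)
  }
  keep <- probes %in% manifest$probe_id
  if (any(!keep)) {
    warning(sum(!keep), " probe(s) absent from manifest dropped from ",
            "beta matrix", call. = FALSE)
    m <- m[keep, , drop = FALSE]
  }
  m
}

#' @param beta Numeric probes x samples matrix with dimnames.
#' @rdname read_beta_matrix
#' @export
write_beta_matrix <- function(beta, path) {
  .assert(is.matrix(beta) && !is.null(rownames(beta)) &&
            !is.null(colnames(beta)),
          "beta must be a matrix with probe and sample dimnames")
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_results(df, path)
}

#' Read / write a sample sheet TSV
#'
#' Columns `sample_id`, `pair_id`, `condition` (`tumor`/`normal`). Each
#' pair must have exactly one tumor and one normal sample.
#'
#' @param path File path.
#' @return `read_sample_sheet()` returns a validated data frame.
#' @export
read_sample_sheet <- function(path) {
  x <- read.delim(path, colClasses = "character", check.names = FALSE)
  validate_sample_sheet(x)
}

#' @param sheet Sample sheet data frame.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- validate_sample_sheet(sheet)
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_sample_sheet
#' @export
validate_sample_sheet <- function(sheet) {
  .assert(is.data.frame(sheet), "sample sheet must be a data frame")
  miss <- setdiff(c("sample_id", "pair_id", "condition"), names(sheet))
  .assert(length(miss) == 0L,
          "sample sheet missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!sheet$condition %in% c("tumor", "normal"))
  .assert(length(bad) == 0L,
          "condition must be 'tumor' or 'normal' in row(s): ",
          paste(head(bad, 5L), collapse = ", "))
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  .assert(length(dup) == 0L,
          "duplicate sample_id(s): ", paste(unique(dup), collapse = ", "))
  for (p in unique(sheet$pair_id)) {
    cond <- sort(sheet$condition[sheet$pair_id == p])
    .assert(identical(cond, c("normal", "tumor")),
            "pair ", p, " must have exactly one tumor and one normal sample")
  }
  sheet
}

#' Write a pipeline result table
#'
#' Writes any result table (probe tests, gene candidates, signature calls,
#' digest predictions) as TSV with a stable column order and numeric
#' columns rendered with 6 significant digits.
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  .assert(is.data.frame(table), "table must be a data frame")
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read CpG-island intervals from a BED file
#'
#' BED is 0-based half-open on disk; intervals are converted to the
#' package-wide 1-based inclusive convention on read.
#'
#' @param path BED file path.
#' @return Data frame with columns `contig`, `start`, `end` (1-based
#'   inclusive) and `name` (empty when absent).
#' @export
read_cgi_bed <- function(path) {
  .assert(file.exists(path), "no such file: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),   # GRanges is already 1-based
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else "",
    stringsAsFactors = FALSE
  )
}

#' Read / write a methylated template (FASTA plus CpG-state sidecar)
#'
#' The sequence travels as single-record FASTA; per-CpG methylation states
#' travel in a sidecar TSV with columns `cpg_position` (1-based position
#' of the C) and `methylated` (`TRUE`/`FALSE`).
#'
#' @param template A [methylated_template()].
#' @param fasta_path,states_path Paths for the FASTA and the sidecar TSV.
#' @param name FASTA record name.
#' @return `read_template()` returns a [methylated_template()].
#' @export
write_template <- function(template, fasta_path, states_path,
                           name = "template") {
  stopifnot(inherits(template, "methylated_template"))
  seqs <- Biostrings::DNAStringSet(template$sequence)
  names(seqs) <- name
  Biostrings::writeXStringSet(seqs, fasta_path)
  write.table(data.frame(cpg_position = template$cpg_positions,
                         methylated = template$methylation),
              states_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' @rdname write_template
#' @export
read_template <- function(fasta_path, states_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  .assert(length(seqs) == 1L, "template FASTA must contain one record")
  states <- read.delim(states_path)
  .assert(all(c("cpg_position", "methylated") %in% names(states)),
          "states TSV must have columns cpg_position, methylated")
  tpl <- methylated_template(as.character(seqs[[1]]))
  .assert(identical(tpl$cpg_positions, as.integer(states$cpg_position)),
          "CpG positions in states TSV do not match the sequence")
  tpl$methylation <- as.logical(states$methylated)
  tpl
}
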