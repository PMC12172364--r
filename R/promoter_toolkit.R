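#' TSS annotation record
#'
#' @param gene,isoform Gene and isoform promoter labels.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param tss_position 1-based genomic coordinate of the first
#'   transcribed base.
#' @return An object of class `tss_annotation`.
#' @export
tss_annotation <- function(gene, isoform = "", contig = "chr1",
                           strand = "+", tss_position) {
  .assert(.is_string(gene), "gene must be a non-empty string")
  .assert(strand %in% c("+", "-"), "strand must be '+' or '-'")
  .assert(.is_count(tss_position, 1L), "tss_position must be >= 1")
  structure(list(gene = gene, isoform = isoform, contig = contig,
                 strand = strand, tss_position = as.integer(tss_position)),
            class = "tss_annotation")
}

#' TSS-relative signed offset
#'
#' Converts genomic coordinates into strand-aware offsets relative to the
#' transcription start site. The default convention has no zero position:
#' +1 is the first transcribed base and -1 the first base upstream of it,
#' so guides "at -179" sit 179 bases upstream of the TSS. A zero-based
#' mode (`convention = "zero_based"`, offset 0 at the TSS) is available;
#' reports should always state the convention used.
#'
#' @param position 1-based genomic coordinate(s).
#' @param tss A [tss_annotation()].
#' @param convention `"no_zero"` (default) or `"zero_based"`.
#' @return Integer vector of signed offsets (never 0 under `"no_zero"`).
#' @examples
#' tss <- tss_annotation("CLDN10-like", "B", tss_position = 1000)
#' tss_offset(1000, tss)  # +1
#' tss_offset(821, tss)   # -179
#' @export
tss_offset <- function(position, tss, convention = c("no_zero",
                                                     "zero_based")) {
  convention <- match.arg(convention)
  stopifnot(inherits(tss, "tss_annotation"))
  .assert(is.numeric(position) && all(position >= 1),
          "position must be >= 1")
  d <- if (tss$strand == "+") position - tss$tss_position
       else tss$tss_position - position
  d <- as.integer(d)
  if (convention == "zero_based") return(d)
  ifelse(d >= 0L, d + 1L, d)
}

#' Scan for E-box motifs
#'
#' Finds all occurrences of the two E-box variants `CAGCTG` and `CAGATG`
#' on the given strand of the query, in ascending position order. The
#' degenerate mode scans the full E-box consensus `CANNTG` instead.
#'
#' @param sequence A/C/G/T string.
#' @param degenerate Scan `CANNTG` instead of the two exact variants.
#' @return Data frame with columns `motif` (matched text), `position`
#'   (1-based) and `strand` (`"+"`, the given strand).
#' @examples
#' scan_ebox("CTGCAGATGGAGAACCCGGG")  # CAGATG at 4
#' @export
scan_ebox <- function(sequence, degenerate = FALSE) {
  .check_dna(sequence)
  subject <- Biostrings::DNAString(sequence)
  if (degenerate) {
    hits <- Biostrings::matchPattern("CANNTG", subject, fixed = FALSE)
    pos <- as.integer(Biostrings::start(hits))
    motif <- substring(sequence, pos, pos + 5L)
  } else {
    pos <- integer(0)
    motif <- character(0)
    for (m in c("CAGCTG", "CAGATG")) {
      hits <- Biostrings::matchPattern(m, subject)
      p <- as.integer(Biostrings::start(hits))
      pos <- c(pos, p)
      motif <- c(motif, rep(m, length(p)))
    }
  }
  ord <- order(pos)
  data.frame(motif = motif[ord], position = pos[ord],
             strand = rep("+", length(ord)), stringsAsFactors = FALSE)
}

#' Count sgRNA off-target sites by mismatch search
#'
#' Enumerates every 20-mer window on both strands of the reference
#' sequences whose Hamming distance to the guide is at most
#' `max_mismatches`. With `require_pam = TRUE` (the SpCas9 default) the
#' window must be immediately followed by an NGG protospacer-adjacent
#' motif on the matched strand; `require_pam = FALSE` reproduces naive
#' k-mismatch counting. The guide's own perfect site is included in the
#' count and flagged `on_target`. Scanning is exact enumeration (no seed
#' heuristics), intended for promoter- to chromosome-scale references.
#'
#' @param guide_sequence 20-nt guide (protospacer) sequence.
#' @param reference_sequences Named character vector or
#'   `Biostrings::DNAStringSet` of reference sequences.
#' @param max_mismatches Maximum Hamming distance (default 1).
#' @param require_pam Require an NGG PAM 3' of the protospacer (default
#'   `TRUE`).
#' @return List with `count` and `sites`, a data frame with columns
#'   `seqname`, `start` (1-based, top-strand leftmost base of the
#'   20-mer), `strand`, `mismatches`, `on_target`.
#' @export
count_offtargets <- function(guide_sequence, reference_sequences,
                             max_mismatches = 1L, require_pam = TRUE) {
  .check_dna(guide_sequence, "guide_sequence")
  .assert(nchar(guide_sequence) == 20L, "guide must be 20 nt")
  .assert(.is_count(max_mismatches, 0L), "max_mismatches must be >= 0")
  if (is.character(reference_sequences)) {
    if (is.null(names(reference_sequences))) {
      names(reference_sequences) <-
        sprintf("ref%d", seq_along(reference_sequences))
    }
    reference_sequences <- Biostrings::DNAStringSet(reference_sequences)
  }
  .assert(methods::is(reference_sequences, "DNAStringSet") &&
            length(reference_sequences) > 0L,
          "reference_sequences must be a non-empty sequence set")
  guide <- Biostrings::DNAString(guide_sequence)
  rows <- list()
  for (i in seq_along(reference_sequences)) {
    ref <- reference_sequences[[i]]
    nm <- names(reference_sequences)[i]
    len <- length(ref)
    for (str in c("+", "-")) {
      subject <- if (str == "+") ref else Biostrings::reverseComplement(ref)
      hits <- Biostrings::matchPattern(guide, subject,
                                       max.mismatch = max_mismatches,
                                       with.indels = FALSE)
      if (length(hits) == 0L) next
      s <- Biostrings::start(hits)
      e <- Biostrings::end(hits)
      keep <- s >= 1L & e <= len
      if (require_pam) {
        subj_chr <- as.character(subject)
        pam <- substring(subj_chr, e + 2L, e + 3L)
        keep <- keep & (e + 3L) <= len & pam == "GG"
      }
      if (!any(keep)) next
      s <- s[keep]
      mism <- Biostrings::neditStartingAt(guide, subject, starting.at = s,
                                          with.indels = FALSE)
      start_top <- if (str == "+") s else len - (s + 19L) + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        seqname = nm, start = as.integer(start_top), strand = str,
        mismatches = as.integer(mism), on_target = mism == 0L,
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seqname = character(0), start = integer(0),
               strand = character(0), mismatches = integer(0),
               on_target = logical(0), stringsAsFactors = FALSE)
  sites <- sites[order(sites$seqname, sites$start, sites$strand), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  list(count = nrow(sites), sites = sites)
}
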