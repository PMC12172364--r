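# Internal sequence helpers. All scanning goes through Biostrings; the
# top strand is the modelled strand throughout (the bottom strand is
# obtained by converting the reverse complement on demand).

.check_dna <- function(sequence, what = "sequence") {
  .assert(.is_string(sequence), what, " must be a non-empty string")
  .assert(grepl("^[ACGT]+$", sequence),
          what, " contains non-ACGT character(s)")
  sequence
}

.find_cpgs <- function(sequence) {
  hits <- Biostrings::matchPattern("CG", Biostrings::DNAString(sequence))
  as.integer(Biostrings::start(hits))
}

#' Methylation-annotated DNA template
#'
#' The computational abstraction of a bisulfite-treatable molecule: a
#' top-strand DNA sequence together with the 1-based positions of the C
#' of every CG dinucleotide and a per-CpG methylation state. The CpG
#' position list always equals the exact set of CG occurrences in the
#' sequence.
#'
#' @param sequence A/C/G/T string.
#' @param methylation `"all"`, `"none"`, or a logical vector with one
#'   state per CpG.
#' @param strand_label `"top"` or `"bottom"` (annotation only).
#' @return An object of class `methylated_template` with fields
#'   `sequence`, `cpg_positions`, `methylation`, `strand_label`.
#' @examples
#' methylated_template("ATCGAT", methylation = "all")
#' @export
methylated_template <- function(sequence, methylation = "all",
                                strand_label = "top") {
  .check_dna(sequence)
  .assert(strand_label %in% c("top", "bottom"),
          "strand_label must be 'top' or 'bottom'")
  cpg <- .find_cpgs(sequence)
  states <- .resolve_states(methylation, length(cpg))
  structure(list(sequence = sequence, cpg_positions = cpg,
                 methylation = states, strand_label = strand_label),
            class = "methylated_template")
}

#' @export
print.methylated_template <- function(x, ...) {
  cat("methylated_template (", x$strand_label, " strand): ",
      nchar(x$sequence), " nt, ", length(x$cpg_positions), " CpGs (",
      sum(x$methylation), " methylated)\n", sep = "")
  invisible(x)
}

#' Restriction enzyme model
#'
#' Only the recognition motif and cut geometry are modelled: the duplex
#' is cut `cut_offset` bases after the motif start (so the left fragment
#' ends `cut_offset` bases into the motif).
#'
#' @param name Enzyme name.
#' @param recognition_motif A/C/G/T motif.
#' @param cut_offset Integer in `[0, nchar(motif)]`.
#' @return An object of class `enzyme`.
#' @export
enzyme <- function(name, recognition_motif, cut_offset) {
  .assert(.is_string(name), "name must be a non-empty string")
  .check_dna(recognition_motif, "recognition_motif")
  .assert(.is_count(cut_offset, 0L) &&
            cut_offset <= nchar(recognition_motif),
          "cut_offset must lie in [0, motif length]")
  structure(list(name = name, recognition_motif = recognition_motif,
                 cut_offset = as.integer(cut_offset)),
            class = "enzyme")
}

#' TaqI enzyme (T^CGA)
#'
#' The CoBRA workhorse: its TCGA site contains a CpG, so bisulfite
#' conversion destroys the site (TCGA becomes TTGA) unless the CpG is
#' methylated.
#'
#' @return An [enzyme()] with motif `TCGA` and cut offset 1.
#' @export
taq1 <- function() enzyme("TaqI", "TCGA", 1L)

#' Bisulfite conversion as a string rewrite
#'
#' Converts a methylation-annotated template the way the chemistry does:
#' every cytosine outside a CpG context is deaminated and read as T, the
#' C of an unmethylated CpG likewise, and the C of a methylated CpG is
#' protected and stays C. All other bases (and the length) are unchanged.
#' The operation is idempotent on its own output.
#'
#' @param template A [methylated_template()].
#' @return The converted sequence as a string.
#' @examples
#' bisulfite_convert(methylated_template("ATCGAT", "all"))   # "ATCGAT"
#' bisulfite_convert(methylated_template("ATCGAT", "none"))  # "ATTGAT"
#' @export
bisulfite_convert <- function(template) {
  stopifnot(inherits(template, "methylated_template"))
  chars <- strsplit(template$sequence, "", fixed = TRUE)[[1]]
  protected <- template$cpg_positions[template$methylation]
  convert <- which(chars == "C")
  convert <- setdiff(convert, protected)
  chars[convert] <- "T"
  paste(chars, collapse = "")
}

#' Virtual PCR on a converted reference
#'
#' Amplifies the unique region delimited by the forward primer (matched
#' verbatim on the given strand) and the reverse primer (matched as its
#' reverse complement). The product spans from the 5' end of the forward
#' match to the 5' end of the reverse primer, i.e. the 3'-most base of
#' its reverse-complement match. Primer matching is exact.
#'
#' @param converted_reference Reference sequence (typically the output of
#'   [bisulfite_convert()]).
#' @param forward_primer,reverse_primer Primer sequences, >= 15 nt.
#' @return List with `sequence`, `start`, `end` (1-based, inclusive) and
#'   `length`.
#' @export
virtual_pcr <- function(converted_reference, forward_primer,
                        reverse_primer) {
  .check_dna(converted_reference, "converted_reference")
  .check_dna(forward_primer, "forward_primer")
  .check_dna(reverse_primer, "reverse_primer")
  .assert(nchar(forward_primer) >= 15L && nchar(reverse_primer) >= 15L,
          "primers must be at least 15 nt")
  ref <- Biostrings::DNAString(converted_reference)
  fhits <- Biostrings::matchPattern(forward_primer, ref)
  .assert(length(fhits) == 1L,
          length(fhits), " forward matches (need exactly 1)")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(reverse_primer)))
  rhits <- Biostrings::matchPattern(rc, ref)
  .assert(length(rhits) == 1L,
          length(rhits), " reverse matches (need exactly 1)")
  start <- Biostrings::start(fhits)[1]
  end <- Biostrings::end(rhits)[1]
  .assert(end >= start + nchar(forward_primer) - 1L,
          "reverse primer site lies upstream of the forward site")
  list(sequence = substr(converted_reference, start, end),
       start = start, end = end, length = end - start + 1L)
}

#' Scan a sequence for enzyme recognition sites
#'
#' Returns all (possibly overlapping) 1-based motif start positions, in
#' ascending order.
#'
#' @param sequence A/C/G/T string.
#' @param enz An [enzyme()].
#' @return Integer vector of motif starts.
#' @examples
#' scan_sites("ATCGATTCGA", taq1())  # 2, 7
#' @export
scan_sites <- function(sequence, enz) {
  .check_dna(sequence)
  stopifnot(inherits(enz, "enzyme"))
  hits <- Biostrings::matchPattern(enz$recognition_motif,
                                   Biostrings::DNAString(sequence))
  sort(as.integer(Biostrings::start(hits)))
}

#' Predict a methylation-dependent restriction digest (in silico CoBRA)
#'
#' Runs the complete combined bisulfite restriction analysis in silico:
#' the template is bisulfite-converted under two scenarios — all CpGs
#' methylated and all CpGs unmethylated — each converted reference is
#' amplified with the same primer pair, and the enzyme sites surviving in
#' each product give the cut coordinates and band sizes of the two gel
#' lanes. A cut coordinate is a prefix length: a site starting at `s`
#' with cut offset `o` cuts after base `s + o - 1`. Fragments in each
#' scenario always sum to the product length.
#'
#' The two scenario products must have identical length; a length
#' difference means a primer footprint covers a CpG (use
#' [validate_primer()]).
#'
#' @param template A [methylated_template()] of the genomic region.
#' @param fwd,rev Primer pair designed against fully converted DNA.
#' @param enz An [enzyme()]; defaults to [taq1()].
#' @return An object of class `digest_prediction` with fields
#'   `product_length`, `product_start`, `product_end`, `site_positions`
#'   (motif starts in the methylated-scenario product),
#'   `site_positions_unmethylated`, `cut_coordinates`,
#'   `cut_coordinates_unmethylated`, `fragments_methylated`,
#'   `fragments_unmethylated`, `enzyme`.
#' @export
predict_digest <- function(template, fwd, rev, enz = taq1()) {
  stopifnot(inherits(template, "methylated_template"),
            inherits(enz, "enzyme"))
  scen <- function(state) {
    tpl <- template
    tpl$methylation <- rep(state, length(tpl$cpg_positions))
    conv <- bisulfite_convert(tpl)
    virtual_pcr(conv, fwd, rev)
  }
  meth <- scen(TRUE)
  unmeth <- scen(FALSE)
  .assert(meth$length == unmeth$length,
          "scenario product lengths differ (", meth$length, " vs ",
          unmeth$length, "); primer sites must be CpG-free")
  len <- meth$length
  cuts_of <- function(product) {
    starts <- scan_sites(product, enz)
    cuts <- starts + enz$cut_offset - 1L
    sort(unique(cuts[cuts > 0L & cuts < len]))
  }
  sites_m <- scan_sites(meth$sequence, enz)
  sites_u <- scan_sites(unmeth$sequence, enz)
  cuts_m <- cuts_of(meth$sequence)
  cuts_u <- cuts_of(unmeth$sequence)
  structure(list(
    product_length = len,
    product_start = meth$start,
    product_end = meth$end,
    site_positions = sites_m,
    site_positions_unmethylated = sites_u,
    cut_coordinates = cuts_m,
    cut_coordinates_unmethylated = cuts_u,
    fragments_methylated = as.integer(diff(c(0L, cuts_m, len))),
    fragments_unmethylated = as.integer(diff(c(0L, cuts_u, len))),
    enzyme = enz
  ), class = "digest_prediction")
}

#' @export
print.digest_prediction <- function(x, ...) {
  band <- function(frags) paste(sort(frags, decreasing = TRUE),
                                collapse = " / ")
  cat("CoBRA digest prediction (", x$enzyme$name, ", motif ",
      x$enzyme$recognition_motif, ")\n", sep = "")
  cat("  product: ", x$product_length, " bp (reference ",
      x$product_start, "..", x$product_end, ")\n", sep = "")
  cat("  sites (methylated scenario): ",
      if (length(x$site_positions)) paste(x$site_positions,
                                          collapse = ", ") else "none",
      "\n", sep = "")
  cat("  virtual gel, methylated:   ", band(x$fragments_methylated),
      " bp\n", sep = "")
  cat("  virtual gel, unmethylated: ", band(x$fragments_unmethylated),
      " bp\n", sep = "")
  invisible(x)
}

#' Validate a bisulfite PCR primer
#'
#' Checks the three design rules for primers on bisulfite-treated DNA:
#' the footprint must not overlap a CpG (binding would depend on
#' methylation state), it should contain at least one non-CpG cytosine of
#' the original template (so the primer binds only fully converted DNA),
#' and it must match the converted reference uniquely.
#'
#' @param primer Primer sequence, >= 15 nt.
#' @param template The original [methylated_template()].
#' @param converted_reference Converted sequence in the same coordinates
#'   as the template (e.g. `bisulfite_convert()` of it).
#' @return List with logical flags `overlaps_cpg`,
#'   `conversion_specific`, `unique_match`, plus `orientation`
#'   (`"forward"`/`"reverse"`), `footprint_start`, `footprint_end`,
#'   `n_matches`. A primer with no conversion evidence triggers a
#'   warning.
#' @export
validate_primer <- function(primer, template, converted_reference) {
  stopifnot(inherits(template, "methylated_template"))
  .check_dna(primer, "primer")
  .assert(nchar(primer) >= 15L, "primer must be at least 15 nt")
  .check_dna(converted_reference, "converted_reference")
  ref <- Biostrings::DNAString(converted_reference)
  fhits <- Biostrings::matchPattern(primer, ref)
  orientation <- "forward"
  hits <- fhits
  if (length(fhits) == 0L) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(primer)))
    hits <- Biostrings::matchPattern(rc, ref)
    orientation <- "reverse"
  }
  .assert(length(hits) > 0L, "primer unmappable to template")
  fs <- Biostrings::start(hits)[1]
  fe <- Biostrings::end(hits)[1]
  cpg <- template$cpg_positions
  overlaps_cpg <- any(cpg <= fe & (cpg + 1L) >= fs)
  chars <- strsplit(template$sequence, "", fixed = TRUE)[[1]]
  foot_c <- which(chars[fs:fe] == "C") + fs - 1L
  conversion_specific <- length(setdiff(foot_c, cpg)) > 0L
  if (!conversion_specific) {
    warning("primer footprint carries no conversion evidence ",
            "(no non-CpG C on the template)", call. = FALSE)
  }
  list(overlaps_cpg = overlaps_cpg,
       conversion_specific = conversion_specific,
       unique_match = length(hits) == 1L,
       orientation = orientation,
       footprint_start = as.integer(fs), footprint_end = as.integer(fe),
       n_matches = length(hits))
}

#' Synthetic CoBRA worked example
#'
#' Constructs a synthetic template and primer pair with the geometry of
#' the claudin-10B CoBRA verification assay: a 172 bp PCR product whose
#' TaqI sites sit at cut coordinates 42, 66 and 126 bp, every site
#' CpG-dependent, and CpG-free primer footprints carrying non-CpG
#' cytosines (conversion-specific binding). The fully methylated scenario
#' therefore yields bands of 42/24/60/46 bp and the unmethylated scenario
#' a single uncut 172 bp band. The sequence itself is synthetic (random
#' A/G/T background with the CpG-containing sites planted), not a genomic
#' extract.
#'
#' @param seed Integer seed for the background sequence.
#' @return List with `template` (a [methylated_template()], all CpGs
#'   methylated), `fwd`, `rev` (primer pair) and `enzyme` ([taq1()]).
#' @examples
#' ex <- cobra_worked_example()
#' predict_digest(ex$template, ex$fwd, ex$rev, ex$enzyme)
#' @export
cobra_worked_example <- function(seed = 42L) {
  set.seed(seed)
  len <- 300L
  chars <- sample(c("A", "G", "T"), len, replace = TRUE)
  p_start <- 50L                       # product spans 50..221 = 172 bp
  site_starts <- p_start - 1L + c(42L, 66L, 126L)  # TaqI cut offset is 1
  for (s in site_starts) chars[s:(s + 3L)] <- c("T", "C", "G", "A")
  # non-CpG cytosines inside both primer footprints (50..69, 202..221)
  chars[55] <- "C"; chars[56] <- "A"
  chars[60] <- "C"; chars[61] <- "T"
  chars[206] <- "C"; chars[207] <- "A"
  chars[214] <- "C"; chars[215] <- "T"
  sequence <- paste(chars, collapse = "")
  template <- methylated_template(sequence, methylation = "all")
  stopifnot(length(template$cpg_positions) == 3L)
  conv <- bisulfite_convert(
    methylated_template(sequence, methylation = "none"))
  fwd <- substr(conv, p_start, p_start + 19L)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(conv, 202L, 221L))))
  list(template = template, fwd = fwd, rev = rev, enzyme = taq1())
}
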