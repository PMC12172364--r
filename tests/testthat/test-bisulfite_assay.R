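test_that("bisulfite conversion follows the per-position rule", {
  # CpGs at 2 (unmethylated) and 6 (methylated): only the protected C stays
  tpl <- methylated_template("ACGATCGT", methylation = c(FALSE, TRUE))
  expect_equal(bisulfite_convert(tpl), "ATGATCGT")
  # the CoBRA principle on a TaqI site
  expect_equal(bisulfite_convert(methylated_template("ATCGAT", "all")),
               "ATCGAT")
  expect_equal(bisulfite_convert(methylated_template("ATCGAT", "none")),
               "ATTGAT")
  expect_error(methylated_template("ATNGAT"), "non-ACGT")
})

test_that("conversion is idempotent on its own output", {
  set.seed(12)
  for (i in 1:20) {
    tpl <- generate_template(length = 150, cpg_density = 0.08,
                             methylation = 0.5)
    conv <- bisulfite_convert(tpl)
    again <- methylated_template(conv, methylation = "all")
    # every CpG in the converted sequence is a protected (methylated) one
    expect_equal(bisulfite_convert(again), conv)
  }
})

test_that("virtual PCR amplifies the unique primer-delimited region", {
  set.seed(4)
  ref <- random_dna(300)
  fwd <- substr(ref, 50, 69)
  rev <- revcomp_chr(substr(ref, 202, 221))
  prod <- virtual_pcr(ref, fwd, rev)
  expect_equal(prod$length, 172)
  expect_equal(prod$start, 50)
  expect_equal(prod$end, 221)
  expect_equal(prod$sequence, substr(ref, 50, 221))
  # adjacent primers spanning the whole reference return it unchanged
  whole <- virtual_pcr(ref, substr(ref, 1, 20),
                       revcomp_chr(substr(ref, 281, 300)))
  expect_equal(whole$sequence, ref)
})

test_that("virtual PCR rejects ambiguous or inverted primer sites", {
  ref <- paste0(strrep("A", 30), "TTTTTGGGGGTTTTTGGGGG",
                strrep("A", 30), "TTTTTGGGGGTTTTTGGGGG", strrep("A", 30))
  expect_error(virtual_pcr(ref, "TTTTTGGGGGTTTTTGGGGG",
                           revcomp_chr(strrep("A", 20))),
               "2 forward matches")
  set.seed(6)
  ref2 <- random_dna(200)
  expect_error(virtual_pcr(ref2, substr(ref2, 150, 169),
                           revcomp_chr(substr(ref2, 20, 39))),
               "upstream")
})

test_that("site scans match a brute-force oracle", {
  expect_equal(scan_sites("ATCGATTCGA", taq1()), c(2L, 7L))
  expect_equal(scan_sites("AAAATTTT", taq1()), integer(0))
  # overlapping occurrences are all reported
  ee <- enzyme("toy", "AA", 1L)
  expect_equal(scan_sites("AAAA", ee), c(1L, 2L, 3L))
  set.seed(9)
  for (i in 1:200) {
    s <- random_dna(sample(20:80, 1))
    expect_identical(scan_sites(s, taq1()),
                     as.integer(scan_oracle(s, "TCGA")))
  }
})

test_that("the worked CoBRA assay yields the published band geometry", {
  ex <- cobra_worked_example()
  dig <- predict_digest(ex$template, ex$fwd, ex$rev, ex$enzyme)
  expect_equal(dig$product_length, 172L)
  expect_equal(dig$cut_coordinates, c(42L, 66L, 126L))
  # successive differences of the cut coordinates: 42+24+60+46 = 172
  expect_equal(dig$fragments_methylated, c(42L, 24L, 60L, 46L))
  expect_equal(sum(dig$fragments_methylated), 172L)
  # every site is CpG-dependent: unmethylated lane is a single band
  expect_equal(dig$fragments_unmethylated, 172L)
  # both primers pass validation against the converted reference
  conv <- bisulfite_convert(ex$template)
  for (p in c(ex$fwd, ex$rev)) {
    rep <- validate_primer(p, ex$template, conv)
    expect_false(rep$overlaps_cpg)
    expect_true(rep$conversion_specific)
    expect_true(rep$unique_match)
  }
})

test_that("digests without motifs or without CpG-free motifs degenerate correctly", {
  set.seed(15)
  base <- strsplit(random_dna(200), "")[[1]]
  base[base == "C"] <- "T"            # no cytosines at all
  seq_nocut <- paste(base, collapse = "")
  tpl <- methylated_template(seq_nocut, "all")
  fwd <- substr(seq_nocut, 1, 20)
  rev <- revcomp_chr(substr(seq_nocut, 181, 200))
  dig <- predict_digest(tpl, fwd, rev)
  expect_equal(dig$fragments_methylated, dig$product_length)
  expect_equal(dig$fragments_unmethylated, dig$product_length)
})

test_that("fragments always sum to the product length (random templates)", {
  set.seed(23)
  for (i in 1:200) {
    tpl <- generate_template(length = 220, cpg_density = 0.06)
    fwd_foot <- substr(tpl$sequence, 1, 20)
    rev_foot <- substr(tpl$sequence, 201, 220)
    # skip templates whose primer footprints touch a CpG (predict_digest
    # rejects those by design) or whose primers are not unique
    cpg <- tpl$cpg_positions
    if (any(cpg <= 20 | (cpg + 1) >= 201)) next
    conv_none <- bisulfite_convert(methylated_template(tpl$sequence,
                                                       "none"))
    fwd <- substr(conv_none, 1, 20)
    rev <- revcomp_chr(substr(conv_none, 201, 220))
    dig <- tryCatch(predict_digest(tpl, fwd, rev),
                    error = function(e) NULL)
    if (is.null(dig)) next
    expect_equal(sum(dig$fragments_methylated), dig$product_length)
    expect_equal(sum(dig$fragments_unmethylated), dig$product_length)
    expect_true(all(diff(dig$cut_coordinates) > 0))
  }
})

test_that("methylating a CpG inside a motif never removes cuts", {
  # TaqI sites whose CpG state flips between scenarios
  seqs <- "AAATCGAAATTCGATTTCGAAAA"
  tpl_all <- methylated_template(seqs, "all")
  tpl_none <- methylated_template(seqs, "none")
  n_all <- length(scan_sites(bisulfite_convert(tpl_all), taq1()))
  n_none <- length(scan_sites(bisulfite_convert(tpl_none), taq1()))
  expect_gte(n_all, n_none)
  # progressive methylation is monotone in cut count
  counts <- vapply(0:3, function(k) {
    st <- rep(FALSE, 3); if (k > 0) st[seq_len(k)] <- TRUE
    length(scan_sites(bisulfite_convert(
      methylated_template(seqs, st)), taq1()))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("primer validation flags CpG overlap and conversion evidence", {
  # footprint with a CpG at position 10
  seq1 <- paste0("ATATTATATCGTATATTATA", strrep("A", 30))
  tpl1 <- methylated_template(seq1, "none")
  conv1 <- bisulfite_convert(tpl1)
  rep1 <- suppressWarnings(validate_primer(substr(conv1, 1, 20), tpl1,
                                           conv1))
  expect_true(rep1$overlaps_cpg)
  # CpG-free footprint with a non-CpG C converts specifically
  seq2 <- paste0("ATATTACATATTGATATTAT", strrep("G", 30))
  tpl2 <- methylated_template(seq2, "none")
  conv2 <- bisulfite_convert(tpl2)
  rep2 <- validate_primer(substr(conv2, 1, 20), tpl2, conv2)
  expect_false(rep2$overlaps_cpg)
  expect_true(rep2$conversion_specific)
  expect_true(rep2$unique_match)
  # no cytosine at all in the footprint: warning, (b) = FALSE
  seq3 <- paste0("ATATTAGATATTGATATTAT", strrep("C", 30))
  tpl3 <- methylated_template(seq3, "none")
  conv3 <- bisulfite_convert(tpl3)
  expect_warning(rep3 <- validate_primer(substr(conv3, 1, 20), tpl3,
                                         conv3),
                 "conversion")
  expect_false(rep3$conversion_specific)
  expect_error(validate_primer(strrep("T", 20), tpl1,
                               strrep("G", 60)), "unmappable")
})
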