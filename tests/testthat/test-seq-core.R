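test_that("revcomp handles hand-checked cases and rejects bad alphabets", {
  expect_identical(revcomp("AATG"), "CATT")
  expect_identical(revcomp(""), "")
  expect_identical(revcomp("GCGGCCGC"), "GCGGCCGC")  # NotI site palindromic
  expect_error(revcomp("ACGX"), class = "vegassim_alphabet_error")
  err <- tryCatch(revcomp("ACGX"), error = identity)
  expect_match(conditionMessage(err), "position 3")
})

test_that("revcomp is an involution on random sequences", {
  withr::with_seed(11, {
    for (i in 1:50) {
      s <- rand_dna(sample(0:300, 1))
      expect_identical(revcomp(revcomp(s)), s)
    }
  })
})

test_that("nuc_seq normalizes case and enforces the alphabet and features", {
  s <- nuc_seq("acgt", name = "x")
  expect_identical(s$bases, "ACGT")
  expect_error(nuc_seq("ACGU"), class = "vegassim_alphabet_error")
  expect_error(
    nuc_seq("ACGT", features = data.frame(label = "f", start = 0L,
                                          end = 9L, strand = "+")),
    class = "vegassim_feature_error")
  # circular molecules may carry wrapping features
  expect_silent(nuc_seq("ACGTACGT", "circular",
                        features = data.frame(label = "w", start = 6L,
                                              end = 2L, strand = "+")))
})

test_that("scan_sites finds literal, adapter and origin-spanning sites", {
  hits <- scan_sites("GGTCTCA", "BsaI")
  expect_equal(hits$position, 0L)
  expect_equal(hits$strand, "+")

  # packaged VA1 is free of BsaI sites on both strands
  va1 <- va_adapters()$sequence[1]
  expect_identical(nrow(scan_sites(va1, "BsaI")), 0L)

  # a BsaI site assembled only across the circular origin
  s <- paste0("TCTCAAATTTGCCGCAAAGG")  # ends GG + starts TCTC -> GGTCTC
  circ <- nuc_seq(s, "circular")
  hits <- scan_sites(circ, "BsaI")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 18L)  # GG at 18, wraps into TCTC
  # the same string scanned linear has no site
  expect_equal(nrow(scan_sites(nuc_seq(s), "BsaI")), 0L)
})

test_that("scan_sites agrees with the naive quadratic oracle", {
  enzymes <- vegas_enzymes()
  withr::with_seed(202, {
    for (i in 1:1000) {
      s <- rand_dna(200)
      e <- enzymes[[sample(length(enzymes), 1)]]
      got <- scan_sites(s, e)
      want <- naive_scan(s, e$recognition)
      expect_equal(got$position, want$position)
      expect_equal(got$strand, want$strand)
    }
  })
})

test_that("offset digestion exposes the 1/5 four-base overhangs", {
  # part-style insert: GGTCTC.N.CCTG...CAGT.N.GAGACC
  core <- "AAACCCGGGTTTAAA"
  ins <- paste0("GGTCTC", "A", "CCTG", core, "CAGT", "T", "GAGACC")
  frags <- digest(nuc_seq(ins, name = "ins"), "BsaI")
  expect_length(frags, 3L)
  mid <- frags[[2]]
  expect_identical(mid$end5$overhang, "CCTG")
  expect_identical(mid$end5$protruding, "top")
  expect_identical(mid$end3$overhang, "CAGT")
  expect_identical(mid$end3$protruding, "bottom")
  # the top strand carries the 5' overhang; the 3' junction 4-mer is
  # single-stranded on the *next* fragment's top strand
  expect_identical(mid$top, paste0("CCTG", core))
  # physical protruding strands are reverse complements at a junction
  expect_identical(protruding_strand_seq(mid, "end5"), "CCTG")
  expect_identical(protruding_strand_seq(mid, "end3"), revcomp("CAGT"))
})

test_that("circular digestion yields n fragments with sticky 4-mers", {
  withr::with_seed(7, {
    # draw spans until free of chance BsaI sites (bounded, deterministic)
    for (try in 1:20) {
      a <- rand_dna(1500); b <- rand_dna(1400)
      plasmid <- nuc_seq(paste0("GGTCTC", "A", a, "GGTCTC", "A", b),
                         "circular", name = "p2")
      if (nrow(scan_sites(plasmid, "BsaI")) == 2L) break
    }
    expect_equal(nrow(scan_sites(plasmid, "BsaI")), 2L)
    frags <- digest(plasmid, "BsaI")
    expect_length(frags, 2L)
    for (f in frags) {
      expect_identical(nchar(f$end5$overhang), 4L)
      expect_identical(nchar(f$end3$overhang), 4L)
      expect_identical(f$end5$protruding, "top")
      expect_identical(f$end3$protruding, "bottom")
    }
    # top strands partition the circle
    expect_identical(sum(vapply(frags, function(f) nchar(f$top), 0L)),
                     nchar(plasmid$bases))
  })
})

test_that("zero-site digestion warns and returns the input; off-end cuts error", {
  s <- nuc_seq("ACGTACGTACGT", name = "plain")
  expect_warning(out <- digest(s, "BsaI"), "no BsaI site")
  expect_length(out, 1L)
  expect_identical(out[[1]], s)
  # cut window runs off the end of a linear molecule
  expect_error(digest(nuc_seq("AAAGGTCTCAA"), "BsaI"),
               class = "vegassim_cut_error")
  err <- tryCatch(digest(nuc_seq("AAAGGTCTCAA"), "BsaI"), error = identity)
  expect_match(conditionMessage(err), "position 3")
})

test_that("digestion conserves length and religation reconstructs the input", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n_sites <- sample(2:4, 1)
      spans <- replicate(n_sites, rand_dna(sample(200:800, 1)))
      s <- paste(paste0("GGTCTC", "A", spans), collapse = "")
      plasmid <- nuc_seq(s, "circular", name = "rand")
      if (nrow(scan_sites(plasmid, "BsaI")) != n_sites) next
      frags <- digest(plasmid, "BsaI")
      expect_length(frags, n_sites)
      ## length conservation: double-stranded extents plus one overhang
      ## per junction sum to the input length
      ds <- vapply(frags, function(f)
        nchar(f$top) - nchar(f$end5$overhang), 0L)
      expect_identical(sum(ds) + sum(vapply(frags, function(f)
        nchar(f$end5$overhang), 0L)), nchar(s))
      ## religation in original order reconstructs the input circle
      relig <- ligate_fragments(frags, circular = TRUE)
      expect_true(circular_identical(relig, plasmid))
    }
  })
})

test_that("flip_fragment mirrors ends and ligation compatibility", {
  ins <- paste0("GGTCTC", "A", "CCTG", "AAATTTCCC", "CAGT", "T", "GAGACC")
  mid <- digest(nuc_seq(ins), "BsaI")[[2]]
  flip <- flip_fragment(mid)
  expect_identical(flip$top, revcomp(mid$top))
  expect_identical(flip$end5$overhang, revcomp(mid$end3$overhang))
  expect_identical(flip$end5$protruding, "top")
  # a flipped copy presents revcomp'd overhangs, so it cannot take the
  # original's place in a chain
  expect_true(ends_compatible(mid$end3, end_spec("CAGT", "top")))
  expect_false(ends_compatible(mid$end3, flip$end5))
})

test_that("NotI and FseI cut within their sites with the right chemistry", {
  s <- nuc_seq(paste0(strrep("A", 20), "GCGGCCGC", strrep("T", 20)))
  frags <- digest(s, "NotI")
  expect_length(frags, 2L)
  expect_identical(frags[[2]]$end5$overhang, "GGCC")
  expect_identical(frags[[2]]$end5$protruding, "top")     # 5' overhang
  s2 <- nuc_seq(paste0(strrep("A", 20), "GGCCGGCC", strrep("T", 20)))
  frags2 <- digest(s2, "FseI")
  expect_identical(frags2[[2]]$end5$overhang, "CCGG")
  expect_identical(frags2[[2]]$end5$protruding, "bottom") # 3' overhang
  expect_identical(get_enzyme("FseI")$overhang_kind, "three_prime")
})
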