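test_that("VA chain validation enforces the adapter-homology pattern", {
  kit <- test_kit()
  d <- kit$designs$bcar_va  # VA1-..-VA3-..-VA4-..-VA5-..-VA6-..-VA2
  expect_true(validate_va_chain(d)$pass)

  broken <- d
  broken$lva[2] <- "VA5"
  broken <- pathway_design(broken, "va_homology")
  rep <- validate_va_chain(broken)
  expect_false(rep$pass)
  expect_match(rep$problems$junction[1], "slot1/slot2")

  single <- pathway_design(
    data.frame(name = "only_TU", lva = "VA1", pro = "pTDH3", cds = "crtE",
               ter = "ttACS2", rva = "VA2", stringsAsFactors = FALSE),
    "va_homology")
  expect_true(validate_va_chain(single)$pass)

  expect_error(validate_va_chain(kit$designs$bcar_pcr),
               class = "vegassim_design_error")
})

test_that("junction primers carry 30-nt tails giving 60 bp shared identity", {
  kit <- test_kit()
  d <- kit$designs$bcar_pcr
  pairs <- design_vegas_primers(d, kit$adapters)
  expect_length(pairs, 5L)
  for (p in pairs) {
    expect_equal(nchar(p$forward$tail), 30L)
    expect_equal(nchar(p$reverse$tail), 30L)
    expect_equal(nchar(p$forward$anneal), 20L)
  }
  # junction crtE(RVA=VA3) / crtI(LVA=VA8): the crtE reverse tail is the
  # revcomp of VA8's first 30 bases; the crtI forward tail is VA3's last 30
  va3 <- adapter_seq("VA3")[[1]]; va8 <- adapter_seq("VA8")[[1]]
  expect_identical(pairs[[1]]$reverse$tail, revcomp(substr(va8, 1, 30)))
  expect_identical(pairs[[2]]$forward$tail, substr(va3, 28, 57))

  # predicted adjacent amplicons share exactly 60 bp of terminal identity
  tu1 <- release_tu(assemble_tu(d, 1, kit)$product)
  tu2 <- release_tu(assemble_tu(d, 2, kit)$product)
  a1 <- predict_amplicon(tu1, pairs[[1]])
  a2 <- predict_amplicon(tu2, pairs[[2]])
  ov <- terminal_overlap(a1, a2)
  expect_equal(as.integer(ov), 60L)
  expect_identical(attr(ov, "orientation"), "forward")

  # degenerate zero-length tails give zero engineered terminal identity
  pairs0 <- design_vegas_primers(d, kit$adapters, tail_len = 0L)
  a10 <- predict_amplicon(tu1, pairs0[[1]])
  a20 <- predict_amplicon(tu2, pairs0[[2]])
  expect_lt(as.integer(terminal_overlap(a10, a20)), 20L)

  expect_error(design_vegas_primers(d, kit$adapters, tail_len = 60L),
               class = "vegassim_design_error")
})

test_that("reordering slots changes primer tails but not the yGG TUs", {
  kit <- test_kit()
  d <- kit$designs$bcar_pcr
  reord <- pathway_design(as.data.frame(d)[c(1, 3, 4, 2, 5), ],
                          "pcr_homology")
  p_orig <- design_vegas_primers(d, kit$adapters)
  p_reord <- design_vegas_primers(reord, kit$adapters)
  # the crtI slot moved from position 2 to 4: same anneal, new tails
  crtI_orig <- p_orig[[2]]; crtI_new <- p_reord[[4]]
  expect_identical(crtI_orig$forward$anneal, crtI_new$forward$anneal)
  expect_false(identical(crtI_orig$forward$tail, crtI_new$forward$tail))
  # the yGG constructs themselves are order-independent
  expect_identical(assemble_tu(d, 2, kit)$product$bases,
                   assemble_tu(reord, 4, kit)$product$bases)
})

test_that("predict_amplicon builds tail+span+tail and checks anneal sites", {
  kit <- test_kit()
  d <- kit$designs$bcar_pcr
  pairs <- design_vegas_primers(d, kit$adapters)
  tu1 <- release_tu(assemble_tu(d, 1, kit)$product)
  amp <- predict_amplicon(tu1, pairs[[1]])
  # TU span minus the CCTG/AACT ends, plus 30-nt tails on both sides
  expect_equal(nchar(amp$bases), (nchar(tu1$top) - 8L) + 60L)
  expect_identical(substr(amp$bases, 31, 87), adapter_seq("VA7")[[1]])

  # empty tails: amplicon equals the adapter-to-adapter template span
  pairs0 <- design_vegas_primers(d, kit$adapters, tail_len = 0L)
  amp0 <- predict_amplicon(tu1, pairs0[[1]])
  expect_identical(amp0$bases, substr(tu1$top, 5, nchar(tu1$top) - 4L))

  # primers from the wrong TU cannot anneal
  expect_error(predict_amplicon(tu1, pairs[[2]]),
               class = "vegassim_pcr_error")
})

test_that("terminal_overlap measures exact shared termini in both senses", {
  withr::with_seed(5, {
    a <- rand_dna(1000); b <- rand_dna(1000)
    expect_lt(as.integer(terminal_overlap(a, b)), 20L)
    ov <- terminal_overlap(a, revcomp(a), window = 150L)
    expect_equal(as.integer(ov), 150L)
    expect_identical(attr(ov, "orientation"), "reverse")
    # a designed 40-bp junction is measured exactly
    shared <- rand_dna(40)
    x <- paste0(rand_dna(500), shared)
    y <- paste0(shared, rand_dna(500))
    expect_equal(as.integer(terminal_overlap(x, y)), 40L)
  })
})

test_that("linearizing the VEGAS vector exposes VA termini around a clean backbone", {
  kit <- test_kit()
  lin <- linearize_vegas_vector(kit$vegas_vector, kit$adapters)
  s <- lin$backbone$top
  # top strand runs from the right-arm adapter (VA2) to the left-arm
  # adapter (VA1); the 3' VA1 copy recombines with TU1's leading VA1
  expect_identical(substr(s, 1, 57), adapter_seq("VA2")[[1]])
  expect_identical(substr(s, nchar(s) - 56, nchar(s)),
                   adapter_seq("VA1")[[1]])
  expect_identical(lin$left_va, "VA1")
  expect_identical(lin$right_va, "VA2")
  expect_equal(nrow(scan_sites(nuc_seq(s), "BsaI")), 0L)

  # already-linearized input: zero-site warning
  expect_warning(linearize_vegas_vector(nuc_seq(s, "linear", name = "lin")),
                 "already linearized")
  # three BsaI sites: architecture error
  bad <- nuc_seq(paste0(kit$vegas_vector$bases, "GGTCTCA"), "circular")
  expect_error(linearize_vegas_vector(bad), class = "vegassim_vector_error")
})

test_that("VA-homology recombination joins five TUs through full adapters", {
  kit <- test_kit()
  run <- assemble_pathway(kit$designs$bcar_va, kit)
  expect_length(run$outcome$products, 1L)
  expect_false(is.null(run$intended_product))
  jn <- run$outcome$junctions[[1]]
  expect_equal(nrow(jn), 6L)  # 5 TUs + backbone closure
  # interior TU-TU junctions recombine through the full 57-bp adapter
  interior <- jn$overlap[jn$from != "vegas_vector_backbone" &
                         jn$to != "vegas_vector_backbone"]
  expect_true(all(interior == 57L))
  # TU order in the product matches the design
  expect_identical(jn$to[1:5], kit$designs$bcar_va$name)
  # product length bookkeeping: pieces minus overlaps minus trimmed flaps
  pieces_len <- nchar(run$outcome$products[[1]]$bases)
  total <- nchar(linearize_vegas_vector(kit$vegas_vector)$backbone$top) +
    sum(vapply(run$pieces, function(p) nchar(p$top), 0L))
  expect_equal(pieces_len,
               total - sum(jn$overlap) - sum(jn$flap_from) - sum(jn$flap_to))
})

test_that("PCR-homology recombination is exact: lengths add up with no flaps", {
  kit <- test_kit()
  run <- assemble_pathway(kit$designs$bcar_pcr, kit)
  expect_length(run$outcome$products, 1L)
  jn <- run$outcome$junctions[[1]]
  expect_true(all(jn$flap_from == 0L))
  expect_true(all(jn$flap_to == 0L))
  total <- nchar(linearize_vegas_vector(kit$vegas_vector)$backbone$top) +
    sum(vapply(run$pieces, function(p) nchar(p$bases), 0L))
  expect_equal(nchar(run$outcome$products[[1]]$bases),
               total - sum(jn$overlap))
})

test_that("a reverse-oriented slot assembles with the TU flipped in place", {
  kit <- test_kit()
  d <- as.data.frame(kit$designs$bcar_pcr)
  d$orientation[4] <- "reverse"
  d <- pathway_design(d, "pcr_homology")
  run <- assemble_pathway(d, kit)
  expect_false(is.null(run$intended_product))
  # the amplicon for a reverse slot is itself built on the flipped
  # template, so the piece joins "forward" but carries the TU flipped:
  # the crtYB CDS appears on the minus strand of the product
  cds <- kit$parts$crtYB$core
  p <- run$intended_product$bases
  expect_false(grepl(cds, p, fixed = TRUE))
  expect_true(grepl(revcomp(cds), p, fixed = TRUE))
})

test_that("recombination fails cleanly without sufficient homology", {
  withr::with_seed(17, {
    frags <- lapply(1:3, function(i) nuc_seq(rand_dna(500),
                                             name = paste0("f", i)))
    expect_error(simulate_recombination(rand_dna(800), frags),
                 class = "vegassim_assembly_error")
  })
})

test_that("the path search agrees with brute-force enumeration (<=7 pieces)", {
  kit <- test_kit()
  for (design_name in c("bcar_va", "vio_pcr")) {
    run <- assemble_pathway(kit$designs[[design_name]], kit)
    pieces <- lapply(run$pieces, seq_string)
    bb <- linearize_vegas_vector(kit$vegas_vector)$backbone$top
    n <- length(pieces)
    ## oriented overlap matrix from the independent binary-search oracle
    strs <- c(list(bb), pieces)
    ors <- function(i, o) if (o == 1L) strs[[i]] else revcomp(strs[[i]])
    edge <- array(FALSE, dim = c(n + 1L, 2L, n + 1L, 2L))
    for (i in seq_len(n + 1L)) for (oi in 1:2) {
      for (j in seq_len(n + 1L)) for (oj in 1:2) {
        if (i != j) {
          edge[i, oi, j, oj] <-
            fwd_overlap_len(ors(i, oi), ors(j, oj)) >= 30L
        }
      }
    }
    ## enumerate every ordering x orientation closing a circle through
    ## the backbone (node 1, orientation fixed)
    count <- 0L
    for (p in perms(seq_len(n) + 1L)) {
      for (mask in 0:(2^n - 1L)) {
        node <- c(1L, p)
        ori <- c(1L, ifelse(bitwAnd(mask,
                                    bitwShiftL(1L, seq_len(n) - 1L)) > 0,
                            2L, 1L))
        good <- TRUE
        for (k in seq_len(n + 1L)) {
          k2 <- if (k == n + 1L) 1L else k + 1L
          if (!edge[node[k], ori[k], node[k2], ori[k2]]) {
            good <- FALSE; break
          }
        }
        if (good) count <- count + 1L
      }
    }
    ## both designs admit exactly one circle; the simulator must agree
    ## with the enumeration
    expect_equal(count, 1L, info = design_name)
    expect_equal(length(run$outcome$products), count, info = design_name)
  }
})
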