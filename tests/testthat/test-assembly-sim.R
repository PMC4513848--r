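test_that("overhang-set diagnostics flag duplicates, revcomps, palindromes", {
  expect_true(check_overhang_set(c("CCTG", "CAGT", "AATG", "TGAG", "TTTT",
                                   "AACT"))$clean)
  d1 <- check_overhang_set(c("AATG", "AATG", "CCTG"))
  expect_false(d1$clean)
  expect_true("AATG" %in% d1$duplicated)
  d2 <- check_overhang_set(c("AATG", "CATT"))
  expect_false(d2$clean)
  expect_length(d2$revcomp_pairs, 1L)
  d3 <- check_overhang_set(c("GATC", "CCTG"))
  expect_false(d3$clean)
  expect_true("GATC" %in% d3$palindromic)
})

test_that("a five-part yGG reaction assembles a single product", {
  kit <- test_kit()
  d <- kit$designs$bcar_va
  inserts <- tu_part_inserts(d, 1, kit)
  expect_length(inserts, 5L)
  res <- simulate_ygg(kit$acceptor, inserts)
  expect_equal(res$n_parts, 5L)
  expect_equal(res$product$topology, "circular")
  # the product is stable: no residual BsaI site on either strand
  expect_equal(nrow(scan_sites(res$product, "BsaI")), 0L)
  # ordered junctions cover the six grammar 4-mers exactly once
  expect_setequal(res$junction_map$junction, unname(junction_grammar()))
  expect_equal(anyDuplicated(res$junction_map$junction), 0L)
  # product length bookkeeping: (backbone double-stranded extent) +
  # part cores + 6 junction 4-mers
  backbone_top <- nchar(kit$acceptor$bases) -
    nchar(res$dropout_fragments[[1]]$top)
  core_len <- 57L + nchar(kit$parts$pTDH3$core) +
    nchar(kit$parts$crtE$core) + nchar(kit$parts$ttACS2$core) + 57L
  expect_equal(nchar(res$product$bases),
               (backbone_top - 4L) + core_len + 6L * 4L)
})

test_that("a missing part gives a structured open-junction error", {
  kit <- test_kit()
  inserts <- tu_part_inserts(kit$designs$bcar_va, 1, kit)
  expect_error(simulate_ygg(kit$acceptor, inserts[-2]),  # drop the PRO
               class = "vegassim_assembly_error")
  err <- tryCatch(simulate_ygg(kit$acceptor, inserts[-2]), error = identity)
  expect_match(conditionMessage(err), "open junction")
})

test_that("a marker TU assembles as a four-piece reaction", {
  kit <- test_kit()
  res <- assemble_tu(kit$designs$bcar_va, 3, kit)  # KanMX slot
  expect_equal(res$n_parts, 3L)  # LVA + marker + RVA (plus backbone)
  expect_setequal(res$junction_map$junction,
                  c("AACT", "CCTG", "CAGT", "TTTT"))
})

test_that("the sticky-chain search agrees with brute-force enumeration", {
  kit <- test_kit()
  inserts <- tu_part_inserts(kit$designs$bcar_va, 1, kit)
  enzyme <- get_enzyme("BsaI")
  acc <- digest(kit$acceptor, enzyme)
  keep <- vapply(acc, function(f)
    !grepl(enzyme$recognition, f$top, fixed = TRUE) &&
      !grepl(revcomp(enzyme$recognition), f$top, fixed = TRUE), TRUE)
  backbone <- acc[[which(keep)]]
  pool <- list()
  for (ins in inserts) {
    for (f in digest(ins, enzyme)) {
      ok <- !grepl(enzyme$recognition, f$top, fixed = TRUE) &&
        !grepl(revcomp(enzyme$recognition), f$top, fixed = TRUE)
      if (ok) pool[[length(pool) + 1L]] <- f
    }
  }
  expect_length(pool, 5L)
  ## brute force: every subset order x orientation that closes a circle
  found <- character()
  for (k in 0:length(pool)) {
    for (subset in if (k == 0) list(integer()) else
         utils::combn(length(pool), k, simplify = FALSE)) {
      for (p in perms(subset)) {
        n_or <- 2^length(p)
        for (mask in seq_len(max(1L, n_or)) - 1L) {
          chain <- list(backbone)
          for (j in seq_along(p)) {
            f <- pool[[p[j]]]
            if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) > 0) {
              f <- flip_fragment(f)
            }
            chain[[length(chain) + 1L]] <- f
          }
          ok <- TRUE
          for (j in seq_along(chain)) {
            nxt <- if (j == length(chain)) 1L else j + 1L
            if (!ends_compatible(chain[[j]]$end3, chain[[nxt]]$end5)) {
              ok <- FALSE; break
            }
          }
          if (ok && length(p) > 0) {
            found <- c(found,
                       paste(vapply(chain[-1], function(f) f$top, ""),
                             collapse = ""))
          }
        }
      }
    }
  }
  res <- simulate_ygg(kit$acceptor, inserts)
  expect_length(unique(found), 1L)
  got <- sub(paste0("^", backbone$top), "", res$product$bases)
  expect_identical(got, unique(found))
})

test_that("released TUs start at CCTG, end at AACT, and carry the LVA", {
  kit <- test_kit()
  res <- assemble_tu(kit$designs$bcar_va, 1, kit)
  tu <- release_tu(res$product, "BsmBI")
  expect_identical(substr(tu$top, 1, 4), "CCTG")
  expect_identical(substr(tu$top, nchar(tu$top) - 3, nchar(tu$top)), "AACT")
  expect_identical(substr(tu$top, 5, 61), adapter_seq("VA1")[[1]])
})

test_that("release errors when the release enzyme cuts inside a part", {
  kit <- test_kit()
  d <- kit$designs$bcar_va
  # plant a BsmBI site inside the CDS core; skip grammar validation so
  # the poisoned part reaches assembly
  poisoned <- kit
  poisoned$parts$crtE$core <- paste0(substr(kit$parts$crtE$core, 1, 300),
                                     "CGTCTC",
                                     substr(kit$parts$crtE$core, 307,
                                            nchar(kit$parts$crtE$core)))
  lva <- ygg_part("LVA", adapter_seq("VA1")[[1]], "VA1")
  rva <- ygg_part("RVA", adapter_seq("VA3")[[1]], "VA3")
  inserts <- c(
    list(build_part_insert(lva)),
    list(build_part_insert(kit_part(poisoned, "pTDH3", "PRO")),
         build_part_insert(kit_part(poisoned, "crtE", "CDS"),
                           validate = FALSE),
         build_part_insert(kit_part(poisoned, "ttACS2", "TER"))),
    list(build_part_insert(rva)))
  res <- simulate_ygg(kit$acceptor, inserts)
  expect_error(release_tu(res$product, "BsmBI"),
               class = "vegassim_release_error")
  err <- tryCatch(release_tu(res$product, "BsmBI"), error = identity)
  expect_match(conditionMessage(err), "crtE")
})

test_that("the NotI-release acceptor yields the same TU span", {
  kit <- test_kit()
  res <- assemble_tu(kit$designs$bcar_va, 1, kit,
                     acceptor = kit$acceptor_noti)
  tu <- release_tu(res$product, "NotI")
  # flanked by NotI half-sites, same CCTG...AACT TU span inside
  expect_match(tu$top, "CCTG.*AACT")
  bsmbi_tu <- release_tu(assemble_tu(kit$designs$bcar_va, 1, kit)$product,
                         "BsmBI")
  expect_true(grepl(bsmbi_tu$top, tu$top, fixed = TRUE))
})
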