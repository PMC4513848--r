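## ---- synthetic sequence helpers ----

forbidden_patterns <- function() {
  vapply(vegas_enzymes(), `[[`, "", "recognition")
}

## replace every forbidden-site occurrence (either strand) with fresh
## random bases until clean; uses the current RNG state
scrub_sites <- function(s, patterns = forbidden_patterns(), budget = 200L) {
  all_pat <- unique(c(patterns, vapply(patterns, revcomp, "")))
  for (it in seq_len(budget)) {
    hit <- FALSE
    for (p in all_pat) {
      m <- regexpr(p, s, fixed = TRUE)
      if (m > 0) {
        substr(s, m, m + nchar(p) - 1L) <- random_dna(nchar(p))
        hit <- TRUE
      }
    }
    if (!hit) return(s)
  }
  vs_stop("could not scrub forbidden sites within the attempt budget",
          class = "vegassim_fixture_error")
}

random_core <- function(len) scrub_sites(random_dna(len))

## ---- vector builders (cassette architecture only; backbone elements
## are placeholder spans carried as named features) ----

#' Construct a synthetic yGG acceptor vector
#'
#' Builds a circular acceptor with the standard cassette architecture: an
#' RFP dropout flanked by outward-facing BsaI sites exposing CCTG (LVA 5'
#' side) and AACT (RVA 3' side), with release sites (inward-facing BsmBI,
#' or NotI pairs) placed outside the BsaI sites so that release cuts fall
#' immediately outside the assembled CCTG...AACT span. Backbone elements
#' (AmpR, ori) are synthetic placeholder spans recorded as features. Uses
#' the current RNG state; call within a seeded context for
#' reproducibility.
#'
#' @param release `"BsmBI"` or `"NotI"` release chemistry.
#' @param backbone_len,rfp_len Placeholder span lengths.
#' @param name Vector name.
#' @return Circular `nuc_seq`.
#' @export
make_acceptor_vector <- function(release = c("BsmBI", "NotI"),
                                 backbone_len = 1200L, rfp_len = 600L,
                                 name = NULL) {
  release <- match.arg(release)
  if (is.null(name)) name <- paste0("acceptor_", tolower(release))
  for (attempt in 1:25) {
    b1 <- random_core(backbone_len)
    rfp <- random_core(rfp_len)
    left_rel  <- if (release == "BsmBI") paste0("CGTCTC", "A")
                 else "GCGGCCGC"
    right_rel <- if (release == "BsmBI")
                   paste0(scrub_sites(random_dna(5L)), "GAGACG")
                 else "GCGGCCGC"
    s <- paste0(b1, left_rel, "CCTG", "A", "GAGACC", rfp,
                "GGTCTC", "A", "AACT", right_rel)
    v <- nuc_seq(s, "circular", name = name)
    ok <- nrow(scan_sites(v, "BsaI")) == 2L &&
      nrow(scan_sites(v, "BsmBI")) == (if (release == "BsmBI") 2L else 0L) &&
      nrow(scan_sites(v, "NotI")) == (if (release == "NotI") 2L else 0L) &&
      nrow(scan_sites(v, "FseI")) == 0L
    if (ok) {
      v <- add_feature(v, "AmpR", 50L, min(950L, backbone_len - 50L))
      v <- add_feature(v, "ori", backbone_len - 180L, backbone_len - 20L)
      v <- add_feature(v, "RFP_dropout", backbone_len + nchar(left_rel) + 11L,
                       backbone_len + nchar(left_rel) + 11L + rfp_len)
      return(v)
    }
  }
  vs_stop("could not build a clean acceptor vector",
          class = "vegassim_fixture_error")
}

#' Construct a synthetic VEGAS assembly vector
#'
#' Circular vector whose RFP dropout is flanked by outward-facing BsaI
#' sites with the VA1 and VA2 adapters encoded terminally on the arms:
#' BsaI digestion releases the dropout and yields a backbone whose top
#' strand reads VA2 ... (URA3, CEN/ARS, AmpR, ori placeholders) ... VA1.
#' Uses the current RNG state.
#'
#' @param adapter_table Adapter table supplying VA1/VA2.
#' @param backbone_len,rfp_len Placeholder span lengths.
#' @param name Vector name.
#' @return Circular `nuc_seq`.
#' @export
make_vegas_vector <- function(adapter_table = va_adapters(),
                              backbone_len = 1500L, rfp_len = 600L,
                              name = "vegas_vector") {
  va1 <- adapter_seq("VA1", adapter_table)[[1]]
  va2 <- adapter_seq("VA2", adapter_table)[[1]]
  for (attempt in 1:25) {
    b2 <- random_core(backbone_len)
    s <- paste0(b2, va1, scrub_sites(random_dna(4L)), "A", "GAGACC",
                random_core(rfp_len), "GGTCTC", "A", va2)
    v <- nuc_seq(s, "circular", name = name)
    ok <- nrow(scan_sites(v, "BsaI")) == 2L &&
      nrow(scan_sites(v, "BsmBI")) == 0L &&
      nrow(scan_sites(v, "NotI")) == 0L && nrow(scan_sites(v, "FseI")) == 0L
    if (ok) {
      v <- add_feature(v, "URA3", 50L, 850L)
      v <- add_feature(v, "CEN_ARS", 900L, 1150L)
      v <- add_feature(v, "AmpR_ori", 1160L, backbone_len - 10L)
      v <- add_feature(v, "VA1", backbone_len, backbone_len + 57L)
      return(v)
    }
  }
  vs_stop("could not build a clean VEGAS vector",
          class = "vegassim_fixture_error")
}

## ---- the three worked pathway designs ----

slot_row <- function(name, lva, pro, cds, ter, rva) {
  data.frame(name = name, lva = lva, pro = pro, cds = cds, ter = ter,
             rva = rva, orientation = "forward", stringsAsFactors = FALSE)
}

bcar_va_slots <- function() rbind(
  slot_row("crtE_TU",  "VA1", "pTDH3", "crtE",  "ttACS2", "VA3"),
  slot_row("crtI_TU",  "VA3", "pPGK1", "crtI",  "ttENO2", "VA4"),
  slot_row("KanMX_TU", "VA4", NA,      "KanMX", NA,       "VA5"),
  slot_row("crtYB_TU", "VA5", "pACT1", "crtYB", "ttASC1", "VA6"),
  slot_row("tHMG1_TU", "VA6", "pRPS2", "tHMG1", "ttCIT1", "VA2"))

bcar_pcr_slots <- function() rbind(
  slot_row("crtE_TU",  "VA7",  "pTDH3", "crtE",  "ttACS2", "VA3"),
  slot_row("crtI_TU",  "VA8",  "pPGK1", "crtI",  "ttENO2", "VA4"),
  slot_row("KanMX_TU", "VA9",  NA,      "KanMX", NA,       "VA5"),
  slot_row("crtYB_TU", "VA10", "pACT1", "crtYB", "ttASC1", "VA6"),
  slot_row("tHMG1_TU", "VA11", "pRPS2", "tHMG1", "ttCIT1", "VA12"))

## the violacein layout duplicates VA5 (marker RVA and vioE RVA), which
## the recombination simulator surfaces as an off-target homology warning
vio_pcr_slots <- function() rbind(
  slot_row("vioA_TU",  "VA7",  "pTDH3", "vioA",  "ttACS2", "VA3"),
  slot_row("vioB_TU",  "VA8",  "pPGK1", "vioB",  "ttENO2", "VA4"),
  slot_row("KanMX_TU", "VA9",  NA,      "KanMX", NA,       "VA5"),
  slot_row("vioC_TU",  "VA10", "pACT1", "vioC",  "ttASC1", "VA6"),
  slot_row("vioD_TU",  "VA11", "pRPS2", "vioD",  "ttCIT1", "VA12"),
  slot_row("vioE_TU",  "VA16", "pZEO1", "vioE",  "ttFUM1", "VA5"))

#' Generate the synthetic fixture kit
#'
#' A complete, self-consistent test bed generated deterministically from
#' a seed: a multi-contig background genome, site-free regulatory and
#' coding part cores (names reuse the standard yeast labels -- pTDH3,
#' crtE, vioA, ... -- as aliases for synthetic sequences), a pre-assembled
#' marker TU core (KanMX), yGG acceptor vectors (BsmBI and NotI release),
#' a VEGAS assembly vector, the packaged adapter table, and three worked
#' pathway designs: the beta-carotene pathway in adapter-homology mode,
#' the same pathway in PCR-homology mode, and the six-TU violacein
#' pathway in PCR-homology mode (a seven-piece assembly including the
#' vector backbone). The default pools of 10 promoters and 5 terminators
#' mirror the combinatorial library configuration.
#'
#' @param seed Integer seed (byte-identical kits for equal seeds).
#' @param genome_len Total background genome length (default 50 kb over
#'   3 contigs).
#' @param n_pro,n_ter Pool sizes (defaults 10 and 5).
#' @return Object of class `fixture_kit`.
#' @export
make_fixture_kit <- function(seed = 1L, genome_len = 50000L, n_pro = 10L,
                             n_ter = 5L) {
  stopifnot(genome_len > 0L, n_pro >= 1L, n_ter >= 1L)
  pro_names <- c("pTDH3", "pPGK1", "pACT1", "pRPS2", "pZEO1", "pIRR1",
                 "pALG7", "pSWE1", "pTIP1", "pHSL1")
  ter_names <- c("ttACS2", "ttENO2", "ttASC1", "ttCIT1", "ttSIK1")
  cds_names <- c("crtE", "crtI", "crtYB", "tHMG1",
                 "vioA", "vioB", "vioC", "vioD", "vioE")
  if (n_pro > length(pro_names)) {
    pro_names <- c(pro_names, sprintf("pSYN%d", seq_len(n_pro - 10L)))
  }
  if (n_ter > length(ter_names)) {
    ter_names <- c(ter_names, sprintf("ttSYN%d", seq_len(n_ter - 5L)))
  }
  with_seed(seed, {
    lens <- c(0.5, 0.3, 0.2) * genome_len
    genome <- lapply(seq_along(lens), function(i) {
      nuc_seq(random_dna(floor(lens[i])), name = sprintf("contig_%d", i))
    })
    mult3 <- function(x) 3L * (as.integer(x) %/% 3L)
    parts <- list()
    for (p in pro_names[seq_len(n_pro)]) {
      parts[[p]] <- list(type = "PRO",
                         core = random_core(sample(300:700, 1)))
    }
    for (t in c(ter_names[seq_len(n_ter)], "ttFUM1")) {
      parts[[t]] <- list(type = "TER",
                         core = random_core(sample(150:300, 1)))
    }
    for (cd in cds_names) {
      parts[[cd]] <- list(type = "CDS",
                          core = random_core(mult3(sample(600:1800, 1))))
    }
    parts[["KanMX"]] <- list(type = "MARKER_TU", core = random_core(1400L))
    adapters <- va_adapters()
    kit <- list(
      seed = as.integer(seed),
      genome = genome,
      parts = parts,
      pro_pool = pro_names[seq_len(n_pro)],
      ter_pool = ter_names[seq_len(n_ter)],
      adapters = adapters,
      acceptor = make_acceptor_vector("BsmBI"),
      acceptor_noti = make_acceptor_vector("NotI"),
      vegas_vector = make_vegas_vector(adapters),
      designs = list(
        bcar_va = pathway_design(bcar_va_slots(), "va_homology"),
        bcar_pcr = pathway_design(bcar_pcr_slots(), "pcr_homology"),
        vio_pcr = pathway_design(vio_pcr_slots(), "pcr_homology")))
    kit$combinatorial <- combinatorial_design(
      kit$designs$bcar_pcr, kit$pro_pool, kit$ter_pool)
    structure(kit, class = "fixture_kit")
  })
}

#' @export
print.fixture_kit <- function(x, ...) {
  cat(sprintf(paste0("<fixture_kit> seed %d: %d contig(s) (%d bp), ",
                     "%d part core(s), pools %d PRO x %d TER, %d design(s)\n"),
              x$seed, length(x$genome),
              sum(vapply(x$genome, function(g) nchar(g$bases), 0L)),
              length(x$parts), length(x$pro_pool), length(x$ter_pool),
              length(x$designs)))
  invisible(x)
}

#' Resolve a named part from a kit
#' @param kit A `fixture_kit`.
#' @param name Part name.
#' @param type Optional grammar type override (e.g. `"PRO"` for a part
#'   used in a promoter slot).
#' @return A `ygg_part`.
#' @export
kit_part <- function(kit, name, type = NULL) {
  p <- kit$parts[[name]]
  if (is.null(p)) {
    vs_stop("no part named '", name, "' in the kit",
            class = "vegassim_lookup_error")
  }
  ygg_part(type %||% p$type, p$core, name)
}

#' Part inserts for one TU slot of a design
#'
#' Builds the clonable inserts for a slot: LVA and RVA adapter parts plus
#' either PRO/CDS/TER parts or a single pre-assembled marker part.
#'
#' @param design A `pathway_design`.
#' @param i Slot index.
#' @param kit A `fixture_kit` resolving part names.
#' @return List of linear `nuc_seq` inserts.
#' @export
tu_part_inserts <- function(design, i, kit) {
  tab <- kit$adapters
  lva <- ygg_part("LVA", adapter_seq(design$lva[i], tab)[[1]], design$lva[i])
  rva <- ygg_part("RVA", adapter_seq(design$rva[i], tab)[[1]], design$rva[i])
  mids <- if (is_marker_slot(design)[i]) {
    list(kit_part(kit, design$cds[i], "MARKER_TU"))
  } else {
    list(kit_part(kit, design$pro[i], "PRO"),
         kit_part(kit, design$cds[i], "CDS"),
         kit_part(kit, design$ter[i], "TER"))
  }
  lapply(c(list(lva), mids, list(rva)), build_part_insert)
}

#' Assemble one TU of a design by simulated yGG
#'
#' @inheritParams tu_part_inserts
#' @param acceptor Acceptor vector (default the kit's BsmBI-release
#'   acceptor).
#' @return A `ygg_result`.
#' @export
assemble_tu <- function(design, i, kit, acceptor = kit$acceptor) {
  res <- simulate_ygg(acceptor, tu_part_inserts(design, i, kit))
  res$product$name <- paste0(design$name[i], "_construct")
  res
}

## the CAGT..TTTT interior of a slot (between its adapters)
slot_interior <- function(design, i, kit) {
  g <- junction_grammar()
  if (is_marker_slot(design)[i]) {
    paste0(g[["LVA_PRO"]], kit$parts[[design$cds[i]]]$core, g[["TER_RVA"]])
  } else {
    paste0(g[["LVA_PRO"]], kit$parts[[design$pro[i]]]$core,
           g[["PRO_CDS"]], kit$parts[[design$cds[i]]]$core,
           g[["CDS_TER"]], kit$parts[[design$ter[i]]]$core,
           g[["TER_RVA"]])
  }
}

#' Reference sequence of a designed pathway
#'
#' Constructs, by direct string arithmetic (independently of the digest /
#' ligate / recombine simulators), the circular sequence a correct
#' assembly of the design must produce: the linearized vector backbone
#' (VA2 ... VA1 on the top strand) followed by each slot's adapter-flanked
#' interior in order, each adapter appearing exactly once per junction.
#'
#' @param design A `pathway_design`.
#' @param kit A `fixture_kit`.
#' @return Circular `nuc_seq`.
#' @export
designed_pathway_sequence <- function(design, kit) {
  tab <- kit$adapters
  bb <- linearize_vegas_vector(kit$vegas_vector, tab)$backbone$top
  n <- nrow(design)
  mode <- attr(design, "mode")
  segs <- character(n)
  for (i in seq_len(n)) {
    interior <- slot_interior(design, i, kit)
    if (mode == "pcr_homology") {
      unit <- paste0(adapter_seq(design$lva[i], tab)[[1]], interior,
                     adapter_seq(design$rva[i], tab)[[1]])
      segs[i] <- if (design$orientation[i] == "reverse") revcomp(unit)
                 else unit
    } else {
      segs[i] <- paste0(interior,
                        if (i < n) adapter_seq(design$rva[i], tab)[[1]]
                        else "")
    }
  }
  nuc_seq(paste0(bb, paste(segs, collapse = "")), "circular",
          name = "designed_pathway")
}

#' Run a pathway design end to end
#'
#' The full workflow on a fixture kit: yGG-assemble every TU into the
#' acceptor, then either release the VA-flanked TUs with the release
#' enzyme (adapter-homology mode) or amplify them with homology-tail
#' primers (PCR mode), linearize the VEGAS vector, and simulate the
#' homologous-recombination assembly. The outcome is checked against the
#' design's reference sequence.
#'
#' @param design A `pathway_design`.
#' @param kit A `fixture_kit`.
#' @param min_homology,window Passed to [simulate_recombination()].
#' @param anneal_len,tail_len Passed to [design_vegas_primers()] (PCR
#'   mode).
#' @param release_enzyme Release enzyme for adapter-homology mode.
#' @return Object of class `vegas_run`: `outcome` (assembly outcome),
#'   `expected` (reference circular `nuc_seq`), `intended_product`
#'   (matching product or `NULL`), `tus`, `pieces`, `primers`.
#' @export
assemble_pathway <- function(design, kit, min_homology = 30L, window = 150L,
                             anneal_len = 20L, tail_len = 30L,
                             release_enzyme = "BsmBI") {
  stopifnot(inherits(design, "pathway_design"), inherits(kit, "fixture_kit"))
  mode <- attr(design, "mode")
  if (mode == "va_homology") {
    chain <- validate_va_chain(design)
    if (!chain$pass) {
      vs_stop("adapter chain invalid at: ",
              paste(chain$problems$junction, collapse = ", "),
              class = "vegassim_design_error")
    }
  }
  tus <- lapply(seq_len(nrow(design)), function(i)
    assemble_tu(design, i, kit))
  released <- lapply(tus, function(r) release_tu(r$product, release_enzyme))
  primers <- NULL
  if (mode == "pcr_homology") {
    primers <- design_vegas_primers(design, kit$adapters,
                                    anneal_len = anneal_len,
                                    tail_len = tail_len)
    pieces <- lapply(seq_along(released), function(i)
      predict_amplicon(released[[i]], primers[[i]]))
  } else {
    pieces <- released
  }
  for (i in seq_along(pieces)) pieces[[i]]$name <- design$name[i]
  lin <- linearize_vegas_vector(kit$vegas_vector, kit$adapters)
  outcome <- simulate_recombination(lin$backbone, pieces,
                                    min_homology = min_homology,
                                    window = window)
  expected <- designed_pathway_sequence(design, kit)
  hit <- which(vapply(outcome$products, circular_identical, TRUE,
                      b = expected))
  structure(list(outcome = outcome, expected = expected,
                 intended_product = if (length(hit)) outcome$products[[hit[1]]]
                                    else NULL,
                 tus = tus, pieces = pieces, primers = primers),
            class = "vegas_run")
}

#' @export
print.vegas_run <- function(x, ...) {
  cat(sprintf("<vegas_run> %d TU(s); %d product(s); intended product %s\n",
              length(x$tus), length(x$outcome$products),
              if (is.null(x$intended_product)) "NOT recovered" else "recovered"))
  if (length(x$outcome$warnings)) cat(paste0("  ! ", x$outcome$warnings, "\n"))
  invisible(x)
}
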