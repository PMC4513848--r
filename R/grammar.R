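#' The yGG junction grammar
#'
#' Fixed 4-bp junction overhangs that order the five parts of a
#' VEGAS-ready transcription unit inside the acceptor vector:
#' vector-CCTG-LVA-CAGT-PRO-AATG-CDS-TGAG-TER-TTTT-RVA-AACT-vector.
#' The AATG junction supplies the CDS start codon and TGAG a stop, which
#' is why CDS cores are conventionally stored from codon 2 up to (not
#' including) the stop codon.
#'
#' @return Named character vector of the six junction 4-mers, in order.
#' @examples
#' junction_grammar()
#' @export
junction_grammar <- function() {
  c(vectorL_LVA = "CCTG", LVA_PRO = "CAGT", PRO_CDS = "AATG",
    CDS_TER = "TGAG", TER_RVA = "TTTT", RVA_vectorR = "AACT")
}

#' Part types of the yGG grammar
#' @return Character vector of valid part types.
#' @export
part_types <- function() c("LVA", "PRO", "CDS", "TER", "RVA", "MARKER_TU")

#' Junction overhangs implied by a part type
#'
#' `MARKER_TU` is a pre-assembled PRO-CDS-TER unit occupying the whole
#' PRO..TER span in a single part, so it takes the PRO-side left overhang
#' (CAGT) and the TER-side right overhang (TTTT).
#'
#' @param part_type One of [part_types()].
#' @return Named character vector `c(left4 = ..., right4 = ...)`.
#' @examples
#' grammar_overhangs("LVA")       # CCTG / CAGT
#' grammar_overhangs("MARKER_TU") # CAGT / TTTT
#' @export
grammar_overhangs <- function(part_type) {
  g <- junction_grammar()
  out <- switch(part_type,
    LVA = c(g[["vectorL_LVA"]], g[["LVA_PRO"]]),
    PRO = c(g[["LVA_PRO"]], g[["PRO_CDS"]]),
    CDS = c(g[["PRO_CDS"]], g[["CDS_TER"]]),
    TER = c(g[["CDS_TER"]], g[["TER_RVA"]]),
    RVA = c(g[["TER_RVA"]], g[["RVA_vectorR"]]),
    MARKER_TU = c(g[["LVA_PRO"]], g[["TER_RVA"]]),
    vs_stop("unknown part type '", part_type, "'",
            class = "vegassim_part_error"))
  names(out) <- c("left4", "right4")
  out
}

#' A typed yGG part
#'
#' A part is a core biological sequence plus a grammar type; the junction
#' 4-mers are implied by the type and attached automatically.
#'
#' @param part_type One of [part_types()].
#' @param core Core sequence (string or `nuc_seq`) between the junction
#'   4-mers.
#' @param name Part name.
#' @return Object of class `ygg_part` with fields `part_type`, `core`,
#'   `name`, `left4`, `right4`.
#' @export
ygg_part <- function(part_type, core, name = "") {
  part_type <- match.arg(part_type, part_types())
  core <- seq_string(core)
  if (grepl("[^ACGTN]", core)) {
    vs_stop("part core contains non-ACGTN characters",
            class = "vegassim_alphabet_error")
  }
  oh <- grammar_overhangs(part_type)
  structure(list(part_type = part_type, core = core, name = name,
                 left4 = oh[["left4"]], right4 = oh[["right4"]]),
            class = "ygg_part")
}

#' @export
print.ygg_part <- function(x, ...) {
  cat(sprintf("<ygg_part> %s [%s]: %d bp core, %s-core-%s\n",
              if (nzchar(x$name)) x$name else "(unnamed)", x$part_type,
              nchar(x$core), x$left4, x$right4))
  invisible(x)
}

#' Validate a part against forbidden restriction sites
#'
#' Scans the part core and both junction-spanning windows (left4+core and
#' core+right4) for hits of each forbidden enzyme on either strand;
#' ligation can create sites the bare core lacks, which is why the
#' junction windows are included. Positions are 0-based relative to the
#' core (junction-window hits may therefore start at -4 .. -1).
#'
#' @param part A `ygg_part` (or plain sequence, validated without junction
#'   context).
#' @param forbidden List of `enzyme_spec`s or built-in names; default all
#'   four workflow enzymes.
#' @return Object of class `validation_report`: list with `pass` (logical)
#'   and `hits` (data.frame enzyme/strand/position/where).
#' @examples
#' validate_part(ygg_part("PRO", "AAATTTCCCGGG", "demo"))$pass
#' @export
validate_part <- function(part, forbidden = c("BsaI", "BsmBI", "NotI", "FseI")) {
  if (!inherits(part, "ygg_part")) part <- ygg_part("PRO", seq_string(part))
  enzymes <- lapply(forbidden, get_enzyme)
  flanked <- paste0(part$left4, part$core, part$right4)
  hits <- NULL
  for (e in enzymes) {
    h <- scan_sites(nuc_seq(flanked), e)
    if (nrow(h)) {
      h$position <- h$position - 4L   # relative to core start
      klen <- nchar(e$recognition)
      core_len <- nchar(part$core)
      h$where <- ifelse(h$position >= 0 & h$position + klen <= core_len,
                        "core", "junction")
      h$enzyme <- e$name
      hits <- rbind(hits, h[, c("enzyme", "strand", "position", "where")])
    }
  }
  if (is.null(hits)) {
    hits <- data.frame(enzyme = character(), strand = character(),
                       position = integer(), where = character(),
                       stringsAsFactors = FALSE)
  }
  structure(list(pass = nrow(hits) == 0L, part = part$name, hits = hits),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %s\n",
              if (nzchar(x$part)) x$part else "(unnamed part)",
              if (x$pass) "PASS" else sprintf("FAIL (%d hit(s))",
                                              nrow(x$hits))))
  if (!x$pass) print(x$hits)
  invisible(x)
}

#' Build the clonable insert for a part
#'
#' Wraps the core and its junction 4-mers in inward-facing BsaI sites,
#' each separated from the overhang by a single spacer base (destroyed on
#' digestion): GGTCTC + spacer + left4 + core + right4 + spacer +
#' revcomp(GGTCTC). BsaI digestion of the result yields an internal
#' fragment whose sticky ends are exactly (left4, right4).
#'
#' @param part A validated `ygg_part`.
#' @param spacer Single spacer base (default `"A"`).
#' @param enzyme Assembly enzyme (default BsaI).
#' @param validate Run [validate_part()] first and error on failure?
#' @return A linear `nuc_seq` insert.
#' @export
build_part_insert <- function(part, spacer = "A", enzyme = "BsaI",
                              validate = TRUE) {
  stopifnot(inherits(part, "ygg_part"), nchar(spacer) == 1L)
  enzyme <- get_enzyme(enzyme)
  if (validate) {
    rep <- validate_part(part)
    if (!rep$pass) {
      vs_stop("part '", part$name, "' fails validation: ",
              nrow(rep$hits), " forbidden-site hit(s); first: ",
              rep$hits$enzyme[1], " ", rep$hits$strand[1], " at ",
              rep$hits$position[1], class = "vegassim_validation_error")
    }
  }
  ins <- paste0(enzyme$recognition, spacer, part$left4, part$core,
                part$right4, spacer, revcomp(enzyme$recognition))
  nuc_seq(ins, topology = "linear",
          name = if (nzchar(part$name)) paste0(part$name, "_insert")
                 else "part_insert")
}
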