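#' Restriction enzyme model
#'
#' A minimal model of a (non-degenerate) restriction enzyme: recognition
#' sequence plus top/bottom cut offsets measured in bp downstream of the
#' recognition's 3' end on the top strand. Offset cutters (BsaI, BsmBI)
#' have positive offsets; within-site cutters (NotI, FseI) have negative
#' offsets addressed back inside the recognition span. The overhang kind is
#' derived from the offsets: `cut_offset_top < cut_offset_bottom` leaves 5'
#' overhangs, the reverse leaves 3' overhangs, equality is blunt.
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (top strand, non-degenerate).
#' @param cut_offset_top,cut_offset_bottom Integer cut offsets relative to
#'   the 3' end of the recognition sequence.
#' @return An object of class `enzyme_spec`.
#' @examples
#' bsai <- enzyme_spec("BsaI", "GGTCTC", 1, 5)
#' overhang_length(bsai)  # 4
#' @export
enzyme_spec <- function(name, recognition, cut_offset_top, cut_offset_bottom) {
  recognition <- toupper(recognition)
  stopifnot(nzchar(recognition), !grepl("[^ACGT]", recognition))
  kind <- if (cut_offset_top < cut_offset_bottom) "five_prime"
          else if (cut_offset_top > cut_offset_bottom) "three_prime"
          else "blunt"
  structure(list(name = name, recognition = recognition,
                 cut_offset_top = as.integer(cut_offset_top),
                 cut_offset_bottom = as.integer(cut_offset_bottom),
                 overhang_kind = kind),
            class = "enzyme_spec")
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s %s (%d/%d, %s overhang of %d)\n",
              x$name, x$recognition, x$cut_offset_top, x$cut_offset_bottom,
              sub("_prime", "'", x$overhang_kind), overhang_length(x)))
  invisible(x)
}

#' Overhang length of an enzyme
#' @param enzyme An `enzyme_spec`.
#' @return Integer (0 for blunt cutters).
#' @export
overhang_length <- function(enzyme) {
  abs(enzyme$cut_offset_bottom - enzyme$cut_offset_top)
}

#' Built-in enzyme table
#'
#' The four enzymes used throughout the yGG/VEGAS workflow, under their
#' standard public definitions: the type-IIS assembly enzymes BsaI
#' (GGTCTC, cutting 1/5 bp downstream) and BsmBI (CGTCTC, 1/5), and the
#' rare 8-bp cutters NotI (GC^GGCCGC) and FseI (GGCCGG^CC) used to release
#' assembled units. NotI/FseI offsets are expressed relative to the
#' recognition 3' end, hence negative.
#'
#' @return Named list of `enzyme_spec` objects.
#' @examples
#' names(vegas_enzymes())
#' @export
vegas_enzymes <- function() {
  list(
    BsaI  = enzyme_spec("BsaI",  "GGTCTC",   1L,  5L),
    BsmBI = enzyme_spec("BsmBI", "CGTCTC",   1L,  5L),
    NotI  = enzyme_spec("NotI",  "GCGGCCGC", -6L, -2L),
    FseI  = enzyme_spec("FseI",  "GGCCGGCC", -2L, -6L)
  )
}

#' Look up a built-in enzyme by name
#' @param name One of `"BsaI"`, `"BsmBI"`, `"NotI"`, `"FseI"`, or an
#'   `enzyme_spec` (returned as-is).
#' @return An `enzyme_spec`.
#' @export
get_enzyme <- function(name) {
  if (inherits(name, "enzyme_spec")) return(name)
  tab <- vegas_enzymes()
  if (!name %in% names(tab)) {
    vs_stop("unknown enzyme '", name, "'; built-ins are ",
            paste(names(tab), collapse = ", "),
            class = "vegassim_enzyme_error")
  }
  tab[[name]]
}
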