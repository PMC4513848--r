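#' Nucleotide sequence with topology
#'
#' `nuc_seq` is the package's basic sequence container: an uppercase DNA
#' string over A/C/G/T/N, a topology (`"linear"` or `"circular"`), a name,
#' and optional feature annotations. Coordinates are 0-based half-open on
#' the top strand throughout the package; on circular molecules feature
#' intervals may wrap across the origin.
#'
#' @param bases Character scalar, DNA over A/C/G/T/N (case-insensitive).
#' @param topology `"linear"` (default) or `"circular"`.
#' @param name Identifier string.
#' @param features `NULL` or a data.frame with columns `label`, `start`,
#'   `end` (0-based half-open) and `strand` (`"+"`/`"-"`).
#' @return An object of class `nuc_seq`.
#' @examples
#' s <- nuc_seq("acgtACGT", topology = "circular", name = "demo")
#' seq_string(s)
#' @export
nuc_seq <- function(bases, topology = c("linear", "circular"), name = "",
                    features = NULL) {
  topology <- match.arg(topology)
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  bad <- regexpr("[^ACGTN]", bases)
  if (bad > 0) {
    vs_stop("invalid character '", substr(bases, bad, bad),
            "' at position ", bad - 1L, " (0-based)",
            class = "vegassim_alphabet_error")
  }
  if (is.null(features)) {
    features <- data.frame(label = character(), start = integer(),
                           end = integer(), strand = character(),
                           stringsAsFactors = FALSE)
  } else {
    features <- as.data.frame(features, stringsAsFactors = FALSE)
    stopifnot(all(c("label", "start", "end", "strand") %in% names(features)))
    L <- nchar(bases)
    if (topology == "linear" &&
        (any(features$start < 0) || any(features$end > L))) {
      vs_stop("feature interval outside [0, length) on a linear molecule",
              class = "vegassim_feature_error")
    }
  }
  structure(list(bases = bases, topology = topology, name = name,
                 features = features),
            class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  L <- nchar(x$bases)
  head <- if (L > 60) paste0(substr(x$bases, 1, 57), "...") else x$bases
  cat(sprintf("<nuc_seq> %s: %d bp, %s, %d feature(s)\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              L, x$topology, nrow(x$features)))
  cat(" ", head, "\n")
  invisible(x)
}

#' @export
length.nuc_seq <- function(x) nchar(x$bases)

#' Extract the top-strand string of a sequence-like object
#'
#' @param x A `nuc_seq`, `fragment`, or character scalar.
#' @return Character scalar (top strand, 5'->3').
#' @export
seq_string <- function(x) {
  if (is.character(x)) return(toupper(x))
  if (inherits(x, "nuc_seq")) return(x$bases)
  if (inherits(x, "fragment")) return(x$top)
  vs_stop("cannot extract a sequence string from class ",
          paste(class(x), collapse = "/"), class = "vegassim_type_error")
}

#' Reverse complement
#'
#' Involution on DNA sequences; accepts and returns either a plain string
#' or a `nuc_seq` (features are remapped to the flipped coordinates).
#'
#' @param x Character scalar or `nuc_seq`.
#' @return Same kind as the input.
#' @examples
#' revcomp("AATG")  # "CATT"
#' @export
revcomp <- function(x) {
  if (inherits(x, "nuc_seq")) {
    rc <- revcomp(x$bases)
    feats <- x$features
    if (nrow(feats)) {
      L <- nchar(x$bases)
      new_start <- L - feats$end
      new_end <- L - feats$start
      feats$start <- new_start
      feats$end <- new_end
      feats$strand <- ifelse(feats$strand == "+", "-", "+")
    }
    return(nuc_seq(rc, topology = x$topology, name = x$name,
                   features = feats))
  }
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  bad <- regexpr("[^ACGTN]", x)
  if (bad > 0) {
    vs_stop("invalid character '", substr(x, bad, bad), "' at position ",
            bad - 1L, " (0-based)", class = "vegassim_alphabet_error")
  }
  if (!nzchar(x)) return("")
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x))))
}

#' Rotation/strand-insensitive identity of circular sequences
#'
#' Two circular molecules are identical when one's top strand is a rotation
#' of the other's on either strand.
#'
#' @param a,b Sequences (`nuc_seq`, `fragment`, or strings) interpreted as
#'   circular.
#' @return Logical scalar.
#' @export
circular_identical <- function(a, b) {
  sa <- seq_string(a); sb <- seq_string(b)
  if (nchar(sa) != nchar(sb)) return(FALSE)
  if (nchar(sa) == 0) return(TRUE)
  doubled <- paste0(sb, sb)
  grepl(sa, doubled, fixed = TRUE) || grepl(revcomp(sa), doubled, fixed = TRUE)
}

## add a feature row to a nuc_seq
add_feature <- function(x, label, start, end, strand = "+") {
  x$features <- rbind(x$features,
                      data.frame(label = label, start = as.integer(start),
                                 end = as.integer(end), strand = strand,
                                 stringsAsFactors = FALSE))
  x
}
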