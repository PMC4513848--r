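#' Double-stranded fragment with sticky ends
#'
#' Digestion products are represented by their full top-strand extent plus
#' an end specification for each terminus. For reporting, `overhang` is
#' always given in top-strand orientation (the 4-mer as it will appear on
#' the top strand of a ligation product); `protruding` records which strand
#' is single-stranded there (`"top"`, `"bottom"`, or `"none"` for
#' blunt/uncut ends). Use [protruding_strand_seq()] for the physical
#' 5'->3' sequence of the single-stranded extension.
#'
#' @param top Top-strand string (including single-stranded regions).
#' @param end5,end3 End specifications from [end_spec()].
#' @param name Fragment name.
#' @param features Optional feature data.frame (as in [nuc_seq()]).
#' @return An object of class `fragment`.
#' @export
fragment <- function(top, end5 = end_spec(), end3 = end_spec(), name = "",
                     features = NULL) {
  if (is.null(features)) {
    features <- data.frame(label = character(), start = integer(),
                           end = integer(), strand = character(),
                           stringsAsFactors = FALSE)
  }
  structure(list(top = toupper(top), end5 = end5, end3 = end3, name = name,
                 features = features),
            class = "fragment")
}

#' @rdname fragment
#' @param overhang Top-strand overhang sequence (`""` for blunt).
#' @param protruding Which strand protrudes: `"top"`, `"bottom"`, `"none"`.
#' @export
end_spec <- function(overhang = "", protruding = "none") {
  stopifnot(protruding %in% c("top", "bottom", "none"))
  list(overhang = toupper(overhang), protruding = protruding)
}

#' @export
print.fragment <- function(x, ...) {
  fmt <- function(e) if (e$protruding == "none") "blunt"
                     else paste0(e$overhang, "(", e$protruding, ")")
  cat(sprintf("<fragment> %s: %d nt top strand, 5'[%s] 3'[%s]\n",
              if (nzchar(x$name)) x$name else "(unnamed)", nchar(x$top),
              fmt(x$end5), fmt(x$end3)))
  invisible(x)
}

#' @export
length.fragment <- function(x) nchar(x$top)

#' Physical sequence of a protruding single strand
#'
#' @param frag A `fragment`.
#' @param which `"end5"` or `"end3"`.
#' @return The 5'->3' sequence of the single-stranded extension (empty for
#'   blunt ends).
#' @export
protruding_strand_seq <- function(frag, which = c("end5", "end3")) {
  which <- match.arg(which)
  e <- frag[[which]]
  if (e$protruding == "none") return("")
  if (which == "end5") {
    if (e$protruding == "top") e$overhang else revcomp(e$overhang)
  } else {
    if (e$protruding == "bottom") revcomp(e$overhang) else e$overhang
  }
}

#' Reverse-complement a fragment
#'
#' Swaps the ends, reverse-complements the top strand and the top-strand
#' overhang representations, and flips which strand protrudes.
#'
#' @param frag A `fragment`.
#' @return The flipped `fragment`.
#' @export
flip_fragment <- function(frag) {
  flip_pro <- function(p) switch(p, top = "bottom", bottom = "top", "none")
  flip_end <- function(e) end_spec(if (nzchar(e$overhang)) revcomp(e$overhang)
                                   else "",
                                   flip_pro(e$protruding))
  feats <- frag$features
  if (nrow(feats)) {
    L <- nchar(frag$top)
    s <- L - feats$end; e <- L - feats$start
    feats$start <- s; feats$end <- e
    feats$strand <- ifelse(feats$strand == "+", "-", "+")
  }
  fragment(revcomp(frag$top), end5 = flip_end(frag$end3),
           end3 = flip_end(frag$end5), name = frag$name, features = feats)
}

#' Can two sticky/blunt ends ligate?
#'
#' The 3' end of one fragment ligates to the 5' end of the next iff both
#' are blunt, or the top-strand overhangs are equal with opposite
#' protruding strands (equivalently: the physical protruding-strand
#' sequences are reverse complements).
#'
#' @param end3 End spec of the upstream fragment's 3' terminus.
#' @param end5 End spec of the downstream fragment's 5' terminus.
#' @return Logical scalar.
#' @export
ends_compatible <- function(end3, end5) {
  if (end3$protruding == "none" && end5$protruding == "none") return(TRUE)
  if (end3$protruding == "none" || end5$protruding == "none") return(FALSE)
  end3$overhang == end5$overhang && end3$protruding != end5$protruding
}

#' Find restriction sites on both strands
#'
#' Reports every occurrence of the recognition sequence on the plus and
#' minus strand. `position` is the 0-based start of the site's footprint on
#' the top strand; `strand` gives the orientation. On circular molecules
#' the origin-spanning window is scanned and positions are reported modulo
#' the length, each hit once. Palindromic sites (their own reverse
#' complement) are reported once, on the plus strand.
#'
#' @param seq A `nuc_seq`, `fragment`, or character scalar (treated as
#'   linear unless a circular `nuc_seq`).
#' @param enzyme An `enzyme_spec` or built-in enzyme name.
#' @return data.frame with columns `position` (integer) and `strand`
#'   (`"+"`/`"-"`), ordered by position.
#' @examples
#' scan_sites("GGTCTCA", "BsaI")
#' @export
scan_sites <- function(seq, enzyme) {
  enzyme <- get_enzyme(enzyme)
  s <- seq_string(seq)
  circular <- inherits(seq, "nuc_seq") && seq$topology == "circular"
  rec <- enzyme$recognition
  k <- nchar(rec)
  L <- nchar(s)
  if (L == 0 || L < k && !circular) {
    return(data.frame(position = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  subject <- if (circular) paste0(s, substr(s, 1, k - 1)) else s
  find <- function(pat) find_all_fixed(pat, subject) - 1L  # to 0-based
  pos_plus <- find(rec)
  rc <- revcomp(rec)
  pos_minus <- if (rc == rec) integer() else find(rc)
  hits <- rbind(
    data.frame(position = pos_plus, strand = rep("+", length(pos_plus)),
               stringsAsFactors = FALSE),
    data.frame(position = pos_minus, strand = rep("-", length(pos_minus)),
               stringsAsFactors = FALSE))
  if (circular && nrow(hits)) {
    hits$position <- hits$position %% L
    hits <- unique(hits)
  }
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

## cut events for an enzyme on a molecule: data.frame(t, b) in top-strand
## coordinates (t = top-strand scission point, b = bottom-strand point);
## both may exceed [0, L) before normalisation on circular molecules.
cut_events <- function(s, hits, enzyme) {
  k <- nchar(enzyme$recognition)
  ## a minus-strand site reads the bottom strand, so the enzyme's
  ## top-strand scission lands on our bottom strand and vice versa
  t <- ifelse(hits$strand == "+",
              hits$position + k + enzyme$cut_offset_top,
              hits$position - enzyme$cut_offset_bottom)
  b <- ifelse(hits$strand == "+",
              hits$position + k + enzyme$cut_offset_bottom,
              hits$position - enzyme$cut_offset_top)
  data.frame(t = as.integer(t), b = as.integer(b), site = hits$position,
             strand = hits$strand, stringsAsFactors = FALSE)
}

#' Digest a molecule with a restriction enzyme
#'
#' Simulates complete digestion. A circular molecule with n sites yields n
#' fragments; a linear molecule yields n+1 (terminal ends blunt-flagged as
#' `"none"`). Each sticky end records its overhang 4-mer (top-strand
#' orientation) and which strand protrudes. Features fully contained in a
#' fragment's top-strand span are carried over with shifted coordinates.
#'
#' A molecule with zero sites is returned unchanged (a one-element list
#' holding the input) with a warning. On a linear molecule, a site whose
#' cut window runs off an end is an error naming the site.
#'
#' @param seq A `nuc_seq` (or character scalar, treated as linear).
#' @param enzyme An `enzyme_spec` or built-in name.
#' @return List of `fragment` objects (see Details for the zero-site case).
#' @examples
#' ins <- paste0("GGTCTCA", "CCTG", "AAACCCGGG", "CAGT", "T", "GAGACC")
#' digest(nuc_seq(ins), "BsaI")
#' @export
digest <- function(seq, enzyme) {
  enzyme <- get_enzyme(enzyme)
  if (is.character(seq)) seq <- nuc_seq(seq)
  s <- seq$bases
  L <- nchar(s)
  circular <- seq$topology == "circular"
  hits <- scan_sites(seq, enzyme)
  if (nrow(hits) == 0) {
    warning("no ", enzyme$name, " site in '", seq$name,
            "'; molecule returned uncut")
    return(list(seq))
  }
  cuts <- cut_events(s, hits, enzyme)
  if (!circular) {
    lo <- pmin(cuts$t, cuts$b); hi <- pmax(cuts$t, cuts$b)
    off <- lo < 0 | hi > L
    if (any(off)) {
      vs_stop("cut window of ", enzyme$name, " site at position ",
              cuts$site[which(off)[1]], " (", cuts$strand[which(off)[1]],
              ") runs off the end of linear molecule '", seq$name, "'",
              class = "vegassim_cut_error")
    }
  } else {
    ## keep b's offset relative to t, normalise t into [0, L)
    delta <- cuts$b - cuts$t
    cuts$t <- cuts$t %% L
    cuts$b <- cuts$t + delta
  }
  cuts <- cuts[!duplicated(cuts[c("t", "b")]), , drop = FALSE]
  cuts <- cuts[order(cuts$t), , drop = FALSE]
  oh_of <- function(i) {
    lo <- min(cuts$t[i], cuts$b[i]); hi <- max(cuts$t[i], cuts$b[i])
    if (hi == lo) "" else circ_substr(s, lo + 1L, hi - lo)
  }
  end_right <- function(i) {  # end5 of the fragment to the right of cut i
    if (cuts$b[i] == cuts$t[i]) return(end_spec("", "none"))
    end_spec(oh_of(i), if (cuts$b[i] > cuts$t[i]) "top" else "bottom")
  }
  end_left <- function(i) {   # end3 of the fragment to the left of cut i
    if (cuts$b[i] == cuts$t[i]) return(end_spec("", "none"))
    end_spec(oh_of(i), if (cuts$b[i] > cuts$t[i]) "bottom" else "top")
  }
  take_feats <- function(start, len) {
    f <- seq$features
    if (!nrow(f)) return(NULL)
    if (circular) {
      ## unroll: feature [fs, fe) (fe may exceed L for wrapping features)
      fs <- f$start; fe <- f$end
      wrap <- fe < fs
      fe[wrap] <- fe[wrap] + L
      keep <- logical(nrow(f)); rs <- integer(nrow(f))
      for (sh in c(0L, L)) {
        inside <- fs + sh >= start & fe + sh <= start + len
        rs[inside & !keep] <- fs[inside & !keep] + sh - start
        keep <- keep | inside
      }
      if (!any(keep)) return(NULL)
      data.frame(label = f$label[keep], start = rs[keep],
                 end = rs[keep] + (fe - fs)[keep], strand = f$strand[keep],
                 stringsAsFactors = FALSE)
    } else {
      keep <- f$start >= start & f$end <= start + len
      if (!any(keep)) return(NULL)
      data.frame(label = f$label[keep], start = f$start[keep] - start,
                 end = f$end[keep] - start, strand = f$strand[keep],
                 stringsAsFactors = FALSE)
    }
  }
  n <- nrow(cuts)
  frags <- list()
  if (circular) {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      len <- if (n == 1L) L else (cuts$t[j] - cuts$t[i]) %% L
      if (len == 0L) len <- L
      top <- circ_substr(s, cuts$t[i] + 1L, len)
      frags[[i]] <- fragment(top, end5 = end_right(i), end3 = end_left(j),
                             name = sprintf("%s_frag%d", seq$name, i),
                             features = take_feats(cuts$t[i], len))
    }
  } else {
    bounds <- c(0L, cuts$t, L)
    for (i in seq_len(n + 1L)) {
      start <- bounds[i]; len <- bounds[i + 1L] - start
      e5 <- if (i == 1L) end_spec("", "none") else end_right(i - 1L)
      e3 <- if (i == n + 1L) end_spec("", "none") else end_left(i)
      frags[[i]] <- fragment(substr(s, start + 1L, start + len),
                             end5 = e5, end3 = e3,
                             name = sprintf("%s_frag%d", seq$name, i),
                             features = take_feats(start, len))
    }
  }
  frags
}

#' Ligate an ordered chain of fragments
#'
#' Joins fragments end-to-end (each 3' end against the next 5' end), after
#' checking sticky-end compatibility at every junction; for a circular
#' ligation the last fragment's 3' end must also match the first
#' fragment's 5' end. Each junction overhang contributes its 4-mer exactly
#' once to the product (it is already carried, in top-strand orientation,
#' by the downstream fragment's top strand).
#'
#' @param frags List of `fragment` objects, in order.
#' @param circular Close the product into a circle?
#' @param name Product name.
#' @return A `nuc_seq` with the combined features of all inputs.
#' @export
ligate_fragments <- function(frags, circular = TRUE, name = "ligation") {
  stopifnot(length(frags) >= 1L)
  n <- length(frags)
  for (i in seq_len(if (circular) n else n - 1L)) {
    j <- if (i == n) 1L else i + 1L
    if (!ends_compatible(frags[[i]]$end3, frags[[j]]$end5)) {
      vs_stop("incompatible ends between fragments ", i, " (",
              frags[[i]]$end3$overhang %||% "", ") and ", j, " (",
              frags[[j]]$end5$overhang, ")", class = "vegassim_ligate_error")
    }
  }
  if (!circular &&
      (frags[[1]]$end5$protruding != "none" ||
       frags[[n]]$end3$protruding != "none")) {
    ## permitted: linear product retains its terminal sticky ends
  }
  tops <- vapply(frags, function(f) f$top, "")
  feats <- NULL
  off <- 0L
  for (f in frags) {
    if (nrow(f$features)) {
      g <- f$features
      g$start <- g$start + off; g$end <- g$end + off
      feats <- rbind(feats, g)
    }
    off <- off + nchar(f$top)
  }
  nuc_seq(paste(tops, collapse = ""),
          topology = if (circular) "circular" else "linear",
          name = name, features = feats)
}
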