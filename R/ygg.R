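#' Diagnose an overhang set for one-pot assembly fidelity
#'
#' For a one-pot Golden Gate reaction to have a unique product, junction
#' overhangs must be pairwise distinct, no two may be reverse complements
#' of one another (that would allow a fragment to ligate flipped), and
#' none should be palindromic (self-ligation risk).
#'
#' @param x Either a character vector of overhang 4-mers or a list of
#'   `fragment`s (whose sticky-end 4-mers are collected).
#' @return Object of class `overhang_diagnostics`: list with `clean`
#'   (logical) and character vectors `duplicated`, `revcomp_pairs`,
#'   `palindromic`.
#' @examples
#' check_overhang_set(c("CCTG", "CAGT", "AATG", "TGAG", "TTTT", "AACT"))$clean
#' @export
check_overhang_set <- function(x) {
  if (is.list(x) && all(vapply(x, inherits, TRUE, "fragment"))) {
    ## a junction pairs one 3' end with one 5' end carrying the same
    ## top-strand 4-mer, so over-use means a repeat within an end class
    e5 <- unlist(lapply(x, function(f)
      if (f$end5$protruding != "none") f$end5$overhang))
    e3 <- unlist(lapply(x, function(f)
      if (f$end3$protruding != "none") f$end3$overhang))
    dup <- unique(c(e5[duplicated(e5)], e3[duplicated(e3)]))
    x <- c(e5, e3)
  } else {
    x <- toupper(x)
    dup <- unique(x[duplicated(x)])
  }
  pal <- unique(x[x == vapply(x, revcomp, "")])
  u <- unique(x)
  pairs <- character()
  if (length(u) > 1) {
    for (i in seq_along(u)) {
      for (j in seq_along(u)) {
        if (i < j && u[j] == revcomp(u[i])) {
          pairs <- c(pairs, paste0(u[i], "/", u[j]))
        }
      }
    }
  }
  structure(list(clean = !length(dup) && !length(pal) && !length(pairs),
                 duplicated = dup, revcomp_pairs = pairs, palindromic = pal),
            class = "overhang_diagnostics")
}

#' @export
print.overhang_diagnostics <- function(x, ...) {
  cat("<overhang_diagnostics>", if (x$clean) "clean" else "problems:", "\n")
  if (length(x$duplicated)) cat("  duplicated:", x$duplicated, "\n")
  if (length(x$revcomp_pairs)) cat("  revcomp pairs:", x$revcomp_pairs, "\n")
  if (length(x$palindromic)) cat("  palindromic:", x$palindromic, "\n")
  invisible(x)
}

## does a fragment still carry the assembly enzyme's recognition sequence
## (on either strand)? Such fragments are re-cut in the cycling reaction
## and never accumulate in the end state.
is_recuttable <- function(frag, enzyme) {
  s <- seq_string(frag)
  grepl(enzyme$recognition, s, fixed = TRUE) ||
    grepl(revcomp(enzyme$recognition), s, fixed = TRUE)
}

## enumerate circular sticky-end chains: backbone (fixed orientation) plus
## each other fragment at most once in either orientation. Returns a list
## of integer/orientation paths.
find_sticky_circles <- function(backbone, frags) {
  oriented <- lapply(frags, function(f) list(fwd = f, rev = flip_fragment(f)))
  circles <- list()
  path <- list()
  recurse <- function(cur_end3, used) {
    if (ends_compatible(cur_end3, backbone$end5)) {
      circles[[length(circles) + 1L]] <<- path
    }
    for (i in seq_along(frags)) {
      if (used[i]) next
      for (ori in c("fwd", "rev")) {
        f <- oriented[[i]][[ori]]
        if (ends_compatible(cur_end3, f$end5)) {
          path[[length(path) + 1L]] <<- list(idx = i, ori = ori, frag = f)
          used[i] <- TRUE
          recurse(f$end3, used)
          used[i] <- FALSE
          path[[length(path)]] <<- NULL
        }
      }
    }
  }
  recurse(backbone$end3, rep(FALSE, length(frags)))
  circles
}

#' Simulate a one-pot yGG digestion--ligation reaction
#'
#' Digests the acceptor vector and every part insert with the assembly
#' enzyme, discards re-cuttable fragments (those still carrying the
#' recognition sequence -- the cycling reaction's end state excludes
#' them), and searches for circular chains that use the acceptor backbone
#' once and every other fragment at most once with perfect overhang
#' complementarity at each junction. The reaction succeeds iff exactly one
#' such circle exists; the product then carries one feature per part and
#' contains no residual recognition site.
#'
#' @param acceptor Circular `nuc_seq` acceptor vector (dropout cassette
#'   flanked by outward-facing assembly-enzyme sites).
#' @param part_inserts List of part inserts (linear `nuc_seq`, from
#'   [build_part_insert()]).
#' @param enzyme Assembly enzyme (offset cutter; default BsaI).
#' @return Object of class `ygg_result`: list with `product` (circular
#'   `nuc_seq` or `NULL`), `dropout_fragments`, `diagnostics` (character),
#'   and `junction_map` (data.frame part/junction 4-mer, in product order).
#' @export
simulate_ygg <- function(acceptor, part_inserts, enzyme = "BsaI") {
  enzyme <- get_enzyme(enzyme)
  if (overhang_length(enzyme) == 0L) {
    vs_stop("assembly enzyme must be an offset cutter with sticky ends",
            class = "vegassim_enzyme_error")
  }
  stopifnot(inherits(acceptor, "nuc_seq"), acceptor$topology == "circular")
  diags <- character()
  acc_frags <- digest(acceptor, enzyme)
  keep <- !vapply(acc_frags, is_recuttable, TRUE, enzyme = enzyme)
  if (sum(keep) != 1L) {
    vs_stop("acceptor must yield exactly one backbone fragment free of ",
            enzyme$name, " sites (got ", sum(keep), ")",
            class = "vegassim_acceptor_error")
  }
  backbone <- acc_frags[[which(keep)]]
  backbone$name <- paste0(acceptor$name, "_backbone")
  dropout <- acc_frags[!keep]
  if (length(dropout)) {
    diags <- c(diags, sprintf("dropout cassette excised from acceptor (%d bp)",
                              nchar(dropout[[1]]$top)))
  }
  pool <- list()
  for (ins in part_inserts) {
    if (is.character(ins)) ins <- nuc_seq(ins)
    fr <- withCallingHandlers(
      digest(ins, enzyme),
      warning = function(w) {
        diags <<- c(diags, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    for (f in fr) {
      if (inherits(f, "fragment") && !is_recuttable(f, enzyme)) {
        f$name <- sub("_insert_frag[0-9]+$", "", f$name)
        pool[[length(pool) + 1L]] <- f
      }
    }
  }
  oh <- check_overhang_set(c(list(backbone), pool))
  if (!oh$clean) {
    diags <- c(diags, paste0(
      "overhang-set diagnostics: ",
      paste(c(if (length(oh$duplicated))
                paste0("duplicated ", paste(oh$duplicated, collapse = ",")),
              if (length(oh$revcomp_pairs))
                paste0("revcomp pair ", paste(oh$revcomp_pairs, collapse = ",")),
              if (length(oh$palindromic))
                paste0("palindromic ", paste(oh$palindromic, collapse = ","))),
            collapse = "; ")))
  }
  circles <- find_sticky_circles(backbone, pool)
  if (length(circles) == 0L) {
    vs_stop("no circular assembly: open junction after overhang ",
            backbone$end3$overhang, " with parts {",
            paste(vapply(pool, function(f) paste0(f$name, ":",
                                                  f$end5$overhang, "/",
                                                  f$end3$overhang), ""),
                  collapse = ", "), "}",
            class = "vegassim_assembly_error")
  }
  seqs <- lapply(circles, function(chain) {
    ligate_fragments(c(list(backbone), lapply(chain, `[[`, "frag")),
                     circular = TRUE, name = "ygg_product")
  })
  uniq <- !duplicated(vapply(seqs, function(s) {
    u <- s$bases
    if (grepl(revcomp(u), paste0(u, u), fixed = TRUE)) revcomp(u) else u
  }, ""))
  ## distinct product sequences (up to strand); rotations identical by
  ## construction since every circle starts at the backbone
  circles <- circles[uniq]; seqs <- seqs[uniq]
  if (length(circles) > 1L) {
    alt <- vapply(circles, function(ch)
      paste(vapply(ch, function(st) st$frag$name, ""), collapse = "+"), "")
    vs_stop("ambiguous assembly: ", length(circles),
            " distinct circular products possible: ",
            paste(alt, collapse = " | "), class = "vegassim_assembly_error")
  }
  chain <- circles[[1]]
  product <- seqs[[1]]
  ## annotate parts and junctions
  off <- nchar(backbone$top)
  jmap <- data.frame(part = paste0(acceptor$name, "_backbone"),
                     junction = backbone$end5$overhang,
                     stringsAsFactors = FALSE)
  product <- add_feature(product, "backbone", 0L, off)
  for (st in chain) {
    f <- st$frag
    product <- add_feature(product, paste0("part:", f$name), off,
                           off + nchar(f$top),
                           if (st$ori == "fwd") "+" else "-")
    jmap <- rbind(jmap, data.frame(part = f$name, junction = f$end5$overhang,
                                   stringsAsFactors = FALSE))
    off <- off + nchar(f$top)
  }
  stopifnot(nrow(scan_sites(product, enzyme)) == 0L)
  structure(list(product = product, dropout_fragments = dropout,
                 diagnostics = diags, junction_map = jmap,
                 n_parts = length(chain)),
            class = "ygg_result")
}

#' @export
print.ygg_result <- function(x, ...) {
  cat(sprintf("<ygg_result> %s: %d part(s) assembled, product %d bp\n",
              if (is.null(x$product)) "failed" else "success", x$n_parts,
              if (is.null(x$product)) 0L else nchar(x$product$bases)))
  if (length(x$diagnostics)) cat(paste0("  - ", x$diagnostics, "\n"))
  invisible(x)
}

#' Release an assembled VA-flanked TU from its acceptor
#'
#' Digests a yGG product with the release enzyme (BsmBI in the standard
#' acceptor, NotI/FseI in the alternative vectors) and returns the unique
#' fragment carrying all assembled part features. With the standard
#' acceptor geometry the released fragment's top strand begins at the
#' CCTG junction and ends right after AACT.
#'
#' @param construct Circular `nuc_seq` from [simulate_ygg()] (must carry
#'   `part:` features).
#' @param release_enzyme Release enzyme (default BsmBI).
#' @return A `fragment` holding the VA-flanked TU.
#' @export
release_tu <- function(construct, release_enzyme = "BsmBI") {
  release_enzyme <- get_enzyme(release_enzyme)
  if (inherits(construct, "ygg_result")) construct <- construct$product
  stopifnot(inherits(construct, "nuc_seq"))
  part_feats <- construct$features[grepl("^part:", construct$features$label), ]
  if (!nrow(part_feats)) {
    vs_stop("construct has no part features; was it built by simulate_ygg()?",
            class = "vegassim_release_error")
  }
  hits <- scan_sites(construct, release_enzyme)
  if (!nrow(hits)) {
    vs_stop("no ", release_enzyme$name, " site in construct",
            class = "vegassim_release_error")
  }
  L <- nchar(construct$bases)
  cuts <- cut_events(construct$bases, hits, release_enzyme)
  win_lo <- pmin(cuts$t, cuts$b) %% L
  for (i in seq_len(nrow(part_feats))) {
    fs <- part_feats$start[i]; fe <- part_feats$end[i]
    inside <- if (fe >= fs) win_lo > fs & win_lo < fe
              else win_lo > fs | win_lo < fe   # wrapping feature
    if (any(inside)) {
      vs_stop(release_enzyme$name, " cuts inside part '",
              sub("^part:", "", part_feats$label[i]), "' at position(s) ",
              paste(cuts$site[inside], collapse = ", "),
              class = "vegassim_release_error")
    }
  }
  frags <- digest(construct, release_enzyme)
  carries_all <- vapply(frags, function(f) {
    inherits(f, "fragment") &&
      all(part_feats$label %in% f$features$label)
  }, TRUE)
  if (sum(carries_all) != 1L) {
    vs_stop("TU-containing fragment not unique after ", release_enzyme$name,
            " digestion (", sum(carries_all), " candidates)",
            class = "vegassim_release_error")
  }
  tu <- frags[[which(carries_all)]]
  tu$name <- paste0(construct$name, "_TU")
  tu
}
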