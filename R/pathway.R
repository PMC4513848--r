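#' Pathway design: ordered TU slots with adapter assignments
#'
#' A pathway design is an ordered table of transcription-unit slots, each
#' carrying a left/right VEGAS adapter (LVA/RVA) assignment, an
#' orientation, and part assignments (PRO/CDS/TER part names; a marker
#' slot such as KanMX leaves PRO and TER empty and is treated as a
#' pre-assembled PRO-CDS-TER part). Two assembly modes exist:
#' `va_homology`, where adjacent TUs must share an adapter (RVA of slot i
#' equals LVA of slot i+1, with VA1/VA2 at the vector ends), and
#' `pcr_homology`, where adapters are unconstrained (duplicates are
#' permitted but surface as off-target homology warnings) and junction
#' homology is introduced by primer tails.
#'
#' @param slots data.frame with columns `name`, `lva`, `pro`, `cds`,
#'   `ter`, `rva`, and optionally `orientation` (`"forward"` default).
#'   `NA` in both `pro` and `ter` marks a marker-TU slot.
#' @param mode `"va_homology"` or `"pcr_homology"`.
#' @param vector_left_va,vector_right_va Adapters encoded terminally on
#'   the assembly vector arms.
#' @return Object of class `pathway_design` (a data.frame with
#'   attributes).
#' @export
pathway_design <- function(slots, mode = c("va_homology", "pcr_homology"),
                           vector_left_va = "VA1", vector_right_va = "VA2") {
  mode <- match.arg(mode)
  slots <- as.data.frame(slots, stringsAsFactors = FALSE)
  need <- c("name", "lva", "pro", "cds", "ter", "rva")
  stopifnot(all(need %in% names(slots)), nrow(slots) >= 1L)
  if (is.null(slots$orientation)) slots$orientation <- "forward"
  stopifnot(all(slots$orientation %in% c("forward", "reverse")))
  structure(slots, class = c("pathway_design", "data.frame"),
            mode = mode, vector_left_va = vector_left_va,
            vector_right_va = vector_right_va)
}

#' @export
print.pathway_design <- function(x, ...) {
  cat(sprintf("<pathway_design> %d TU slot(s), mode %s (%s ... %s)\n",
              nrow(x), attr(x, "mode"), attr(x, "vector_left_va"),
              attr(x, "vector_right_va")))
  print.data.frame(x)
  invisible(x)
}

is_marker_slot <- function(design) is.na(design$pro) & is.na(design$ter)

#' Validate the adapter chain of a VA-homology design
#'
#' In VA-homology mode the adapters themselves provide junction homology,
#' so the left-most TU's LVA must be the vector's left-arm adapter (VA1),
#' each slot's RVA must equal the next slot's LVA, and the right-most
#' TU's RVA must be the right-arm adapter (VA2).
#'
#' @param design A `pathway_design` with mode `va_homology`.
#' @return List with `pass` (logical) and `problems` (data.frame
#'   junction/expected/found).
#' @export
validate_va_chain <- function(design) {
  stopifnot(inherits(design, "pathway_design"))
  if (attr(design, "mode") != "va_homology") {
    vs_stop("validate_va_chain applies to va_homology designs",
            class = "vegassim_design_error")
  }
  n <- nrow(design)
  probs <- NULL
  chk <- function(junction, expected, found) {
    if (!identical(expected, found)) {
      probs <<- rbind(probs, data.frame(junction = junction,
                                        expected = expected, found = found,
                                        stringsAsFactors = FALSE))
    }
  }
  chk("vector_left/slot1", attr(design, "vector_left_va"), design$lva[1])
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      chk(sprintf("slot%d/slot%d", i, i + 1), design$rva[i],
          design$lva[i + 1])
    }
  }
  chk(sprintf("slot%d/vector_right", n), attr(design, "vector_right_va"),
      design$rva[n])
  if (is.null(probs)) {
    probs <- data.frame(junction = character(), expected = character(),
                        found = character(), stringsAsFactors = FALSE)
  }
  list(pass = nrow(probs) == 0L, problems = probs)
}

## adapter presented at the left (head) or right (tail) terminus of a
## slot's oriented TU, as a top-strand sequence of the oriented molecule
slot_head_adapter <- function(design, i, table) {
  if (design$orientation[i] == "forward") adapter_seq(design$lva[i], table)[[1]]
  else revcomp(adapter_seq(design$rva[i], table)[[1]])
}
slot_tail_adapter <- function(design, i, table) {
  if (design$orientation[i] == "forward") adapter_seq(design$rva[i], table)[[1]]
  else revcomp(adapter_seq(design$lva[i], table)[[1]])
}

#' Design homology-tail primer pairs for PCR-mediated assembly
#'
#' For each TU slot, the forward primer anneals to the first `anneal_len`
#' bases of the slot's (orientation-adjusted) left adapter and carries a
#' `tail_len`-bp tail copying the facing terminus of the upstream
#' neighbour (the upstream slot's right adapter, or the vector's VA1 arm
#' for the first slot). The reverse primer mirrors this downstream.
#' Adjacent amplicons therefore share 2*`tail_len` bp of exact terminal
#' identity, and each terminal amplicon shares `tail_len` bp with its
#' vector arm. All primers are reported 5'->3' with the tail/anneal split
#' retained.
#'
#' @param design A `pathway_design` (mode `pcr_homology`).
#' @param adapter_table Adapter table resolving the design's adapter ids.
#' @param anneal_len Annealing length in nt (default 20).
#' @param tail_len Homology-tail length in nt (default 30).
#' @return List of `primer_pair` objects (fields `slot`, `name`,
#'   `forward`, `reverse`; each primer has `tail`, `anneal`, `seq`).
#' @export
design_vegas_primers <- function(design, adapter_table = va_adapters(),
                                 anneal_len = 20L, tail_len = 30L) {
  stopifnot(inherits(design, "pathway_design"))
  if (attr(design, "mode") != "pcr_homology") {
    vs_stop("primer design applies to pcr_homology designs",
            class = "vegassim_design_error")
  }
  alen <- nchar(adapter_table$sequence[1])
  if (tail_len > alen) {
    vs_stop("tail_len (", tail_len, ") exceeds adapter length (", alen, ")",
            class = "vegassim_design_error")
  }
  n <- nrow(design)
  vleft <- adapter_seq(attr(design, "vector_left_va"), adapter_table)[[1]]
  vright <- adapter_seq(attr(design, "vector_right_va"), adapter_table)[[1]]
  lastn <- function(s, k) if (k == 0) "" else substr(s, nchar(s) - k + 1, nchar(s))
  firstn <- function(s, k) if (k == 0) "" else substr(s, 1, k)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    head_i <- slot_head_adapter(design, i, adapter_table)
    tail_i <- slot_tail_adapter(design, i, adapter_table)
    left_ctx <- if (i == 1) vleft else slot_tail_adapter(design, i - 1,
                                                         adapter_table)
    right_ctx <- if (i == n) vright else slot_head_adapter(design, i + 1,
                                                           adapter_table)
    fwd_tail <- lastn(left_ctx, tail_len)
    fwd_anneal <- firstn(head_i, anneal_len)
    rev_tail <- revcomp(firstn(right_ctx, tail_len))
    rev_anneal <- revcomp(lastn(tail_i, anneal_len))
    out[[i]] <- structure(list(
      slot = i, name = design$name[i],
      forward = list(tail = fwd_tail, anneal = fwd_anneal,
                     seq = paste0(fwd_tail, fwd_anneal)),
      reverse = list(tail = rev_tail, anneal = rev_anneal,
                     seq = paste0(rev_tail, rev_anneal))),
      class = "primer_pair")
  }
  out
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s\n  F: %s|%s\n  R: %s|%s\n", x$name,
              x$forward$tail, x$forward$anneal, x$reverse$tail,
              x$reverse$anneal))
  invisible(x)
}

#' Primer pairs as a TSV-ready table
#' @param pairs List of `primer_pair`s.
#' @return data.frame with name, direction, sequence, tail, anneal.
#' @export
primer_table <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(name = paste0(p$name, c("_F", "_R")),
               direction = c("forward", "reverse"),
               sequence = c(p$forward$seq, p$reverse$seq),
               tail = c(p$forward$tail, p$reverse$tail),
               anneal = c(p$forward$anneal, p$reverse$anneal),
               stringsAsFactors = FALSE)
  }))
}

count_fixed <- function(pattern, subject) {
  if (!nzchar(pattern)) return(0L)
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Predict the amplicon of a primer pair on a template
#'
#' Exact string construction without an error model: the amplicon is the
#' forward tail, then the template span from the forward anneal site to
#' the end of the reverse anneal site, then the reverse complement of the
#' reverse tail. Each anneal region must occur exactly once in the
#' template; a template given in the opposite orientation (reverse slot)
#' is flipped automatically when the anneal sites are only found there.
#'
#' @param template `nuc_seq`, `fragment`, or string (the VA-flanked TU).
#' @param pair A `primer_pair`.
#' @return Linear `nuc_seq` amplicon.
#' @export
predict_amplicon <- function(template, pair) {
  tpl <- seq_string(template)
  fa <- pair$forward$anneal
  ra_rc <- revcomp(pair$reverse$anneal)
  if (count_fixed(fa, tpl) == 0L && count_fixed(fa, revcomp(tpl)) >= 1L) {
    tpl <- revcomp(tpl)
  }
  nf <- count_fixed(fa, tpl)
  nr <- count_fixed(ra_rc, tpl)
  if (nf == 0L || nr == 0L) {
    vs_stop("anneal region absent from template (forward: ", nf,
            " hit(s), reverse: ", nr, " hit(s))",
            class = "vegassim_pcr_error")
  }
  if (nf > 1L || nr > 1L) {
    vs_stop("anneal region not unique in template (forward: ", nf,
            ", reverse: ", nr, ")", class = "vegassim_pcr_error")
  }
  fs <- as.integer(regexpr(fa, tpl, fixed = TRUE))
  re <- as.integer(regexpr(ra_rc, tpl, fixed = TRUE)) + nchar(ra_rc) - 1L
  if (re < fs + nchar(fa) - 1L) {
    vs_stop("reverse anneal site lies upstream of the forward site",
            class = "vegassim_pcr_error")
  }
  amp <- paste0(pair$forward$tail, substr(tpl, fs, re),
                revcomp(pair$reverse$tail))
  nuc_seq(amp, "linear", name = paste0(pair$name, "_amplicon"))
}

## longest common substring of two strings with end positions (1-based);
## vectorised row-scan DP
lcs_positions <- function(x, y) {
  nx <- nchar(x); ny <- nchar(y)
  if (nx == 0L || ny == 0L) return(list(len = 0L, end_x = 0L, end_y = 0L))
  xv <- utf8ToInt(x); yv <- utf8ToInt(y)
  prev <- integer(ny)
  best <- 0L; bx <- 0L; by <- 0L
  for (i in seq_len(nx)) {
    cur <- integer(ny)
    hit <- yv == xv[i]
    if (any(hit)) {
      shifted <- c(0L, prev[-ny])
      cur[hit] <- shifted[hit] + 1L
      m <- max(cur)
      if (m > best) {
        best <- m; bx <- i; by <- which.max(cur)
      }
    }
    prev <- cur
  }
  list(len = best, end_x = bx, end_y = by)
}

#' Longest exact terminal overlap between two linear sequences
#'
#' Length of the longest exact substring shared between the 3'-terminal
#' `window` of `a` and the 5'-terminal `window` of `b`. Both relative
#' orientations are considered: `forward` compares the windows on the
#' same strand, `reverse` compares `a`'s tail window against the reverse
#' complement of `b`'s head window (the flipped-annealing case, e.g.
#' `a` against `revcomp(a)` scores the full window). The winning
#' orientation is reported. This is the homology measure used by the
#' recombination simulator; designed junctions are exact, so no gapped
#' alignment is attempted.
#'
#' @param a,b Linear sequences (`nuc_seq`, `fragment`, or strings).
#' @param window Terminal window size in bp (default 150).
#' @return Integer overlap length with attributes `orientation`
#'   (`"forward"`/`"reverse"`), `end_a` (1-based match end in `a`) and
#'   `end_b` (1-based match end in the compared window of `b`).
#' @export
terminal_overlap <- function(a, b, window = 150L) {
  sa <- seq_string(a); sb <- seq_string(b)
  tail_a <- substr(sa, max(1L, nchar(sa) - window + 1L), nchar(sa))
  off_a <- nchar(sa) - nchar(tail_a)
  head_b <- substr(sb, 1L, min(window, nchar(sb)))
  fwd <- lcs_positions(tail_a, head_b)
  rev <- lcs_positions(tail_a, revcomp(head_b))
  pick <- if (rev$len > fwd$len) "reverse" else "forward"
  r <- if (pick == "reverse") rev else fwd
  structure(r$len, orientation = pick, end_a = off_a + r$end_x,
            end_b = r$end_y)
}

#' Linearize a VEGAS assembly vector
#'
#' Digests the vector with BsaI, discards the dropout cassette, and
#' verifies the backbone architecture: exactly two fragments, a
#' site-free backbone whose termini carry adapter sequences. Reading the
#' backbone's top strand 5'->3' runs from the right-arm adapter (VA2) to
#' the left-arm adapter (VA1): the VA1 copy at the 3' terminus is what
#' the first TU's leading VA1 recombines with, and the VA2 copy at the 5'
#' terminus closes the circle with the last TU.
#'
#' @param vector Circular `nuc_seq` VEGAS vector (or an already-linear
#'   backbone, accepted with a zero-site warning).
#' @param adapter_table Adapter table used to identify the arm termini.
#' @param enzyme Linearization enzyme (default BsaI).
#' @return List of class `linearized_vector`: `backbone` (`fragment`),
#'   `left_arm_terminus` / `right_arm_terminus` (`nuc_seq` 57-mers),
#'   `left_va` / `right_va` (adapter names).
#' @export
linearize_vegas_vector <- function(vector, adapter_table = va_adapters(),
                                   enzyme = "BsaI") {
  enzyme <- get_enzyme(enzyme)
  stopifnot(inherits(vector, "nuc_seq"))
  hits <- scan_sites(vector, enzyme)
  if (nrow(hits) == 0L) {
    warning("no ", enzyme$name, " site in vector; ",
            "treating it as already linearized")
    if (vector$topology != "linear") {
      vs_stop("circular vector without ", enzyme$name,
              " sites cannot be linearized",
              class = "vegassim_vector_error")
    }
    backbone <- fragment(vector$bases, name = vector$name,
                         features = vector$features)
  } else {
    frags <- digest(vector, enzyme)
    keep <- !vapply(frags, is_recuttable, TRUE, enzyme = enzyme)
    if (length(frags) != 2L || sum(keep) != 1L) {
      vs_stop("unexpected vector architecture: ", nrow(hits), " ",
              enzyme$name, " site(s) giving ", length(frags),
              " fragment(s), ", sum(keep), " site-free",
              class = "vegassim_vector_error")
    }
    backbone <- frags[[which(keep)]]
    backbone$name <- paste0(vector$name, "_backbone")
  }
  alen <- nchar(adapter_table$sequence[1])
  s <- backbone$top
  head_va <- match(substr(s, 1L, alen), adapter_table$sequence)
  tail_va <- match(substr(s, nchar(s) - alen + 1L, nchar(s)),
                   adapter_table$sequence)
  if (is.na(head_va) || is.na(tail_va)) {
    vs_stop("backbone termini do not carry adapter sequences from the table",
            class = "vegassim_vector_error")
  }
  structure(list(
    backbone = backbone,
    left_arm_terminus = nuc_seq(adapter_table$sequence[tail_va],
                                name = adapter_table$name[tail_va]),
    right_arm_terminus = nuc_seq(adapter_table$sequence[head_va],
                                 name = adapter_table$name[head_va]),
    left_va = adapter_table$name[tail_va],
    right_va = adapter_table$name[head_va]),
    class = "linearized_vector")
}

#' @export
print.linearized_vector <- function(x, ...) {
  cat(sprintf("<linearized_vector> backbone %d bp, arms %s (left) / %s (right)\n",
              nchar(x$backbone$top), x$left_va, x$right_va))
  invisible(x)
}

#' Simulate homologous-recombination assembly of linear pieces
#'
#' Builds a directed overlap graph over the backbone (fixed orientation)
#' and every fragment in both orientations, with an edge wherever the
#' 3'-terminal window of one oriented piece and the 5'-terminal window of
#' another share an exact substring of at least `min_homology` bp. It
#' then enumerates circular paths that use the backbone once and every
#' fragment exactly once, and returns all distinct circular products.
#' At each junction the shared block appears once in the product and any
#' non-homologous terminal flap outside the block is trimmed (free-end
#' resection); junction records report overlap and flap lengths, so
#' product length equals the summed piece lengths minus summed overlaps
#' and flaps. Homology edges not used in any returned product are
#' reported as warnings (potential misassembly), as is ambiguity when
#' more than one distinct circle exists.
#'
#' @param backbone Linearized vector backbone (`fragment`, `nuc_seq`,
#'   string, or a `linearized_vector`).
#' @param fragments List of linear pieces (`nuc_seq`/`fragment`/strings).
#' @param min_homology Minimum junction homology in bp (default 30;
#'   designed junctions are 50-60 bp in PCR mode and 57 bp in VA mode).
#' @param window Terminal window scanned for homology (default 150 bp).
#' @return Object of class `assembly_outcome`: `products` (list of
#'   circular `nuc_seq`), `junctions` (list of data.frames, one per
#'   product: from/to/orientation/overlap/flap lengths), `warnings`
#'   (character), `n_pieces`.
#' @export
simulate_recombination <- function(backbone, fragments, min_homology = 30L,
                                   window = 150L) {
  if (inherits(backbone, "linearized_vector")) backbone <- backbone$backbone
  sb <- seq_string(backbone)
  bname <- if (inherits(backbone, c("nuc_seq", "fragment")) &&
               nzchar(backbone$name)) backbone$name else "backbone"
  if (length(fragments) < 1L) {
    vs_stop("at least one fragment is required",
            class = "vegassim_assembly_error")
  }
  fs <- lapply(fragments, seq_string)
  fnames <- vapply(seq_along(fragments), function(i) {
    f <- fragments[[i]]
    if (inherits(f, c("nuc_seq", "fragment")) && nzchar(f$name)) f$name
    else paste0("fragment", i)
  }, "")
  n <- length(fs)
  ## oriented piece strings; node 1 = backbone fwd; nodes 2..: fragment i
  ## in orientation o
  oriented <- list(list(piece = 0L, ori = "forward", s = sb))
  for (i in seq_len(n)) {
    oriented[[length(oriented) + 1L]] <- list(piece = i, ori = "forward",
                                              s = fs[[i]])
    oriented[[length(oriented) + 1L]] <- list(piece = i, ori = "reverse",
                                              s = revcomp(fs[[i]]))
  }
  nn <- length(oriented)
  ## edge table
  edges <- vector("list", nn)
  for (u in seq_len(nn)) {
    edges[[u]] <- list()
    for (v in seq_len(nn)) {
      if (oriented[[u]]$piece == oriented[[v]]$piece) next
      ## overlap between u's 3' window and v's 5' window, same strand
      su <- oriented[[u]]$s
      tail_u <- substr(su, max(1L, nchar(su) - window + 1L), nchar(su))
      head_v <- substr(oriented[[v]]$s, 1L, window)
      r <- lcs_positions(tail_u, head_v)
      if (r$len >= min_homology) {
        edges[[u]][[as.character(v)]] <-
          list(v = v, len = r$len,
               end_u = nchar(su) - nchar(tail_u) + r$end_x,
               end_v = r$end_y)
      }
    }
  }
  ## enumerate circular paths: start at node 1 (backbone), use each piece
  ## exactly once, close back to node 1
  cycles <- list()
  path <- integer()
  used <- rep(FALSE, n)
  recurse <- function(u) {
    if (all(used)) {
      if (!is.null(edges[[u]][["1"]])) {
        cycles[[length(cycles) + 1L]] <<- path
      }
      return()
    }
    for (e in edges[[u]]) {
      pc <- oriented[[e$v]]$piece
      if (pc == 0L || used[pc]) next
      used[pc] <<- TRUE
      path <<- c(path, e$v)
      recurse(e$v)
      path <<- path[-length(path)]
      used[pc] <<- FALSE
    }
  }
  recurse(1L)
  if (length(cycles) == 0L) {
    deg_in <- rep(FALSE, n); deg_out <- rep(FALSE, n)
    for (u in seq_len(nn)) {
      for (e in edges[[u]]) {
        if (oriented[[e$v]]$piece > 0L) deg_in[oriented[[e$v]]$piece] <- TRUE
        if (oriented[[u]]$piece > 0L) deg_out[oriented[[u]]$piece] <- TRUE
      }
    }
    orphan <- fnames[!(deg_in & deg_out)]
    vs_stop("no circular assembly with homology >= ", min_homology,
            " bp; unreachable fragment(s): ",
            if (length(orphan)) paste(orphan, collapse = ", ")
            else "(none; overlaps exist but no full circle)",
            class = "vegassim_assembly_error")
  }
  build <- function(cycle) {
    L <- sb
    jn <- NULL
    used_edges <- character()
    nodes <- c(1L, cycle)
    for (k in seq_along(cycle)) {
      u <- nodes[k]; v <- nodes[k + 1L]
      e <- edges[[u]][[as.character(v)]]
      su_len <- nchar(oriented[[u]]$s)
      end_in_L <- nchar(L) - (su_len - e$end_u)
      flap_u <- su_len - e$end_u
      flap_v <- e$end_v - e$len
      L <- paste0(substr(L, 1L, end_in_L),
                  substr(oriented[[v]]$s, e$end_v + 1L,
                         nchar(oriented[[v]]$s)))
      nm_u <- if (oriented[[u]]$piece == 0L) bname
              else fnames[oriented[[u]]$piece]
      nm_v <- fnames[oriented[[v]]$piece]
      jn <- rbind(jn, data.frame(from = nm_u, to = nm_v,
                                 orientation = oriented[[v]]$ori,
                                 overlap = e$len, flap_from = flap_u,
                                 flap_to = flap_v, stringsAsFactors = FALSE))
      used_edges <- c(used_edges, paste0(u, ">", v))
    }
    ## closing junction back to the backbone head
    u <- nodes[length(nodes)]
    e <- edges[[u]][["1"]]
    su_len <- nchar(oriented[[u]]$s)
    t2 <- nchar(L) - (su_len - e$end_u)
    h2 <- e$end_v
    circ <- substr(L, h2 + 1L, t2)
    jn <- rbind(jn, data.frame(
      from = if (oriented[[u]]$piece == 0L) bname else fnames[oriented[[u]]$piece],
      to = bname, orientation = "forward", overlap = e$len,
      flap_from = su_len - e$end_u, flap_to = e$end_v - e$len,
      stringsAsFactors = FALSE))
    used_edges <- c(used_edges, paste0(u, ">", 1L))
    list(seq = circ, junctions = jn, used_edges = used_edges)
  }
  built <- lapply(cycles, build)
  ## distinct products
  keep <- rep(TRUE, length(built))
  for (i in seq_along(built)) {
    if (!keep[i]) next
    for (j in seq_along(built)) {
      if (j > i && keep[j] &&
          circular_identical(built[[i]]$seq, built[[j]]$seq)) {
        keep[j] <- FALSE
      }
    }
  }
  built <- built[keep]
  warnings <- character()
  if (length(built) > 1L) {
    warnings <- c(warnings, sprintf(
      "ambiguous assembly: %d distinct circular products", length(built)))
  }
  ## unused homology edges (skipping mirror images of used edges)
  used_all <- unique(unlist(lapply(built, `[[`, "used_edges")))
  mirror_node <- function(v) {
    p <- oriented[[v]]$piece
    if (p == 0L) 1L
    else if (oriented[[v]]$ori == "forward") v + 1L else v - 1L
  }
  reported <- character()
  for (u in seq_len(nn)) {
    for (e in edges[[u]]) {
      id <- paste0(u, ">", e$v)
      mid <- paste0(mirror_node(e$v), ">", mirror_node(u))
      if (!(id %in% used_all) && !(mid %in% used_all) &&
          !(mid %in% reported)) {
        reported <- c(reported, id)
        ## prefer the all-forward description of a physical edge
        uu <- u; vv <- e$v
        if (oriented[[uu]]$ori == "reverse" &&
            oriented[[vv]]$ori == "reverse") {
          tmp <- mirror_node(uu); uu <- mirror_node(vv); vv <- tmp
        }
        nm_u <- if (oriented[[uu]]$piece == 0L) bname
                else paste0(fnames[oriented[[uu]]$piece],
                            if (oriented[[uu]]$ori == "reverse") "(rc)" else "")
        nm_v <- if (oriented[[vv]]$piece == 0L) bname
                else paste0(fnames[oriented[[vv]]$piece],
                            if (oriented[[vv]]$ori == "reverse") "(rc)" else "")
        warnings <- c(warnings, sprintf(
          "unused homology edge %s -> %s (%d bp): potential misassembly",
          nm_u, nm_v, e$len))
      }
    }
  }
  products <- lapply(seq_along(built), function(i) {
    nuc_seq(built[[i]]$seq, "circular", name = sprintf("assembly_%d", i))
  })
  structure(list(products = products,
                 junctions = lapply(built, `[[`, "junctions"),
                 warnings = warnings, n_pieces = n + 1L),
            class = "assembly_outcome")
}

#' @export
print.assembly_outcome <- function(x, ...) {
  cat(sprintf("<assembly_outcome> %d piece(s) -> %d product(s)\n",
              x$n_pieces, length(x$products)))
  for (i in seq_along(x$products)) {
    cat(sprintf("  product %d: %d bp, %d junction(s)\n", i,
                nchar(x$products[[i]]$bases), nrow(x$junctions[[i]])))
  }
  if (length(x$warnings)) cat(paste0("  ! ", x$warnings, "\n"))
  invisible(x)
}
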