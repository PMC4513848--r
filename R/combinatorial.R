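#' Combinatorial promoter/terminator library design
#'
#' Describes a pathway whose variable TU slots each draw a promoter from
#' a PRO pool and a terminator from a TER pool in a single pooled yGG
#' reaction (fixed slots, e.g. a marker TU, have singleton pools). Two
#' counting modes are supported: `with_replacement_across_slots` (the
#' default; the same part may serve several slots, as in a pooled
#' reaction) and `distinct_parts_across_slots` (every slot must receive a
#' different pool member).
#'
#' @param slots A `pathway_design` (or its slot data.frame); slots where
#'   both `pro` and `ter` are `NA` are fixed marker slots.
#' @param pro_pool,ter_pool Character vectors of pool member names
#'   (shared by all variable slots).
#' @param mode Counting mode.
#' @return Object of class `combinatorial_design`.
#' @export
combinatorial_design <- function(slots, pro_pool, ter_pool,
                                 mode = c("with_replacement_across_slots",
                                          "distinct_parts_across_slots")) {
  mode <- match.arg(mode)
  slots <- as.data.frame(slots, stringsAsFactors = FALSE)
  stopifnot(length(pro_pool) >= 1L, length(ter_pool) >= 1L,
            !anyDuplicated(pro_pool), !anyDuplicated(ter_pool))
  structure(list(slots = slots, pro_pool = pro_pool, ter_pool = ter_pool,
                 mode = mode),
            class = "combinatorial_design")
}

#' @export
print.combinatorial_design <- function(x, ...) {
  cat(sprintf("<combinatorial_design> %d slot(s) (%d variable), %d PRO x %d TER, %s\n",
              nrow(x$slots), sum(!is_marker_slot(x$slots)),
              length(x$pro_pool), length(x$ter_pool), x$mode))
  invisible(x)
}

falling_factorial <- function(p, v) {
  if (v > p) return(0)
  prod(seq(p, by = -1, length.out = v))
}

#' Theoretical complexity of a combinatorial library
#'
#' With replacement across slots, each of the v variable slots chooses
#' independently among |PRO| x |TER| regulatory combinations, giving
#' (|PRO| x |TER|)^v variants. In distinct mode the PRO choices form a
#' falling factorial |PRO|!/(|PRO|-v)! and likewise for TER; pools
#' smaller than the slot count give 0 with a warning.
#'
#' @param design A `combinatorial_design`.
#' @return Numeric count of distinct pathway variants.
#' @examples
#' # four variable slots, pools of 10 promoters and 5 terminators:
#' # (10 * 5)^4 = 6,250,000
#' @export
library_complexity <- function(design) {
  stopifnot(inherits(design, "combinatorial_design"))
  v <- sum(!is_marker_slot(design$slots))
  p <- length(design$pro_pool); t <- length(design$ter_pool)
  if (design$mode == "with_replacement_across_slots") {
    (p * t)^v
  } else {
    if (v > p || v > t) {
      warning("pool smaller than the number of variable slots; complexity 0")
      return(0)
    }
    falling_factorial(p, v) * falling_factorial(t, v)
  }
}

#' Sample fully specified designs from a combinatorial space
#'
#' Draws `n` uniform, independent variants: per variable slot a PRO and a
#' TER from the pools (jointly without replacement across slots in
#' distinct mode). Deterministic given the seed. Each draw is a complete
#' [pathway_design()] runnable through the assembly simulators.
#'
#' @param design A `combinatorial_design`.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return List of `pathway_design` objects (mode `pcr_homology`, the
#'   workflow used for pooled assemblies).
#' @export
sample_designs <- function(design, n, seed = 1L) {
  stopifnot(inherits(design, "combinatorial_design"), n >= 1L)
  slots <- design$slots
  variable <- which(!is_marker_slot(slots))
  v <- length(variable)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      s <- slots
      if (design$mode == "with_replacement_across_slots") {
        s$pro[variable] <- sample(design$pro_pool, v, replace = TRUE)
        s$ter[variable] <- sample(design$ter_pool, v, replace = TRUE)
      } else {
        s$pro[variable] <- sample(design$pro_pool, v, replace = FALSE)
        s$ter[variable] <- sample(design$ter_pool, v, replace = FALSE)
      }
      pathway_design(s, mode = "pcr_homology")
    })
  })
}

#' Identify the assembled variant from a recovered plasmid
#'
#' The in-silico analogue of sequencing a plasmid recovered from yeast:
#' for each variable slot, exactly one PRO pool member's core must occur
#' immediately upstream of that slot's CDS core (joined by the AATG
#' junction) on either strand of the plasmid, and exactly one TER pool
#' member immediately downstream (joined by TGAG). Zero or multiple
#' matches (e.g. pool members related by containment) fail with the slot
#' named.
#'
#' @param plasmid Circular `nuc_seq` (a simulated recovered product).
#' @param design The `combinatorial_design` that generated it.
#' @param parts Named list mapping part names to core sequences (strings
#'   or `nuc_seq`), covering the pools and the slot CDSs.
#' @return data.frame with one row per variable slot: `slot`, `cds`,
#'   `pro`, `ter`.
#' @export
identify_assembled_variant <- function(plasmid, design, parts) {
  stopifnot(inherits(design, "combinatorial_design"))
  s <- seq_string(plasmid)
  if (inherits(plasmid, "nuc_seq") && plasmid$topology == "circular") {
    s <- paste0(s, substr(s, 1L, 200L))  # expose origin-spanning junctions
  }
  both <- c(s, revcomp(s))
  core_of <- function(name) seq_string(parts[[name]])
  present <- function(x) any(vapply(both, function(b)
    grepl(x, b, fixed = TRUE), TRUE))
  g <- junction_grammar()
  slots <- design$slots
  variable <- which(!is_marker_slot(slots))
  out <- NULL
  for (i in variable) {
    cds <- core_of(slots$cds[i])
    pro_hits <- design$pro_pool[vapply(design$pro_pool, function(p)
      present(paste0(core_of(p), g[["PRO_CDS"]], cds)), TRUE)]
    ter_hits <- design$ter_pool[vapply(design$ter_pool, function(t)
      present(paste0(cds, g[["CDS_TER"]], core_of(t))), TRUE)]
    if (length(pro_hits) != 1L) {
      vs_stop("slot '", slots$name[i], "': ", length(pro_hits),
              " PRO pool member(s) adjacent to CDS (need exactly 1)",
              class = "vegassim_identify_error")
    }
    if (length(ter_hits) != 1L) {
      vs_stop("slot '", slots$name[i], "': ", length(ter_hits),
              " TER pool member(s) adjacent to CDS (need exactly 1)",
              class = "vegassim_identify_error")
    }
    out <- rbind(out, data.frame(slot = slots$name[i], cds = slots$cds[i],
                                 pro = pro_hits, ter = ter_hits,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
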