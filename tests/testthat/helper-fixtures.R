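## shared fixtures: one small kit per (seed, genome size), built once
.kit_cache <- new.env(parent = emptyenv())

test_kit <- function(seed = 42L, genome_len = 5000L) {
  key <- paste(seed, genome_len)
  if (is.null(.kit_cache[[key]])) {
    .kit_cache[[key]] <- make_fixture_kit(seed, genome_len = genome_len)
  }
  .kit_cache[[key]]
}

## naive quadratic both-strand site scan: the oracle for scan_sites
naive_scan <- function(s, recognition) {
  k <- nchar(recognition)
  rc <- revcomp(recognition)
  out <- NULL
  for (i in seq_len(max(0L, nchar(s) - k + 1L))) {
    w <- substr(s, i, i + k - 1L)
    if (w == recognition) {
      out <- rbind(out, data.frame(position = i - 1L, strand = "+",
                                   stringsAsFactors = FALSE))
    }
    if (rc != recognition && w == rc) {
      out <- rbind(out, data.frame(position = i - 1L, strand = "-",
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(position = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$position, out$strand), , drop = FALSE]
}

## seeded random DNA for test cases
rand_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

## independent forward-only terminal overlap: longest exact substring
## shared between the 3' window of a and the 5' window of b, by binary
## search over the (monotone) shared length using substring enumeration
fwd_overlap_len <- function(a, b, window = 150L) {
  ta <- substr(a, max(1L, nchar(a) - window + 1L), nchar(a))
  hb <- substr(b, 1L, min(window, nchar(b)))
  na <- nchar(ta); nb <- nchar(hb)
  shared <- function(L) {
    if (L == 0L) return(TRUE)
    if (L > na || L > nb) return(FALSE)
    any(substring(ta, 1:(na - L + 1L), L:na) %in%
          substring(hb, 1:(nb - L + 1L), L:nb))
  }
  lo <- 0L; hi <- min(na, nb)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (shared(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

## all permutations of a vector (small n only)
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}
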