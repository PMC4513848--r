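## ---- k-mer index arithmetic (A=0, C=1, G=2, T=3; lexicographic order,
## matching Biostrings::oligonucleotideFrequency column order) ----

kmer_rc_index <- function(idx, k) {
  ## reverse-complement index, vectorised; idx is 0-based (double-safe up
  ## to 4^k for k <= 10)
  rc <- numeric(length(idx))
  rest <- idx
  for (j in seq_len(k)) {
    digit <- rest %% 4
    rest <- rest %/% 4
    ## digit j counted from the least-significant (3') end becomes the
    ## j-th most-significant digit of the complemented reverse
    rc <- rc * 4 + (3 - digit)
  }
  rc
}

kmer_decode <- function(idx, k) {
  letters4 <- c("A", "C", "G", "T")
  vapply(idx, function(v) {
    out <- character(k)
    for (j in k:1) {
      out[j] <- letters4[v %% 4 + 1]
      v <- v %/% 4
    }
    paste(out, collapse = "")
  }, "")
}

#' Canonical k-mer census of a background genome
#'
#' Counts every length-k window over all contigs, keyed by canonical
#' k-mer (the lexicographic minimum of a k-mer and its reverse
#' complement), so both strands are covered without double counting: the
#' counts sum to the number of windows, sum over contigs of
#' (length - k + 1).
#'
#' @param genome A `nuc_seq`, list of `nuc_seq`, character vector, or
#'   `DNAStringSet` of contigs.
#' @param k Word size (default 10).
#' @return Object of class `kmer_census`: list with `k`, `idx` (0-based
#'   canonical k-mer indices), `counts` (parallel integer vector), and
#'   `n_windows`.
#' @export
kmer_census <- function(genome, k = 10L) {
  k <- as.integer(k)
  if (k < 4L) vs_stop("k must be >= 4", class = "vegassim_kmer_error")
  seqs <- genome_strings(genome)
  if (!length(seqs) || all(!nzchar(seqs))) {
    vs_stop("genome is empty", class = "vegassim_kmer_error")
  }
  if (min(nchar(seqs)) < k) {
    vs_stop("k (", k, ") exceeds the shortest contig (", min(nchar(seqs)),
            " bp)", class = "vegassim_kmer_error")
  }
  dss <- Biostrings::DNAStringSet(seqs)
  freq <- Biostrings::oligonucleotideFrequency(dss, width = k,
                                               simplify.as = "collapsed")
  freq <- unname(freq)
  total <- 4^k
  idx_all <- seq_len(total) - 1
  rc_all <- kmer_rc_index(idx_all, k)
  canon <- idx_all <= rc_all
  counts <- freq[canon] + ifelse(rc_all[canon] == idx_all[canon], 0L,
                                 freq[rc_all[canon] + 1])
  structure(list(k = k, idx = idx_all[canon], counts = as.integer(counts),
                 n_windows = sum(nchar(seqs) - k + 1L)),
            class = "kmer_census")
}

#' @export
print.kmer_census <- function(x, ...) {
  cat(sprintf("<kmer_census> k=%d: %d canonical k-mers, %d windows, %d with count 0\n",
              x$k, length(x$idx), x$n_windows, sum(x$counts == 0L)))
  invisible(x)
}

genome_strings <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(as.character(genome))
  if (inherits(genome, "nuc_seq")) return(genome$bases)
  if (is.character(genome)) return(toupper(genome))
  if (is.list(genome)) return(vapply(genome, seq_string, ""))
  vs_stop("unsupported genome representation", class = "vegassim_type_error")
}

#' Extract the rare k-mer pool from a census
#'
#' Rare k-mers (default: absent from the genome on both strands) are the
#' building blocks for orthogonal adapter candidates. If the pool at the
#' requested threshold is smaller than `required`, the threshold is
#' raised to the smallest count yielding a large enough pool, with a
#' warning.
#'
#' @param census A [kmer_census()].
#' @param threshold Maximum occurrence count to call a k-mer rare
#'   (default 0).
#' @param required Minimum pool size, or `NULL` for no floor.
#' @return Object of class `kmer_set`: list with `k`, `idx` (0-based
#'   canonical indices) and the `threshold` actually used.
#' @export
rare_kmers <- function(census, threshold = 0L, required = NULL) {
  stopifnot(inherits(census, "kmer_census"))
  sel <- census$counts <= threshold
  if (!is.null(required) && sum(sel) < required) {
    thr <- sort(census$counts)[required]
    warning("rare-k-mer pool at threshold ", threshold, " has only ",
            sum(sel), " members; threshold raised to ", thr)
    threshold <- thr
    sel <- census$counts <= threshold
  }
  structure(list(k = census$k, idx = census$idx[sel],
                 threshold = as.integer(threshold)),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("<kmer_set> %d k-mers (k=%d, count <= %d)\n",
              length(x$idx), x$k, x$threshold))
  invisible(x)
}

#' @export
as.character.kmer_set <- function(x, ...) kmer_decode(x$idx, x$k)

seq_has_forbidden <- function(s, patterns) {
  for (p in patterns) {
    if (grepl(p, s, fixed = TRUE) || grepl(revcomp(p), s, fixed = TRUE)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Generate orthogonal adapter candidates by k-mer concatenation
#'
#' Each candidate concatenates `n_concat` rare k-mers sampled without
#' replacement (within a candidate; the pool is reused across
#' candidates), giving 60-mers at the defaults. Candidates containing a
#' forbidden restriction site on either strand -- including sites created
#' at k-mer junctions -- are rejected and resampled. Deterministic given
#' the seed.
#'
#' @param rare A `kmer_set` (or character vector of k-mers).
#' @param n_candidates Number of candidates to emit.
#' @param n_concat k-mers per candidate (default 6).
#' @param seed Integer seed.
#' @param forbidden Enzymes whose sites are excluded (default all four).
#' @param max_attempts Attempt budget per emitted candidate (default 50).
#' @return data.frame with columns `sequence` and `source_kmers`
#'   (comma-separated).
#' @export
generate_candidates <- function(rare, n_candidates, n_concat = 6L, seed = 1L,
                                forbidden = c("BsaI", "BsmBI", "NotI", "FseI"),
                                max_attempts = 50L) {
  if (inherits(rare, "kmer_set")) {
    pool_idx <- rare$idx
    k <- rare$k
    decode <- function(i) kmer_decode(pool_idx[i], k)
  } else {
    pool <- toupper(rare)
    pool_idx <- seq_along(pool)
    decode <- function(i) pool[i]
  }
  if (length(pool_idx) < n_concat) {
    vs_stop("rare pool (", length(pool_idx),
            ") smaller than n_concat (", n_concat, ")",
            class = "vegassim_design_error")
  }
  patterns <- vapply(lapply(forbidden, get_enzyme), `[[`, "", "recognition")
  with_seed(seed, {
    out_seq <- character(n_candidates)
    out_src <- character(n_candidates)
    for (i in seq_len(n_candidates)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        pick <- sample(length(pool_idx), n_concat, replace = FALSE)
        kmers <- decode(pick)
        cand <- paste(kmers, collapse = "")
        if (!seq_has_forbidden(cand, patterns)) {
          out_seq[i] <- cand
          out_src[i] <- paste(kmers, collapse = ",")
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        vs_stop("could not generate candidate ", i, " within ",
                max_attempts, " attempts (forbidden-site rejection)",
                class = "vegassim_design_error")
      }
    }
    data.frame(sequence = out_seq, source_kmers = out_src,
               stringsAsFactors = FALSE)
  })
}

#' Similarity of a candidate to a background genome
#'
#' Defined as the length of the longest substring shared between the
#' candidate and the genome on either strand; lower means more
#' orthogonal. Computed by a monotone binary search on the shared length
#' (a shared substring of length L implies one of every shorter length).
#'
#' @param candidate Candidate string.
#' @param genome Genome (as in [kmer_census()]).
#' @return Integer score in `[0, nchar(candidate)]`.
#' @export
similarity_score <- function(candidate, genome) {
  candidate <- toupper(seq_string(candidate))
  seqs <- genome_strings(genome)
  seqs <- seqs[nzchar(seqs)]
  if (!length(seqs)) return(0L)
  both <- c(seqs, vapply(seqs, revcomp, ""))
  n <- nchar(candidate)
  shared_at <- function(L) {
    if (L == 0L) return(TRUE)
    if (L > n) return(FALSE)
    wins <- unique(substring(candidate, 1:(n - L + 1L), L:n))
    for (w in wins) {
      if (any(grepl(w, both, fixed = TRUE))) return(TRUE)
    }
    FALSE
  }
  lo <- 0L; hi <- n
  while (lo < hi) {
    mid <- as.integer((lo + hi + 1L) %/% 2L)
    if (shared_at(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

## number of length-k windows of a candidate present in the genome
## (either strand); used as the similarity tiebreak
shared_kmer_count <- function(candidate, genome, k = 10L) {
  seqs <- genome_strings(genome)
  both <- c(seqs, vapply(seqs, revcomp, ""))
  n <- nchar(candidate)
  if (n < k) return(0L)
  wins <- substring(candidate, 1:(n - k + 1L), k:n)
  sum(vapply(wins, function(w) any(grepl(w, both, fixed = TRUE)), TRUE))
}

#' Design a set of orthogonal VEGAS adapters against a genome
#'
#' Full pipeline: census the genome's k-mers, pool the rare ones,
#' randomly concatenate them into forbidden-site-free 60-mer candidates,
#' rank candidates by genome similarity (ties broken by shared-k-mer
#' count, then sequence), keep the `n` most orthogonal, and trim 3 bp
#' from one terminus to the final 57-mer length (re-screening the
#' trimmed sequences). Deterministic given the seed.
#'
#' @param genome Background genome (as in [kmer_census()]).
#' @param n Number of adapters (default 18).
#' @param k k-mer size (default 10).
#' @param n_concat k-mers per candidate (default 6; candidates are
#'   `n_concat * k` = 60-mers).
#' @param final_len Final adapter length after trimming (default 57).
#' @param n_candidates Candidate pool size before ranking (default
#'   `10 * n`).
#' @param seed Integer seed.
#' @param rare_threshold Initial rarity threshold (default 0,
#'   auto-raised if the pool is too small).
#' @param trim_end Which terminus loses the trimmed bases (`"3prime"`
#'   default, `"5prime"` optional).
#' @return An `adapter_table` (names `DVA1..DVAn`) with a `design_report`
#'   attribute (data.frame of pre-trim sequences, similarity scores,
#'   shared-k-mer counts and source k-mers) and a `seed` attribute.
#' @export
design_adapters <- function(genome, n = 18L, k = 10L, n_concat = 6L,
                            final_len = 57L, n_candidates = 10L * n,
                            seed = 1L, rare_threshold = 0L,
                            trim_end = c("3prime", "5prime")) {
  trim_end <- match.arg(trim_end)
  cand_len <- n_concat * k
  if (final_len > cand_len) {
    vs_stop("final_len (", final_len, ") exceeds candidate length (",
            cand_len, ")", class = "vegassim_design_error")
  }
  census <- kmer_census(genome, k = k)
  rare <- rare_kmers(census, threshold = rare_threshold,
                     required = max(10L * n_concat, n_concat))
  cands <- generate_candidates(rare, n_candidates = n_candidates,
                               n_concat = n_concat, seed = seed)
  cands <- cands[!duplicated(cands$sequence), , drop = FALSE]
  if (nrow(cands) < n) {
    vs_stop("only ", nrow(cands), " distinct candidates for n = ", n,
            class = "vegassim_design_error")
  }
  cands$similarity <- vapply(cands$sequence, similarity_score, 0L,
                             genome = genome)
  cands$shared_kmers <- vapply(cands$sequence, shared_kmer_count, 0L,
                               genome = genome, k = k)
  ord <- order(cands$similarity, cands$shared_kmers, cands$sequence)
  cands <- cands[ord, , drop = FALSE]
  cands$rank <- seq_len(nrow(cands))
  sel <- cands[seq_len(n), , drop = FALSE]
  trim <- cand_len - final_len
  trimmed <- if (trim_end == "3prime") substr(sel$sequence, 1L, final_len)
             else substr(sel$sequence, trim + 1L, cand_len)
  patterns <- vapply(vegas_enzymes(), `[[`, "", "recognition")
  bad <- vapply(trimmed, seq_has_forbidden, TRUE, patterns = patterns)
  if (any(bad)) {
    vs_stop("trimmed adapter(s) contain forbidden sites: ",
            paste(which(bad), collapse = ", "),
            class = "vegassim_design_error")
  }
  if (anyDuplicated(trimmed)) {
    vs_stop("trimmed adapters are not pairwise distinct",
            class = "vegassim_design_error")
  }
  tab <- data.frame(name = paste0("DVA", seq_len(n)), sequence = trimmed,
                    note = "", stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  sel$trimmed <- trimmed
  structure(tab, class = c("adapter_table", "data.frame"),
            design_report = sel, seed = seed,
            rare_threshold = rare$threshold)
}
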