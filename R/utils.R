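#' Evaluate code with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds R's generator, evaluates `code`, and
#' restores the previous state on exit, so seeded package operations never
#' disturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Random DNA string
#'
#' Uniform i.i.d. bases; uses the current RNG state (wrap in [with_seed()]
#' for reproducibility).
#'
#' @param n Length in bases.
#' @return A character scalar over ACGT.
#' @keywords internal
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## circular substring: 1-based start, length len, wrapping over the origin
circ_substr <- function(s, start, len) {
  L <- nchar(s)
  if (len == 0) return("")
  start <- ((start - 1) %% L) + 1
  if (start + len - 1 <= L) return(substr(s, start, start + len - 1))
  paste0(substr(s, start, L), substr(s, 1, len - (L - start + 1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## all 1-based start positions of a fixed pattern in subject, including
## overlapping occurrences (gregexpr alone skips overlaps)
find_all_fixed <- function(pattern, subject) {
  if (!nzchar(pattern) || !nzchar(subject)) return(integer())
  hits <- integer()
  off <- 0L
  n <- nchar(subject)
  while (off < n) {
    m <- regexpr(pattern, substr(subject, off + 1L, n), fixed = TRUE)
    if (m < 0L) break
    hits <- c(hits, off + m)
    off <- off + m  # advance one past the match start: overlap-safe
  }
  hits
}

vs_stop <- function(..., class) {
  stop(structure(class = c(class, "vegassim_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
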