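#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param topology Topology assigned to all records (FASTA carries none);
#'   a `topology=circular` tag in a header overrides it per record.
#' @return Named list of `nuc_seq` objects.
#' @export
read_fasta <- function(path, topology = "linear") {
  dss <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(dss), function(i) {
    hdr <- names(dss)[i]
    topo <- if (grepl("topology=circular", hdr)) "circular" else topology
    nuc_seq(as.character(dss[[i]]), topology = topo,
            name = sub("\\s.*$", "", hdr))
  })
  names(out) <- vapply(out, function(s) s$name, "")
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A `nuc_seq` or list of them (or named character vector).
#' @param path Output file.
#' @param tags Optional character vector of extra header tags (recycled).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, tags = NULL) {
  if (inherits(seqs, "nuc_seq")) seqs <- list(seqs)
  if (is.character(seqs)) {
    seqs <- lapply(seq_along(seqs), function(i)
      nuc_seq(seqs[i], name = names(seqs)[i] %||% paste0("seq", i)))
  }
  strs <- vapply(seqs, seq_string, "")
  hdrs <- vapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    h <- if (inherits(s, "nuc_seq") && nzchar(s$name)) s$name
         else names(seqs)[i] %||% paste0("seq", i)
    if (inherits(s, "nuc_seq") && s$topology == "circular") {
      h <- paste(h, "topology=circular")
    }
    if (!is.null(tags)) h <- paste(h, tags[(i - 1L) %% length(tags) + 1L])
    h
  }, "")
  dss <- Biostrings::DNAStringSet(strs)
  names(dss) <- hdrs
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Write a sequence as a GenBank flat file
#'
#' Minimal writer covering what the toolkit needs: LOCUS line with
#' topology, one `misc_feature` with a `/label` qualifier per feature
#' (minus-strand features as `complement(..)`), and the ORIGIN sequence
#' block. Coordinates are converted to GenBank's 1-based inclusive
#' convention.
#'
#' @param seq A `nuc_seq`.
#' @param path Output file.
#' @param comment Optional COMMENT line (e.g. provenance).
#' @return `path`, invisibly.
#' @export
write_genbank <- function(seq, path, comment = NULL) {
  stopifnot(inherits(seq, "nuc_seq"))
  L <- nchar(seq$bases)
  con <- file(path, "w")
  on.exit(close(con))
  nm <- if (nzchar(seq$name)) gsub("\\s", "_", seq$name) else "sequence"
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN %s",
                     substr(nm, 1, 16), L,
                     if (seq$topology == "circular") "circular" else "linear",
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s.", nm), con)
  if (!is.null(comment)) writeLines(sprintf("COMMENT     %s", comment), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  f <- seq$features
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      s <- f$start[i]; e <- f$end[i]
      loc <- if (e <= L && e >= s) sprintf("%d..%d", s + 1L, e)
             else sprintf("join(%d..%d,1..%d)", s + 1L, L, ((e - 1L) %% L) + 1L)
      if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     misc_feature    %s", loc), con)
      writeLines(sprintf("                     /label=\"%s\"", f$label[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  i <- 1L
  while (i <= L) {
    chunk <- substr(seq$bases, i, min(i + 59L, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", i, paste(tolower(tens), collapse = " ")), con)
    i <- i + 60L
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a GenBank flat file written by this package
#'
#' Parses LOCUS topology, `misc_feature` records with `/label`
#' qualifiers, and the ORIGIN block. Join-across-origin and
#' `complement()` locations are supported.
#'
#' @param path GenBank file.
#' @return A `nuc_seq`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- lines[grepl("^LOCUS", lines)][1]
  if (is.na(locus)) vs_stop("not a GenBank file: no LOCUS line",
                            class = "vegassim_io_error")
  topo <- if (grepl("circular", locus)) "circular" else "linear"
  nm <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]
  ori <- which(grepl("^ORIGIN", lines))[1]
  if (is.na(ori)) vs_stop("no ORIGIN block", class = "vegassim_io_error")
  seq_lines <- lines[(ori + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  bases <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feats <- NULL
  idx <- which(grepl("^\\s{5}misc_feature\\s", lines))
  for (i in idx) {
    loc <- trimws(sub("^\\s{5}misc_feature\\s+", "", lines[i]))
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
      strand <- "-"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    nums <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
    if (grepl("^join", loc)) {
      start <- nums[1] - 1L
      end <- nchar(bases) + nums[4]
    } else {
      start <- nums[1] - 1L
      end <- nums[2]
    }
    lab <- ""
    j <- i + 1L
    while (j <= length(lines) && grepl("^\\s{10,}/", lines[j])) {
      if (grepl("/label=", lines[j])) {
        lab <- sub('.*?/label="?([^"]*)"?\\s*$', "\\1", lines[j])
      }
      j <- j + 1L
    }
    feats <- rbind(feats, data.frame(label = lab, start = start, end = end,
                                     strand = strand,
                                     stringsAsFactors = FALSE))
  }
  nuc_seq(bases, topology = topo, name = nm, features = feats)
}

#' Read a pathway design table
#'
#' TSV with columns `name`, `lva`, `pro`, `cds`, `ter`, `rva`, and
#' optionally `orientation`; empty strings become `NA` (marker slots). A
#' leading `#mode=...` comment sets the assembly mode (default
#' `pcr_homology`).
#'
#' @param path TSV file.
#' @param mode Override the mode (else from the `#mode=` header).
#' @return A `pathway_design`.
#' @export
read_design_table <- function(path, mode = NULL) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  if (is.null(mode)) {
    m <- hdr[grepl("^#mode=", hdr)]
    mode <- if (length(m)) sub("^#mode=", "", m[1]) else "pcr_homology"
  }
  tab <- utils::read.delim(text = paste(lines[!grepl("^#", lines)],
                                        collapse = "\n"),
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  pathway_design(tab, mode = mode)
}

#' Write a pathway design table
#' @param design A `pathway_design`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#mode=", attr(design, "mode")), con)
  utils::write.table(as.data.frame(design), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a fixture kit to a directory
#'
#' Emits the kit as plain-text files: `genome.fa`, `parts.fa` (headers
#' tagged `type=...` and `synthetic`), `adapters.tsv`, the vectors as
#' GenBank, and one design TSV per packaged design.
#'
#' @param kit A `fixture_kit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_kit <- function(kit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(kit$genome, file.path(dir, "genome.fa"), tags = "synthetic")
  part_seqs <- lapply(names(kit$parts), function(n)
    nuc_seq(kit$parts[[n]]$core, name = n))
  write_fasta(part_seqs, file.path(dir, "parts.fa"),
              tags = paste0("type=", vapply(kit$parts, `[[`, "", "type"),
                            " synthetic"))
  write_adapter_table(kit$adapters, file.path(dir, "adapters.tsv"))
  write_genbank(kit$acceptor, file.path(dir, "acceptor_bsmbi.gb"),
                comment = "synthetic acceptor vector")
  write_genbank(kit$acceptor_noti, file.path(dir, "acceptor_noti.gb"),
                comment = "synthetic acceptor vector (NotI release)")
  write_genbank(kit$vegas_vector, file.path(dir, "vegas_vector.gb"),
                comment = "synthetic VEGAS assembly vector")
  for (n in names(kit$designs)) {
    write_design_table(kit$designs[[n]], file.path(dir, paste0(n, ".tsv")))
  }
  writeLines(jsonlite::toJSON(list(seed = kit$seed,
                                   pro_pool = kit$pro_pool,
                                   ter_pool = kit$ter_pool),
                              auto_unbox = TRUE),
             file.path(dir, "kit.json"))
  invisible(dir)
}
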