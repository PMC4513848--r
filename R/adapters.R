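## First packaged adapter, used as an integrity anchor for the shipped TSV.
.VA1 <- "CCCCTTAGGTTGCAAATGCTCCGTCGACGGGATCTGTCCTTCTCTGCCGGCGATCGT"

#' Load the packaged VEGAS adapter table
#'
#' The 18 VEGAS adapter (VA) sequences, each 57 bp, orthogonal to the
#' S. cerevisiae genome and free of BsaI/BsmBI/NotI/FseI sites. VA1 and
#' VA2 are additionally encoded terminally on the left and right arms of
#' the linearized VEGAS assembly vector. The table ships as a TSV resource
#' and is integrity-checked on load (entry count, lengths, alphabet,
#' anchor sequence).
#'
#' @param path Path to an adapter TSV (columns `name`, `sequence`,
#'   optional `note`); defaults to the packaged resource. Users may point
#'   this at their own expanded adapter tables.
#' @return Object of class `adapter_table`: a data.frame with columns
#'   `name`, `sequence`, `note`.
#' @examples
#' nrow(va_adapters())            # 18
#' nchar(va_adapters()$sequence)  # all 57
#' @export
va_adapters <- function(path = NULL) {
  builtin <- is.null(path)
  if (builtin) {
    path <- system.file("extdata", "va_adapters.tsv", package = "vegassim")
  }
  if (!nzchar(path) || !file.exists(path)) {
    vs_stop("adapter table resource not found", class = "vegassim_io_error")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "sequence") %in% names(tab))) {
    vs_stop("adapter table must have columns 'name' and 'sequence'",
            class = "vegassim_io_error")
  }
  if (is.null(tab$note)) tab$note <- ""
  tab$note[is.na(tab$note)] <- ""
  tab$sequence <- toupper(tab$sequence)
  if (any(grepl("[^ACGT]", tab$sequence)) || anyDuplicated(tab$sequence) ||
      anyDuplicated(tab$name)) {
    vs_stop("adapter table corrupted: bad alphabet or duplicate entries",
            class = "vegassim_resource_error")
  }
  if (builtin) {
    if (nrow(tab) != 18L || any(nchar(tab$sequence) != 57L) ||
        tab$sequence[tab$name == "VA1"] != .VA1) {
      vs_stop("packaged adapter table corrupted (checksum mismatch)",
              class = "vegassim_resource_error")
    }
  }
  structure(tab[, c("name", "sequence", "note")], class = c("adapter_table",
                                                            "data.frame"))
}

#' Look up adapter sequences by name
#'
#' @param names Character vector of adapter names (e.g. `"VA3"`).
#' @param table An `adapter_table` (default the packaged one).
#' @return Character vector of sequences, named by adapter name.
#' @export
adapter_seq <- function(names, table = va_adapters()) {
  idx <- match(names, table$name)
  if (anyNA(idx)) {
    vs_stop("adapter(s) not found in table: ",
            paste(names[is.na(idx)], collapse = ", "),
            class = "vegassim_lookup_error")
  }
  stats::setNames(table$sequence[idx], names)
}

#' Export an adapter table as TSV
#'
#' Writes the two-column (name, sequence) layout used for packaged and
#' designed adapter sets.
#'
#' @param table An `adapter_table` or data.frame with `name`/`sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_adapter_table <- function(table, path) {
  utils::write.table(table[, c("name", "sequence")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
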