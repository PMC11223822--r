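# FASTA reading/writing.  Reading is backed by Biostrings; alphabet
# validation and error reporting are layered on top so that a bad character
# is reported with its record id and position.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either `"dna"` or `"protein"`.  DNA records may contain
#'   `A,C,G,T,N`; protein records the 20 amino acids plus `X`.  Lowercase is
#'   accepted and uppercased on ingest.
#' @return A tibble with columns `id`, `desc`, `seq`, one row per record in
#'   file order.  An empty file yields a zero-row tibble.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    return(tibble(id = character(), desc = character(), seq = character()))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  allowed <- if (alphabet == "dna") "ACGTN" else paste0(paste(AA_ALPHABET, collapse = ""), "X")
  bad <- regexpr(sprintf("[^%s]", allowed), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("read_fasta: invalid %s character '%s' in record '%s' at position %d",
                 alphabet, substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  if (any(nchar(seqs) == 0)) {
    stop("read_fasta: empty sequence in record '", ids[which(nchar(seqs) == 0)[1]], "'")
  }
  if (anyDuplicated(ids)) {
    stop("read_fasta: duplicate record id '", ids[anyDuplicated(ids)], "'")
  }
  tibble(id = ids, desc = desc, seq = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param records A tibble/data.frame with columns `id`, `seq` (and optionally
#'   `desc`), or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(records, path, width = 60) {
  if (is.character(records)) {
    records <- tibble(id = names(records), desc = "", seq = unname(records))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    if (!is.null(records$desc) && nzchar(records$desc[i])) {
      hdr <- paste(hdr, records$desc[i])
    }
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
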