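# Multiple sequence alignment reading: Stockholm (possibly multi-record) and
# aligned FASTA, auto-detected.  Gap symbols '.' and '-' are normalized to '-'.

new_msa <- function(name, ids, rows, alphabet = "protein") {
  stopifnot(length(ids) == length(rows), length(rows) >= 1)
  if (length(unique(nchar(rows))) != 1) {
    stop("MSA '", name, "' has ragged rows")
  }
  structure(list(name = name, ids = ids, rows = toupper(rows),
                 alphabet = alphabet),
            class = "fh_msa")
}

#' @export
print.fh_msa <- function(x, ...) {
  cat(sprintf("<fh_msa '%s': %d rows x %d columns (%s)>\n",
              x$name, length(x$rows), nchar(x$rows[1]), x$alphabet))
  invisible(x)
}

#' Read one or more multiple sequence alignments
#'
#' Auto-detects Stockholm (leading `# STOCKHOLM` token; may contain several
#' alignments separated by `//`) or aligned FASTA (one alignment per file).
#'
#' @param path Path to the alignment file.
#' @param alphabet Alphabet tag stored on the result (`"protein"` or `"dna"`).
#' @return A list of `fh_msa` objects, each with fields `name`, `ids`, `rows`
#'   (aligned strings with `-` gaps), `alphabet`.
#' @export
read_msa <- function(path, alphabet = "protein") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  first <- lines[nzchar(trimws(lines))][1]
  if (is.na(first)) stop("read_msa: empty file")
  if (grepl("^# STOCKHOLM", first)) {
    msas <- parse_stockholm(lines, alphabet)
  } else if (grepl("^>", first)) {
    msas <- list(parse_aligned_fasta(lines, basename(path), alphabet))
  } else {
    stop("read_msa: unknown alignment dialect (expected '# STOCKHOLM' or FASTA '>')")
  }
  msas
}

parse_stockholm <- function(lines, alphabet) {
  msas <- list()
  ids <- character()
  seqs <- list()
  name <- NULL
  n_block <- 0
  flush <- function() {
    if (length(ids) == 0) return(NULL)
    rows <- vapply(seqs[ids], paste, character(1), collapse = "")
    rows <- chartr(".", "-", rows)
    nm <- if (is.null(name)) sprintf("msa%d", length(msas) + 1) else name
    new_msa(nm, ids, unname(rows), alphabet)
  }
  for (ln in lines) {
    if (grepl("^# STOCKHOLM", ln)) next
    if (grepl("^//", ln)) {
      m <- flush()
      if (!is.null(m)) msas[[length(msas) + 1]] <- m
      ids <- character(); seqs <- list(); name <- NULL; n_block <- 0
      next
    }
    if (grepl("^#=GF\\s+ID\\s+", ln)) {
      name <- sub("^#=GF\\s+ID\\s+", "", ln)
      next
    }
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) stop("read_msa: malformed Stockholm line: ", ln)
    id <- parts[1]
    if (!(id %in% ids)) {
      ids <- c(ids, id)
      seqs[[id]] <- character()
    }
    seqs[[id]] <- c(seqs[[id]], parts[2])
  }
  m <- flush()  # tolerate a missing trailing '//'
  if (!is.null(m)) msas[[length(msas) + 1]] <- m
  if (length(msas) == 0) stop("read_msa: no alignments found")
  msas
}

parse_aligned_fasta <- function(lines, name, alphabet) {
  ids <- character()
  rows <- character()
  cur <- NULL
  for (ln in lines) {
    if (grepl("^>", ln)) {
      ids <- c(ids, sub("\\s.*$", "", sub("^>", "", ln)))
      rows <- c(rows, "")
      cur <- length(rows)
    } else if (!is.null(cur)) {
      rows[cur] <- paste0(rows[cur], trimws(ln))
    }
  }
  rows <- chartr(".", "-", rows)
  new_msa(name, ids, rows, alphabet)
}
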