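# Tabular hit output (TSV) and alignment rendering.

#' Write hits to a tab-separated table
#'
#' One row per hit with 1-based inclusive DNA coordinates on the forward
#' strand; minus-strand hits have start > end.  Internally the package uses
#' 0-based half-open forward-strand coordinates; the conversion happens only
#' here.
#'
#' @param hits Hit tibble from [run_search()], sorted by E-value.
#' @param path Output path.
#' @export
write_tabular_hits <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste("query", "target", "strand", "start", "end",
                               "score", "evalue", "frameshifts", "stops",
                               sep = "\t")), con)
  if (nrow(hits) > 0) {
    hits <- hits[order(hits$evalue), ]
    start1 <- ifelse(hits$strand == "+", hits$dna_start + 1L, hits$dna_end)
    end1 <- ifelse(hits$strand == "+", hits$dna_end, hits$dna_start + 1L)
    writeLines(paste(hits$query, hits$target, hits$strand, start1, end1,
                     sprintf("%.2f", hits$score),
                     sprintf("%.3g", hits$evalue),
                     hits$frameshift_count, hits$stop_count, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a hit table written by [write_tabular_hits()]
#'
#' @param path Path to the TSV file.
#' @return A tibble with 0-based half-open forward-strand coordinates.
#' @export
read_tabular_hits <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0) {
    return(tibble(query = character(), target = character(),
                  strand = character(), dna_start = integer(),
                  dna_end = integer(), score = numeric(), evalue = numeric(),
                  frameshift_count = integer(), stop_count = integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  m <- do.call(rbind, f)
  start1 <- as.integer(m[, 4]); end1 <- as.integer(m[, 5])
  strand <- m[, 3]
  tibble(query = m[, 1], target = m[, 2], strand = strand,
         dna_start = ifelse(strand == "+", start1 - 1L, end1 - 1L),
         dna_end = ifelse(strand == "+", end1, start1),
         score = as.numeric(m[, 6]), evalue = as.numeric(m[, 7]),
         frameshift_count = as.integer(m[, 8]),
         stop_count = as.integer(m[, 9]))
}

#' Render a hit alignment as text
#'
#' Four rows per block of up to `width` alignment columns: (1) query
#' consensus residues; (2) match line (the residue on identity, `+` on a
#' positive-scoring mismatch, blank otherwise); (3) the amino acid assigned
#' to each target (quasi-)codon; (4) the target nucleotides grouped per
#' (quasi-)codon, quasi-codons flagged by lowercase.
#'
#' @param hit One hit row from [run_search()].
#' @param profile The query `fh_profile`.
#' @param target_seq The full target DNA string (needed for standard-path
#'   hits; frameshift-aware hits carry their window sequence).
#' @param code An `fh_genetic_code`.
#' @param width Alignment columns per block.
#' @return A single string (the rendered block).
#' @export
render_alignment <- function(hit, profile, target_seq = NULL,
                             code = genetic_code(1), width = 60) {
  aln <- hit$alignment[[1]]
  cons <- strsplit(consensus_sequence(profile)$seq, "")[[1]]
  bg <- profile$background
  lodds <- log(profile$match_emissions) -
    matrix(log(bg), profile$M, 20, byrow = TRUE)
  cols <- list()
  if (aln$type == "fa") {
    path <- aln$path[aln$path$kind %in% c("M", "I", "D"), ]
    qsets <- quasi_candidate_sets(code)
    for (r in seq_len(nrow(path))) {
      st <- path$state[r]
      chunk <- substr(aln$seq, path$from[r] + 1, path$to[r])
      l <- nchar(chunk)
      if (path$kind[r] == "D") {
        cols[[length(cols) + 1]] <- list(q = cons[st], m = " ", a = "-", t = "---")
        next
      }
      cls <- path$class[r]
      if (cls == "sense") {
        aa <- code$codon_to_aa[toupper(chunk)]
      } else if (cls == "stop") {
        aa <- "*"
      } else if (cls == "neutral") {
        aa <- "X"
      } else {
        v <- encode_dna(chunk)
        qidx <- sum(v * 4^((l - 1):0)) + 1L
        cand <- qsets[[as.character(l)]][[qidx]]
        em <- if (path$kind[r] == "M") profile$match_emissions else profile$insert_emissions
        aa <- if (length(cand)) AA_ALPHABET[cand[which.max(em[st, cand])]] else "X"
      }
      tgt <- if (cls %in% c("quasi1", "quasi2", "quasi4", "quasi5"))
        tolower(chunk) else toupper(chunk)
      if (path$kind[r] == "I") {
        cols[[length(cols) + 1]] <- list(q = ".", m = " ", a = tolower(aa), t = tgt)
      } else {
        ai <- match(aa, AA_ALPHABET)
        mch <- if (!is.na(ai) && aa == cons[st]) aa
        else if (!is.na(ai) && lodds[st, ai] > 0) "+"
        else " "
        cols[[length(cols) + 1]] <- list(q = cons[st], m = mch, a = aa, t = tgt)
      }
    }
  } else {
    if (is.null(target_seq)) stop("render_alignment: target_seq required for standard-path hits")
    path <- aln$path
    orf <- aln$orf
    pep <- strsplit(aln$seq, "")[[1]]
    for (r in seq_len(nrow(path))) {
      st <- path$state[r]
      if (path$kind[r] == "D") {
        cols[[length(cols) + 1]] <- list(q = cons[st], m = " ", a = "-", t = "---")
        next
      }
      aa_abs_from <- aln$env_aa[1] + path$from[r]
      span <- if (orf$strand == "+") {
        c(orf$dna_start + 3 * aa_abs_from, orf$dna_start + 3 * aa_abs_from + 3)
      } else {
        c(orf$dna_end - 3 * aa_abs_from - 3, orf$dna_end - 3 * aa_abs_from)
      }
      chunk <- substr(target_seq, span[1] + 1, span[2])
      if (orf$strand == "-") chunk <- revcomp(chunk)
      aa <- pep[path$from[r] + 1]
      if (path$kind[r] == "I") {
        cols[[length(cols) + 1]] <- list(q = ".", m = " ", a = tolower(aa), t = toupper(chunk))
      } else {
        ai <- match(aa, AA_ALPHABET)
        mch <- if (!is.na(ai) && aa == cons[st]) aa
        else if (!is.na(ai) && lodds[st, ai] > 0) "+"
        else " "
        cols[[length(cols) + 1]] <- list(q = cons[st], m = mch, a = aa, t = toupper(chunk))
      }
    }
  }
  # fixed-width columns (5 nt max chunk + separator)
  w <- 6
  fmt <- function(x) formatC(x, width = w, flag = "-")
  out <- character(0)
  nb <- ceiling(length(cols) / width)
  for (b in seq_len(nb)) {
    idx <- ((b - 1) * width + 1):min(b * width, length(cols))
    out <- c(out,
             paste0(vapply(cols[idx], function(cc) fmt(cc$q), character(1)), collapse = ""),
             paste0(vapply(cols[idx], function(cc) fmt(cc$m), character(1)), collapse = ""),
             paste0(vapply(cols[idx], function(cc) fmt(cc$a), character(1)), collapse = ""),
             paste0(vapply(cols[idx], function(cc) fmt(cc$t), character(1)), collapse = ""),
             "")
  }
  paste(out, collapse = "\n")
}
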