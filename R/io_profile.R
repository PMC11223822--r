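# Profile file formats: the native line-oriented "FRAMEHMM/1" text format
# (read/write) and the HMMER3 ASCII ".hmm" format (read-only).

fmt_nums <- function(x) paste(sprintf("%.15g", x), collapse = " ")

#' Write profiles to a FRAMEHMM/1 file
#'
#' Probabilities are written with 15 significant digits so a round trip
#' reproduces them to at least 12 significant digits; calibration parameters
#' are written verbatim.
#'
#' @param profiles A single `fh_profile` or a list of them.
#' @param path Output path.
#' @export
write_profile <- function(profiles, path) {
  if (inherits(profiles, "fh_profile")) profiles <- list(profiles)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in profiles) {
    writeLines("FRAMEHMM/1", con)
    writeLines(paste("NAME", p$name), con)
    writeLines(paste("LENG", p$M), con)
    writeLines(paste("BG", fmt_nums(p$background)), con)
    if (!is.null(p$max_len_aa)) writeLines(paste("MAXL", p$max_len_aa), con)
    if (!is.null(p$calibration)) {
      cal <- p$calibration
      for (key in names(cal)) {
        writeLines(paste("CAL", key, fmt_nums(cal[[key]])), con)
      }
    }
    for (i in seq_len(p$M)) {
      writeLines(paste("MATCH", i, fmt_nums(p$match_emissions[i, ])), con)
      writeLines(paste("INSERT", i, fmt_nums(p$insert_emissions[i, ])), con)
      writeLines(paste("TRANS", i, fmt_nums(p$transitions[i, ])), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Read profiles from a FRAMEHMM/1 file
#'
#' @param path Path to a file written by [write_profile()].
#' @return A list of `fh_profile` objects in file order.
#' @export
read_profile <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  profiles <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!identical(lines[i], "FRAMEHMM/1")) {
      stop("read_profile: expected version tag 'FRAMEHMM/1', got: ", lines[i])
    }
    i <- i + 1
    name <- NULL; M <- NULL; bg <- NULL; maxl <- NULL; cal <- NULL
    me <- NULL; ie <- NULL; tr <- NULL
    done <- FALSE
    while (i <= length(lines)) {
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      key <- parts[1]
      i <- i + 1
      if (key == "//") { done <- TRUE; break }
      if (key == "NAME") name <- paste(parts[-1], collapse = " ")
      else if (key == "LENG") {
        M <- as.integer(parts[2])
        me <- matrix(NA_real_, M, 20); ie <- matrix(NA_real_, M, 20)
        tr <- matrix(NA_real_, M, 7)
      }
      else if (key == "BG") bg <- as.numeric(parts[-1])
      else if (key == "MAXL") maxl <- as.integer(parts[2])
      else if (key == "CAL") {
        if (is.null(cal)) cal <- list()
        v <- if (parts[3] == "NA") NA_real_ else as.numeric(parts[3])
        if (parts[2] %in% c("seed", "n")) v <- as.integer(v)
        cal[[parts[2]]] <- v
      }
      else if (key %in% c("MATCH", "INSERT", "TRANS")) {
        k <- as.integer(parts[2])
        v <- as.numeric(parts[-(1:2)])
        if (key == "MATCH") me[k, ] <- v
        else if (key == "INSERT") ie[k, ] <- v
        else tr[k, ] <- v
      }
      else stop("read_profile: unknown record '", key, "'")
    }
    if (!done) stop("read_profile: truncated file (missing '//')")
    if (is.null(M) || anyNA(me) || anyNA(ie) || anyNA(tr)) {
      stop("read_profile: incomplete model '", name, "'")
    }
    profiles[[length(profiles) + 1]] <-
      new_profile(name, me, ie, tr, background = bg, calibration = cal,
                  max_len_aa = maxl)
  }
  profiles
}

#' Read profiles from a HMMER3 ASCII file
#'
#' Parses the `HMMER3/f` text format.  Stored values are negated natural
#' logs of probabilities (`*` meaning probability 0) and are converted back
#' to probabilities.  Stored Gumbel/exponential calibration lines
#' (`STATS LOCAL MSV/VITERBI/FORWARD`) are retained; the frameshift-aware
#' Forward tail has no counterpart in HMMER files and is left unset.
#'
#' @param path Path to a `.hmm` file.
#' @return A list of `fh_profile` objects.
#' @export
read_hmmer3_ascii <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  profiles <- list()
  i <- 1
  n <- length(lines)
  from_log <- function(tok) {
    v <- suppressWarnings(as.numeric(tok))
    out <- exp(-v)
    out[tok == "*"] <- 0
    out
  }
  while (i <= n) {
    while (i <= n && !grepl("^HMMER3", lines[i])) i <- i + 1
    if (i > n) break
    if (!grepl("^HMMER3/f", lines[i])) {
      stop("read_hmmer3_ascii: unsupported format line: ", lines[i])
    }
    i <- i + 1
    name <- NULL; M <- NULL
    stats <- list()
    while (i <= n && !grepl("^HMM\\s", lines[i])) {
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (parts[1] == "NAME") name <- parts[2]
      if (parts[1] == "LENG") M <- as.integer(parts[2])
      if (parts[1] == "STATS" && parts[2] == "LOCAL") {
        stats[[parts[3]]] <- as.numeric(parts[4:5])
      }
      i <- i + 1
    }
    if (is.null(M)) stop("read_hmmer3_ascii: missing LENG")
    i <- i + 2  # skip the two HMM header lines
    me <- matrix(0, M, 20); ie <- matrix(0, M, 20); tr <- matrix(0, M, 7)
    # HMMER3 match emission columns are in alphabetical aa order, same as ours
    node <- 0
    while (i <= n && !grepl("^//", lines[i])) {
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (parts[1] == "COMPO") {
        i <- i + 3  # COMPO line, node-0 insert line, node-0 transition line
        next
      }
      k <- suppressWarnings(as.integer(parts[1]))
      if (is.na(k)) { i <- i + 1; next }
      node <- k
      if (k > M) stop("read_hmmer3_ascii: node index ", k, " exceeds LENG ", M)
      me[k, ] <- from_log(parts[2:21])
      ins <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
      ie[k, ] <- from_log(ins[1:20])
      trn <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
      tr[k, ] <- from_log(trn[1:7])
      i <- i + 3
    }
    if (i > n) stop("read_hmmer3_ascii: truncated file (missing '//')")
    if (node != M) {
      stop("read_hmmer3_ascii: LENG ", M, " but ", node, " nodes parsed")
    }
    i <- i + 1
    cal <- NULL
    if (length(stats)) {
      cal <- list(msv_mu = stats$MSV[1], msv_lambda = stats$MSV[2],
                  vit_mu = stats$VITERBI[1], vit_lambda = stats$VITERBI[2],
                  fwd_tau = stats$FORWARD[1], fwd_lambda = stats$FORWARD[2],
                  ffwd_tau = NA_real_, ffwd_lambda = NA_real_,
                  seed = NA_integer_, n = NA_integer_)
    }
    profiles[[length(profiles) + 1]] <-
      new_profile(name, me, ie, tr, calibration = cal)
  }
  if (length(profiles) == 0) stop("read_hmmer3_ascii: no models found")
  profiles
}
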