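#' Construct a position weight matrix
#'
#' Builds a [PWMotif] from a 4 x L matrix of per-position counts or
#' probabilities over A/C/G/T.  Every column is regularised with the
#' pseudocount and renormalised: `p_ij = (x_ij + pc) / (sum_i x_ij + 4 pc)`,
#' which handles count and probability input alike and guarantees strictly
#' positive entries.
#'
#' @param tfName transcription factor name.
#' @param matrix 4 x L numeric matrix; rows A, C, G, T (rownames optional in
#'   that order).
#' @param pseudocount small positive regulariser (default 0.001).
#' @return a [PWMotif].
#' @export
#' @examples
#' pwMotif("TF1", matrix(c(4, 0, 0, 0, 0, 4, 0, 0), nrow = 4))
pwMotif <- function(tfName, matrix, pseudocount = 0.001) {
  checkScalar(pseudocount, "pseudocount", min = 1e-12)
  m <- as.matrix(matrix)
  if (nrow(m) != 4L) stop("PWM matrix must have 4 rows (A, C, G, T)")
  if (ncol(m) < 1L) stop("PWM must have length >= 1")
  if (any(!is.finite(m)) || any(m < 0))
    stop("PWM entries must be finite and non-negative")
  if (any(colSums(m) == 0)) stop("PWM has a column of all zeros")
  m <- sweep(m + pseudocount, 2L, colSums(m) + 4 * pseudocount, "/")
  rownames(m) <- c("A", "C", "G", "T")
  new("PWMotif", tfName = as.character(tfName), matrix = m,
      pseudocount = pseudocount)
}

#' Consensus sequence of a motif
#'
#' @param pwm a [PWMotif].
#' @return the consensus string (highest-probability base per position; ties
#'   resolved in A,C,G,T order).
#' @export
pwmConsensus <- function(pwm) {
  stopifnot(is(pwm, "PWMotif"))
  paste(rownames(pwm@matrix)[apply(pwm@matrix, 2L, which.max)],
        collapse = "")
}

#' Read a motif library
#'
#' Parses transcription-factor motifs from JASPAR-style count blocks or a
#' minimal MEME text format, returning one [PWMotif] per motif.  Counts (or
#' probabilities) are pseudocount-regularised via [pwMotif()].
#'
#' JASPAR format: a header line `>ID NAME` (the name keys the motif; the ID
#' is kept when no name is present) followed by four rows
#' `A [ 4 19 0 ... ]` (brackets optional) in A, C, G, T order.
#'
#' Minimal MEME format: `MOTIF name` headers, each followed by a
#' `letter-probability matrix:` line and `w` rows of 4 probabilities in
#' A, C, G, T column order.
#'
#' @param path motif file path.
#' @param format `"jaspar"` or `"meme"`.
#' @param pseudocount passed to [pwMotif()].
#' @return a named list of [PWMotif] objects keyed by TF name.
#' @export
readMotifLibrary <- function(path, format = c("jaspar", "meme"),
                             pseudocount = 0.001) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path)
  motifs <- if (format == "jaspar") parseJaspar(lines) else parseMeme(lines)
  if (!length(motifs)) stop("no motifs found in ", path)
  out <- lapply(names(motifs), function(nm)
    pwMotif(nm, motifs[[nm]], pseudocount = pseudocount))
  names(out) <- names(motifs)
  if (anyDuplicated(names(out)))
    stop("duplicate motif name: ", names(out)[duplicated(names(out))][1L])
  out
}

parseJaspar <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR header lines ('>') found")
  ends <- c(starts[-1L] - 1L, length(lines))
  motifs <- list()
  for (k in seq_along(starts)) {
    hdr <- strsplit(sub("^>\\s*", "", lines[starts[k]]), "\\s+")[[1L]]
    nm <- if (length(hdr) >= 2L) hdr[2L] else hdr[1L]
    body <- lines[(starts[k] + 1L):ends[k]]
    if (length(body) != 4L)
      stop("JASPAR block for ", nm, " must have 4 base rows")
    rows <- lapply(body, function(l) {
      l <- trimws(l)
      base <- toupper(substr(l, 1L, 1L))
      if (!base %in% c("A", "C", "G", "T"))
        stop("unknown base symbol '", base, "' in motif ", nm)
      nums <- gsub("[][]", " ", substr(l, 2L, nchar(l)))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums),
                                                   "\\s+")[[1L]]))
      if (!length(vals) || anyNA(vals))
        stop("unparseable count row for base ", base, " in motif ", nm)
      list(base = base, vals = vals)
    })
    bases <- vapply(rows, `[[`, character(1L), "base")
    if (!setequal(bases, c("A", "C", "G", "T")))
      stop("motif ", nm, " must have one row per base A,C,G,T")
    lens <- vapply(rows, function(r) length(r$vals), integer(1L))
    if (length(unique(lens)) != 1L)
      stop("ragged count rows in motif ", nm)
    m <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(m) <- bases
    motifs[[nm]] <- m[c("A", "C", "G", "T"), , drop = FALSE]
  }
  motifs
}

parseMeme <- function(lines) {
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MEME 'MOTIF' lines found")
  ends <- c(starts[-1L] - 1L, length(lines))
  motifs <- list()
  for (k in seq_along(starts)) {
    hdr <- strsplit(trimws(lines[starts[k]]), "\\s+")[[1L]]
    if (length(hdr) < 2L) stop("MEME MOTIF line without a name")
    nm <- hdr[2L]
    body <- lines[(starts[k] + 1L):ends[k]]
    lp <- grep("letter-probability matrix", body)
    if (!length(lp)) stop("motif ", nm, " lacks a letter-probability matrix")
    rows <- list()
    for (l in body[(lp[1L] + 1L):length(body)]) {
      l <- trimws(l)
      if (!nzchar(l)) break
      vals <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1L]]))
      if (anyNA(vals) || length(vals) != 4L) break
      rows[[length(rows) + 1L]] <- vals
    }
    if (!length(rows)) stop("motif ", nm, " has length 0")
    m <- t(do.call(rbind, rows))  # rows become positions -> transpose
    rownames(m) <- c("A", "C", "G", "T")
    motifs[[nm]] <- m
  }
  motifs
}

#' Write a motif library in JASPAR count format
#'
#' Probabilities are scaled to integer counts (out of 1000) for a compact,
#' deterministic text representation readable by [readMotifLibrary()].
#'
#' @param pwms named list of [PWMotif] objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMotifLibrary <- function(pwms, path) {
  nm <- sort(names(pwms), method = "radix")
  con <- file(path, "w")
  on.exit(close(con))
  for (n in nm) {
    m <- round(motifMatrix(pwms[[n]]) * 1000)
    writeLines(sprintf(">%s %s", n, n), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b,
                         paste(m[b, ], collapse = " ")), con)
  }
  invisible(path)
}
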