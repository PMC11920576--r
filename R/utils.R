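# Internal helpers shared across modules.

#' Derive a per-stage seed from a global seed
#'
#' One global integer seed fans out to per-stage seeds through a fixed
#' splitting rule (a hash of the stage name), so each pipeline stage is
#' individually reproducible.  The result is always a valid 32-bit integer
#' seed.
#'
#' @param seed global integer seed.
#' @param stage stage name (character scalar).
#' @return an integer seed.
#' @export
#' @examples
#' stageSeed(1, "simulate")
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage),
            length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

#' Write a table deterministically
#'
#' Emits a header-bearing TSV with a fixed column order and rows sorted by the
#' primary key (the first column, with ties broken by subsequent columns), so
#' repeated runs are byte-identical.
#'
#' @param records a `data.frame`.
#' @param path output file path.
#' @param sort sort rows by the columns in order (default `TRUE`).
#' @return the path, invisibly.
#' @export
writeTable <- function(records, path, sort = TRUE) {
  stopifnot(is.data.frame(records))
  if (sort && nrow(records) > 1L) {
    ord <- do.call(order, c(unname(as.list(records)), list(method = "radix")))
    records <- records[ord, , drop = FALSE]
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a tab-separated table with required columns
#'
#' @param path file path.
#' @param required character vector of required column names; aliases may be
#'   supplied as a named list via `aliases` (`canonical = c(alternatives)`).
#' @param aliases named list mapping canonical names to accepted alternatives.
#' @return a `data.frame` with canonical column names.
#' @keywords internal
readHeaderTable <- function(path, required, aliases = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  for (canon in names(aliases)) {
    if (!canon %in% colnames(df)) {
      hit <- intersect(aliases[[canon]], colnames(df))
      if (length(hit)) colnames(df)[match(hit[1L], colnames(df))] <- canon
    }
  }
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  df
}

# Cheap content identifier used to tie SECutoff objects to their table.
tableDigest <- function(scores) {
  if (!length(scores)) return("empty")
  sprintf("n%d-s%.10g-x%.10g", length(scores), sum(scores), max(scores))
}

# Validate a single non-negative number.
checkScalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(name, " must be a single number in [", min, ", ", max, "]")
  invisible(x)
}
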