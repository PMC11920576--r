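#' Exact log-odds score threshold for a PWM at a p-value
#'
#' Computes, by exact dynamic programming over the integer-discretised score
#' distribution, the smallest score whose background tail probability is at
#' most `pThreshold`.  The p-value of a score `s` is the probability that a
#' random background k-mer (bases i.i.d. from `background`) attains log-odds
#' score `>= s`.  Scores are log2 odds `log2(p_ij / background_i)` summed
#' over motif positions, discretised at 1/1000 log-odds units
#' (`round(1000 * log2(p/b))`) so the DP is exact on the discretised scale.
#'
#' @param pwm a [PWMotif].
#' @param pThreshold p-value threshold in (0, 1); default `1e-4`.
#' @param background named numeric of base frequencies for A, C, G, T summing
#'   to 1; default uniform.
#' @return an object of class `PWMThreshold`: a list with elements `tfName`,
#'   `intMatrix` (the 4 x L integer score matrix), `threshold` (smallest
#'   discretised score with tail probability `<= pThreshold`; windows scoring
#'   `>= threshold` are hits), `pThreshold`, `tailAtThreshold`, `background`,
#'   and the full support/tail tables used for exact hit p-values.
#' @export
#' @examples
#' thr <- pwmThresholdScore(pwMotif("T", matrix(c(97, 1, 1, 1), 4)),
#'                          pThreshold = 0.25)
#' thr$tailAtThreshold  # 0.25: only 'A' passes under a uniform background
pwmThresholdScore <- function(pwm, pThreshold = 1e-4,
                              background = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25)) {
  stopifnot(is(pwm, "PWMotif"))
  if (!is.numeric(pThreshold) || length(pThreshold) != 1L ||
      pThreshold <= 0 || pThreshold > 1)
    stop("pThreshold must lie in (0, 1]")
  background <- background[c("A", "C", "G", "T")]
  if (anyNA(background) || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must give positive A,C,G,T frequencies summing to 1")
  m <- motifMatrix(pwm)
  intMatrix <- round(1000 * log2(sweep(m, 1L, background, "/")))
  storage.mode(intMatrix) <- "integer"
  dp <- pwmScoreDistribution(intMatrix, background)
  # smallest discretised score with tail <= pThreshold;
  # tail is non-increasing in score, tail(maxScore + 1) = 0
  ok <- which(dp$tail <= pThreshold)
  threshold <- if (length(ok)) dp$support[min(ok)] else dp$support[length(dp$support)] + 1L
  tailAt <- if (length(ok)) dp$tail[min(ok)] else 0
  structure(list(tfName = tfName(pwm), intMatrix = intMatrix,
                 threshold = threshold, pThreshold = pThreshold,
                 tailAtThreshold = tailAt, background = background,
                 support = dp$support, tail = dp$tail, prob = dp$prob),
            class = "PWMThreshold")
}

# Exact distribution of the discretised log-odds score of a random
# background k-mer.  Returns the integer support and P(S = s), P(S >= s).
pwmScoreDistribution <- function(intMatrix, background) {
  lo <- 0L; hi <- 0L
  d <- 1  # probability vector over scores lo..hi
  for (j in seq_len(ncol(intMatrix))) {
    col <- intMatrix[, j]
    nlo <- lo + min(col); nhi <- hi + max(col)
    nd <- numeric(nhi - nlo + 1L)
    for (b in 1:4) {
      shift <- (lo + col[b]) - nlo  # offset of d within nd for base b
      idx <- seq_along(d) + shift
      nd[idx] <- nd[idx] + d * background[b]
    }
    d <- nd; lo <- nlo; hi <- nhi
  }
  support <- seq.int(lo, hi)
  tail <- rev(cumsum(rev(d)))
  list(support = support, prob = d, tail = tail)
}

#' @export
print.PWMThreshold <- function(x, ...) {
  cat("PWMThreshold for", x$tfName, "- score >=", x$threshold,
      "(1/1000 log2-odds units), tail p =",
      format(x$tailAtThreshold, digits = 4), "at p <=", x$pThreshold, "\n")
  invisible(x)
}

# Exact tail probability P(S >= s) for a discretised score.
pwmTailProbability <- function(thr, score) {
  out <- numeric(length(score))
  lo <- thr$support[1L]; hi <- thr$support[length(thr$support)]
  out[score <= lo] <- 1
  inside <- score > lo & score <= hi
  out[inside] <- thr$tail[score[inside] - lo + 1L]
  out  # score > hi -> 0
}

#' Scan sequences for motif hits on both strands
#'
#' FIMO-style scan: every window of every sequence is scored on both strands
#' with the discretised log-odds matrix, and windows scoring at least the
#' exact p-value threshold from [pwmThresholdScore()] are reported as hits.
#' `N` bases contribute zero log-odds (the background expectation).
#' Sequences shorter than the motif yield no hits.
#'
#' @param sequences a named `DNAStringSet` (or named character vector) of
#'   super-enhancer constituent sequences.  By default each name is the
#'   `seId` and the constituent index is 1; pass `seMap` to map sequence
#'   names to `(seId, constituent)`.
#' @param pwms named list of [PWMotif] objects.
#' @param pThreshold FIMO-style p-value threshold (default `1e-4`).
#' @param background base frequencies (default uniform).
#' @param seMap optional `data.frame` with columns `seqName`, `seId`,
#'   `constituent`.
#' @return a `data.frame` of motif hits with columns `tf`, `seId`,
#'   `constituent`, `offset` (0-based on the forward strand), `strand`,
#'   `score` (log2 odds) and `pvalue` (exact tail probability).
#' @export
scanMotifs <- function(sequences, pwms, pThreshold = 1e-4,
                       background = c(A = 0.25, C = 0.25,
                                      G = 0.25, T = 0.25),
                       seMap = NULL) {
  nms <- names(sequences)
  seqs <- as.character(sequences)
  names(seqs) <- nms
  emptyHits <- data.frame(tf = character(), seId = character(),
                          constituent = integer(), offset = integer(),
                          strand = character(), score = numeric(),
                          pvalue = numeric(), stringsAsFactors = FALSE)
  if (!length(seqs) || !length(pwms)) return(emptyHits)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  if (is.null(seMap))
    seMap <- data.frame(seqName = names(seqs), seId = names(seqs),
                        constituent = 1L, stringsAsFactors = FALSE)
  thresholds <- lapply(pwms, pwmThresholdScore, pThreshold = pThreshold,
                       background = background)
  hits <- vector("list", length(pwms) * length(seqs))
  k <- 0L
  lut <- baseLookup()
  codes <- lapply(seqs, function(s) lut[as.integer(charToRaw(s)) + 1L])
  for (ti in seq_along(thresholds)) {
    thr <- thresholds[[ti]]
    im <- rbind(thr$intMatrix, N = 0L)
    imRC <- im[c(4:1, 5L), rev(seq_len(ncol(im))), drop = FALSE]
    for (si in seq_along(codes)) {
      cd <- codes[[si]]
      for (strand in c("+", "-")) {
        mat <- if (strand == "+") im else imRC
        sc <- slideScores(cd, mat)
        if (is.null(sc)) next
        pass <- which(sc >= thr$threshold)
        if (!length(pass)) next
        row <- match(names(seqs)[si], seMap$seqName)
        k <- k + 1L
        hits[[k]] <- data.frame(
          tf = thr$tfName, seId = seMap$seId[row],
          constituent = seMap$constituent[row], offset = pass - 1L,
          strand = strand, score = sc[pass] / 1000,
          pvalue = pwmTailProbability(thr, sc[pass]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!k) return(emptyHits)
  out <- do.call(rbind, hits[seq_len(k)])
  out[order(out$tf, out$seId, out$constituent, out$offset, out$strand,
            method = "radix"), , drop = FALSE]
}

# ASCII -> row index of the extended score matrix (A,C,G,T,N).
baseLookup <- function() {
  lut <- rep(NA_integer_, 256L)
  lut[as.integer(charToRaw("AaCcGgTtNn")) + 1L] <-
    c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L)
  lut
}

# Window scores of a coded sequence against a 5-row integer matrix.
slideScores <- function(codes, mat) {
  L <- length(codes); w <- ncol(mat)
  if (L < w) return(NULL)
  if (anyNA(codes)) stop("sequence contains bases outside ACGTN")
  n <- L - w + 1L
  sc <- integer(n)
  for (j in seq_len(w)) sc <- sc + mat[codes[seq.int(j, j + n - 1L)], j]
  sc
}

#' Count motif hits per transcription factor and super-enhancer
#'
#' @param hits hit table from [scanMotifs()].
#' @return a `data.frame` with columns `tf`, `seId`, `n`.
#' @export
countMotifHits <- function(hits) {
  if (!nrow(hits))
    return(data.frame(tf = character(), seId = character(), n = integer(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(n = rep(1L, nrow(hits))),
                          by = list(tf = hits$tf, seId = hits$seId), FUN = sum)
  agg[order(agg$tf, agg$seId, method = "radix"), , drop = FALSE]
}
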