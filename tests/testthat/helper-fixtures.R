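# Shared fixtures and independent brute-force oracles.

# GRanges peak set from 0-based half-open coordinates.
makePeaks <- function(chrom, start, end, sampleSignal = 1,
                      inputSignal = 0, name = NULL) {
  n <- length(start)
  if (is.null(name)) name <- sprintf("p%03d", seq_len(n))
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start + 1L, end),
                         name = name,
                         sampleSignal = rep_len(sampleSignal, n),
                         inputSignal = rep_len(inputSignal, n))
}

makeGenes <- function(chrom, tss, geneId = NULL, strand = "+",
                      isTF = FALSE) {
  n <- length(tss)
  if (is.null(geneId)) geneId <- sprintf("g%03d", seq_len(n))
  data.frame(geneId = geneId, chrom = rep_len(chrom, n),
             strand = rep_len(strand, n), txStart = tss,
             txEnd = tss + 1000L, tss = tss,
             isTF = rep_len(isTF, n), stringsAsFactors = FALSE)
}

# Brute-force stitching oracle: transitive merge on 0-based half-open
# intervals honouring the gap rule and TSS exclusion.  Returns a list of
# region span matrices per exclusion class.
stitchOracle <- function(peaks, tssByChrom, stitch = 12500,
                         excl = 2500) {
  # peaks: data.frame chrom/start/end (0-based half-open)
  excluded <- vapply(seq_len(nrow(peaks)), function(i) {
    tss <- tssByChrom[[peaks$chrom[i]]]
    if (is.null(tss)) return(FALSE)
    any(peaks$start[i] <= tss + excl & peaks$end[i] - 1L >= tss - excl)
  }, logical(1L))
  merge1 <- function(df) {
    n <- nrow(df)
    if (!n) return(df[0, c("chrom", "start", "end")])
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        if (df$chrom[i] != df$chrom[j] || comp[i] == comp[j]) next
        gap <- max(df$start[j] - df$end[i], df$start[i] - df$end[j])
        if (gap <= stitch) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    out <- do.call(rbind, lapply(unique(comp), function(cc) {
      sub <- df[comp == cc, , drop = FALSE]
      data.frame(chrom = sub$chrom[1L], start = min(sub$start),
                 end = max(sub$end), stringsAsFactors = FALSE)
    }))
    out[order(out$chrom, out$start), , drop = FALSE]
  }
  list(merged = merge1(peaks[!excluded, , drop = FALSE]),
       excluded = peaks[excluded, c("chrom", "start", "end"),
                        drop = FALSE],
       excludedFlag = excluded)
}

# Exhaustive argmin oracle for the rank-curve cutoff.
cutoffOracle <- function(scores) {
  s <- sort(scores)
  n <- length(s)
  if (n < 3L || s[n] == s[1L]) return(list(nSuper = 0L))
  d <- vapply(seq_len(n), function(i)
    (s[i] - s[1L]) / (s[n] - s[1L]) - (i - 1) / (n - 1), numeric(1L))
  i <- max(which(d == min(d)))
  list(cutoffIndex = i, cutoffScore = s[i],
       nSuper = sum(scores > s[i]))
}

# Exhaustive nearest-TSS oracle.
nearestOracle <- function(chrom, mid, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(list(geneId = NA_character_,
                            distance = NA_integer_))
  d <- g$tss - mid
  best <- which(abs(d) == min(abs(d)))
  best <- best[order(g$tss[best], g$geneId[best])][1L]
  list(geneId = g$geneId[best], distance = d[best])
}

# Exhaustive fully-interconnected-circuit oracle: all maximal vertex sets
# (size >= 2) whose every ordered pair is an edge of the digraph.
circuitOracle <- function(nodes, adj) {
  n <- length(nodes)
  sets <- list()
  for (mask in seq_len(2^n - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(members) < 2L) next
    ok <- all(adj[members, members] | diag(length(members)) == 1)
    if (ok) sets[[length(sets) + 1L]] <- members
  }
  maximal <- Filter(function(s)
    !any(vapply(sets, function(t)
      length(t) > length(s) && all(s %in% t), logical(1L))), sets)
  out <- lapply(maximal, function(s) sort(nodes[s]))
  unique(out[order(vapply(out, paste, character(1L),
                          collapse = "\r"))])
}

# CircuitGraph from an explicit directed edge list (self-loops added).
graphFromEdges <- function(nodes, from, to) {
  e <- data.frame(from = c(from, nodes), to = c(to, nodes),
                  nHits = 3L, stringsAsFactors = FALSE)
  e <- e[!duplicated(e[, 1:2]), , drop = FALSE]
  methods::new("CircuitGraph", nodes = sort(nodes), edges = e,
               minInstances = 3)
}

# Exact hypergeometric upper tail via binomial coefficients.
hyperOracle <- function(N, K, n, k) {
  i <- seq.int(k, min(n, K))
  if (k > min(n, K)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Small simulation config used across tests.
smallConfig <- function(seed = 1, ...) {
  args <- list(seed = seed, nChroms = 2, chromLength = 3e6,
               nGenes = 40, tfFraction = 0.3, nTranscriptome = 400,
               nTypicalPeaks = 60,
               nPlantedSE = c(model = 12, ea = 12), plantedShared = 4,
               seGenesModel = 60, seGenesEa = 30,
               sharedSEGeneOverlap = 10, nUpModel = 120, nUpEa = 20,
               candidateOverlap = 18, sequenceScope = "se")
  override <- list(...)
  args[names(override)] <- override
  do.call(simulationConfig, args)
}

# Random probability PWM of the given width.
randomPWM <- function(width, name = "TF", concentration = 1) {
  m <- matrix(stats::rgamma(4 * width, concentration), nrow = 4)
  pwMotif(name, m)
}
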