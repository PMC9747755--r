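suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

# Independent oracles and fixture builders.  Everything here deliberately
# avoids the package's vectorized/classified code paths: energies are
# summed position by position through explicit if/else chains, scans are
# exhaustive enumerations, and rounding is checked by integer arithmetic.

# per-pair energy by explicit enumeration of the four pair types
oraclePairEnergy <- function(a, b, model = PairEnergyModel()) {
  e <- pairEnergies(model)
  s <- paste(sort(c(a, b)), collapse = "")
  if (s == "CG") e[["GC"]]
  else if (s == "AU") e[["AU"]]
  else if (s == "GU") e[["GU"]]
  else if (s == "AC") e[["AC"]]
  else 0
}

# hand summation of a duplex: window position i against piRNA position
# l - i + 1 (antiparallel), accumulated left to right
oracleDuplexEnergy <- function(window, pirna, model = PairEnergyModel()) {
  w <- strsplit(window, "", fixed = TRUE)[[1L]]
  p <- strsplit(pirna, "", fixed = TRUE)[[1L]]
  stopifnot(length(w) == length(p))
  l <- length(p)
  tot <- 0
  for (i in seq_len(l))
    tot <- tot + oraclePairEnergy(w[i], p[l - i + 1L], model)
  tot
}

oracleDeltaGmax <- function(pirna, model = PairEnergyModel()) {
  e <- pairEnergies(model)
  p <- strsplit(pirna, "", fixed = TRUE)[[1L]]
  tot <- 0
  for (b in p) tot <- tot + if (b == "G" || b == "C") e[["GC"]] else e[["AU"]]
  tot
}

# exhaustive enumeration of every (piRNA, position) placement passing the
# ratio threshold; no local-maximum thinning
oracleScan <- function(tseq, pirnas, minRatio = 90,
                       model = PairEnergyModel()) {
  L <- nchar(tseq)
  rows <- list()
  for (pid in names(pirnas)) {
    p <- pirnas[[pid]]
    l <- nchar(p)
    dgm <- oracleDeltaGmax(p, model)
    if (L < l) next
    for (s in seq_len(L - l + 1L)) {
      win <- substr(tseq, s, s + l - 1L)
      dg <- oracleDuplexEnergy(win, p, model)
      ratio <- 100 * dg / dgm
      if (ratio >= minRatio)
        rows[[length(rows) + 1L]] <- data.frame(
          pirna_id = pid, start = s, dG = dg, ratio = ratio,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(pirna_id = character(0), start = integer(0),
                      dG = numeric(0), ratio = numeric(0)))
  df <- do.call(rbind, rows)
  df[order(df$pirna_id, df$start), , drop = FALSE]
}

# quadratic pairwise local-maximum filter (same rule, independent code):
# keep a placement unless an overlapping placement of the same piRNA has
# greater dG, or equal dG at a smaller start
oracleLocalMax <- function(df, l) {
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (j in seq_len(nrow(df))) {
      if (i == j) next
      if (abs(df$start[j] - df$start[i]) >= l) next
      if (df$dG[j] > df$dG[i] ||
          (df$dG[j] == df$dG[i] && df$start[j] < df$start[i])) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  df[keep, , drop = FALSE]
}

# rounding oracle: one decimal, halves away from zero, by integer
# comparison of 2 * 10 * a against (2k + 1) * b
oracleRatioRound <- function(a, b) {
  q <- (10 * a) %/% b
  r <- (10 * a) %% b
  if (2 * r >= b) q <- q + 1
  q / 10
}

randomRnaStr <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rnaComplement <- function(x) chartr("ACGU", "UGCA", x)

revComp <- function(x) {
  paste(rev(strsplit(rnaComplement(x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# plant the perfect reverse complement of `pirna` into `tseq` at `start`
plantPerfect <- function(tseq, pirna, start) {
  paste0(substr(tseq, 1L, start - 1L), revComp(pirna),
         substr(tseq, start + nchar(pirna), nchar(tseq)))
}

# build a binding-site GRanges by hand for cluster/marker tests
makeSitesGR <- function(gene, start, width, pirna_id,
                        dG = 100, dGm = 120, region = "CDS") {
  n <- length(start)
  dG <- rep_len(dG, n); dGm <- rep_len(dGm, n)
  gr <- GenomicRanges::GRanges(
    seqnames = rep_len(gene, n),
    ranges = IRanges::IRanges(start = start,
                              width = rep_len(width, n)))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    pirna_id = pirna_id, region = rep_len(region, n),
    dG = dG, dGm = dGm, ratio = 100 * dG / dGm,
    n_GC = 0L, n_AU = 0L, n_GU = 0L, n_AC = 0L, n_mismatch = 0L,
    pairing = strrep("|", rep_len(width, n)))
  gr
}

siteKeys <- function(sites) {
  paste(S4Vectors::mcols(sites)$pirna_id,
        as.character(GenomicRanges::seqnames(sites)),
        BiocGenerics::start(sites))
}
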