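#' Scan transcripts for piRNA binding sites
#'
#' Slides each full-length piRNA over every start position of each
#' transcript (positions `1 .. L - l + 1`), scores every ungapped
#' antiparallel placement with the additive hybridization model, and
#' keeps placements whose dG/dGm ratio meets the threshold.  Only the
#' sense strand is scanned.  With `suppressOverlaps = TRUE` (default),
#' overlapping placements of the *same* piRNA are thinned to local maxima
#' by dG (ties keep the smaller start), so a strong site is reported at a
#' single start coordinate rather than as a run of shifted near-copies;
#' overlapping sites of *different* piRNAs are always all retained (their
#' competition is a separate step, [resolveCompetition()]).
#'
#' Transcripts shorter than a piRNA yield no sites for that piRNA.
#'
#' @param transcripts a [TranscriptSet-class].
#' @param pirnas named character vector or [Biostrings::RNAStringSet] of
#'   piRNA sequences (5'->3').
#' @param model a [PairEnergyModel].
#' @param minRatioPct selection threshold on `100 * dG/dGm`, percent;
#'   default 90 (95 and 97 are common stricter choices).
#' @param suppressOverlaps thin overlapping same-piRNA placements to
#'   local dG maxima (default `TRUE`).  Set `FALSE` to obtain the raw
#'   exhaustive enumeration.
#' @return a `GRanges` with seqnames = gene id, ranges = site span in
#'   1-based inclusive transcript coordinates, and metadata columns
#'   `pirna_id`, `region` (label of the start position), `dG`, `dGm`
#'   (kJ/mol magnitudes), `ratio` (percent), pair counts `n_GC`, `n_AU`,
#'   `n_GU`, `n_AC`, `n_mismatch`, and the `pairing` string.  Rows are
#'   sorted by gene id, start, descending dG, piRNA id.
#' @examples
#' ts <- makeTranscriptSet(c(G1 = strrep("AGCU", 30)),
#'   data.frame(gene_id = "G1", cds_start = 21, cds_end = 80))
#' scanTargets(ts, c(p1 = "AGCUAGCUAGCUAGCUAGCUAGCU"), minRatioPct = 90)
#' @export
scanTargets <- function(transcripts, pirnas, model = PairEnergyModel(),
                        minRatioPct = 90, suppressOverlaps = TRUE) {
  stopifnot(is(transcripts, "TranscriptSet"))
  pseqs <- .pirnaChars(pirnas)
  rows <- vector("list", length(transcripts))
  for (j in seq_along(rows)) {
    rows[[j]] <- .scanCore(transcripts[j], pseqs, model,
                           minRatioPct, suppressOverlaps)
  }
  df <- do.call(rbind, rows)
  .sitesGRanges(df, transcripts)
}

#' @describeIn scanTargets Scan a single transcript; `transcript` must be
#'   a length-1 `TranscriptSet` (or give `gene` to select one).
#' @param transcript a length-1 [TranscriptSet-class].
#' @param gene gene id selecting one transcript from a larger set.
#' @export
scanTranscript <- function(transcript, pirnas, model = PairEnergyModel(),
                           minRatioPct = 90, suppressOverlaps = TRUE,
                           gene = NULL) {
  if (!is.null(gene)) transcript <- transcript[gene]
  if (length(transcript) != 1L)
    stop("scanTranscript expects a single transcript; see scanTargets",
         call. = FALSE)
  scanTargets(transcript, pirnas, model, minRatioPct, suppressOverlaps)
}

# piRNA input -> validated named character vector
.pirnaChars <- function(pirnas) {
  seqs <- vapply(as.character(pirnas), .normalizeRna, character(1L),
                 USE.NAMES = FALSE)
  names(seqs) <- names(pirnas)
  if (length(seqs) && (is.null(names(seqs)) || anyDuplicated(names(seqs))))
    stop("piRNAs must carry unique ids", call. = FALSE)
  .checkAlphabet(seqs, "piRNA set")
  seqs
}

# scan one transcript (length-1 TranscriptSet) against all piRNAs;
# returns a data.frame of passing sites (possibly 0 rows)
.scanCore <- function(transcript, pseqs, model, minRatioPct,
                      suppressOverlaps) {
  geneId <- names(transcript)[1L]
  tchars <- .seqChars(as.character(transcriptSeqs(transcript))[[1L]])
  m <- .encodeBases(tchars)
  L <- length(m)
  E <- .energyMatrix(model)
  dgmAll <- deltaGmax(stats::setNames(pseqs, names(pseqs)), model)
  out <- list()
  for (p in seq_along(pseqs)) {
    q <- rev(.encodeBases(.seqChars(pseqs[[p]])))
    l <- length(q)
    n <- L - l + 1L
    if (n < 1L) next
    dg <- numeric(n)
    for (i in seq_len(l))
      dg <- dg + E[cbind(m[i:(i + n - 1L)], q[i])]
    ratio <- 100 * dg / dgmAll[[p]]
    keep <- which(ratio >= minRatioPct)
    if (!length(keep)) next
    if (suppressOverlaps && length(keep) > 1L)
      keep <- keep[.localMaxKeep(keep, dg[keep], l)]
    # rescore kept placements through scoreDuplex so that reported
    # energies, counts and pairing all come from the one reference path
    sc <- lapply(keep, function(s) {
      scoreDuplex(paste(tchars[s:(s + l - 1L)], collapse = ""),
                  pseqs[[p]], model)
    })
    out[[length(out) + 1L]] <- data.frame(
      gene_id = geneId,
      pirna_id = names(pseqs)[p],
      start = keep,
      end = keep + l - 1L,
      region = regionOfPosition(transcript, keep),
      dG = vapply(sc, dG, numeric(1L)),
      dGm = vapply(sc, dGm, numeric(1L)),
      ratio = vapply(sc, ratioPct, numeric(1L)),
      n_GC = vapply(sc, function(x) pairCounts(x)[["GC"]], integer(1L)),
      n_AU = vapply(sc, function(x) pairCounts(x)[["AU"]], integer(1L)),
      n_GU = vapply(sc, function(x) pairCounts(x)[["GU"]], integer(1L)),
      n_AC = vapply(sc, function(x) pairCounts(x)[["AC"]], integer(1L)),
      n_mismatch = vapply(sc, function(x) pairCounts(x)[["mismatch"]],
                          integer(1L)),
      pairing = vapply(sc, pairingString, character(1L)),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# local-maximum thinning of overlapping same-piRNA placements:
# a placement survives iff no overlapping placement has greater dG, or
# equal dG at a smaller start.  `starts` ascending; `l` = piRNA length.
.localMaxKeep <- function(starts, dg, l) {
  k <- length(starts)
  keep <- logical(k)
  lo <- 1L
  for (i in seq_len(k)) {
    while (starts[lo] < starts[i] - (l - 1L)) lo <- lo + 1L
    hi <- i
    while (hi < k && starts[hi + 1L] <= starts[i] + (l - 1L)) hi <- hi + 1L
    js <- setdiff(lo:hi, i)
    keep[i] <- !any(dg[js] > dg[i] |
                    (dg[js] == dg[i] & starts[js] < starts[i]))
  }
  keep
}

# site rows -> sorted GRanges with transcript seqlengths
.sitesGRanges <- function(df, transcripts) {
  seqlens <- stats::setNames(
    BiocGenerics::width(transcriptSeqs(transcripts)), names(transcripts))
  if (is.null(df) || nrow(df) == 0L) {
    gr <- GenomicRanges::GRanges(seqlengths = seqlens)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      pirna_id = character(0), region = character(0),
      dG = numeric(0), dGm = numeric(0), ratio = numeric(0),
      n_GC = integer(0), n_AU = integer(0), n_GU = integer(0),
      n_AC = integer(0), n_mismatch = integer(0), pairing = character(0))
    return(gr)
  }
  df <- df[order(df$gene_id, df$start, -df$dG, df$pirna_id), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$gene_id, levels = names(seqlens)),
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    seqlengths = seqlens)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    pirna_id = df$pirna_id, region = df$region,
    dG = df$dG, dGm = df$dGm, ratio = df$ratio,
    n_GC = df$n_GC, n_AU = df$n_AU, n_GU = df$n_GU, n_AC = df$n_AC,
    n_mismatch = df$n_mismatch, pairing = df$pairing)
  gr
}

#' Region labels for binding sites
#'
#' Returns the region (`5UTR`, `CDS`, `3UTR`) containing each site's
#' start position; a site straddling a region boundary takes its start's
#' region.
#'
#' @param sites binding-site `GRanges` (from [scanTargets()]).
#' @param transcripts the [TranscriptSet-class] the sites were called on.
#' @return character vector of region labels, parallel to `sites`.
#' @export
annotateRegion <- function(sites, transcripts) {
  genes <- as.character(GenomicRanges::seqnames(sites))
  out <- character(length(sites))
  for (g in unique(genes)) {
    i <- genes == g
    out[i] <- regionOfPosition(transcripts[g], BiocGenerics::start(sites)[i])
  }
  out
}

#' Resolve competition between overlapping binding sites
#'
#' Overlapping sites cannot be occupied simultaneously; the preferred
#' site of each maximal set of mutually overlapping sites (connected
#' component of the overlap graph, any piRNAs) is the one with the
#' greatest binding free energy |dG|, ties broken by higher dG/dGm ratio
#' and then lexicographically smaller piRNA id.  All sites are retained -
#' competitors are part of the result - with a logical `preferred`
#' metadata column added (or recomputed; the operation is idempotent).
#'
#' @param sites binding-site `GRanges` on one or more transcripts.
#' @return `sites` with a `preferred` metadata column.
#' @export
resolveCompetition <- function(sites) {
  n <- length(sites)
  preferred <- logical(n)
  genes <- as.character(GenomicRanges::seqnames(sites))
  st <- BiocGenerics::start(sites)
  en <- BiocGenerics::end(sites)
  mc <- S4Vectors::mcols(sites)
  for (g in unique(genes)) {
    idx <- which(genes == g)
    idx <- idx[order(st[idx], en[idx])]
    compEnd <- -Inf
    comp <- integer(0)
    flush <- function(comp) {
      if (!length(comp)) return()
      o <- order(-mc$dG[comp], -mc$ratio[comp], mc$pirna_id[comp])
      preferred[comp[o[1L]]] <<- TRUE
    }
    for (i in idx) {
      if (st[i] > compEnd) {         # no overlap with the open component
        flush(comp)
        comp <- i
        compEnd <- en[i]
      } else {
        comp <- c(comp, i)
        compEnd <- max(compEnd, en[i])
      }
    }
    flush(comp)
  }
  S4Vectors::mcols(sites)$preferred <- preferred
  sites
}
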