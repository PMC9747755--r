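#' TranscriptSet: mRNA transcripts with 5'UTR / CDS / 3'UTR structure
#'
#' A set of mRNA transcript sequences together with per-transcript CDS
#' boundaries in 1-based inclusive transcript coordinates.  The three
#' regions partition each transcript: the 5'UTR is `[1, cds_start - 1]`
#' (possibly empty), the CDS `[cds_start, cds_end]`, and the 3'UTR
#' `[cds_end + 1, length]` (possibly empty).  A transcript with `NA`
#' boundaries carries no annotated CDS and is treated as all 3'UTR
#' (see `allowMissing` in [makeTranscriptSet()]).
#'
#' @slot sequences [Biostrings::RNAStringSet] of transcript sequences,
#'   named by gene id.
#' @slot cdsStart,cdsEnd integer vectors of 1-based inclusive CDS
#'   boundaries, parallel to `sequences`; `NA` = no annotated CDS.
#'
#' @examples
#' ts <- makeTranscriptSet(
#'   c(G1 = "AAGGCCUUAAGGCCUUAAGG"),
#'   data.frame(gene_id = "G1", cds_start = 6, cds_end = 15))
#' regionWidths(ts)
#' @aliases TranscriptSet
#' @exportClass TranscriptSet
setClass("TranscriptSet",
  representation(sequences = "RNAStringSet",
                 cdsStart = "integer", cdsEnd = "integer"))

setValidity("TranscriptSet", function(object) {
  n <- length(object@sequences)
  nm <- names(object@sequences)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    return("every transcript must have a gene id")
  if (anyDuplicated(nm))
    return(paste0("duplicate gene ids: ",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (length(object@cdsStart) != n || length(object@cdsEnd) != n)
    return("cdsStart/cdsEnd must be parallel to sequences")
  if (any(is.na(object@cdsStart) != is.na(object@cdsEnd)))
    return("cdsStart and cdsEnd must be both given or both NA")
  i <- !is.na(object@cdsStart)
  w <- BiocGenerics::width(object@sequences)
  bad <- i & (object@cdsStart < 1L | object@cdsEnd < object@cdsStart |
              object@cdsEnd > w)
  if (any(bad))
    return(paste0("CDS boundaries violate 1 <= cds_start <= cds_end <= ",
                  "length for: ", paste(nm[bad], collapse = ", ")))
  TRUE
})

#' Build a TranscriptSet from sequences and a regions table
#'
#' @param sequences named character vector or [Biostrings::RNAStringSet]
#'   (DNA alphabet accepted; normalized to RNA and uppercased).
#' @param regions data.frame with columns `gene_id`, `cds_start`,
#'   `cds_end` (1-based inclusive), as returned by [readRegions()].
#' @param allowMissing if `TRUE`, transcripts absent from `regions` are
#'   kept with no annotated CDS and all their positions labelled 3'UTR;
#'   if `FALSE` (default) such transcripts are an error.
#' @return a [TranscriptSet-class] object.
#' @export
makeTranscriptSet <- function(sequences, regions = NULL,
                              allowMissing = FALSE) {
  seqs <- vapply(as.character(sequences), .normalizeRna, character(1L))
  names(seqs) <- names(sequences)
  .checkAlphabet(seqs, "transcript")
  n <- length(seqs)
  cs <- rep(NA_integer_, n)
  ce <- rep(NA_integer_, n)
  if (!is.null(regions)) {
    .checkRegionsFrame(regions)
    idx <- match(names(seqs), regions$gene_id)
    if (anyNA(idx) && !allowMissing)
      stop("no CDS annotation for transcript(s): ",
           paste(names(seqs)[is.na(idx)], collapse = ", "),
           " (set allowMissing = TRUE to treat them as all 3'UTR)",
           call. = FALSE)
    cs <- as.integer(regions$cds_start[idx])
    ce <- as.integer(regions$cds_end[idx])
  }
  new("TranscriptSet", sequences = Biostrings::RNAStringSet(seqs),
      cdsStart = cs, cdsEnd = ce)
}

#' @describeIn TranscriptSet-class the transcript sequences.
#' @param x,object a `TranscriptSet`.
#' @export
setGeneric("transcriptSeqs", function(x) standardGeneric("transcriptSeqs"))
#' @rdname TranscriptSet-class
#' @export
setMethod("transcriptSeqs", "TranscriptSet", function(x) x@sequences)

#' @describeIn TranscriptSet-class 1-based inclusive CDS start positions
#'   (`NA` = no annotated CDS).
#' @export
setGeneric("cdsStart", function(x) standardGeneric("cdsStart"))
#' @rdname TranscriptSet-class
#' @export
setMethod("cdsStart", "TranscriptSet", function(x) {
  stats::setNames(x@cdsStart, names(x@sequences))
})

#' @describeIn TranscriptSet-class 1-based inclusive CDS end positions.
#' @export
setGeneric("cdsEnd", function(x) standardGeneric("cdsEnd"))
#' @rdname TranscriptSet-class
#' @export
setMethod("cdsEnd", "TranscriptSet", function(x) {
  stats::setNames(x@cdsEnd, names(x@sequences))
})

#' @describeIn TranscriptSet-class widths of the three regions per
#'   transcript; the rows of the returned matrix sum to the transcript
#'   lengths.
#' @export
setGeneric("regionWidths", function(x) standardGeneric("regionWidths"))
#' @rdname TranscriptSet-class
#' @export
setMethod("regionWidths", "TranscriptSet", function(x) {
  w <- BiocGenerics::width(x@sequences)
  cs <- x@cdsStart
  ce <- x@cdsEnd
  utr5 <- ifelse(is.na(cs), 0L, cs - 1L)
  cds <- ifelse(is.na(cs), 0L, ce - cs + 1L)
  utr3 <- w - utr5 - cds
  m <- cbind(`5UTR` = utr5, CDS = cds, `3UTR` = utr3)
  rownames(m) <- names(x@sequences)
  m
})

#' @rdname TranscriptSet-class
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@sequences))

#' @rdname TranscriptSet-class
#' @export
setMethod("names", "TranscriptSet", function(x) names(x@sequences))

#' @rdname TranscriptSet-class
#' @param i index (numeric, logical, or gene ids).
#' @param j,drop,... ignored; present for generic compatibility.
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  new("TranscriptSet", sequences = x@sequences[i],
      cdsStart = x@cdsStart[i], cdsEnd = x@cdsEnd[i])
})

setMethod("show", "TranscriptSet", function(object) {
  n <- length(object)
  cat("TranscriptSet with ", n, " transcript",
      if (n == 1L) "" else "s", "\n", sep = "")
  w <- BiocGenerics::width(object@sequences)
  k <- min(n, 5L)
  for (i in seq_len(k)) {
    if (is.na(object@cdsStart[i])) {
      cat(sprintf("  %s: %d nt, no annotated CDS (all 3'UTR)\n",
                  names(object)[i], w[i]))
    } else {
      cat(sprintf("  %s: %d nt, CDS %d-%d\n", names(object)[i], w[i],
                  object@cdsStart[i], object@cdsEnd[i]))
    }
  }
  if (n > k) cat("  ...\n")
})

#' Region label of transcript positions
#'
#' Maps 1-based transcript positions to the region containing them
#' (`5UTR`, `CDS` or `3UTR`).  Binding sites are labelled by the region
#' of their start position; a site straddling a region boundary takes its
#' start's region.
#'
#' @param transcript a length-1 [TranscriptSet-class] (or larger set with
#'   `gene` given).
#' @param pos integer vector of 1-based positions.
#' @param gene gene id to select when `transcript` has several.
#' @return character vector of region labels.
#' @export
regionOfPosition <- function(transcript, pos, gene = NULL) {
  if (!is.null(gene)) transcript <- transcript[gene]
  if (length(transcript) != 1L)
    stop("give a single transcript (or a gene id)", call. = FALSE)
  L <- BiocGenerics::width(transcriptSeqs(transcript))[1L]
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > L))
    stop("position outside transcript [1, ", L, "]", call. = FALSE)
  cs <- transcript@cdsStart[1L]
  ce <- transcript@cdsEnd[1L]
  if (is.na(cs)) return(rep("3UTR", length(pos)))
  ifelse(pos < cs, "5UTR", ifelse(pos <= ce, "CDS", "3UTR"))
}
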