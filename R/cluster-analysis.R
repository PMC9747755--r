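#' Inclusive length of a cluster span
#'
#' Spans are 1-based inclusive, so a cluster from `spanStart` to
#' `spanEnd` covers `spanEnd - spanStart + 1` nucleotides.
#'
#' @param spanStart,spanEnd integer vectors, 1-based inclusive.
#' @return integer vector of lengths in nt.
#' @examples
#' clusterLength(4940, 5125)  # 186
#' clusterLength(108, 172)    # 65
#' @export
clusterLength <- function(spanStart, spanEnd) {
  spanStart <- as.integer(spanStart)
  spanEnd <- as.integer(spanEnd)
  if (any(spanEnd < spanStart))
    stop("inverted span: span_end < span_start", call. = FALSE)
  spanEnd - spanStart + 1L
}

#' Compaction ratio of a binding-site cluster
#'
#' Total length of the member piRNAs divided by the cluster length -
#' the factor by which overlapping sites compress the sequence needed to
#' host them.  Rounded to one decimal, halves away from zero.
#'
#' @param totalPirnaLength summed member piRNA lengths, nt.
#' @param clusterLength cluster span length, nt (> 0).
#' @return numeric vector, one decimal.
#' @examples
#' compactionRatio(1367, 65)  # 21.0
#' @export
compactionRatio <- function(totalPirnaLength, clusterLength) {
  if (any(clusterLength <= 0))
    stop("cluster length must be positive", call. = FALSE)
  roundHalfAway(totalPirnaLength / clusterLength, 1L)
}

#' Region-to-cluster length ratio
#'
#' Length of the transcript region (5'UTR, CDS or 3'UTR) hosting a
#' cluster divided by the cluster length: how much shorter the cluster is
#' than its region.  Rounded to one decimal, halves away from zero.
#'
#' @param regionLength region length, nt (> 0).
#' @param clusterLength cluster span length, nt (> 0).
#' @return numeric vector, one decimal.
#' @examples
#' regionToClusterRatio(1408, 224)  # 6.3
#' regionToClusterRatio(188, 65)    # 2.9
#' @export
regionToClusterRatio <- function(regionLength, clusterLength) {
  if (any(regionLength <= 0) || any(clusterLength <= 0))
    stop("region and cluster lengths must be positive", call. = FALSE)
  roundHalfAway(regionLength / clusterLength, 1L)
}

#' Merge overlapping binding sites into clusters
#'
#' Clusters are the connected components of the graph whose edges join
#' sites overlapping by at least `minOverlapNt` nucleotides.  Sites are
#' grouped by gene and by region label first, so a cluster never crosses
#' a 5'UTR/CDS/3'UTR boundary; singleton clusters are allowed.  The
#' result is independent of the input order of `sites`.
#'
#' @param sites binding-site `GRanges` (from [scanTargets()]).
#' @param transcripts optional [TranscriptSet-class]; when given, each
#'   cluster also carries its region's length and the region-to-cluster
#'   ratio.
#' @param minOverlapNt minimum overlap joining two sites (default 1: any
#'   overlap).
#' @return a `GRanges`, one row per cluster, ranges = inclusive span;
#'   metadata columns `region`, `n_sites`, `total_pirna_len` (summed
#'   member piRNA lengths, nt), `compaction_ratio`, `pirna_ids`
#'   (comma-joined member ids in start order) and, with `transcripts`,
#'   `region_len` and `region_ratio`.  Sorted by gene id and span start.
#' @export
buildClusters <- function(sites, transcripts = NULL, minOverlapNt = 1L) {
  minOverlapNt <- as.integer(minOverlapNt)
  stopifnot(minOverlapNt >= 1L)
  genes <- as.character(GenomicRanges::seqnames(sites))
  st <- BiocGenerics::start(sites)
  en <- BiocGenerics::end(sites)
  mc <- S4Vectors::mcols(sites)
  rows <- list()
  for (g in sort(unique(genes))) {
    for (rg in .REGIONS) {
      idx <- which(genes == g & mc$region == rg)
      if (!length(idx)) next
      idx <- idx[order(st[idx], en[idx], mc$pirna_id[idx])]
      compEnd <- -Inf
      comp <- integer(0)
      emit <- function(comp) {
        if (!length(comp)) return()
        spanStart <- min(st[comp])
        spanEnd <- max(en[comp])
        len <- clusterLength(spanStart, spanEnd)
        tot <- sum(en[comp] - st[comp] + 1L)
        rows[[length(rows) + 1L]] <<- data.frame(
          gene_id = g, region = rg,
          span_start = spanStart, span_end = spanEnd,
          length_nt = len, n_sites = length(comp),
          total_pirna_len = tot,
          compaction_ratio = compactionRatio(tot, len),
          pirna_ids = paste(mc$pirna_id[comp], collapse = ","),
          stringsAsFactors = FALSE)
      }
      for (i in idx) {
        # a site joins the open component iff it overlaps its span by
        # >= minOverlapNt nucleotides
        if (st[i] > compEnd - minOverlapNt + 1L) {
          emit(comp)
          comp <- i
          compEnd <- en[i]
        } else {
          comp <- c(comp, i)
          compEnd <- max(compEnd, en[i])
        }
      }
      emit(comp)
    }
  }
  if (!length(rows)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      region = character(0), n_sites = integer(0),
      total_pirna_len = integer(0), compaction_ratio = numeric(0),
      pirna_ids = character(0))
    return(gr)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$gene_id, df$span_start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = df$gene_id,
    ranges = IRanges::IRanges(start = df$span_start, end = df$span_end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    region = df$region, n_sites = df$n_sites,
    total_pirna_len = df$total_pirna_len,
    compaction_ratio = df$compaction_ratio,
    pirna_ids = df$pirna_ids)
  if (!is.null(transcripts)) {
    rw <- regionWidths(transcripts)
    rl <- rw[cbind(match(df$gene_id, rownames(rw)),
                   match(df$region, colnames(rw)))]
    S4Vectors::mcols(gr)$region_len <- as.integer(rl)
    S4Vectors::mcols(gr)$region_ratio <- ifelse(
      rl > 0, regionToClusterRatio(pmax(rl, 1L), df$length_nt), NA_real_)
  }
  gr
}

#' Find identical-start groups of binding sites
#'
#' Groups of at least `minGroup` distinct piRNAs whose sites begin at the
#' identical transcript position - a recurrent arrangement inside
#' clusters where many piRNAs compete for one register.
#'
#' @param sites binding-site `GRanges`.
#' @param minGroup minimum number of distinct piRNAs sharing a start
#'   (default 5).
#' @return data.frame with columns `gene_id`, `start`, `n_pirnas`,
#'   `pirna_ids` (comma-joined, sorted), ordered by gene and position.
#' @export
findStartGroups <- function(sites, minGroup = 5L) {
  genes <- as.character(GenomicRanges::seqnames(sites))
  st <- BiocGenerics::start(sites)
  ids <- S4Vectors::mcols(sites)$pirna_id
  key <- paste(genes, st, sep = "\r")
  rows <- lapply(split(seq_along(key), key), function(i) {
    members <- sort(unique(ids[i]))
    if (length(members) < minGroup) return(NULL)
    data.frame(gene_id = genes[i[1L]], start = st[i[1L]],
               n_pirnas = length(members),
               pirna_ids = paste(members, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(data.frame(gene_id = character(0), start = integer(0),
                      n_pirnas = integer(0), pirna_ids = character(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df[order(df$gene_id, df$start), , drop = FALSE]
}
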