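#' Select piRNA-gene marker associations
#'
#' Proposes (piRNA, gene) pairs as candidate disease markers when the
#' pair's best binding site satisfies either threshold: binding free
#' energy |dG| at least `minAbsDg` kJ/mol, or dG/dGm ratio at least
#' `minRatioPct` percent.  The best site of a pair is the one with
#' maximal |dG| (ties: higher ratio, then smaller start).  Raising either
#' cutoff can only shrink the selected set.
#'
#' @param sites binding-site `GRanges` across one or more genes.
#' @param minAbsDg free-energy cutoff, kJ/mol magnitude (default 170).
#' @param minRatioPct ratio cutoff, percent (default 97).
#' @return data.frame with columns `pirna_id`, `gene_id`, `start`, `end`,
#'   `region`, `dG_kJ_mol`, `dGm_kJ_mol`, `ratio_pct`, `criterion`
#'   (`"dg_threshold"`, `"ratio_threshold"` or `"both"`), ordered by
#'   gene id, descending dG, piRNA id.
#' @export
selectMarkers <- function(sites, minAbsDg = 170, minRatioPct = 97) {
  if (length(sites) == 0L)
    return(.emptyMarkers())
  genes <- as.character(GenomicRanges::seqnames(sites))
  mc <- S4Vectors::mcols(sites)
  st <- BiocGenerics::start(sites)
  en <- BiocGenerics::end(sites)
  key <- paste(genes, mc$pirna_id, sep = "\r")
  best <- vapply(split(seq_along(key), key), function(i) {
    i[order(-mc$dG[i], -mc$ratio[i], st[i])][1L]
  }, integer(1L))
  passDg <- mc$dG[best] >= minAbsDg
  passRatio <- mc$ratio[best] >= minRatioPct
  keep <- best[passDg | passRatio]
  if (!length(keep))
    return(.emptyMarkers())
  criterion <- ifelse(passDg & passRatio, "both",
                      ifelse(passDg, "dg_threshold", "ratio_threshold"))
  criterion <- criterion[passDg | passRatio]
  df <- data.frame(
    pirna_id = mc$pirna_id[keep], gene_id = genes[keep],
    start = st[keep], end = en[keep], region = mc$region[keep],
    dG_kJ_mol = mc$dG[keep], dGm_kJ_mol = mc$dGm[keep],
    ratio_pct = mc$ratio[keep], criterion = criterion,
    stringsAsFactors = FALSE)
  df <- df[order(df$gene_id, -df$dG_kJ_mol, df$pirna_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.emptyMarkers <- function() {
  data.frame(pirna_id = character(0), gene_id = character(0),
             start = integer(0), end = integer(0), region = character(0),
             dG_kJ_mol = numeric(0), dGm_kJ_mol = numeric(0),
             ratio_pct = numeric(0), criterion = character(0),
             stringsAsFactors = FALSE)
}

#' piRNAs with binding sites in several genes
#'
#' A marker piRNA is only as informative as it is selective; this lists
#' every piRNA with passing sites in at least `minGenes` distinct genes,
#' together with its gene set - piRNAs that can simultaneously regulate
#' several transcripts.
#'
#' @param sites binding-site `GRanges` across genes (one run), or a named
#'   list of per-gene site `GRanges`.
#' @param minGenes minimum number of distinct target genes (default 2).
#' @return data.frame with columns `pirna_id`, `n_genes`, `gene_ids`
#'   (comma-joined, sorted), ordered by piRNA id.
#' @export
crossGenePirnas <- function(sites, minGenes = 2L) {
  if (is.list(sites) && !is(sites, "GRanges")) {
    pir <- unlist(lapply(sites, function(s) S4Vectors::mcols(s)$pirna_id),
                  use.names = FALSE)
    gen <- rep(names(sites),
               vapply(sites, length, integer(1L)))
  } else {
    pir <- S4Vectors::mcols(sites)$pirna_id
    gen <- as.character(GenomicRanges::seqnames(sites))
  }
  sets <- lapply(split(gen, pir), function(g) sort(unique(g)))
  sets <- sets[vapply(sets, length, integer(1L)) >= minGenes]
  if (!length(sets))
    return(data.frame(pirna_id = character(0), n_genes = integer(0),
                      gene_ids = character(0), stringsAsFactors = FALSE))
  df <- data.frame(
    pirna_id = names(sets),
    n_genes = vapply(sets, length, integer(1L)),
    gene_ids = vapply(sets, paste, character(1L), collapse = ","),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df[order(df$pirna_id), , drop = FALSE]
}

#' Render a piRNA/mRNA interaction scheme as text
#'
#' Fixed-width, three-line alignment of one binding site: the mRNA window
#' 5'->3' with its start coordinate, a pairing-symbol line (`|` canonical,
#' `:` wobble or noncanonical A-C, `.` mismatch), the piRNA 3'->5' with
#' its id, and a footer with the free energy and the dG/dGm percentage.
#'
#' @param site a length-1 binding-site `GRanges` row.
#' @param transcripts the [TranscriptSet-class] scanned.
#' @param pirnas the piRNA sequences used in the scan (named character or
#'   `RNAStringSet`).
#' @param model a [PairEnergyModel].
#' @return a single character string (lines joined with newlines).
#' @examples
#' ts <- makeTranscriptSet(c(G1 = strrep("AGCU", 30)),
#'   data.frame(gene_id = "G1", cds_start = 21, cds_end = 80))
#' pir <- c(p1 = "AGCUAGCUAGCUAGCUAGCUAGCU")
#' s <- scanTargets(ts, pir)
#' cat(renderScheme(s[1], ts, pir), "\n")
#' @export
renderScheme <- function(site, transcripts, pirnas,
                         model = PairEnergyModel()) {
  if (length(site) != 1L)
    stop("renderScheme takes exactly one site", call. = FALSE)
  gene <- as.character(GenomicRanges::seqnames(site))
  pid <- S4Vectors::mcols(site)$pirna_id
  pseqs <- .pirnaChars(pirnas)
  if (!pid %in% names(pseqs))
    stop("piRNA '", pid, "' not found in the supplied set", call. = FALSE)
  if (!gene %in% names(transcripts))
    stop("gene '", gene, "' not found in the transcript set", call. = FALSE)
  tchars <- .seqChars(as.character(transcriptSeqs(transcripts[gene]))[[1L]])
  s <- BiocGenerics::start(site)
  e <- BiocGenerics::end(site)
  if (e > length(tchars))
    stop("site extends beyond transcript '", gene, "'", call. = FALSE)
  window <- paste(tchars[s:e], collapse = "")
  sc <- scoreDuplex(window, pseqs[[pid]], model)
  left <- format(c(gene, "", pid), width = max(nchar(c(gene, pid))))
  lines <- c(
    paste0(left[1L], "  5'-", window, "-3'  (", s, ")"),
    paste0(left[2L], "     ", pairingString(sc)),
    paste0(left[3L], "  3'-",
           paste(rev(.seqChars(pseqs[[pid]])), collapse = ""), "-5'"),
    sprintf("dG = -%.1f kJ/mol; dG/dGm = %.1f%%",
            roundHalfAway(dG(sc), 1L), roundHalfAway(ratioPct(sc), 1L)))
  paste(lines, collapse = "\n")
}
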