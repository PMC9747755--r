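#' Read piRNA sequences from FASTA
#'
#' Reads a FASTA file of piRNA sequences, normalizes to the RNA alphabet
#' (uppercase, T -> U), and validates: only A/C/G/U after normalization,
#' unique record ids, and lengths in the accepted piRNA range.  Record
#' order is preserved.
#'
#' @param path path to a FASTA file.
#' @param minLength,maxLength accepted piRNA length range in nt; the
#'   class spans roughly 24-34 nt but slightly wider inputs are tolerated
#'   by default.
#' @return a named [Biostrings::RNAStringSet].
#' @export
readPirnaFasta <- function(path, minLength = 16L, maxLength = 40L) {
  seqs <- .readFastaNormalized(path)
  w <- nchar(seqs)
  bad <- w < minLength | w > maxLength
  if (any(bad))
    stop("piRNA length outside [", minLength, ", ", maxLength, "] nt for: ",
         paste(utils::head(names(seqs)[bad], 5L), collapse = ", "),
         call. = FALSE)
  Biostrings::RNAStringSet(seqs)
}

#' Read transcript sequences from FASTA
#'
#' As [readPirnaFasta()] but without a length restriction; combine with a
#' regions table via [makeTranscriptSet()].
#'
#' @inheritParams readPirnaFasta
#' @return a named [Biostrings::RNAStringSet].
#' @export
readTranscriptFasta <- function(path) {
  Biostrings::RNAStringSet(.readFastaNormalized(path))
}

.readFastaNormalized <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(raw) == 0L)
    stop("no FASTA records in '", path, "'", call. = FALSE)
  ids <- sub("\\s.*$", "", names(raw))   # id = first whitespace-separated token
  if (any(ids == ""))
    stop("FASTA record with empty id in '", path, "'", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  seqs <- vapply(as.character(raw), .normalizeRna, character(1L),
                 USE.NAMES = FALSE)
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  .checkAlphabet(seqs, paste0("'", path, "'"))
  seqs
}

.checkRegionsFrame <- function(regions) {
  need <- c("gene_id", "cds_start", "cds_end")
  if (!all(need %in% names(regions)))
    stop("regions table needs columns gene_id, cds_start, cds_end",
         call. = FALSE)
  if (anyDuplicated(regions$gene_id))
    stop("duplicate gene_id in regions table: ",
         paste(unique(regions$gene_id[duplicated(regions$gene_id)]),
               collapse = ", "), call. = FALSE)
  cs <- regions$cds_start
  ce <- regions$cds_end
  if (anyNA(cs) || anyNA(ce) || any(cs != floor(cs)) || any(ce != floor(ce)))
    stop("cds_start/cds_end must be integers", call. = FALSE)
  bad <- cs < 1L | ce < cs
  if (any(bad))
    stop("invalid CDS interval (need 1 <= cds_start <= cds_end) for: ",
         paste(regions$gene_id[bad], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Read a CDS regions table
#'
#' Tab-separated table with header columns `gene_id`, `cds_start`,
#' `cds_end`; coordinates are 1-based inclusive transcript coordinates.
#' Boundaries beyond the sequence length are only detectable once paired
#' with sequences, in [makeTranscriptSet()].
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene_id` (character), `cds_start`,
#'   `cds_end` (integer).
#' @export
readRegions <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .checkRegionsFrame(df)
  data.frame(gene_id = as.character(df$gene_id),
             cds_start = as.integer(df$cds_start),
             cds_end = as.integer(df$cds_end),
             stringsAsFactors = FALSE)
}

# canonical column order of sites.tsv
.SITE_COLS <- c("gene_id", "pirna_id", "start", "end", "region",
                "dG_kJ_mol", "dGm_kJ_mol", "ratio_pct",
                "n_GC", "n_AU", "n_GU", "n_AC", "n_mismatch")

# sites GRanges -> canonical data.frame, in deterministic output order
.sitesFrame <- function(sites) {
  df <- data.frame(
    gene_id = as.character(GenomicRanges::seqnames(sites)),
    pirna_id = S4Vectors::mcols(sites)$pirna_id,
    start = BiocGenerics::start(sites),
    end = BiocGenerics::end(sites),
    region = S4Vectors::mcols(sites)$region,
    dG_kJ_mol = S4Vectors::mcols(sites)$dG,
    dGm_kJ_mol = S4Vectors::mcols(sites)$dGm,
    ratio_pct = S4Vectors::mcols(sites)$ratio,
    n_GC = S4Vectors::mcols(sites)$n_GC,
    n_AU = S4Vectors::mcols(sites)$n_AU,
    n_GU = S4Vectors::mcols(sites)$n_GU,
    n_AC = S4Vectors::mcols(sites)$n_AC,
    n_mismatch = S4Vectors::mcols(sites)$n_mismatch,
    stringsAsFactors = FALSE)
  if (!is.null(S4Vectors::mcols(sites)$preferred))
    df$preferred <- S4Vectors::mcols(sites)$preferred
  df[order(df$gene_id, df$start, -df$dG_kJ_mol, df$pirna_id), , drop = FALSE]
}

#' Write binding sites to TSV
#'
#' Deterministic, byte-stable TSV: fixed column order, rows sorted by
#' gene id, start, descending |dG|, then piRNA id; dG, dGm and the ratio
#' printed with one decimal.
#'
#' @param sites a `GRanges` of binding sites as returned by
#'   [scanTargets()] / [scanTranscript()].
#' @param path output path.
#' @return invisibly, the written data.frame.
#' @seealso [readSites()] for the inverse.
#' @export
writeSites <- function(sites, path) {
  df <- .sitesFrame(sites)
  for (cn in c("dG_kJ_mol", "dGm_kJ_mol", "ratio_pct"))
    df[[cn]] <- sprintf("%.1f", roundHalfAway(df[[cn]], 1L))
  .writeTsv(df, path)
}

#' Read a sites TSV back into a GRanges
#'
#' @param path path to a file written by [writeSites()].
#' @return a `GRanges` with the same metadata columns as [scanTargets()]
#'   output except the pairing string, which is not serialized (recompute
#'   with [scoreDuplex()] / [renderScheme()] when needed).  Energies and
#'   ratios carry the file's one-decimal precision.
#' @export
readSites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(.SITE_COLS, names(df))
  if (length(miss))
    stop("sites file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = df$gene_id,
    ranges = IRanges::IRanges(start = df$start, end = df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    pirna_id = df$pirna_id, region = df$region,
    dG = df$dG_kJ_mol, dGm = df$dGm_kJ_mol, ratio = df$ratio_pct,
    n_GC = df$n_GC, n_AU = df$n_AU, n_GU = df$n_GU, n_AC = df$n_AC,
    n_mismatch = df$n_mismatch)
  if ("preferred" %in% names(df))
    S4Vectors::mcols(gr)$preferred <- df$preferred
  gr
}

#' Write binding-site clusters to TSV
#'
#' @param clusters a `GRanges` of clusters from [buildClusters()].
#' @param path output path.
#' @return invisibly, the written data.frame.
#' @export
writeClusters <- function(clusters, path) {
  mc <- S4Vectors::mcols(clusters)
  df <- data.frame(
    gene_id = as.character(GenomicRanges::seqnames(clusters)),
    region = mc$region,
    span_start = BiocGenerics::start(clusters),
    span_end = BiocGenerics::end(clusters),
    length_nt = BiocGenerics::width(clusters),
    n_sites = mc$n_sites,
    total_pirna_len_nt = mc$total_pirna_len,
    compaction_ratio = sprintf("%.1f", mc$compaction_ratio),
    region_len_nt = if (is.null(mc$region_len)) NA_integer_ else mc$region_len,
    region_to_cluster_ratio = if (is.null(mc$region_ratio)) ""
      else sprintf("%.1f", mc$region_ratio),
    member_pirna_ids = mc$pirna_ids,
    stringsAsFactors = FALSE)
  df <- df[order(df$gene_id, df$span_start), , drop = FALSE]
  .writeTsv(df, path)
}

#' Write marker associations to TSV
#'
#' @param markers data.frame from [selectMarkers()].
#' @param path output path.
#' @return invisibly, the written data.frame.
#' @export
writeMarkers <- function(markers, path) {
  df <- markers
  for (cn in c("dG_kJ_mol", "dGm_kJ_mol", "ratio_pct"))
    df[[cn]] <- sprintf("%.1f", roundHalfAway(df[[cn]], 1L))
  .writeTsv(df, path)
}

.writeTsv <- function(df, path) {
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e)
                    stop("cannot write '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(df)
}
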