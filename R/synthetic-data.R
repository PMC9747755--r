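#' Simulation configuration for synthetic piRNA/transcript datasets
#'
#' Describes a fully deterministic synthetic world: background piRNAs and
#' transcripts of realistic sizes, plus planted structures emulating what
#' the scanner and the cluster statistics are meant to detect - single
#' binding sites of controlled pair composition, staggered overlapping
#' clusters, identical-start groups, and a homologous region shared by
#' several genes.  All randomness derives from `seed`; each transcript
#' and each shared-region plan draws from its own seeded stream, so
#' adding one transcript never reshuffles the others.
#'
#' @param seed integer master seed.
#' @param nPirnas number of background piRNAs.
#' @param pirnaLengthRange inclusive nt range of piRNA lengths (the
#'   piRNA class spans roughly 24-34 nt).
#' @param gcContent background G+C fraction for piRNAs and transcripts.
#' @param transcripts data.frame `gene_id`, `length`, `cds_start`,
#'   `cds_end` (1-based inclusive).
#' @param plants data.frame `pirna_id` (a background piRNA), `gene_id`,
#'   `start`, `n_wobble`, `n_noncanonical`, `n_mismatch`: each plant
#'   writes the piRNA's reverse complement at `start` and then converts
#'   the stated numbers of canonical pairs into G-U wobbles, A-C pairs
#'   and mismatches by substituting the mRNA side at distinct random
#'   positions.
#' @param clusterPlans data.frame `gene_id`, `start`, `n_sites`,
#'   `stagger_nt`, `pirna_length`: each plan derives `n_sites` new
#'   perfect-complement piRNAs from transcript windows staggered by
#'   `stagger_nt`, emulating a cluster of overlapping sites.
#' @param startGroupPlans data.frame `gene_id`, `start`, `n_pirnas`,
#'   `pirna_length`: derives a group of distinct piRNAs all binding at
#'   one start (the first perfect, the rest with one piRNA-side wobble
#'   substitution each).
#' @param sharedRegionPlans list of plans, each a list with fields
#'   `genes` (character vector), `starts` (parallel insert positions),
#'   `region_length`, `n_pirnas`, `stagger_nt`, `pirna_length`: one
#'   random region inserted into every member transcript, targeted by a
#'   staggered set of derived piRNAs - the cross-gene homology structure.
#' @param extraPirnas optional named character vector of additional piRNA
#'   sequences (e.g. of controlled base composition) appended to the
#'   background set; plants may reference them by id.
#'
#' Each planted-structure argument defaults to a small realistic plan
#' when left unspecified; pass `NULL` explicitly to omit that structure
#' altogether.
#' @return a validated list of class `SimulationConfig`.
#' @seealso [generateDataset()]
#' @export
simulationConfig <- function(seed = 1L,
                             nPirnas = 60L,
                             pirnaLengthRange = c(24L, 34L),
                             gcContent = 0.5,
                             transcripts = NULL,
                             plants,
                             clusterPlans,
                             startGroupPlans,
                             sharedRegionPlans,
                             extraPirnas = NULL) {
  if (is.null(transcripts)) {
    transcripts <- data.frame(
      gene_id = c("G1", "G2", "G3"),
      length = c(2000L, 4000L, 6000L),
      cds_start = c(201L, 301L, 501L),
      cds_end = c(1400L, 2100L, 3500L),
      stringsAsFactors = FALSE)
  }
  if (missing(plants)) {
    plants <- data.frame(
      pirna_id = sprintf("piR-%04d", 1:8),
      gene_id = c("G1", "G1", "G2", "G2", "G2", "G3", "G3", "G3"),
      start = c(500L, 1500L, 150L, 1000L, 2500L, 700L, 2000L, 4000L),
      n_wobble = c(0L, 2L, 0L, 1L, 0L, 0L, 2L, 0L),
      n_noncanonical = c(0L, 0L, 2L, 1L, 0L, 0L, 1L, 0L),
      n_mismatch = c(0L, 0L, 0L, 0L, 1L, 2L, 0L, 4L),
      stringsAsFactors = FALSE)
  }
  if (missing(clusterPlans)) {
    clusterPlans <- data.frame(
      gene_id = "G3", start = 4500L, n_sites = 5L,
      stagger_nt = 3L, pirna_length = 27L, stringsAsFactors = FALSE)
  }
  if (missing(startGroupPlans)) {
    startGroupPlans <- data.frame(
      gene_id = "G2", start = 3000L, n_pirnas = 6L,
      pirna_length = 27L, stringsAsFactors = FALSE)
  }
  if (missing(sharedRegionPlans)) {
    sharedRegionPlans <- list(list(
      genes = c("G1", "G2", "G3"),
      starts = c(1700L, 3500L, 5500L),
      region_length = 54L, n_pirnas = 4L,
      stagger_nt = 9L, pirna_length = 27L))
  }
  cfg <- list(seed = as.integer(seed), nPirnas = as.integer(nPirnas),
              pirnaLengthRange = as.integer(pirnaLengthRange),
              gcContent = gcContent, transcripts = transcripts,
              plants = .normPlan(plants, c(
                pirna_id = "character", gene_id = "character",
                start = "integer", n_wobble = "integer",
                n_noncanonical = "integer", n_mismatch = "integer")),
              clusterPlans = .normPlan(clusterPlans, c(
                gene_id = "character", start = "integer",
                n_sites = "integer", stagger_nt = "integer",
                pirna_length = "integer")),
              startGroupPlans = .normPlan(startGroupPlans, c(
                gene_id = "character", start = "integer",
                n_pirnas = "integer", pirna_length = "integer")),
              sharedRegionPlans = if (is.null(sharedRegionPlans)) list()
                else sharedRegionPlans,
              extraPirnas = extraPirnas)
  class(cfg) <- "SimulationConfig"
  .validateSimConfig(cfg)
  cfg
}

# NULL / zero-row plan -> canonical empty data.frame with typed columns
.normPlan <- function(df, cols) {
  if (is.null(df) || nrow(df) == 0L) {
    out <- lapply(cols, function(tp) vector(tp, 0L))
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  miss <- setdiff(names(cols), names(df))
  if (length(miss))
    stop("plan table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

.validateSimConfig <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, !is.na(cfg$seed),
            cfg$nPirnas >= 0L,
            length(cfg$pirnaLengthRange) == 2L,
            cfg$pirnaLengthRange[1L] >= 16L,
            cfg$pirnaLengthRange[2L] <= 40L,
            cfg$pirnaLengthRange[1L] <= cfg$pirnaLengthRange[2L],
            cfg$gcContent > 0, cfg$gcContent < 1)
  tr <- cfg$transcripts
  if (!all(c("gene_id", "length", "cds_start", "cds_end") %in% names(tr)))
    stop("transcripts needs gene_id, length, cds_start, cds_end",
         call. = FALSE)
  if (anyDuplicated(tr$gene_id))
    stop("duplicate gene_id in transcripts", call. = FALSE)
  if (any(tr$cds_start < 1L | tr$cds_end < tr$cds_start |
          tr$cds_end > tr$length))
    stop("invalid CDS boundaries in transcripts", call. = FALSE)
  for (df in list(cfg$plants, cfg$clusterPlans, cfg$startGroupPlans)) {
    if (nrow(df) && !all(df$gene_id %in% tr$gene_id))
      stop("plan references unknown gene_id", call. = FALSE)
  }
  if (!is.null(cfg$extraPirnas)) {
    ep <- vapply(cfg$extraPirnas, .normalizeRna, character(1L))
    if (is.null(names(ep)) || anyDuplicated(names(ep)))
      stop("extraPirnas must carry unique names", call. = FALSE)
    .checkAlphabet(ep, "extraPirnas")
  }
  for (plan in cfg$sharedRegionPlans) {
    if (!all(plan$genes %in% tr$gene_id))
      stop("shared-region plan references unknown gene_id", call. = FALSE)
    if (length(plan$starts) != length(plan$genes))
      stop("shared-region plan: starts must parallel genes", call. = FALSE)
    if ((plan$n_pirnas - 1L) * plan$stagger_nt + plan$pirna_length >
        plan$region_length)
      stop("shared-region plan: piRNAs do not fit in the region",
           call. = FALSE)
  }
  invisible(cfg)
}

# per-stream seeds below 2^31, disjoint between transcripts (j = 1..n)
# and shared-region plans (offset 500000)
.streamSeed <- function(seed, j) {
  (((seed %% 1048573L) + 1L) * 2039L + j) %% 2147483647L
}

.randomRna <- function(n, gc) {
  paste(sample(.RNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.revcompChars <- function(chars) {
  rev(chartr("ACGU", "UGCA", chars))
}

# write the reverse complement of `pirna` into `tchars` at `start`, then
# degrade the stated numbers of pairs (mRNA-side substitutions at
# distinct random positions).  Returns the modified transcript.
.plantSite <- function(tchars, pirna, start, nWobble, nNoncanonical,
                       nMismatch, geneId, pirnaId) {
  p <- .seqChars(pirna)
  l <- length(p)
  if (start < 1L || start + l - 1L > length(tchars))
    stop("plant of '", pirnaId, "' outside transcript '", geneId, "'",
         call. = FALSE)
  window <- .revcompChars(p)
  alignedPirna <- rev(p)   # piRNA base paired with window position i
  pool <- seq_len(l)
  pickFrom <- function(eligible, k, what) {
    eligible <- intersect(eligible, pool)
    if (length(eligible) < k)
      stop("plant of '", pirnaId, "': not enough eligible positions for ",
           what, call. = FALSE)
    sel <- if (k == 0L) integer(0)
           else eligible[sample.int(length(eligible), k)]
    pool <<- setdiff(pool, sel)
    sel
  }
  # wobble: piRNA G faces window C -> U; piRNA U faces window A -> G
  wob <- pickFrom(which(alignedPirna %in% c("G", "U")), nWobble, "wobble")
  window[wob] <- ifelse(alignedPirna[wob] == "G", "U", "G")
  # noncanonical A-C: piRNA A faces window U -> C; piRNA C faces G -> A
  nc <- pickFrom(which(alignedPirna %in% c("A", "C")), nNoncanonical,
                 "noncanonical A-C")
  window[nc] <- ifelse(alignedPirna[nc] == "A", "C", "A")
  # mismatch: identical bases never pair in this model
  mm <- pickFrom(seq_len(l), nMismatch, "mismatch")
  window[mm] <- alignedPirna[mm]
  tchars[start:(start + l - 1L)] <- window
  tchars
}

#' Derive a planted cluster of overlapping binding sites
#'
#' Emulates a cluster of `nSites` piRNAs whose sites start
#' `staggerNt` nt apart: each member piRNA is the perfect reverse
#' complement of the transcript window at its staggered start, so every
#' member binds with ratio 100\% and the sites overlap whenever
#' `staggerNt < pirnaLength`.  The transcript itself is not modified
#' (deriving piRNAs from the existing sequence is what keeps k mutually
#' overlapping perfect sites consistent - physically inserting k
#' overlapping complements would destroy each other).
#'
#' @param transcript transcript sequence (character scalar or
#'   [Biostrings::RNAString]).
#' @param start 1-based start of the first site.
#' @param nSites number of member piRNAs.
#' @param staggerNt start-to-start offset in nt.
#' @param pirnaLength member piRNA length in nt.
#' @param ids optional character vector of `nSites` piRNA ids.
#' @return list with `transcript` (unchanged), `pirnas` (named
#'   [Biostrings::RNAStringSet]) and `specs` (data.frame `pirna_id`,
#'   `start`, `end`).
#' @export
plantCluster <- function(transcript, start, nSites, staggerNt,
                         pirnaLength, ids = NULL) {
  tchars <- .seqChars(transcript)
  start <- as.integer(start)
  nSites <- as.integer(nSites)
  staggerNt <- as.integer(staggerNt)
  pirnaLength <- as.integer(pirnaLength)
  lastEnd <- start + (nSites - 1L) * staggerNt + pirnaLength - 1L
  if (start < 1L || lastEnd > length(tchars))
    stop("cluster plan overflows the transcript (last site ends at ",
         lastEnd, ", length ", length(tchars), ")", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("piR-cluster-%03d", seq_len(nSites))
  starts <- start + (seq_len(nSites) - 1L) * staggerNt
  seqs <- vapply(starts, function(s) {
    paste(.revcompChars(tchars[s:(s + pirnaLength - 1L)]), collapse = "")
  }, character(1L))
  names(seqs) <- ids
  list(transcript = transcript,
       pirnas = Biostrings::RNAStringSet(seqs),
       specs = data.frame(pirna_id = ids, start = starts,
                          end = starts + pirnaLength - 1L,
                          stringsAsFactors = FALSE))
}

# derive an identical-start group: first member perfect, member k > 1
# carries one piRNA-side wobble substitution at the (k-1)-th eligible
# position, so all members are distinct but all bind at `start`
.deriveStartGroup <- function(tchars, start, nPirnas, pirnaLength,
                              idPrefix, geneId) {
  if (start < 1L || start + pirnaLength - 1L > length(tchars))
    stop("start-group plan outside transcript '", geneId, "'",
         call. = FALSE)
  window <- tchars[start:(start + pirnaLength - 1L)]
  perfect <- .revcompChars(window)     # piRNA 5'->3'
  # piRNA-side wobble: C -> U (faces window G), A -> G (faces window U)
  eligible <- which(perfect %in% c("C", "A"))
  if (length(eligible) < nPirnas - 1L)
    stop("start-group plan at ", geneId, ":", start,
         ": window has too few wobble-eligible positions", call. = FALSE)
  seqs <- character(nPirnas)
  seqs[1L] <- paste(perfect, collapse = "")
  for (k in seq_len(nPirnas - 1L)) {
    v <- perfect
    pos <- eligible[k]
    v[pos] <- if (v[pos] == "C") "U" else "G"
    seqs[k + 1L] <- paste(v, collapse = "")
  }
  names(seqs) <- sprintf("%s-%02d", idPrefix, seq_len(nPirnas))
  seqs
}

#' Generate a synthetic piRNA/transcript dataset
#'
#' Realizes a [simulationConfig()]: i.i.d. background sequences at the
#' configured G+C content, planted binding sites of controlled pair
#' composition, derived cluster / identical-start / shared-region piRNA
#' sets, and a truth table in which every planted or derived site's
#' `expected_dG` and `expected_ratio` are recomputed with
#' [scoreDuplex()] from the *final* transcript sequences - the generator
#' and the scorer therefore agree by construction, and the scanner can be
#' audited against the table.  Byte-identical outputs for equal seeds.
#'
#' @param config a `SimulationConfig` from [simulationConfig()].
#' @return list of class `SyntheticDataset` with elements `pirnas`
#'   (named [Biostrings::RNAStringSet]: background plus derived),
#'   `transcripts` ([TranscriptSet-class]), `regions` (data.frame) and
#'   `truth` (data.frame: `pirna_id`, `gene_id`, `start`, `end`,
#'   `n_wobble`, `n_noncanonical`, `n_mismatch`, `expected_dG`,
#'   `expected_ratio`, `source`).
#' @examples
#' ds <- generateDataset(simulationConfig(seed = 7))
#' head(ds$truth)
#' @export
generateDataset <- function(config = simulationConfig()) {
  cfg <- .validateSimConfig(config)
  tr <- cfg$transcripts
  nT <- nrow(tr)

  # background piRNAs from the master stream
  set.seed(cfg$seed %% 2147483647L)
  lens <- sample(seq(cfg$pirnaLengthRange[1L], cfg$pirnaLengthRange[2L]),
                 cfg$nPirnas, replace = TRUE)
  pirnas <- vapply(lens, .randomRna, character(1L), gc = cfg$gcContent)
  names(pirnas) <- sprintf("piR-%04d", seq_len(cfg$nPirnas))
  if (!is.null(cfg$extraPirnas)) {
    extra <- vapply(cfg$extraPirnas, .normalizeRna, character(1L))
    if (any(names(extra) %in% names(pirnas)))
      stop("extraPirnas ids collide with background piRNA ids",
           call. = FALSE)
    pirnas <- c(pirnas, extra)
  }

  # background transcripts + mRNA-side plants, one RNG stream each
  seqsByGene <- vector("list", nT)
  names(seqsByGene) <- tr$gene_id
  reserved <- stats::setNames(vector("list", nT), tr$gene_id)
  truth <- list()
  addTruth <- function(pirna_id, gene_id, start, len, nW, nN, nM, source) {
    truth[[length(truth) + 1L]] <<- data.frame(
      pirna_id = pirna_id, gene_id = gene_id, start = as.integer(start),
      end = as.integer(start + len - 1L),
      n_wobble = nW, n_noncanonical = nN, n_mismatch = nM,
      source = source, stringsAsFactors = FALSE)
  }
  reserve <- function(gene, from, to, hard, what) {
    iv <- reserved[[gene]]
    if (!is.null(iv) && nrow(iv)) {
      clash <- iv$from <= to & iv$to >= from & (hard | iv$hard)
      if (any(clash))
        stop("colliding plants on '", gene, "': ", what, " [", from, ", ",
             to, "] overlaps ", iv$what[clash][1L], call. = FALSE)
    }
    reserved[[gene]] <<- rbind(iv, data.frame(
      from = from, to = to, hard = hard, what = what,
      stringsAsFactors = FALSE))
  }

  for (j in seq_len(nT)) {
    set.seed(.streamSeed(cfg$seed, j))
    tchars <- .seqChars(.randomRna(tr$length[j], cfg$gcContent))
    g <- tr$gene_id[j]
    pl <- cfg$plants[cfg$plants$gene_id == g, , drop = FALSE]
    for (r in seq_len(nrow(pl))) {
      pid <- pl$pirna_id[r]
      if (!pid %in% names(pirnas))
        stop("plant references unknown piRNA '", pid, "'", call. = FALSE)
      l <- nchar(pirnas[[pid]])
      reserve(g, pl$start[r], pl$start[r] + l - 1L, hard = TRUE,
              what = paste0("plant ", pid))
      tchars <- .plantSite(tchars, pirnas[[pid]], pl$start[r],
                           pl$n_wobble[r], pl$n_noncanonical[r],
                           pl$n_mismatch[r], g, pid)
      addTruth(pid, g, pl$start[r], l, pl$n_wobble[r],
               pl$n_noncanonical[r], pl$n_mismatch[r], "plant")
    }
    seqsByGene[[j]] <- tchars
  }

  # shared homologous regions: one random region per plan, inserted into
  # every member transcript, targeted by staggered derived piRNAs
  for (k in seq_along(cfg$sharedRegionPlans)) {
    plan <- cfg$sharedRegionPlans[[k]]
    set.seed(.streamSeed(cfg$seed, 500000L + k))
    region <- .seqChars(.randomRna(plan$region_length, cfg$gcContent))
    starts <- seq(1L, by = plan$stagger_nt, length.out = plan$n_pirnas)
    ids <- sprintf("piR-shared%d-%02d", k, seq_len(plan$n_pirnas))
    derived <- vapply(starts, function(s) {
      paste(.revcompChars(region[s:(s + plan$pirna_length - 1L)]),
            collapse = "")
    }, character(1L))
    names(derived) <- ids
    pirnas <- c(pirnas, derived)
    for (gI in seq_along(plan$genes)) {
      g <- plan$genes[gI]
      at <- plan$starts[gI]
      if (at < 1L || at + plan$region_length - 1L > length(seqsByGene[[g]]))
        stop("shared region outside transcript '", g, "'", call. = FALSE)
      reserve(g, at, at + plan$region_length - 1L, hard = TRUE,
              what = paste0("shared region ", k))
      seqsByGene[[g]][at:(at + plan$region_length - 1L)] <- region
      for (m in seq_len(plan$n_pirnas))
        addTruth(ids[m], g, at + starts[m] - 1L, plan$pirna_length,
                 0L, 0L, 0L, "shared_region")
    }
  }

  # planted clusters: derive staggered perfect complements (read-only)
  cp <- cfg$clusterPlans
  for (r in seq_len(nrow(cp))) {
    g <- cp$gene_id[r]
    res <- plantCluster(paste(seqsByGene[[g]], collapse = ""),
                        cp$start[r], cp$n_sites[r], cp$stagger_nt[r],
                        cp$pirna_length[r],
                        ids = sprintf("piR-cl%d-%02d", r,
                                      seq_len(cp$n_sites[r])))
    reserve(g, cp$start[r],
            cp$start[r] + (cp$n_sites[r] - 1L) * cp$stagger_nt[r] +
              cp$pirna_length[r] - 1L,
            hard = FALSE, what = paste0("cluster plan ", r))
    seqs <- as.character(res$pirnas)
    pirnas <- c(pirnas, seqs)
    for (m in seq_len(nrow(res$specs)))
      addTruth(res$specs$pirna_id[m], g, res$specs$start[m],
               cp$pirna_length[r], 0L, 0L, 0L, "cluster")
  }

  # identical-start groups (read-only derivation)
  sg <- cfg$startGroupPlans
  for (r in seq_len(nrow(sg))) {
    g <- sg$gene_id[r]
    seqs <- .deriveStartGroup(seqsByGene[[g]], sg$start[r],
                              sg$n_pirnas[r], sg$pirna_length[r],
                              sprintf("piR-sg%d", r), g)
    reserve(g, sg$start[r], sg$start[r] + sg$pirna_length[r] - 1L,
            hard = FALSE, what = paste0("start-group plan ", r))
    pirnas <- c(pirnas, seqs)
    for (m in seq_along(seqs))
      addTruth(names(seqs)[m], g, sg$start[r], sg$pirna_length[r],
               if (m == 1L) 0L else 1L, 0L, 0L, "start_group")
  }

  regions <- data.frame(gene_id = tr$gene_id, cds_start = tr$cds_start,
                        cds_end = tr$cds_end, stringsAsFactors = FALSE)
  transcripts <- makeTranscriptSet(
    stats::setNames(vapply(seqsByGene, paste, character(1L),
                           collapse = ""), tr$gene_id),
    regions)

  # close the loop: expected values recomputed from the final sequences
  truthDf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(pirna_id = character(0), gene_id = character(0),
               start = integer(0), end = integer(0), n_wobble = integer(0),
               n_noncanonical = integer(0), n_mismatch = integer(0),
               source = character(0), stringsAsFactors = FALSE)
  if (nrow(truthDf)) {
    sc <- lapply(seq_len(nrow(truthDf)), function(i) {
      g <- truthDf$gene_id[i]
      win <- paste(seqsByGene[[g]][truthDf$start[i]:truthDf$end[i]],
                   collapse = "")
      scoreDuplex(win, pirnas[[truthDf$pirna_id[i]]])
    })
    truthDf$expected_dG <- vapply(sc, dG, numeric(1L))
    truthDf$expected_ratio <- vapply(sc, ratioPct, numeric(1L))
  } else {
    truthDf$expected_dG <- numeric(0)
    truthDf$expected_ratio <- numeric(0)
  }
  truthDf <- truthDf[, c("pirna_id", "gene_id", "start", "end",
                         "n_wobble", "n_noncanonical", "n_mismatch",
                         "expected_dG", "expected_ratio", "source")]
  rownames(truthDf) <- NULL

  out <- list(pirnas = Biostrings::RNAStringSet(pirnas),
              transcripts = transcripts, regions = regions,
              truth = truthDf, config = cfg)
  class(out) <- "SyntheticDataset"
  out
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat("SyntheticDataset:", length(x$pirnas), "piRNAs,",
      length(x$transcripts), "transcripts,",
      nrow(x$truth), "planted sites\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes `pirnas.fasta`, `transcripts.fasta`, `regions.tsv` and
#' `truth.tsv` into `dir`; outputs are byte-identical for equal seeds.
#'
#' @param dataset a `SyntheticDataset` from [generateDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the four file paths.
#' @export
writeDataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("pirnas.fasta", "transcripts.fasta",
                            "regions.tsv", "truth.tsv"))
  Biostrings::writeXStringSet(dataset$pirnas, paths[1L])
  Biostrings::writeXStringSet(transcriptSeqs(dataset$transcripts),
                              paths[2L])
  .writeTsv(dataset$regions, paths[3L])
  .writeTsv(dataset$truth, paths[4L])
  invisible(paths)
}
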