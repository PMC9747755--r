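test_that("marker selection applies the |dG| and ratio thresholds", {
  s <- makeSitesGR("CD55", c(100, 400, 800), 30, c("a", "b", "c"),
                   dG = c(172, 169.9, 150), dGm = c(190, 175.4, 150))
  # ratios: 90.5, 96.9, 100
  mk <- selectMarkers(s, minAbsDg = 170, minRatioPct = 97)
  expect_identical(mk$pirna_id, c("a", "c"))
  expect_identical(mk$criterion, c("dg_threshold", "ratio_threshold"))
  # site with dG 169.9 and ratio 96.9: both strictly below, excluded
  expect_false("b" %in% mk$pirna_id)

  # a site passing both records "both"
  s2 <- makeSitesGR("G", 10, 30, "d", dG = 180, dGm = 182)
  expect_identical(selectMarkers(s2)$criterion, "both")

  # one association per (piRNA, gene): the best site represents the pair
  s3 <- makeSitesGR("G", c(10, 500), 30, c("p", "p"),
                    dG = c(120, 175), dGm = c(180, 180))
  mk3 <- selectMarkers(s3)
  expect_identical(nrow(mk3), 1L)
  expect_identical(mk3$start, 500L)
})

test_that("marker selection equals a brute-force filter and is anti-monotone", {
  set.seed(202)
  for (rep in 1:8) {
    n <- 60
    dgm <- runif(n, 120, 200)
    dg <- dgm * runif(n, 0.75, 1)
    s <- makeSitesGR("G", sample(1:5000, n), 30, paste0("p", 1:n),
                     dG = dg, dGm = dgm)
    cutDg <- runif(1, 140, 185)
    cutRatio <- runif(1, 85, 99)
    mk <- selectMarkers(s, cutDg, cutRatio)
    ref <- sort(paste0("p", which(dg >= cutDg | 100 * dg / dgm >= cutRatio)))
    expect_identical(sort(mk$pirna_id), ref)

    # raising either cutoff never grows the selection
    mkUp <- selectMarkers(s, cutDg + 10, cutRatio)
    expect_true(all(mkUp$pirna_id %in% mk$pirna_id))
    mkUp2 <- selectMarkers(s, cutDg, min(cutRatio + 5, 100.1))
    expect_true(all(mkUp2$pirna_id %in% mk$pirna_id))
  }
})

test_that("cross-gene piRNAs are reported with their full gene sets", {
  sA <- makeSitesGR("GA", c(10, 50), 30, c("p1", "p2"))
  sB <- makeSitesGR("GB", c(10, 50), 30, c("p2", "p3"))
  all <- suppressWarnings(c(sA, sB))
  xg <- crossGenePirnas(all)
  expect_identical(xg$pirna_id, "p2")
  expect_identical(xg$gene_ids, "GA,GB")

  # disjoint piRNA sets: empty result
  expect_identical(nrow(crossGenePirnas(suppressWarnings(
    c(makeSitesGR("GA", 10, 30, "x"), makeSitesGR("GB", 10, 30, "y"))))),
    0L)

  # minGenes = 1 returns every piRNA with a site
  expect_identical(crossGenePirnas(all, minGenes = 1)$pirna_id,
                   c("p1", "p2", "p3"))

  # a list of per-gene tables is accepted too
  xg2 <- crossGenePirnas(list(GA = sA, GB = sB))
  expect_identical(xg2, xg)
})

test_that("a shared homologous region links its piRNAs to every member gene", {
  cfg <- simulationConfig(seed = 5, plants = NULL, clusterPlans = NULL,
                          startGroupPlans = NULL)
  ds <- generateDataset(cfg)
  sites <- scanTargets(ds$transcripts, ds$pirnas)
  xg <- crossGenePirnas(sites, minGenes = 3)
  shared <- sort(unique(ds$truth$pirna_id[ds$truth$source == "shared_region"]))
  expect_true(all(shared %in% xg$pirna_id))
  expect_identical(unique(xg$gene_ids[xg$pirna_id %in% shared]),
                   "G1,G2,G3")
})

test_that("rendered schemes are consistent with the duplex score", {
  set.seed(9)
  p <- randomRnaStr(24)
  tseq <- plantPerfect(randomRnaStr(400), p, 200)
  ts <- makeTranscriptSet(c(G = tseq),
                          data.frame(gene_id = "G", cds_start = 100,
                                     cds_end = 300))
  sites <- scanTargets(ts, c(p1 = p))
  txt <- renderScheme(sites[1], ts, c(p1 = p))
  lines <- strsplit(txt, "\n")[[1]]
  expect_identical(length(lines), 4L)
  pairing <- gsub("[^|:.]", "", lines[2])
  expect_identical(pairing, strrep("|", 24))       # perfect complement
  expect_match(lines[1], "\\(200\\)")              # start coordinate
  expect_match(lines[4], "dG/dGm = 100.0%", fixed = TRUE)

  # exactly one ':' for a single noncanonical A-C pair
  p2 <- paste0(strrep("G", 10), "A", strrep("G", 9))  # 20 nt
  win <- revComp(p2)
  wv <- strsplit(win, "", fixed = TRUE)[[1]]
  wv[wv == "U"] <- "C"                  # the lone U faces the A: now A-C
  tseq2 <- paste0(strrep("A", 50), paste(wv, collapse = ""),
                  strrep("A", 50))
  ts2 <- makeTranscriptSet(c(H = tseq2),
                           data.frame(gene_id = "H", cds_start = 1,
                                      cds_end = 120))
  sites2 <- scanTargets(ts2, c(p2 = p2))
  i <- which(S4Vectors::mcols(sites2)$pirna_id == "p2" &
               BiocGenerics::start(sites2) == 51)
  txt2 <- renderScheme(sites2[i], ts2, c(p2 = p2))
  pl <- strsplit(txt2, "\n")[[1]][2]
  expect_identical(lengths(regmatches(pl, gregexpr(":", pl))), 1L)

  # symbol counts equal the pair counts for arbitrary sites
  set.seed(10)
  for (rep in 1:5) {
    q <- randomRnaStr(26)
    t3 <- plantPerfect(randomRnaStr(300), q, 100)
    # degrade two positions to force a mixed pairing line
    tv <- strsplit(t3, "", fixed = TRUE)[[1]]
    tv[c(105, 110)] <- c("A", "C")
    ts3 <- makeTranscriptSet(c(K = paste(tv, collapse = "")),
                             data.frame(gene_id = "K", cds_start = 1,
                                        cds_end = 300))
    st3 <- scanTargets(ts3, c(q = q), minRatioPct = 70)
    j <- which(BiocGenerics::start(st3) == 100)
    if (!length(j)) next
    sc <- scoreDuplex(substr(paste(tv, collapse = ""), 100, 125), q)
    pl3 <- strsplit(renderScheme(st3[j], ts3, c(q = q)), "\n")[[1]][2]
    sym <- strsplit(gsub("[^|:.]", "", pl3), "")[[1]]
    expect_identical(sum(sym == "|"),
                     pairCounts(sc)[["GC"]] + pairCounts(sc)[["AU"]])
    expect_identical(sum(sym == ":"),
                     pairCounts(sc)[["GU"]] + pairCounts(sc)[["AC"]])
    expect_identical(sum(sym == "."), pairCounts(sc)[["mismatch"]])
  }
})
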