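test_that("a planted perfect complement is found at its exact start", {
  set.seed(42)
  p <- randomRnaStr(28)
  tseq <- plantPerfect(randomRnaStr(1200), p, 500)
  ts <- makeTranscriptSet(c(G1 = tseq),
                          data.frame(gene_id = "G1", cds_start = 201,
                                     cds_end = 900))
  sites <- scanTargets(ts, c(p1 = p))
  expect_identical(length(sites), 1L)
  expect_identical(BiocGenerics::start(sites), 500L)
  expect_equal(S4Vectors::mcols(sites)$ratio, 100)
  expect_identical(S4Vectors::mcols(sites)$region, "CDS")

  # unsatisfiable threshold
  expect_identical(length(scanTargets(ts, c(p1 = p), minRatioPct = 101)), 0L)

  # transcript shorter than the piRNA: no sites, not an error
  short <- makeTranscriptSet(c(S = "ACGUACGUACGUACGU"),
                             data.frame(gene_id = "S", cds_start = 1,
                                        cds_end = 16))
  expect_identical(length(scanTargets(short, c(p1 = p))), 0L)
})

test_that("at threshold 0 without thinning every placement is scored", {
  set.seed(8)
  L <- 300L
  ts <- makeTranscriptSet(c(G = randomRnaStr(L)),
                          data.frame(gene_id = "G", cds_start = 100,
                                     cds_end = 200))
  pir <- c(a = randomRnaStr(24), b = randomRnaStr(31))
  sites <- scanTargets(ts, pir, minRatioPct = 0, suppressOverlaps = FALSE)
  tab <- table(S4Vectors::mcols(sites)$pirna_id)
  expect_identical(as.integer(tab[["a"]]), L - 24L + 1L)
  expect_identical(as.integer(tab[["b"]]), L - 31L + 1L)
})

test_that("scan output equals the exhaustive brute-force enumeration", {
  set.seed(2024)
  for (rep in 1:12) {
    L <- sample(120:220, 1)
    tseq <- randomRnaStr(L)
    pir <- stats::setNames(
      vapply(sample(18:30, 3, replace = TRUE), randomRnaStr, character(1)),
      paste0("p", 1:3))
    minRatio <- sample(c(0, 40, 60, 75), 1)
    ts <- makeTranscriptSet(c(G = tseq),
                            data.frame(gene_id = "G", cds_start = 10,
                                       cds_end = L - 10))
    got <- scanTargets(ts, pir, minRatioPct = minRatio,
                       suppressOverlaps = FALSE)
    mc <- S4Vectors::mcols(got)
    gdf <- data.frame(pirna_id = mc$pirna_id,
                      start = BiocGenerics::start(got),
                      dG = mc$dG, ratio = mc$ratio,
                      stringsAsFactors = FALSE)
    gdf <- gdf[order(gdf$pirna_id, gdf$start), , drop = FALSE]
    exp <- oracleScan(tseq, pir, minRatio)
    expect_identical(nrow(gdf), nrow(exp))
    expect_identical(gdf$pirna_id, exp$pirna_id)
    expect_identical(gdf$start, exp$start)
    expect_equal(gdf$dG, exp$dG, tolerance = 1e-12)
    expect_equal(gdf$ratio, exp$ratio, tolerance = 1e-12)

    # with thinning on, the survivors are the oracle's local maxima
    thinned <- scanTargets(ts, pir, minRatioPct = minRatio)
    tmc <- S4Vectors::mcols(thinned)
    for (pid in names(pir)) {
      mine <- BiocGenerics::start(thinned)[tmc$pirna_id == pid]
      ref <- oracleLocalMax(exp[exp$pirna_id == pid, , drop = FALSE],
                            nchar(pir[[pid]]))$start
      expect_identical(sort(mine), sort(as.integer(ref)))
    }
  }
})

test_that("sites are labelled by the region of their start position", {
  set.seed(3)
  ts <- makeTranscriptSet(c(G = randomRnaStr(1000)),
                          data.frame(gene_id = "G", cds_start = 189,
                                     cds_end = 700))
  expect_identical(regionOfPosition(ts, 108), "5UTR")   # 108 < 189
  expect_identical(regionOfPosition(ts, 188), "5UTR")
  expect_identical(regionOfPosition(ts, 189), "CDS")    # boundary inclusion
  expect_identical(regionOfPosition(ts, 700), "CDS")
  expect_identical(regionOfPosition(ts, 701), "3UTR")   # cds_end + 1
  expect_error(regionOfPosition(ts, 1001), "outside")

  sites <- makeSitesGR("G", c(100, 189, 690, 701), 26, letters[1:4])
  expect_identical(annotateRegion(sites, ts),
                   c("5UTR", "CDS", "CDS", "3UTR"))
})

test_that("competition prefers the greatest |dG|, with documented tie-breaks", {
  # overlapping pair: stronger binder wins
  s <- makeSitesGR("G", c(100, 110), 30, c("x", "y"), dG = c(183, 170))
  r <- resolveCompetition(s)
  expect_identical(S4Vectors::mcols(r)$preferred, c(TRUE, FALSE))

  # isolated site is trivially preferred
  s1 <- makeSitesGR("G", 400, 30, "z", dG = 90)
  expect_true(S4Vectors::mcols(resolveCompetition(s1))$preferred)

  # full tie: lexicographically smallest piRNA id wins, whatever the
  # input order
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    s3 <- makeSitesGR("G", c(100, 105, 110)[perm], 30,
                      c("pB", "pA", "pC")[perm], dG = 150)
    r3 <- resolveCompetition(s3)
    expect_identical(
      S4Vectors::mcols(r3)$pirna_id[S4Vectors::mcols(r3)$preferred], "pA")
  }

  # dG tie broken by ratio before id
  s2 <- makeSitesGR("G", c(100, 105), 30, c("pA", "pB"),
                    dG = c(150, 150), dGm = c(160, 150))
  r2 <- resolveCompetition(s2)
  expect_identical(
    S4Vectors::mcols(r2)$pirna_id[S4Vectors::mcols(r2)$preferred], "pB")

  # all sites are retained; one preferred per overlap component;
  # the operation is idempotent
  set.seed(77)
  big <- makeSitesGR("G", sample(1:2000, 40), 30, paste0("p", 1:40),
                     dG = round(runif(40, 80, 190), 2))
  r <- resolveCompetition(big)
  expect_identical(length(r), 40L)
  rr <- resolveCompetition(r)
  expect_identical(S4Vectors::mcols(rr)$preferred,
                   S4Vectors::mcols(r)$preferred)
  # each non-preferred site overlaps a preferred one transitively:
  # count components by a sweep and compare
  st <- sort(BiocGenerics::start(big))
  comps <- sum(diff(st) >= 30) + 1L  # width 30: a gap of >= 30 separates
  expect_identical(sum(S4Vectors::mcols(r)$preferred), comps)
})
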