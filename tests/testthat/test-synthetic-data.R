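test_that("generation is byte-deterministic given the seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeDataset(generateDataset(simulationConfig(seed = 11)), d1)
  writeDataset(generateDataset(simulationConfig(seed = 11)), d2)
  for (f in c("pirnas.fasta", "transcripts.fasta", "regions.tsv",
              "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)

  d3 <- withr::local_tempdir()
  writeDataset(generateDataset(simulationConfig(seed = 12)), d3)
  expect_false(identical(readLines(file.path(d1, "pirnas.fasta")),
                         readLines(file.path(d3, "pirnas.fasta"))))
})

test_that("adding a transcript does not reshuffle the others", {
  tr <- data.frame(gene_id = c("G1", "G2", "G3"),
                   length = c(2000L, 4000L, 6000L),
                   cds_start = c(201L, 301L, 501L),
                   cds_end = c(1400L, 2100L, 3500L))
  base <- generateDataset(simulationConfig(
    seed = 4, transcripts = tr, plants = NULL, clusterPlans = NULL,
    startGroupPlans = NULL, sharedRegionPlans = NULL))
  tr4 <- rbind(tr, data.frame(gene_id = "G4", length = 1500L,
                              cds_start = 101L, cds_end = 900L))
  ext <- generateDataset(simulationConfig(
    seed = 4, transcripts = tr4, plants = NULL, clusterPlans = NULL,
    startGroupPlans = NULL, sharedRegionPlans = NULL))
  expect_identical(
    as.character(transcriptSeqs(base$transcripts)),
    as.character(transcriptSeqs(ext$transcripts[c("G1", "G2", "G3")])))
})

test_that("truth-table energies equal an independent rescoring of the windows", {
  ds <- generateDataset(simulationConfig(seed = 21))
  seqs <- as.character(transcriptSeqs(ds$transcripts))
  pir <- as.character(ds$pirnas)
  for (i in seq_len(nrow(ds$truth))) {
    row <- ds$truth[i, ]
    win <- substr(seqs[[row$gene_id]], row$start, row$end)
    expect_equal(row$expected_dG,
                 oracleDuplexEnergy(win, pir[[row$pirna_id]]),
                 tolerance = 1e-12, info = paste(row$pirna_id, row$gene_id))
    expect_equal(row$expected_ratio,
                 100 * row$expected_dG / oracleDeltaGmax(pir[[row$pirna_id]]),
                 tolerance = 1e-12)
  }
  # planned pair degradations are realised exactly
  plants <- ds$truth[ds$truth$source == "plant", ]
  for (i in seq_len(nrow(plants))) {
    row <- plants[i, ]
    sc <- scoreDuplex(substr(seqs[[row$gene_id]], row$start, row$end),
                      pir[[row$pirna_id]])
    expect_identical(pairCounts(sc)[["GU"]], row$n_wobble)
    expect_identical(pairCounts(sc)[["AC"]], row$n_noncanonical)
    expect_identical(pairCounts(sc)[["mismatch"]], row$n_mismatch)
  }
})

test_that("wobble plants on G-C positions lose exactly (6.37 - 2.12) each", {
  # an all-G/C piRNA restricts wobble substitutions to G-C pairs
  pgc <- strrep("GC", 15)   # 30 nt, dGm = 30 * 6.37
  cfg <- simulationConfig(
    seed = 2, extraPirnas = c(pX = pgc),
    plants = data.frame(pirna_id = "pX", gene_id = "G1", start = 600L,
                        n_wobble = 2L, n_noncanonical = 0L,
                        n_mismatch = 0L),
    clusterPlans = NULL, startGroupPlans = NULL, sharedRegionPlans = NULL)
  ds <- generateDataset(cfg)
  row <- ds$truth[ds$truth$pirna_id == "pX", ]
  expect_equal(row$expected_dG, 30 * 6.37 - 2 * (6.37 - 2.12),
               tolerance = 1e-12)
  expect_equal(row$expected_ratio, 100 * row$expected_dG / (30 * 6.37),
               tolerance = 1e-12)
})

test_that("colliding plants and out-of-range plants are config errors", {
  bad <- simulationConfig(
    seed = 3,
    plants = data.frame(pirna_id = c("piR-0001", "piR-0002"),
                        gene_id = "G1", start = c(500L, 510L),
                        n_wobble = 0L, n_noncanonical = 0L,
                        n_mismatch = 0L),
    clusterPlans = NULL, startGroupPlans = NULL, sharedRegionPlans = NULL)
  expect_error(generateDataset(bad), "colliding")

  off <- simulationConfig(
    seed = 3,
    plants = data.frame(pirna_id = "piR-0001", gene_id = "G1",
                        start = 1995L, n_wobble = 0L,
                        n_noncanonical = 0L, n_mismatch = 0L),
    clusterPlans = NULL, startGroupPlans = NULL, sharedRegionPlans = NULL)
  expect_error(generateDataset(off), "outside transcript")
})

test_that("the full pipeline recovers exactly the above-threshold plants", {
  ds <- generateDataset(simulationConfig(seed = 31))
  sites <- scanTargets(ds$transcripts, ds$pirnas, minRatioPct = 90)
  keys <- siteKeys(sites)
  up <- ds$truth[ds$truth$expected_ratio >= 90, ]
  down <- ds$truth[ds$truth$expected_ratio < 90, ]
  expect_gt(nrow(up), 0)
  expect_gt(nrow(down), 0)   # the stated world includes a failing plant
  upKeys <- paste(up$pirna_id, up$gene_id, up$start)
  expect_true(all(upKeys %in% keys))
  # recovered energies are exact
  m <- match(upKeys, keys)
  expect_equal(S4Vectors::mcols(sites)$dG[m], up$expected_dG,
               tolerance = 1e-12)
  expect_false(any(paste(down$pirna_id, down$gene_id, down$start) %in% keys))
})

test_that("plant-free transcripts yield (almost) no sites at the 90% cutoff", {
  cfg <- simulationConfig(seed = 8, nPirnas = 40, plants = NULL,
                          clusterPlans = NULL, startGroupPlans = NULL,
                          sharedRegionPlans = NULL)
  ds <- generateDataset(cfg)
  sites <- scanTargets(ds$transcripts, ds$pirnas, minRatioPct = 90)
  nPlacements <- sum(vapply(
    BiocGenerics::width(transcriptSeqs(ds$transcripts)),
    function(L) sum(pmax(L - nchar(as.character(ds$pirnas)) + 1L, 0L)),
    numeric(1)))
  expect_lt(length(sites) / nPlacements, 1e-4)
})

test_that("start-group members are distinct piRNAs sharing one start", {
  ds <- generateDataset(simulationConfig(seed = 13))
  sg <- ds$truth[ds$truth$source == "start_group", ]
  expect_identical(length(unique(sg$start)), 1L)
  expect_identical(anyDuplicated(as.character(ds$pirnas[sg$pirna_id])), 0L)
  expect_true(all(sg$expected_ratio >= 90))
  sites <- scanTargets(ds$transcripts, ds$pirnas)
  g <- findStartGroups(sites, minGroup = 5)
  hit <- g[g$gene_id == sg$gene_id[1] & g$start == sg$start[1], ]
  expect_identical(nrow(hit), 1L)
  expect_true(all(sg$pirna_id %in% strsplit(hit$pirna_ids, ",")[[1]]))
})
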