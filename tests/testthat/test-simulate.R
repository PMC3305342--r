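test_that("configs are validated", {
  expect_error(simulationConfig("(A:1,B:1);", nTargets = 0), "zero proteins")
  expect_error(simulationConfig("(A:1,B:1);", edgeLossRate = -1), ">= 0")
  expect_error(simulationConfig("(A:1,(B:1,C:1,D:1):1);"), "binary")
  expect_error(simulationConfig("(A:1,B:1,C:1);"), "rooted|binary")
  cfg <- simulationConfig("(A:1,B:1);")
  expect_s3_class(cfg, "netrewire_config")
})

test_that("the no-event limit leaves every leaf equal to the ancestor", {
  cfg <- simulationConfig("((A:10,B:10):20,C:30);", nTargets = 40,
                          nClasses = 4, edgeDensity = 0.4, seed = 71)
  sim <- simulateNetworkEvolution(cfg)
  anc <- sort(paste(sim@ancestralEdges$class_id,
                    sim@ancestralEdges$target_protein))
  for (sp in names(sim@networks)) {
    genes <- sub(paste0("^", sp, "_"), "", sim@networks[[sp]]$target_protein)
    expect_equal(sort(paste(sim@networks[[sp]]$class_id, genes)), anc)
  }
  expect_equal(nrow(sim@events), 0)
})

test_that("pure-loss branches survive at the closed-form rate", {
  ll <- 0.01; t <- 50
  cfg <- simulationConfig(sprintf("(A:%d,B:0);", t), nTargets = 120,
                          nClasses = 10, edgeLossRate = ll,
                          edgeDensity = 0.5, seed = 72)
  sim <- simulateNetworkEvolution(cfg)
  anc <- paste(sim@ancestralEdges$class_id, sim@ancestralEdges$target_protein)
  expect_gte(length(anc), 500)
  leafA <- paste(sim@networks$A$class_id,
                 sub("^A_", "", sim@networks$A$target_protein))
  expect_true(all(leafA %in% anc))            # no gains possible
  pSurv <- exp(-ll * t)
  n <- length(anc)
  sdBin <- sqrt(n * pSurv * (1 - pSurv))
  expect_lt(abs(length(leafA) - n * pSurv), 3 * sdBin)
  # branch B has length zero: unchanged
  leafB <- paste(sim@networks$B$class_id,
                 sub("^B_", "", sim@networks$B$target_protein))
  expect_setequal(leafB, anc)
})

test_that("identical seeds give byte-identical fixture sets", {
  cfg <- simulationConfig("(A:20,B:20);", nTargets = 15, nClasses = 3,
                          proteinLength = 60, edgeGainRate = 0.002,
                          edgeLossRate = 0.002, substitutionRate = 0,
                          edgeDensity = 0.3, seed = 73)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  unlink(c(d1, d2), recursive = TRUE)
  writeFixtures(simulateNetworkEvolution(cfg), d1)
  writeFixtures(simulateNetworkEvolution(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # fixture set is complete
  expect_true(all(c("orthology.tsv", "species_tree.nwk", "events.tsv",
                    "manifest.json") %in% f1))
  expect_true(any(grepl("^proteomes/", f1)) && any(grepl("^pwms/", f1)) &&
                any(grepl("^tracks/", f1)) && any(grepl("^families/", f1)))
})

test_that("gene-static direct runs have identity orthology everywhere", {
  cfg <- simulationConfig("((A:5,B:5):5,C:10);", nTargets = 20,
                          nClasses = 3, edgeGainRate = 0.01,
                          edgeLossRate = 0.01, edgeDensity = 0.3, seed = 74)
  sim <- simulateNetworkEvolution(cfg)
  g <- orthoGroups(sim@orthology)
  tab <- table(g$orthogroup_id, g$species)
  expect_true(all(tab == 1))                 # one member per species
  expect_equal(length(unique(g$orthogroup_id)), 23)
  # every species has the same protein inventory (same genes)
  for (sp in c("A", "B", "C"))
    expect_equal(sum(g$species == sp), 23)
})

test_that("event-log replay reproduces every leaf network exactly", {
  cfg <- simulationConfig("(((A:8,B:8):10,C:18):10,D:28);", nTargets = 50,
                          nClasses = 5, edgeGainRate = 0.005,
                          edgeLossRate = 0.008, edgeDensity = 0.4,
                          seed = 75)
  sim <- simulateNetworkEvolution(cfg)
  expect_gt(nrow(sim@events), 0)
  rep <- replayEvents(sim)
  for (sp in names(rep)) {
    expect_setequal(
      paste(rep[[sp]]$domain_protein, rep[[sp]]$class_id,
            rep[[sp]]$target_protein),
      paste(sim@networks[[sp]]$domain_protein, sim@networks[[sp]]$class_id,
            sim@networks[[sp]]$target_protein))
  }
})

test_that("gene loss removes proteins and their interactions", {
  cfg <- simulationConfig("(A:40,B:40);", nTargets = 40, nClasses = 4,
                          geneLossRate = 0.004, edgeDensity = 0.5,
                          seed = 76)
  sim <- simulateNetworkEvolution(cfg)
  g <- orthoGroups(sim@orthology)
  lostA <- setdiff(unique(g$orthogroup_id),
                   g$orthogroup_id[g$species == "A"])
  expect_gt(length(lostA), 0)                # some genes died at this rate
  # no network edge touches a lost gene
  inA <- g$protein_id[g$species == "A"]
  expect_true(all(sim@networks$A$target_protein %in% inA))
  expect_true(all(sim@networks$A$domain_protein %in% inA))
  # gene events were logged
  expect_true(any(sim@events$type == "gene_loss"))
})

test_that("duplications create paralogs resolvable by the gene tree", {
  cfg <- simulationConfig("(A:60,B:60);", nTargets = 30, nClasses = 3,
                          geneGainRate = 0.004, edgeDensity = 0.4,
                          seed = 77)
  sim <- simulateNetworkEvolution(cfg)
  g <- orthoGroups(sim@orthology)
  counts <- table(g$orthogroup_id, g$species)
  expect_gt(max(counts), 1)                  # at least one paralog pair
  # constrained mapping still has at most one ortholog per species
  mp <- orthoMapping(sim@orthology)
  expect_false(anyDuplicated(paste(mp$ref_protein, mp$species)) > 0)
})

test_that("mechanistic proteomes embed recoverable consensus sites", {
  cfg <- simulationConfig("(A:1,B:1);", nTargets = 25, nClasses = 4,
                          proteinLength = 120, substitutionRate = 0,
                          edgeDensity = 0.2, mode = "mechanistic",
                          seed = 78)
  sim <- simulateNetworkEvolution(cfg)
  expect_length(sim@networks, 0)             # networks must be rediscovered
  ts <- sim@trueSites$A
  for (i in seq_len(nrow(ts))) {
    pwm <- sim@pwms[[ts$class_id[i]]]
    seqs <- as.character(sim@proteomes$A[[ts$target_protein[i]]])
    pep <- substr(seqs, ts$start[i] + 1, ts$end[i])
    expect_equal(scoreSite(pwm, pep), 1)     # consensus planted intact
  }
  # scanning + selection rebuilds exactly the true network (mu = 0)
  s <- scanProteome(sim@pwms, sim@proteomes$A, sim@tracks$A, species = "A")
  net <- buildNetwork(s, classMap = classMapFor(sim, "A"), topN = 5,
                      minAccessibility = 3, minDisorder = 0.6,
                      species = "A")
  expect_setequal(
    paste(edgeTable(net)$class_id, edgeTable(net)$target_protein),
    paste(ts$class_id, ts$target_protein))
})

test_that("substitutions erode planted sites over long branches", {
  cfg <- simulationConfig("(A:0,B:300);", nTargets = 25, nClasses = 4,
                          proteinLength = 120, substitutionRate = 0.002,
                          edgeDensity = 0.2, mode = "mechanistic",
                          seed = 79)
  sim <- simulateNetworkEvolution(cfg)
  ts <- sim@trueSites$B
  scores <- vapply(seq_len(nrow(ts)), function(i) {
    pwm <- sim@pwms[[ts$class_id[i]]]
    seqs <- as.character(sim@proteomes$B[[ts$target_protein[i]]])
    scoreSite(pwm, substr(seqs, ts$start[i] + 1, ts$end[i]))
  }, numeric(1))
  expect_lt(min(scores), 1)                  # some anchors mutated
  # reference species A (zero branch) keeps all sites intact
  tsA <- sim@trueSites$A
  scoresA <- vapply(seq_len(nrow(tsA)), function(i) {
    pwm <- sim@pwms[[tsA$class_id[i]]]
    seqs <- as.character(sim@proteomes$A[[tsA$target_protein[i]]])
    scoreSite(pwm, substr(seqs, tsA$start[i] + 1, tsA$end[i]))
  }, numeric(1))
  expect_true(all(scoresA == 1))
})

test_that("families from a simulation align one row per species", {
  cfg <- simulationConfig("(A:5,B:5);", nTargets = 10, nClasses = 2,
                          proteinLength = 50, mode = "mechanistic",
                          seed = 80)
  sim <- simulateNetworkEvolution(cfg)
  fams <- familiesFromSim(sim)
  expect_length(fams, 12)                    # targets + domain proteins
  for (f in fams[1:3]) {
    expect_setequal(names(msaRows(f)), c("A", "B"))
    expect_true(validObject(f))
  }
})
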