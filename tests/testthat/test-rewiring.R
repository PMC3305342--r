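test_that("global conservation is exact on identity and empty networks", {
  prots <- c(paste0("d", 1:3), paste0("t", 1:6))
  map <- identityOrthology(prots, c("sc", "sp"))
  edges <- edgeDf("d1", "c1", "t1", "d1", "c1", "t2", "d2", "c2", "t3",
                  "d3", "c3", "t4")
  ref <- networkFromEdges(edges, "sc", paste0("d", 1:3))
  same <- networkFromEdges(edges, "sp", paste0("d", 1:3))
  cc <- conservedGlobal(ref, same, map)
  expect_equal(cc$conserved, 4)
  expect_equal(cc$intChanges, 0)
  # empty partner network: every orthologous reference edge is lost
  empty <- networkFromEdges(edges[0, ], "sp", paste0("d", 1:3))
  cc0 <- conservedGlobal(ref, empty, map)
  expect_equal(cc0$lost, 4)
  expect_equal(cc0$gained, 0)
})

test_that("global conservation matches the brute-force double loop", {
  set.seed(41)
  for (rep in 1:5) {
    prots <- c(paste0("d", 1:3), paste0("t", 1:8))
    map <- identityOrthology(prots, c("sc", "sp"))
    mkEdges <- function(n) unique(data.frame(
      domain_protein = sample(paste0("d", 1:3), n, TRUE),
      class_id = sample(paste0("c", 1:3), n, TRUE),
      target_protein = sample(paste0("t", 1:8), n, TRUE),
      stringsAsFactors = FALSE))
    e1 <- mkEdges(10); e2 <- mkEdges(10)
    got <- conservedGlobal(networkFromEdges(e1, "sc"),
                           networkFromEdges(e2, "sp"), map)
    expect_identical(got[c("conserved", "gained", "lost")],
                     bruteGlobal(e1, e2, map, "sp")[
                       c("conserved", "gained", "lost")])
  }
})

test_that("one-to-many target orthology rescues global conservation", {
  groups <- data.frame(
    orthogroup_id = c("ogd", "ogd", "ogt", "ogt", "ogt"),
    species = c("sc", "sp", "sc", "sp", "sp"),
    protein_id = c("sc_d", "sp_d", "sc_t", "sp_t1", "sp_t2"),
    stringsAsFactors = FALSE)
  trees <- list(
    ogd = ape::read.tree(text = "(sc_d:0.1,sp_d:0.1);"),
    ogt = ape::read.tree(text = "(sc_t:0.1,(sp_t1:0.3,sp_t2:0.05):0.1);"))
  map <- orthologyMap(groups, trees, "sc")
  ref <- networkFromEdges(edgeDf("sc_d", "c1", "sc_t"), "sc", "sc_d")
  # edge present only on the paralog that is NOT the constrained ortholog
  oth <- networkFromEdges(edgeDf("sp_d", "c1", "sp_t1"), "sp", "sp_d")
  expect_equal(conservedGlobal(ref, oth, map)$conserved, 1)
})

test_that("local conservation respects the +/-10 residue window", {
  prots <- c("d1", "t1")
  map <- identityOrthology(prots, c("sc", "sp"))
  L <- 80
  seqs <- paste(rep("G", L), collapse = "")
  fam <- alignedFamily(c(sc = seqs, sp = seqs), "sc", "t1")
  mkNet <- function(sp, start) {
    sites <- data.frame(species = sp, target_protein = "t1",
                        class_id = "c1", start = start, end = start + 7,
                        peptide = "GGGGGGG", score = 0.9, disorder = 0.8,
                        accessibility = 5, domain_protein = "d1",
                        stringsAsFactors = FALSE)
    new("SpeciesNetwork", species = sp,
        edges = edgeDf("d1", "c1", "t1"), sites = sites,
        domainProteins = "d1")
  }
  ref <- mkNet("sc", 30)
  # site inside the window (start within [20, 47))
  expect_equal(conservedLocal(ref, mkNet("sp", 40),
                              list(t1 = fam), map)$conserved, 1)
  expect_equal(conservedLocal(ref, mkNet("sp", 46),
                              list(t1 = fam), map)$conserved, 1)
  # shifted beyond the window: lost (and the reverse-mapped site is a gain)
  cc <- conservedLocal(ref, mkNet("sp", 48), list(t1 = fam), map)
  expect_equal(cc$lost, 1)
  expect_equal(cc$gained, 1)
  # missing family: skipped with a warning
  expect_warning(
    ccm <- conservedLocal(ref, mkNet("sp", 30), list(), map),
    "missing family")
  expect_equal(ccm$skipped, 2)
  expect_equal(ccm$conserved + ccm$lost, 0)
})

test_that("local conservation never exceeds global on shared fixtures", {
  set.seed(43)
  cfg <- simulationConfig("(A:30,B:30);", nTargets = 25, nClasses = 4,
                          proteinLength = 120, substitutionRate = 0.003,
                          edgeDensity = 0.25, mode = "mechanistic", seed = 43)
  sim <- simulateNetworkEvolution(cfg)
  fams <- familiesFromSim(sim)
  mk <- function(sp) {
    s <- scanProteome(sim@pwms, sim@proteomes[[sp]], sim@tracks[[sp]],
                      species = sp)
    buildNetwork(s, classMap = classMapFor(sim, sp), topN = 7,
                 minAccessibility = 3, minDisorder = 0.6, species = sp)
  }
  a <- mk("A"); b <- mk("B")
  lc <- conservedLocal(a, b, fams, sim@orthology)
  gc <- conservedGlobal(a, b, sim@orthology)
  expect_lte(lc$conserved, gc$conserved)
})

test_that("protein-change counting follows ortholog existence", {
  groups <- data.frame(
    orthogroup_id = c("og1", "og1", "og2", "og2", "og3"),
    species = c("sc", "sp", "sc", "sp", "sc"),
    protein_id = c("sc_d", "sp_d", "sc_t1", "sp_t1", "sc_t2"),
    stringsAsFactors = FALSE)
  map <- new("OrthologyMap", reference = "sc", groups = groups,
             mapping = data.frame(ref_protein = character(),
                                  species = character(),
                                  ortholog = character(),
                                  distance = numeric()),
             geneTrees = list())
  edges <- edgeDf("sc_d", "c1", "sc_t1", "sc_d", "c1", "sc_t2")
  ref <- networkFromEdges(edges, "sc", "sc_d")
  cc <- countProteinChanges(ref, map, "sp")
  # sc_t2's gene (og3) is absent from sp: that edge is a protein change
  expect_equal(cc$conserved, 1)
  expect_equal(cc$lost, 1)
  # set-membership oracle over all edges
  present <- function(p) any(groups$species == "sp" &
    groups$orthogroup_id %in% groups$orthogroup_id[groups$protein_id == p])
  manual <- sum(!vapply(seq_len(nrow(edges)), function(i)
    present(edges$domain_protein[i]) && present(edges$target_protein[i]),
    logical(1)))
  expect_equal(cc$lost, manual)
})

test_that("the rate equation reproduces its worked examples exactly", {
  expect_equal(signif(changeRate(497, 21, 5096, 10), 3), 4.64e-4)
  expect_equal(signif(changeRate(1172, 15, 3247, 600), 3), 4.01e-5)
  expect_equal(changeRate(0, 10, 100, 5), 0)
  # linear in the numerator, inverse-linear in each denominator factor
  expect_equal(changeRate(20, 3, 50, 4), 2 * changeRate(10, 3, 50, 4))
  expect_equal(changeRate(10, 6, 50, 4), changeRate(10, 3, 50, 4) / 2)
  expect_error(changeRate(5, 0, 10, 10), "positive")
  expect_error(changeRate(5, 10, 10, 0), "positive")
})

test_that("degree-preserving randomization keeps all degrees", {
  set.seed(44)
  for (rep in 1:5) {
    edges <- unique(data.frame(
      domain_protein = sample(paste0("d", 1:4), 30, TRUE),
      class_id = sample(paste0("c", 1:4), 30, TRUE),
      target_protein = sample(paste0("t", 1:10), 30, TRUE),
      stringsAsFactors = FALSE))
    net <- networkFromEdges(edges, "sc")
    rnd <- randomizeNetwork(net, seed = rep)
    e2 <- edgeTable(rnd)
    expect_equal(nrow(e2), nrow(edges))
    expect_false(anyDuplicated(paste(e2$domain_protein, e2$class_id,
                                     e2$target_protein)) > 0)
    expect_equal(table(paste(e2$domain_protein, e2$class_id)),
                 table(paste(edges$domain_protein, edges$class_id)))
    expect_equal(table(e2$target_protein), table(edges$target_protein))
  }
  # single edge: nothing to swap
  one <- networkFromEdges(edgeDf("d1", "c1", "t1"), "sc")
  expect_equal(edgeTable(randomizeNetwork(one, seed = 1)),
               edgeTable(one))
})

test_that("constrained fixtures admit no swap: randomization is identity", {
  # degrees force the original matching: d1 -> {t1, t2}, d2 -> {t1}
  edges <- edgeDf("d1", "c", "t1", "d1", "c", "t2", "d2", "c", "t1")
  net <- networkFromEdges(edges, "sc")
  for (s in 1:5) {
    got <- edgeTable(randomizeNetwork(net, seed = s))
    expect_setequal(paste(got$domain_protein, got$class_id,
                          got$target_protein),
                    paste(edges$domain_protein, edges$class_id,
                          edges$target_protein))
  }
})

test_that("null-rate empirical p uses the add-one rank estimator", {
  # networks the swap cannot alter: nulls all equal the observed rate
  prots <- c("d1", "d2", "t1", "t2")
  map <- identityOrthology(prots, c("sc", "sp"))
  edges <- edgeDf("d1", "c", "t1", "d1", "c", "t2", "d2", "c", "t1")
  ref <- networkFromEdges(edges, "sc", c("d1", "d2"))
  oth <- networkFromEdges(edges, "sp", c("d1", "d2"))
  nt <- nullRateTest(ref, oth, map, divergenceTime = 10, nReps = 10,
                     seed = 2)
  expect_equal(nt$p, 1)
  expect_true(all(nt$replicates == nt$observed))
})

test_that("rate error bound is twice the false changes over the denominator", {
  expect_equal(estimateRateError(0, 0, 100), 0)
  expect_equal(signif(estimateRateError(50, 41, 21 * 5096 * 10), 3), 1.7e-4)
  expect_equal(estimateRateError(20, 10, 500),
               2 * estimateRateError(10, 5, 500))
  expect_error(estimateRateError(1, 1, 0), "positive")
})

test_that("expected observed changes follow the two-state chain", {
  expect_equal(expectedObservedChanges(0.1, 0.2, 0, 50, 200), 0)
  expect_equal(expectedObservedChanges(0, 0, 10, 50, 200), 0)
  # stationary limit
  lg <- 0.3; ll <- 0.1
  exp_inf <- 50 * (ll / (lg + ll)) + 150 * (lg / (lg + ll))
  expect_equal(expectedObservedChanges(lg, ll, 1e6, 50, 200), exp_inf,
               tolerance = 1e-10)
  # small-t first-order Taylor agreement within 1%
  for (t in c(0.001, 0.01, 0.03)) {
    lam <- 0.3
    exact <- expectedObservedChanges(lam, lam, t, 400, 1000)
    taylor <- t * (400 * lam + 600 * lam)
    expect_lt(abs(taylor - exact) / exact, 0.01)
  }
  expect_error(expectedObservedChanges(-1, 0, 1, 1, 2), ">= 0")
})

test_that("saturation curve tabulates rates by divergence", {
  set.seed(46)
  cfg <- simulationConfig("((A:5,B:5):45,C:50);", nTargets = 60,
                          nClasses = 6, edgeGainRate = 0.004,
                          edgeLossRate = 0.004, edgeDensity = 0.5,
                          seed = 46)
  sim <- simulateNetworkEvolution(cfg)
  nets <- simNetworks(sim)
  div <- c(B = 5, C = 50)
  tab <- saturationCurve(nets$A, nets[c("B", "C")], sim@orthology, div)
  expect_equal(tab$species, c("B", "C"))
  expect_true(all(tab$intChanges == tab$gained + tab$lost))
  expect_true(all(tab$rate > 0))
  # self-comparison has zero changes
  self <- saturationCurve(nets$A, list(A = nets$A), sim@orthology,
                          c(A = 1))
  expect_equal(self$intChanges, 0)
})
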