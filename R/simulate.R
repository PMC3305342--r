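#' @include AllClasses.R AllGenerics.R pwm.R network.R orthology.R
NULL

#' Configuration for a network-evolution simulation
#'
#' Bundles and validates the parameters of [simulateNetworkEvolution()].
#' Rates are per My; branch lengths of the species tree are interpreted as
#' millions of years. In `direct` mode interaction edges toggle as a
#' two-state Poisson process on the potential edge set (all domain proteins
#' x all target proteins); in `mechanistic` mode protein sequences evolve by
#' per-residue substitution and no networks are emitted — they must emerge
#' downstream by scanning the evolved proteomes.
#'
#' @param speciesTree newick string or `ape::phylo`; rooted, binary,
#'   >= 2 leaves, branch lengths in My.
#' @param nTargets number of target proteins (>= 1).
#' @param nClasses number of PWM classes; each class belongs to one
#'   domain-bearing protein.
#' @param proteinLength target protein length in residues.
#' @param pwmLength motif length in residues (short linear motifs,
#'   default 7).
#' @param edgeGainRate,edgeLossRate events per absent/existing potential
#'   edge per My (direct mode).
#' @param substitutionRate substitutions per residue per My (mechanistic
#'   mode).
#' @param geneGainRate,geneLossRate duplication/loss events per gene per My.
#' @param edgeDensity ancestral probability that a potential edge is
#'   present (direct mode) / fraction of targets planted with a site per
#'   class (mechanistic mode).
#' @param degreeCoupling logical; when TRUE (direct mode) each edge's loss
#'   hazard is divided by its target's ancestral in-degree, coupling
#'   retention to in-degree.
#' @param mode "direct" or "mechanistic".
#' @param seed integer; fully determines the simulation output.
#' @return A validated config list of class `netrewire_config`.
#' @export
simulationConfig <- function(speciesTree, nTargets = 100, nClasses = 10,
                             proteinLength = 150, pwmLength = 7,
                             edgeGainRate = 0, edgeLossRate = 0,
                             substitutionRate = 0,
                             geneGainRate = 0, geneLossRate = 0,
                             edgeDensity = 0.25, degreeCoupling = FALSE,
                             mode = c("direct", "mechanistic"), seed = 1) {
  mode <- match.arg(mode)
  if (is.character(speciesTree)) speciesTree <- ape::read.tree(text = speciesTree)
  if (!inherits(speciesTree, "phylo")) stop("speciesTree must be newick/phylo")
  if (length(speciesTree$tip.label) < 2L) stop("tree needs >= 2 leaves")
  if (!ape::is.rooted(speciesTree)) stop("tree must be rooted")
  if (!ape::is.binary(speciesTree)) stop("tree must be binary")
  if (is.null(speciesTree$edge.length)) stop("tree needs branch lengths")
  rates <- c(edgeGainRate, edgeLossRate, substitutionRate, geneGainRate,
             geneLossRate)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (nTargets < 1L) stop("zero proteins")
  if (nClasses < 1L) stop("need >= 1 PWM class")
  if (edgeDensity < 0 || edgeDensity > 1) stop("edgeDensity in [0, 1]")
  structure(list(
    speciesTree = speciesTree, nTargets = as.integer(nTargets),
    nClasses = as.integer(nClasses),
    proteinLength = as.integer(proteinLength),
    pwmLength = as.integer(pwmLength),
    edgeGainRate = edgeGainRate, edgeLossRate = edgeLossRate,
    substitutionRate = substitutionRate,
    geneGainRate = geneGainRate, geneLossRate = geneLossRate,
    edgeDensity = edgeDensity, degreeCoupling = degreeCoupling,
    mode = mode, seed = as.integer(seed)), class = "netrewire_config")
}

#' Expected observed edge differences under the two-state edge process
#'
#' Analytic oracle for the saturation phenomenon: under independent
#' two-state Markov edge dynamics with gain hazard \eqn{\lambda_g} and loss
#' hazard \eqn{\lambda_l}, the expected count of OBSERVED differences
#' between ancestor and descendant after time t (loss followed by regain
#' counts as conserved) is
#' \deqn{n_{edges} P_{10}(t) + (n_{potential} - n_{edges}) P_{01}(t)} with
#' the standard transition probabilities
#' \eqn{P_{10}(t) = \pi_{off} (1 - e^{-(\lambda_g+\lambda_l) t})},
#' \eqn{P_{01}(t) = \pi_{on} (1 - e^{-(\lambda_g+\lambda_l) t})}.
#'
#' @param edgeGainRate,edgeLossRate hazards per My (>= 0).
#' @param t elapsed time in My (>= 0).
#' @param nEdges edges present in the ancestor.
#' @param nPotential size of the potential edge set.
#' @return numeric expected count of observed differences.
#' @export
expectedObservedChanges <- function(edgeGainRate, edgeLossRate, t,
                                    nEdges, nPotential) {
  if (edgeGainRate < 0 || edgeLossRate < 0 || t < 0)
    stop("rates and t must be >= 0")
  r <- edgeGainRate + edgeLossRate
  if (r == 0 || t == 0) return(0)
  decay <- 1 - exp(-r * t)
  p10 <- (edgeLossRate / r) * decay
  p01 <- (edgeGainRate / r) * decay
  nEdges * p10 + (nPotential - nEdges) * p01
}

# ---- gene content evolution -------------------------------------------------

# Evolve one gene along the species tree with duplication/loss; returns
# leaves (species, protein_id), a newick gene tree and event rows.
.evolveGene <- function(gene, tree, gainRate, lossRate) {
  nTip <- length(tree$tip.label)
  root <- nTip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  leaves <- list()
  events <- list()
  copyCounter <- new.env()

  protId <- function(sp) {
    key <- sp
    k <- if (is.null(copyCounter[[key]])) 1L else copyCounter[[key]] + 1L
    copyCounter[[key]] <- k
    if (k == 1L) paste0(sp, "_", gene) else paste0(sp, "_", gene, ".", k)
  }
  logEv <- function(type, branch, time) {
    events[[length(events) + 1L]] <<- data.frame(
      type = type, branch = branch, time = time, class_id = NA_character_,
      target = NA_character_, gene = gene, stringsAsFactors = FALSE)
  }
  nodeLabel <- function(node) {
    if (node <= nTip) tree$tip.label[node] else paste0("n", node)
  }

  # descend from position `u` along species-tree edge row `e`;
  # returns NULL (extinct) or list(nwk, top) with `top` the branch length
  # from the query point to the subtree root.
  onEdge <- function(e, u) {
    len <- tree$edge.length[e]
    child <- tree$edge[e, 2L]
    tLoss <- if (lossRate > 0) stats::rexp(1L, lossRate) else Inf
    tDup <- if (gainRate > 0) stats::rexp(1L, gainRate) else Inf
    tEvt <- min(tLoss, tDup)
    if (u + tEvt < len) {
      if (tLoss <= tDup) {
        logEv("gene_loss", nodeLabel(child), u + tLoss)
        return(NULL)
      }
      logEv("gene_duplication", nodeLabel(child), u + tDup)
      a <- onEdge(e, u + tDup)
      b <- onEdge(e, u + tDup)
      return(.joinSubtrees(a, b, tEvt))
    }
    rem <- len - u
    if (child <= nTip) {
      sp <- tree$tip.label[child]
      pid <- protId(sp)
      leaves[[length(leaves) + 1L]] <<- data.frame(
        species = sp, protein_id = pid, stringsAsFactors = FALSE)
      return(list(nwk = pid, top = rem))
    }
    es <- kids[[as.character(child)]]
    a <- onEdge(es[1L], 0)
    b <- onEdge(es[2L], 0)
    .joinSubtrees(a, b, rem)
  }

  rootEdges <- kids[[as.character(root)]]
  a <- onEdge(rootEdges[1L], 0)
  b <- onEdge(rootEdges[2L], 0)
  res <- .joinSubtrees(a, b, 0)
  leavesDf <- if (length(leaves)) do.call(rbind, leaves) else
    data.frame(species = character(), protein_id = character())
  gt <- NULL
  if (!is.null(res) && nrow(leavesDf) > 0L) {
    nwk <- if (nrow(leavesDf) == 1L)
      paste0("(", res$nwk, ":", res$top, ");")
    else paste0(res$nwk, ";")
    gt <- ape::read.tree(text = nwk)
  }
  list(leaves = leavesDf, geneTree = gt,
       events = if (length(events)) do.call(rbind, events) else NULL)
}

.joinSubtrees <- function(a, b, top) {
  if (is.null(a) && is.null(b)) return(NULL)
  if (is.null(a)) return(list(nwk = b$nwk, top = top + b$top))
  if (is.null(b)) return(list(nwk = a$nwk, top = top + a$top))
  list(nwk = paste0("(", a$nwk, ":", a$top, ",", b$nwk, ":", b$top, ")"),
       top = top)
}

# Fast path for zero gene rates: every species keeps exactly one copy and
# the gene tree is the species tree with relabeled tips.
.staticGene <- function(gene, tree) {
  gt <- tree
  gt$tip.label <- paste0(tree$tip.label, "_", gene)
  list(leaves = data.frame(species = tree$tip.label,
                           protein_id = gt$tip.label,
                           stringsAsFactors = FALSE),
       geneTree = gt, events = NULL)
}

# ---- main simulator ---------------------------------------------------------

#' Forward-simulate network evolution along a species tree
#'
#' Generates a ground-truthed data set for the whole analysis stack. One
#' global RNG stream is seeded from `config$seed`; branches are processed
#' in preorder, so identical configs give byte-identical fixture sets.
#'
#' In `direct` mode the ancestral network is drawn at `edgeDensity` over
#' the potential edge set and every potential edge follows an independent
#' two-state jump process (gain hazard `edgeGainRate` on absent edges, loss
#' hazard `edgeLossRate` on present ones) down the tree, with every toggle
#' logged; leaf networks are the leaf states restricted to genes surviving
#' in that species. In `mechanistic` mode, PWMs with planted consensus
#' sites define the ancestral truth, sequences accumulate random
#' substitutions, and leaf networks are left to be rediscovered by
#' [scanProteome()] + [buildNetwork()].
#'
#' @param config a [simulationConfig()].
#' @return An [EvolvedNetworks-class].
#' @export
simulateNetworkEvolution <- function(config) {
  stopifnot(inherits(config, "netrewire_config"))
  withSeed(config$seed, .simulate(config))
}

.simulate <- function(cfg) {
  tree <- cfg$speciesTree
  nTip <- length(tree$tip.label)
  species <- tree$tip.label
  domGenes <- sprintf("dom%02d", seq_len(cfg$nClasses))
  tgtGenes <- sprintf("tgt%03d", seq_len(cfg$nTargets))
  classes <- sprintf("cls%02d", seq_len(cfg$nClasses))
  classMap <- data.frame(class_id = classes, domain_protein = domGenes,
                         stringsAsFactors = FALSE)
  genes <- c(domGenes, tgtGenes)

  # --- gene content + orthology ---
  static <- cfg$geneGainRate == 0 && cfg$geneLossRate == 0
  geneRes <- lapply(genes, function(g) {
    if (static) .staticGene(g, tree)
    else .evolveGene(g, tree, cfg$geneGainRate, cfg$geneLossRate)
  })
  names(geneRes) <- genes
  groups <- do.call(rbind, lapply(genes, function(g) {
    lv <- geneRes[[g]]$leaves
    if (!nrow(lv)) return(NULL)
    cbind(orthogroup_id = paste0("og_", g), lv)
  }))
  rownames(groups) <- NULL
  gTrees <- lapply(geneRes, function(x) x$geneTree)
  names(gTrees) <- paste0("og_", genes)
  gTrees <- gTrees[!vapply(gTrees, is.null, logical(1L))]
  geneEvents <- do.call(rbind, c(list(NULL),
                                 lapply(geneRes, function(x) x$events)))

  # gene presence per species (first copy carries the edges)
  presence <- lapply(species, function(sp) {
    lv <- groups[groups$species == sp, , drop = FALSE]
    base <- sub("^og_", "", lv$orthogroup_id)
    first <- !duplicated(base)
    stats::setNames(lv$protein_id[first], base[first])
  })
  names(presence) <- species

  # --- PWMs ---
  pwms <- lapply(seq_len(cfg$nClasses), function(k) {
    consensus <- paste(sample(AA20, cfg$pwmLength, replace = TRUE),
                       collapse = "")
    buildPWM(consensusCounts(consensus), classId = classes[k])
  })
  names(pwms) <- classes

  if (cfg$mode == "direct") {
    out <- .simulateDirect(cfg, tree, classMap, tgtGenes, presence)
    networks <- out$networks
    trueSites <- out$trueSites
    edgeEvents <- out$events
    ancestral <- out$ancestral
    proteomes <- .rootProteomes(cfg, tree, genes, presence, evolve = FALSE)
    tracks <- .flatTracks(proteomes)
  } else {
    mech <- .simulateMechanistic(cfg, tree, classMap, tgtGenes, pwms,
                                 presence, genes)
    networks <- list()
    trueSites <- mech$trueSites
    edgeEvents <- mech$events
    ancestral <- mech$ancestral
    proteomes <- mech$proteomes
    tracks <- mech$tracks
  }

  events <- do.call(rbind, c(list(NULL), list(geneEvents), list(edgeEvents)))
  if (is.null(events))
    events <- data.frame(type = character(), branch = character(),
                         time = numeric(), class_id = character(),
                         target = character(), gene = character())
  orth <- orthologyMap(groups, gTrees, reference = species[1L])
  new("EvolvedNetworks",
      config = unclass(cfg), tree = tree, mode = cfg$mode,
      networks = networks, trueSites = trueSites, orthology = orth,
      events = events, proteomes = proteomes, tracks = tracks, pwms = pwms,
      ancestralEdges = ancestral, classMap = classMap)
}

# two-state jump process for all potential edges along one branch
.evolveEdgesOnBranch <- function(state, gainRate, lossHaz, tLen, branch) {
  events <- list()
  for (i in seq_along(state)) {
    u <- 0
    s <- state[i]
    repeat {
      rate <- if (s) lossHaz[i] else gainRate
      if (rate <= 0) break
      dt <- stats::rexp(1L, rate)
      if (u + dt > tLen) break
      u <- u + dt
      s <- !s
      events[[length(events) + 1L]] <- c(i = i, time = u, gain = as.integer(s))
    }
    state[i] <- s
  }
  list(state = state,
       events = if (length(events)) do.call(rbind, events) else NULL,
       branch = branch)
}

.simulateDirect <- function(cfg, tree, classMap, tgtGenes, presence) {
  nTip <- length(tree$tip.label)
  classes <- classMap$class_id
  # potential edges: class k x target j, row-major over classes
  pot <- expand.grid(class_id = classes, target = tgtGenes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nPot <- nrow(pot)
  ancState <- stats::runif(nPot) < cfg$edgeDensity

  lossHaz <- rep(cfg$edgeLossRate, nPot)
  if (isTRUE(cfg$degreeCoupling)) {
    indeg <- tapply(ancState, pot$target, sum)[pot$target]
    lossHaz <- cfg$edgeLossRate / pmax(as.numeric(indeg), 1)
  }

  edgeOrd <- ape::reorder.phylo(tree, "cladewise")   # preorder edge walk
  states <- vector("list", nTip + tree$Nnode)
  root <- nTip + 1L
  states[[root]] <- ancState
  events <- list()
  for (r in seq_len(nrow(edgeOrd$edge))) {
    par <- edgeOrd$edge[r, 1L]
    chd <- edgeOrd$edge[r, 2L]
    lab <- if (chd <= nTip) tree$tip.label[chd] else paste0("n", chd)
    res <- .evolveEdgesOnBranch(states[[par]], cfg$edgeGainRate, lossHaz,
                                edgeOrd$edge.length[r], lab)
    states[[chd]] <- res$state
    if (!is.null(res$events)) {
      ev <- as.data.frame(res$events)
      events[[length(events) + 1L]] <- data.frame(
        type = ifelse(ev$gain == 1, "edge_gain", "edge_loss"),
        branch = lab, time = ev$time, class_id = pot$class_id[ev$i],
        target = pot$target[ev$i], gene = NA_character_,
        stringsAsFactors = FALSE)
    }
  }

  domOf <- stats::setNames(classMap$domain_protein, classMap$class_id)
  edgesAt <- function(state, sp) {
    idx <- which(state)
    pr <- presence[[sp]]
    d <- pr[domOf[pot$class_id[idx]]]
    t <- pr[pot$target[idx]]
    keep <- !is.na(d) & !is.na(t)
    data.frame(domain_protein = unname(d[keep]),
               class_id = pot$class_id[idx][keep],
               target_protein = unname(t[keep]), stringsAsFactors = FALSE)
  }
  networks <- lapply(seq_len(nTip), function(i)
    edgesAt(states[[i]], tree$tip.label[i]))
  names(networks) <- tree$tip.label
  ancestral <- data.frame(domain_protein = domOf[pot$class_id[ancState]],
                          class_id = pot$class_id[ancState],
                          target_protein = pot$target[ancState],
                          stringsAsFactors = FALSE)
  rownames(ancestral) <- NULL
  list(networks = networks, trueSites = list(),
       events = if (length(events)) do.call(rbind, events) else NULL,
       ancestral = ancestral)
}

.rootProteomes <- function(cfg, tree, genes, presence, evolve) {
  rootSeq <- vapply(genes, function(g)
    paste(sample(AA20, cfg$proteinLength, replace = TRUE), collapse = ""),
    character(1L))
  lapply(stats::setNames(tree$tip.label, tree$tip.label), function(sp) {
    pr <- presence[[sp]]
    s <- Biostrings::AAStringSet(rootSeq[names(pr)])
    names(s) <- unname(pr)
    s
  })
}

.flatTracks <- function(proteomes) {
  lapply(proteomes, function(ps) {
    stats::setNames(lapply(seq_along(ps), function(i) {
      L <- Biostrings::width(ps)[i]
      list(disorder = rep(0.9, L), accessibility = rep(5, L))
    }), names(ps))
  })
}

.simulateMechanistic <- function(cfg, tree, classMap, tgtGenes, pwms,
                                 presence, genes) {
  nTip <- length(tree$tip.label)
  L <- cfg$proteinLength
  nC <- cfg$pwmLength
  classes <- classMap$class_id

  # ancestral sequences
  rootSeqs <- lapply(stats::setNames(genes, genes), function(g)
    sample(AA20, L, replace = TRUE))

  # plant sites: per class, edgeDensity * nTargets targets get the consensus
  nPerClass <- max(1L, round(cfg$edgeDensity * cfg$nTargets))
  slotStarts <- seq(3L, L - nC - 2L, by = nC + 8L)   # 0-based, non-overlapping
  sites <- list()
  slotUse <- stats::setNames(rep(0L, length(tgtGenes)), tgtGenes)
  for (k in seq_along(classes)) {
    cons <- strsplit(consensusSeq(pwms[[k]]), "", fixed = TRUE)[[1L]]
    open <- names(slotUse)[slotUse < length(slotStarts)]
    pick <- sample(open, min(nPerClass, length(open)))
    for (g in pick) {
      slotUse[g] <- slotUse[g] + 1L
      st <- slotStarts[slotUse[g]]
      rootSeqs[[g]][(st + 1L):(st + nC)] <- cons
      sites[[length(sites) + 1L]] <- data.frame(
        class_id = classes[k], target = g, start = st, end = st + nC,
        stringsAsFactors = FALSE)
    }
  }
  siteTab <- do.call(rbind, sites)

  # tracks: disordered accessible stretches around planted sites, drawn once
  trackOf <- lapply(stats::setNames(genes, genes), function(g) {
    dis <- stats::runif(L, 0, 0.55)
    acc <- stats::runif(L, 0, 3.0)
    gs <- siteTab[siteTab$target == g, , drop = FALSE]
    for (j in seq_len(nrow(gs))) {
      span <- max(1L, gs$start[j] - 2L):min(L, gs$end[j] + 3L)
      dis[span] <- stats::runif(length(span), 0.7, 1)
      acc[span] <- stats::runif(length(span), 4, 8)
    }
    list(disorder = dis, accessibility = acc)
  })

  # evolve sequences down the tree (preorder), uniform substitutions
  edgeOrd <- ape::reorder.phylo(tree, "cladewise")
  seqStates <- vector("list", nTip + tree$Nnode)
  root <- nTip + 1L
  seqStates[[root]] <- rootSeqs
  events <- list()
  mu <- cfg$substitutionRate
  for (r in seq_len(nrow(edgeOrd$edge))) {
    par <- edgeOrd$edge[r, 1L]
    chd <- edgeOrd$edge[r, 2L]
    lab <- if (chd <= nTip) tree$tip.label[chd] else paste0("n", chd)
    tLen <- edgeOrd$edge.length[r]
    cur <- seqStates[[par]]
    if (mu > 0 && tLen > 0) {
      for (g in names(cur)) {
        nSub <- stats::rpois(1L, mu * tLen * L)
        if (nSub > 0L) {
          posns <- sample.int(L, nSub, replace = TRUE)
          for (p in posns)
            cur[[g]][p] <- sample(setdiff(AA20, cur[[g]][p]), 1L)
          events[[length(events) + 1L]] <- data.frame(
            type = "substitutions", branch = lab, time = NA_real_,
            class_id = NA_character_, target = NA_character_, gene = g,
            stringsAsFactors = FALSE)
        }
      }
    }
    seqStates[[chd]] <- cur
  }

  proteomes <- lapply(seq_len(nTip), function(i) {
    sp <- tree$tip.label[i]
    pr <- presence[[sp]]
    s <- Biostrings::AAStringSet(vapply(names(pr), function(g)
      paste(seqStates[[i]][[g]], collapse = ""), character(1L)))
    names(s) <- unname(pr)
    s
  })
  names(proteomes) <- tree$tip.label

  tracks <- lapply(tree$tip.label, function(sp) {
    pr <- presence[[sp]]
    stats::setNames(lapply(names(pr), function(g) trackOf[[g]]),
                    unname(pr))
  })
  names(tracks) <- tree$tip.label

  domOf <- stats::setNames(classMap$domain_protein, classMap$class_id)
  ancestral <- data.frame(domain_protein = unname(domOf[siteTab$class_id]),
                          class_id = siteTab$class_id,
                          target_protein = siteTab$target,
                          stringsAsFactors = FALSE)
  trueSites <- lapply(stats::setNames(tree$tip.label, tree$tip.label),
                      function(sp) {
    pr <- presence[[sp]]
    st <- siteTab[siteTab$target %in% names(pr), , drop = FALSE]
    st$target_protein <- unname(pr[st$target])
    st
  })
  list(proteomes = proteomes, tracks = tracks, trueSites = trueSites,
       events = if (length(events)) do.call(rbind, events) else NULL,
       ancestral = ancestral)
}

# ---- ground-truth helpers ---------------------------------------------------

#' Replay the event log of a direct-mode simulation
#'
#' Reconstructs each leaf network from the ancestral edge set by applying
#' the logged gain/loss events along the root-to-leaf path in time order,
#' then restricting to genes present in the species — the leaf networks of
#' the simulation must be reproduced exactly.
#'
#' @param sim an [EvolvedNetworks-class] in direct mode.
#' @return named list of edge data.frames, one per species.
#' @export
replayEvents <- function(sim) {
  stopifnot(sim@mode == "direct")
  tree <- sim@tree
  nTip <- length(tree$tip.label)
  cfg <- sim@config
  classes <- sim@classMap$class_id
  tgtGenes <- sprintf("tgt%03d", seq_len(cfg$nTargets))
  pot <- expand.grid(class_id = classes, target = tgtGenes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  potKey <- paste(pot$class_id, pot$target)
  # ancestralEdges target ids are gene names in direct mode
  anc <- potKey %in% paste(sim@ancestralEdges$class_id,
                           sim@ancestralEdges$target_protein)
  ev <- sim@events[sim@events$type %in% c("edge_gain", "edge_loss"), ,
                   drop = FALSE]
  domOf <- stats::setNames(sim@classMap$domain_protein, sim@classMap$class_id)

  pathTo <- function(leaf) {
    # node labels of branches from root to leaf, in order
    labs <- character()
    node <- leaf
    repeat {
      r <- which(tree$edge[, 2L] == node)
      if (!length(r)) break
      labs <- c(if (node <= nTip) tree$tip.label[node] else paste0("n", node),
                labs)
      node <- tree$edge[r, 1L]
    }
    labs
  }
  groups <- sim@orthology@groups
  out <- lapply(seq_len(nTip), function(i) {
    sp <- tree$tip.label[i]
    state <- anc
    for (lab in pathTo(i)) {
      be <- ev[ev$branch == lab, , drop = FALSE]
      be <- be[order(be$time), , drop = FALSE]
      for (j in seq_len(nrow(be))) {
        idx <- match(paste(be$class_id[j], be$target[j]), potKey)
        state[idx] <- be$type[j] == "edge_gain"
      }
    }
    lv <- groups[groups$species == sp, , drop = FALSE]
    base <- sub("^og_", "", lv$orthogroup_id)
    pr <- stats::setNames(lv$protein_id[!duplicated(base)],
                          base[!duplicated(base)])
    idx <- which(state)
    d <- pr[unname(domOf[pot$class_id[idx]])]
    t <- pr[pot$target[idx]]
    keep <- !is.na(d) & !is.na(t)
    data.frame(domain_protein = unname(d[keep]),
               class_id = pot$class_id[idx][keep],
               target_protein = unname(t[keep]), stringsAsFactors = FALSE)
  })
  names(out) <- tree$tip.label
  out
}

#' Per-family alignments from a simulation
#'
#' Builds one [AlignedFamily-class] per reference target protein from the
#' simulated proteomes. With indels disabled (the default and only mode)
#' sequences are equal-length, so the alignment is exact by construction.
#'
#' @param sim an [EvolvedNetworks-class].
#' @param reference reference species; default the orthology map's.
#' @return named list of [AlignedFamily-class], keyed by reference protein
#'   id.
#' @export
familiesFromSim <- function(sim, reference = refSpecies(sim@orthology)) {
  map <- sim@orthology
  g <- map@groups
  refProts <- g$protein_id[g$species == reference]
  fams <- lapply(refProts, function(rp) {
    mp <- map@mapping[map@mapping$ref_protein == rp, , drop = FALSE]
    seqs <- vapply(seq_len(nrow(mp)), function(i) {
      ps <- sim@proteomes[[mp$species[i]]]
      as.character(ps[[mp$ortholog[i]]])
    }, character(1L))
    names(seqs) <- mp$species
    alignedFamily(seqs, reference = reference, familyId = rp,
                  proteins = stats::setNames(mp$ortholog, mp$species))
  })
  names(fams) <- refProts
  fams
}

#' Species-local class map of a simulation
#'
#' Maps each PWM class to the given species' protein id of its
#' domain-bearing gene (classes whose domain gene was lost in the species
#' are dropped), for use as the `classMap` of [buildNetwork()].
#'
#' @param sim an [EvolvedNetworks-class].
#' @param species species id.
#' @return data.frame with columns `class_id`, `domain_protein`.
#' @export
classMapFor <- function(sim, species) {
  g <- sim@orthology@groups
  lv <- g[g$species == species, , drop = FALSE]
  base <- sub("^og_", "", lv$orthogroup_id)
  pr <- stats::setNames(lv$protein_id[!duplicated(base)],
                        base[!duplicated(base)])
  cm <- sim@classMap
  cm$domain_protein <- unname(pr[cm$domain_protein])
  cm[!is.na(cm$domain_protein), , drop = FALSE]
}

#' Networks of a simulation as SpeciesNetwork objects
#'
#' @param sim a direct-mode [EvolvedNetworks-class].
#' @return named list of [SpeciesNetwork-class].
#' @export
simNetworks <- function(sim) {
  stopifnot(sim@mode == "direct")
  out <- lapply(names(sim@networks), function(sp) {
    pr <- sim@proteomes[[sp]]
    doms <- names(pr)[grepl("_dom", names(pr))]
    networkFromEdges(sim@networks[[sp]], species = sp, domainProteins = doms)
  })
  names(out) <- names(sim@networks)
  out
}

# ---- fixture emission -------------------------------------------------------

#' Write the on-disk fixture set of a simulation
#'
#' Emits FASTA proteomes, per-residue track TSVs, the orthology TSV,
#' per-orthogroup newick gene trees, aligned FASTA per family, the species
#' tree, PWM TSVs, direct-mode network TSVs, the true-site table, the event
#' log and a JSON manifest, under `dir/`.
#'
#' @param sim an [EvolvedNetworks-class].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writeFixtures <- function(sim, dir) {
  mk <- function(...) {
    p <- file.path(dir, ...)
    dir.create(p, showWarnings = FALSE, recursive = TRUE)
    p
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pd <- mk("proteomes")
  for (sp in names(sim@proteomes))
    Biostrings::writeXStringSet(sim@proteomes[[sp]],
                                file.path(pd, paste0(sp, ".fasta")))
  td <- mk("tracks")
  for (sp in names(sim@tracks)) {
    tr <- sim@tracks[[sp]]
    tab <- do.call(rbind, lapply(names(tr), function(p) data.frame(
      protein_id = p, position = seq_along(tr[[p]]$disorder),
      disorder = tr[[p]]$disorder, accessibility = tr[[p]]$accessibility)))
    utils::write.table(tab, file.path(td, paste0(sp, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  writeOrthologyTable(sim@orthology@groups, file.path(dir, "orthology.tsv"))
  writeGeneTrees(sim@orthology@geneTrees, mk("genetrees"))
  ape::write.tree(sim@tree, file.path(dir, "species_tree.nwk"))
  wd <- mk("pwms")
  for (p in sim@pwms) writePWM(p, file.path(wd, paste0(classId(p), ".tsv")))
  fd <- mk("families")
  fams <- familiesFromSim(sim)
  for (f in fams) {
    s <- Biostrings::AAStringSet(f@msa)
    names(s) <- paste0(f@proteins[names(f@msa)])
    Biostrings::writeXStringSet(s, file.path(fd, paste0(f@familyId, ".fasta")))
  }
  if (sim@mode == "direct") {
    nd <- mk("networks")
    for (sp in names(sim@networks))
      utils::write.table(sim@networks[[sp]],
                         file.path(nd, paste0(sp, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  if (length(sim@trueSites)) {
    ts <- do.call(rbind, lapply(names(sim@trueSites), function(sp)
      cbind(species = sp, sim@trueSites[[sp]])))
    utils::write.table(ts, file.path(dir, "true_sites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(sim@events, file.path(dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    mode = sim@mode, seed = sim@config$seed,
    species = sim@tree$tip.label,
    nClasses = sim@config$nClasses, nTargets = sim@config$nTargets,
    nEvents = nrow(sim@events))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
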