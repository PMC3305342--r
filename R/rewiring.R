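#' @include AllClasses.R AllGenerics.R network.R orthology.R
NULL

.changeCount <- function(conserved, gained, lost, skipped = 0L) {
  list(conserved = conserved, gained = gained, lost = lost,
       intChanges = gained + lost, skipped = skipped)
}

#' Conserved vs changed interactions under the global criterion
#'
#' A reference edge (d, c, t) is conserved if any ortholog of the target t
#' (one-to-one or one-to-many orthology) is a target of (ortholog of d, c)
#' in the other species' network; otherwise it is lost. Gains are
#' other-species edges whose domain is the image of a reference domain
#' protein and whose target has at least one reference ortholog, with no
#' reference counterpart. Reference edges whose endpoints have no ortholog
#' at all are excluded from the rewiring counts (they belong to the
#' protein-change mechanism) and reported as `skipped`.
#'
#' @param refNet,otherNet [SpeciesNetwork-class] objects; `refNet` belongs
#'   to the orthology map's reference species.
#' @param map an [OrthologyMap-class] (domain-filtered where appropriate).
#' @return list with `conserved`, `gained`, `lost`, `intChanges`, `skipped`.
#' @export
conservedGlobal <- function(refNet, otherNet, map) {
  sp <- otherNet@species
  refEdges <- refNet@edges
  othKeys <- .edgeKey(otherNet@edges)

  doms <- unique(refEdges$domain_protein)
  dImage <- mappedOrtholog(map, doms, sp)
  names(dImage) <- doms

  conserved <- lost <- skipped <- 0L
  consKeysRef <- character(0)            # reverse lookup for gain counting
  for (i in seq_len(nrow(refEdges))) {
    d <- refEdges$domain_protein[i]
    cl <- refEdges$class_id[i]
    t <- refEdges$target_protein[i]
    dd <- dImage[[d]]
    tOrth <- orthologsOf(map, t, sp)
    if (is.na(dd) || !length(tOrth)) {
      skipped <- skipped + 1L
      next
    }
    hit <- paste(dd, cl, tOrth, sep = "\r") %in% othKeys
    if (any(hit)) conserved <- conserved + 1L else lost <- lost + 1L
  }

  # gains: other-species edges on orthologous proteins with no ref counterpart
  refKeys <- .edgeKey(refEdges)
  refSp <- map@reference
  preimage <- split(names(dImage), dImage)   # ortholog -> ref domain(s)
  gained <- 0L
  oe <- otherNet@edges
  for (i in seq_len(nrow(oe))) {
    d2 <- oe$domain_protein[i]
    cl <- oe$class_id[i]
    t2 <- oe$target_protein[i]
    dPre <- preimage[[d2]]
    if (is.null(dPre)) next
    tPre <- orthologsOf(map, t2, refSp)
    if (!length(tPre)) next
    cand <- as.vector(outer(dPre, tPre, function(a, b)
      paste(a, cl, b, sep = "\r")))
    if (!any(cand %in% refKeys)) gained <- gained + 1L
  }
  .changeCount(conserved, gained, lost, skipped)
}

#' Conserved vs changed interactions under the local (binding-site) criterion
#'
#' A reference edge is conserved if the other species' network contains an
#' accepted site of the same PWM class, on the constrained target ortholog,
#' whose start coordinate falls inside the window obtained by mapping the
#' reference site plus `flank` residues on each side through the family
#' alignment. Gains are counted symmetrically: other-species edges on
#' constrained-orthologous endpoints none of whose sites map back onto a
#' reference site window of the same class. Edges whose target family MSA is
#' missing are skipped with a warning.
#'
#' @param refNet,otherNet [SpeciesNetwork-class] objects with site tables.
#' @param families named list of [AlignedFamily-class], keyed by reference
#'   target protein id.
#' @param map the constrained [OrthologyMap-class].
#' @param flank residues added on each side of the site window (default 10).
#' @return list with `conserved`, `gained`, `lost`, `intChanges`, `skipped`.
#' @export
conservedLocal <- function(refNet, otherNet, families, map, flank = 10) {
  sp <- otherNet@species
  refSp <- map@reference
  refEdges <- refNet@edges
  refSites <- refNet@sites
  othSites <- otherNet@sites

  doms <- unique(c(refEdges$domain_protein, refNet@domainProteins))
  dImage <- mappedOrtholog(map, doms, sp)
  names(dImage) <- doms

  conserved <- lost <- skippedFam <- skippedOrth <- 0L
  for (i in seq_len(nrow(refEdges))) {
    d <- refEdges$domain_protein[i]
    cl <- refEdges$class_id[i]
    t <- refEdges$target_protein[i]
    dd <- dImage[[d]]
    tt <- mappedOrtholog(map, t, sp)
    if (is.na(dd) || is.na(tt)) {
      skippedOrth <- skippedOrth + 1L
      next
    }
    fam <- families[[t]]
    if (is.null(fam) || !(sp %in% names(fam@msa))) {
      skippedFam <- skippedFam + 1L
      next
    }
    es <- refSites[refSites$domain_protein == d & refSites$class_id == cl &
                     refSites$target_protein == t, , drop = FALSE]
    os <- othSites[othSites$class_id == cl &
                     othSites$target_protein == tt, , drop = FALSE]
    ok <- FALSE
    for (j in seq_len(nrow(es))) {
      win <- mapWindow(fam, es$start[j], es$end[j], flank)
      w <- win[win$species == sp, , drop = FALSE]
      if (nrow(os) && any(os$start >= w$start & os$start < w$end)) {
        ok <- TRUE
        break
      }
    }
    if (ok) conserved <- conserved + 1L else lost <- lost + 1L
  }

  # gains: map other-species sites back onto the reference row
  preimageD <- split(names(dImage), dImage)
  tmap <- map@mapping[map@mapping$species == sp, , drop = FALSE]
  preimageT <- split(tmap$ref_protein, tmap$ortholog)
  gained <- 0L
  oe <- otherNet@edges
  for (i in seq_len(nrow(oe))) {
    d2 <- oe$domain_protein[i]
    cl <- oe$class_id[i]
    t2 <- oe$target_protein[i]
    dPre <- preimageD[[d2]]
    tPre <- preimageT[[t2]]
    if (is.null(dPre) || is.null(tPre)) next
    matched <- FALSE
    famMissing <- TRUE
    for (t in tPre) {
      fam <- families[[t]]
      if (is.null(fam) || !(sp %in% names(fam@msa))) next
      famMissing <- FALSE
      os <- othSites[othSites$domain_protein == d2 & othSites$class_id == cl &
                       othSites$target_protein == t2, , drop = FALSE]
      rs <- refSites[refSites$class_id == cl &
                       refSites$target_protein == t, , drop = FALSE]
      for (j in seq_len(nrow(os))) {
        win <- mapWindow(fam, os$start[j], os$end[j], flank, species = sp)
        w <- win[win$species == refSp, , drop = FALSE]
        if (nrow(rs) && any(rs$start >= w$start & rs$start < w$end)) {
          matched <- TRUE
          break
        }
      }
      if (matched) break
    }
    if (famMissing) {
      skippedFam <- skippedFam + 1L
    } else if (!matched) {
      gained <- gained + 1L
    }
  }
  if (skippedFam > 0L)
    warning(skippedFam, " edge(s) skipped: missing family MSA")
  .changeCount(conserved, gained, lost, skippedOrth + skippedFam)
}

#' Interaction changes due to gene gain/loss (protein change)
#'
#' Under the protein-change mechanism an interaction is conserved purely on
#' the existence of orthologs: a reference edge counts as changed if either
#' endpoint has no ortholog (one-to-many) in the other species.
#'
#' @param refNet a [SpeciesNetwork-class].
#' @param map an [OrthologyMap-class].
#' @param species the other species.
#' @return list with `conserved`, `gained`, `lost`, `intChanges`, `skipped`.
#' @export
countProteinChanges <- function(refNet, map, species) {
  refEdges <- refNet@edges
  conserved <- lost <- 0L
  hasOrth <- function(p) length(orthologsOf(map, p, species)) > 0L
  prots <- unique(c(refEdges$domain_protein, refEdges$target_protein))
  ok <- vapply(prots, hasOrth, logical(1L))
  names(ok) <- prots
  for (i in seq_len(nrow(refEdges))) {
    if (ok[[refEdges$domain_protein[i]]] && ok[[refEdges$target_protein[i]]])
      conserved <- conserved + 1L
    else lost <- lost + 1L
  }
  .changeCount(conserved, 0L, lost)
}

#' Normalized interaction change rate
#'
#' \deqn{rate = \frac{intChanges}{orthDomainProteins \times orthProteins
#' \times divergenceTime}} — the fraction of observed interaction changes
#' over all possible interactions among proteins with orthologs, per million
#' years.
#'
#' @param intChanges number of gained plus lost interactions.
#' @param orthDomainProteins number of orthologous domain-bearing proteins
#'   shared by the species pair.
#' @param orthProteins number of orthologous proteins shared by the pair.
#' @param divergenceTime millions of years since the last common ancestor.
#' @return numeric rate (interaction changes per protein pair per My).
#' @export
#' @examples
#' changeRate(497, 21, 5096, 10)   # 4.64e-4
changeRate <- function(intChanges, orthDomainProteins, orthProteins,
                       divergenceTime) {
  if (orthDomainProteins <= 0 || orthProteins <= 0 || divergenceTime <= 0)
    stop("denominator terms must be positive")
  if (intChanges < 0) stop("intChanges must be >= 0")
  intChanges / (orthDomainProteins * orthProteins * divergenceTime)
}

#' Ortholog counts entering the rate denominator
#'
#' `orthDomainProteins` counts reference domain proteins with a constrained
#' (and domain-filtered) ortholog in the other species; `orthProteins`
#' counts reference proteins with at least one ortholog there.
#'
#' @param map an [OrthologyMap-class].
#' @param species the partner species.
#' @param domainProteins the reference species' domain-bearing proteins.
#' @return list with `orthDomainProteins`, `orthProteins`.
#' @export
orthologCounts <- function(map, species, domainProteins) {
  mp <- map@mapping[map@mapping$species == species, , drop = FALSE]
  g <- map@groups
  refProts <- unique(g$protein_id[g$species == map@reference])
  ogHasSp <- unique(g$orthogroup_id[g$species == species])
  withOrth <- unique(g$protein_id[g$species == map@reference &
                                    g$orthogroup_id %in% ogHasSp])
  list(
    orthDomainProteins = sum(domainProteins %in% mp$ref_protein),
    orthProteins = length(withOrth)
  )
}

#' Change counts and rates against a reference across species
#'
#' Runs the chosen conservation criterion for every species network against
#' the reference and tabulates the change counts and normalized rates by
#' divergence time (the saturation-curve view).
#'
#' @param refNet the reference [SpeciesNetwork-class].
#' @param networks named list of other-species [SpeciesNetwork-class]
#'   objects.
#' @param map an [OrthologyMap-class].
#' @param divergences named numeric vector, species -> My since the last
#'   common ancestor with the reference.
#' @param mode "global", "local" or "protein".
#' @param families required for `mode = "local"`.
#' @param flank window flank for local mode.
#' @return data.frame sorted by divergence with columns `species`,
#'   `divergence`, `conserved`, `gained`, `lost`, `intChanges`,
#'   `orthDomainProteins`, `orthProteins`, `rate`.
#' @export
saturationCurve <- function(refNet, networks, map, divergences,
                            mode = c("global", "local", "protein"),
                            families = NULL, flank = 10) {
  mode <- match.arg(mode)
  if (length(networks) < 1L) stop("need >= 1 comparison network")
  rows <- lapply(names(networks), function(sp) {
    cc <- switch(mode,
      global = conservedGlobal(refNet, networks[[sp]], map),
      local = conservedLocal(refNet, networks[[sp]], families, map, flank),
      protein = countProteinChanges(refNet, map, sp))
    oc <- orthologCounts(map, sp, refNet@domainProteins)
    data.frame(species = sp, divergence = divergences[[sp]],
               conserved = cc$conserved, gained = cc$gained, lost = cc$lost,
               intChanges = cc$intChanges,
               orthDomainProteins = oc$orthDomainProteins,
               orthProteins = oc$orthProteins,
               rate = changeRate(cc$intChanges, oc$orthDomainProteins,
                                 oc$orthProteins, divergences[[sp]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$divergence), , drop = FALSE]
}

#' Degree-preserving network randomization
#'
#' Double-edge swaps on the bipartite (domain, class) -> target graph: two
#' edges exchange their targets. Every (domain, class) keeps its out-degree
#' and every target its in-degree; swaps that would create a duplicate edge
#' are rejected. Networks with fewer than two edges are returned unchanged.
#'
#' @param net a [SpeciesNetwork-class].
#' @param nSwapAttempts number of attempted swaps (default 100 x edges).
#' @param seed integer RNG seed.
#' @return The randomized [SpeciesNetwork-class] (site table dropped).
#' @export
randomizeNetwork <- function(net, nSwapAttempts = NULL, seed = 1) {
  ed <- net@edges
  m <- nrow(ed)
  if (m < 2L) return(net)
  if (is.null(nSwapAttempts)) nSwapAttempts <- 100L * m
  keys <- new.env(hash = TRUE, size = m)
  kOf <- function(i) paste(ed$domain_protein[i], ed$class_id[i],
                           ed$target_protein[i], sep = "\r")
  for (i in seq_len(m)) assign(kOf(i), TRUE, envir = keys)
  withSeed(seed, {
    for (a in seq_len(nSwapAttempts)) {
      ij <- sample.int(m, 2L)
      i <- ij[1L]; j <- ij[2L]
      ti <- ed$target_protein[i]; tj <- ed$target_protein[j]
      if (ti == tj) next
      ki <- paste(ed$domain_protein[i], ed$class_id[i], tj, sep = "\r")
      kj <- paste(ed$domain_protein[j], ed$class_id[j], ti, sep = "\r")
      if (exists(ki, envir = keys, inherits = FALSE) ||
          exists(kj, envir = keys, inherits = FALSE)) next
      rm(list = c(kOf(i), kOf(j)), envir = keys)
      ed$target_protein[i] <- tj
      ed$target_protein[j] <- ti
      assign(ki, TRUE, envir = keys)
      assign(kj, TRUE, envir = keys)
    }
  })
  new("SpeciesNetwork", species = net@species, edges = ed,
      sites = data.frame(), domainProteins = net@domainProteins)
}

#' Test an observed rewiring rate against degree-preserving random networks
#'
#' Randomizes both networks of a species pair `nReps` times, recomputes the
#' global change counts and rate each time, and returns the add-one
#' empirical p-value for the one-sided "observed slower than random" test:
#' \eqn{p = (1 + \#\{null \le observed\}) / (1 + n_{reps})}.
#'
#' @param refNet,otherNet [SpeciesNetwork-class] objects.
#' @param map an [OrthologyMap-class].
#' @param divergenceTime My separating the pair.
#' @param nReps number of null replicates (default 1000).
#' @param seed integer RNG seed.
#' @return list with `observed`, `replicates`, `p`.
#' @export
nullRateTest <- function(refNet, otherNet, map, divergenceTime,
                         nReps = 1000, seed = 1) {
  if (nReps < 1L) stop("nReps must be >= 1")
  oc <- orthologCounts(map, otherNet@species, refNet@domainProteins)
  obs <- changeRate(conservedGlobal(refNet, otherNet, map)$intChanges,
                    oc$orthDomainProteins, oc$orthProteins, divergenceTime)
  reps <- numeric(nReps)
  for (r in seq_len(nReps)) {
    rRef <- randomizeNetwork(refNet, seed = seed + 2L * r)
    rOth <- randomizeNetwork(otherNet, seed = seed + 2L * r + 1L)
    reps[r] <- changeRate(conservedGlobal(rRef, rOth, map)$intChanges,
                          oc$orthDomainProteins, oc$orthProteins,
                          divergenceTime)
  }
  list(observed = obs, replicates = reps,
       p = (1 + sum(reps <= obs)) / (1 + nReps))
}

#' Upper bound on the rate error from prediction mistakes
#'
#' The maximum number of incorrect interaction changes is twice the number
#' of false interactions (false positives plus false negatives) in the
#' reference network, normalized like the rate itself:
#' `2 * (FP + FN) / denominator`.
#'
#' @param falsePositives,falseNegatives counts of wrong predictions.
#' @param denominator `orthDomainProteins * orthProteins * divergenceTime`.
#' @return numeric error bound.
#' @export
estimateRateError <- function(falsePositives, falseNegatives, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  if (falsePositives < 0 || falseNegatives < 0) stop("counts must be >= 0")
  2 * (falsePositives + falseNegatives) / denominator
}
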