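#' @include AllClasses.R AllGenerics.R pwm.R orthology.R rewiring.R
NULL

.overlapOK <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2)
  ov > 0.5 * min(e1 - s1, e2 - s2)
}

#' Greedy detection of binding-site clusters on one target
#'
#' A binding-site cluster is a set of sites on one target protein in which
#' every pair overlaps, and each pair's overlap exceeds 50% of the shorter
#' site's length. Sites are sorted (start asc, length desc, class id lex)
#' and assigned greedily: the first unassigned site seeds a cluster, each
#' following site joins the active cluster only if the pairwise predicate
#' holds against every current member; a failing site closes the active
#' cluster and seeds a new one. The result is a partition of the input.
#'
#' @param sites data.frame of sites sharing one target and species, with
#'   columns `start`, `end`, `class_id` (0-based half-open coordinates).
#' @return list with `members` (the input rows plus `cluster_id`, in greedy
#'   order) and `clusters` (one row per cluster: `cluster_id`, `span_start`,
#'   `span_end`, `size`, `n_classes`).
#' @export
detectClusters <- function(sites) {
  if (nrow(sites) == 0L)
    return(list(members = cbind(sites, cluster_id = integer(0)),
                clusters = data.frame(cluster_id = integer(),
                                      span_start = integer(),
                                      span_end = integer(), size = integer(),
                                      n_classes = integer())))
  ord <- order(sites$start, -(sites$end - sites$start), sites$class_id,
               method = "radix")
  sites <- sites[ord, , drop = FALSE]
  n <- nrow(sites)
  cid <- integer(n)
  current <- 1L
  members <- 1L                       # row indices of the active cluster
  cid[1L] <- 1L
  for (i in seq_len(n)[-1L]) {
    fits <- all(vapply(members, function(j)
      .overlapOK(sites$start[i], sites$end[i],
                 sites$start[j], sites$end[j]), logical(1L)))
    if (fits) {
      members <- c(members, i)
    } else {
      current <- current + 1L
      members <- i
    }
    cid[i] <- current
  }
  sites$cluster_id <- cid
  rownames(sites) <- NULL
  summ <- do.call(rbind, lapply(split(seq_len(n), cid), function(idx) {
    data.frame(cluster_id = cid[idx[1L]],
               span_start = min(sites$start[idx]),
               span_end = max(sites$end[idx]),
               size = length(idx),
               n_classes = length(unique(sites$class_id[idx])))
  }))
  rownames(summ) <- NULL
  list(members = sites, clusters = summ)
}

#' In-degree of a target protein
#'
#' Number of distinct (domain protein, PWM class) partners binding the
#' target.
#'
#' @param net a [SpeciesNetwork-class].
#' @param target protein id; must be a node of the network.
#' @return integer count.
#' @export
inDegree <- function(net, target) {
  ed <- net@edges
  nodes <- unique(c(ed$domain_protein, ed$target_protein, net@domainProteins))
  if (!(target %in% nodes)) stop("unknown target: ", target)
  sel <- ed[ed$target_protein == target, , drop = FALSE]
  nrow(unique(sel[, c("domain_protein", "class_id"), drop = FALSE]))
}

#' Per-edge conservation fraction across species
#'
#' For every reference edge, the fraction of non-reference species in which
#' the edge is conserved under the global criterion (species in which an
#' endpoint has no ortholog count as not conserved, consistent with the
#' binary profile coding).
#'
#' @param refNet the reference [SpeciesNetwork-class].
#' @param networks named list of other-species [SpeciesNetwork-class]
#'   objects.
#' @param map an [OrthologyMap-class].
#' @return data.frame: the reference edges plus `conserved_fraction` and one
#'   logical column per compared species.
#' @export
conservationFraction <- function(refNet, networks, map) {
  refEdges <- refNet@edges
  out <- refEdges
  flags <- matrix(FALSE, nrow(refEdges), length(networks),
                  dimnames = list(NULL, names(networks)))
  for (sp in names(networks)) {
    oth <- networks[[sp]]
    othKeys <- .edgeKey(oth@edges)
    dImage <- mappedOrtholog(map, refEdges$domain_protein, sp)
    for (i in seq_len(nrow(refEdges))) {
      dd <- dImage[i]
      if (is.na(dd)) next
      tOrth <- orthologsOf(map, refEdges$target_protein[i], sp)
      if (!length(tOrth)) next
      flags[i, sp] <- any(paste(dd, refEdges$class_id[i], tOrth,
                                sep = "\r") %in% othKeys)
    }
  }
  out$conserved_fraction <- rowMeans(flags)
  cbind(out, as.data.frame(flags))
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation on midranks, with
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom
#' (two-sided).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p`.
#' @export
spearmanRho <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("lengths differ")
  if (n < 3L) stop("need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Gap-weighted column conservation of an alignment
#'
#' Per column, the unweighted-frequency conservation score — one minus the
#' Shannon entropy (base 2) of the non-gap residue frequencies divided by
#' log2(20) — multiplied by the gap weight `max(0, 1 - gaps/non-gaps)`.
#' Columns with at least as many gaps as residues score 0.
#'
#' @param msa named character vector of equal-width aligned rows, or an
#'   [AlignedFamily-class].
#' @return numeric vector, one score per column in [0, 1].
#' @export
columnConservation <- function(msa) {
  if (is(msa, "AlignedFamily")) msa <- msa@msa
  msa <- as.character(msa)
  if (length(msa) < 2L) stop("need >= 2 aligned rows")
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  apply(mat, 2L, function(col) {
    res <- col[col != "-"]
    nGap <- length(col) - length(res)
    if (length(res) == 0L) return(0)
    w <- max(0, 1 - nGap / length(res))
    if (w == 0) return(0)
    f <- table(res) / length(res)
    H <- -sum(f * log2(f))
    w * (1 - H / log2(20))
  })
}

#' Divergence-weighted binding-site conservation metric
#'
#' For a reference binding site, computes for every ortholog in the family
#' the best PWM score inside the window obtained by mapping the site plus
#' `flank` residues through the alignment, takes the score difference to
#' the reference site (\eqn{\delta_o = score_o - score_{ref}}), floors
#' differences below \eqn{-\tau} (with \eqn{\tau} twice the worst accepted
#' score in the reference network, `2 * sMin`) and returns the weighted
#' mean with weights the reciprocal gene-tree divergence distances
#' (\eqn{w_o = 1/d_o}; zero distances are floored at 1e-6). Values near 0
#' indicate a conserved site; negative values an evolutionarily changing
#' one. Orthologs whose window is shorter than the PWM are excluded.
#'
#' @param start,end 0-based half-open site coordinates on the reference row.
#' @param family an [AlignedFamily-class].
#' @param pwm the [PWM-class] of the site's class.
#' @param distances named numeric vector, species -> gene-tree patristic
#'   distance of the ortholog from the reference protein.
#' @param sMin the worst (lowest) accepted site score in the reference
#'   network, on the normalized score scale.
#' @param flank window flank in residues (default 10).
#' @return list with `metric` (weighted mean; `NA` and `n = 0` when no
#'   ortholog can be scored), `n`, and `perSpecies` (species, score, delta,
#'   weight).
#' @export
domainConservationMetric <- function(start, end, family, pwm, distances,
                                     sMin, flank = 10) {
  refSp <- family@reference
  nC <- pwmLength(pwm)
  if (end - start != nC)
    stop("site width ", end - start, " != PWM length ", nC)
  win <- mapWindow(family, start, end, flank)
  refRow <- win[win$species == refSp, ]
  refSeqAll <- gsub("-", "", family@msa[[refSp]], fixed = TRUE)
  refPep <- substr(refSeqAll, start + 1L, end)
  scoreRef <- scoreSite(pwm, refPep)
  tau <- 2 * sMin
  rows <- list()
  for (sp in setdiff(names(family@msa), refSp)) {
    w <- win[win$species == sp, ]
    if (nchar(w$seq) < nC) next
    best <- max(vapply(
      seq_len(nchar(w$seq) - nC + 1L),
      function(s) scoreSite(pwm, substr(w$seq, s, s + nC - 1L)),
      numeric(1L)))
    delta <- best - scoreRef
    if (delta < -tau) delta <- -tau
    d <- if (sp %in% names(distances)) distances[[sp]] else NA_real_
    if (is.na(d)) next
    rows[[sp]] <- data.frame(species = sp, score = best, delta = delta,
                             weight = 1 / max(d, 1e-6),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(metric = NA_real_, n = 0L, perSpecies = data.frame()))
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  list(metric = sum(per$weight * per$delta) / sum(per$weight),
       n = nrow(per), perSpecies = per)
}
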