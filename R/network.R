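#' @include AllClasses.R AllGenerics.R
NULL

#' Assemble a species interaction network from scored sites
#'
#' Implements the per-species selection rule: sites are first filtered on
#' their feature gates (`accessibility > minAccessibility` and
#' `disorder > minDisorder`, strict), then per PWM class the `topN`
#' highest-scoring surviving sites are kept and merged into directed
#' (domain protein, class, target) edges. The ranking is made total —
#' score desc, accessibility desc, target id lexicographic, start asc — so
#' the result is deterministic and independent of the input row order.
#'
#' @param sites data.frame of scored sites as produced by [scanProteome()].
#' @param classMap data.frame with columns `class_id`, `domain_protein`
#'   assigning each specificity class to its domain-bearing protein. Defaults
#'   to using the class id itself as the domain protein.
#' @param topN sites kept per PWM class (>= 1).
#' @param minAccessibility,minDisorder strict lower feature gates.
#' @param species species label; defaults to the one in `sites`.
#' @return A [SpeciesNetwork-class].
#' @export
buildNetwork <- function(sites, classMap = NULL, topN = 30,
                         minAccessibility = 3, minDisorder = 0,
                         species = NULL) {
  stopifnot(topN >= 1)
  if (is.null(species))
    species <- if (nrow(sites)) sites$species[1L] else "species"
  if (is.null(classMap)) {
    ids <- unique(sites$class_id)
    classMap <- data.frame(class_id = ids, domain_protein = ids,
                           stringsAsFactors = FALSE)
  }
  keep <- sites[sites$accessibility > minAccessibility &
                  sites$disorder > minDisorder, , drop = FALSE]
  picked <- vector("list", length(unique(keep$class_id)))
  if (nrow(keep)) {
    ord <- order(keep$class_id, -keep$score, -keep$accessibility,
                 keep$target_protein, keep$start, method = "radix")
    keep <- keep[ord, , drop = FALSE]
    picked <- lapply(split(keep, keep$class_id),
                     function(d) d[seq_len(min(topN, nrow(d))), , drop = FALSE])
  }
  acc <- do.call(rbind, picked)
  if (is.null(acc) || nrow(acc) == 0L) {
    acc <- sites[0, , drop = FALSE]
  }
  acc$domain_protein <- classMap$domain_protein[
    match(acc$class_id, classMap$class_id)]
  if (nrow(acc) && anyNA(acc$domain_protein))
    stop("classMap does not cover every class in the accepted sites")
  edges <- unique(acc[, c("domain_protein", "class_id", "target_protein"),
                      drop = FALSE])
  rownames(edges) <- NULL
  rownames(acc) <- NULL
  new("SpeciesNetwork", species = species, edges = edges, sites = acc,
      domainProteins = unique(classMap$domain_protein))
}

#' Wrap a plain edge table as a SpeciesNetwork
#'
#' For networks that do not originate from site scanning (e.g. the direct
#' simulation mode); the site table is left empty.
#'
#' @param edges data.frame with `domain_protein`, `class_id`,
#'   `target_protein`.
#' @param species species label.
#' @param domainProteins character vector; defaults to the domains in
#'   `edges`.
#' @return A [SpeciesNetwork-class].
#' @export
networkFromEdges <- function(edges, species, domainProteins = NULL) {
  edges <- unique(edges[, c("domain_protein", "class_id", "target_protein"),
                        drop = FALSE])
  rownames(edges) <- NULL
  if (is.null(domainProteins)) domainProteins <- unique(edges$domain_protein)
  new("SpeciesNetwork", species = species, edges = edges,
      sites = data.frame(), domainProteins = domainProteins)
}

.mcc <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Evaluate predicted interactions against labeled pairs
#'
#' Subsamples the negative set to the requested positive:negative ratio
#' (seeded), computes the AUROC by the midrank (Mann-Whitney) statistic, and
#' the Matthews correlation coefficient and confusion counts at the
#' network's accept/reject decision.
#'
#' @param score numeric prediction score per labeled pair.
#' @param label logical, TRUE for positives.
#' @param accepted logical, the accept/reject decision per pair (e.g. "edge
#'   present in the built network").
#' @param negativeRatio negatives kept per positive (a 1:5 design ->
#'   `negativeRatio = 5`).
#' @param seed integer seed for the negative subsample.
#' @return list with `auroc`, `mcc`, `tp`, `fp`, `tn`, `fn`, `nPos`, `nNeg`.
#' @export
evaluatePredictions <- function(score, label, accepted,
                                negativeRatio = 5, seed = 1) {
  stopifnot(length(score) == length(label), length(label) == length(accepted))
  if (!any(label)) stop("no positive pairs")
  if (all(label)) stop("no negative pairs")
  pos <- which(label)
  neg <- which(!label)
  nWant <- min(length(neg), round(negativeRatio * length(pos)))
  if (nWant < length(neg)) {
    neg <- sort(withSeed(seed, sample(neg, nWant)))
  }
  use <- c(pos, neg)
  sc <- score[use]; lb <- label[use]; ac <- accepted[use]
  r <- rank(sc)                       # midranks
  np <- sum(lb); nn <- sum(!lb)
  auroc <- (sum(r[lb]) - np * (np + 1) / 2) / (np * nn)
  tp <- sum(lb & ac); fp <- sum(!lb & ac)
  fn <- sum(lb & !ac); tn <- sum(!lb & !ac)
  list(auroc = auroc, mcc = .mcc(tp, fp, tn, fn),
       tp = tp, fp = fp, tn = tn, fn = fn, nPos = np, nNeg = nn)
}

#' Read / write species network edge lists
#'
#' TSV with a `#coords=1-based-inclusive` header: exported coordinates are
#' 1-based inclusive (internal representation is 0-based half-open).
#'
#' @param net a [SpeciesNetwork-class].
#' @param path file path.
#' @return `readNetwork` returns a [SpeciesNetwork-class]; `writeNetwork`
#'   returns `path` invisibly.
#' @export
writeNetwork <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#coords=1-based-inclusive", con)
  if (nrow(net@sites)) {
    out <- net@sites[, c("species", "domain_protein", "class_id",
                         "target_protein", "start", "end", "score",
                         "accessibility", "disorder")]
    out$start <- out$start + 1L          # 1-based inclusive on disk
  } else {
    out <- cbind(species = rep(net@species, nrow(net@edges)), net@edges,
                 start = NA_integer_, end = NA_integer_, score = NA_real_,
                 accessibility = NA_real_, disorder = NA_real_)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#")
  species <- if (nrow(tab)) tab$species[1L] else "species"
  edges <- unique(tab[, c("domain_protein", "class_id", "target_protein")])
  rownames(edges) <- NULL
  if (all(is.na(tab$score))) {
    sites <- data.frame()
  } else {
    sites <- tab
    sites$start <- sites$start - 1L      # back to 0-based half-open
  }
  new("SpeciesNetwork", species = species, edges = edges, sites = sites,
      domainProteins = unique(edges$domain_protein))
}
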