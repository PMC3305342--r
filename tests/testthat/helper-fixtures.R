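# Shared fixture builders: everything is generated in code at test time.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomPeptide <- function(n) paste(sample(aa20, n, replace = TRUE),
                                   collapse = "")

# a random site table on one target, for clustering tests
randomSites <- function(n, targetLen = 60, minLen = 5, maxLen = 9) {
  len <- sample(minLen:maxLen, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(targetLen - l, 1L) - 1L,
                  integer(1L))
  data.frame(start = start, end = start + len,
             class_id = sample(sprintf("cls%02d", 1:5), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# identity orthology over shared protein ids (same ids in every species)
identityOrthology <- function(proteins, species, reference = species[1L]) {
  groups <- do.call(rbind, lapply(proteins, function(p)
    data.frame(orthogroup_id = paste0("og_", p), species = species,
               protein_id = p, stringsAsFactors = FALSE)))
  # star gene trees with unit branch lengths are enough for identity maps;
  # but identical ids across species collide, so skip trees and build the
  # constrained mapping directly.
  mapping <- do.call(rbind, lapply(proteins, function(p)
    data.frame(ref_protein = p, species = species, ortholog = p,
               distance = ifelse(species == reference, 0, 1),
               stringsAsFactors = FALSE)))
  new("OrthologyMap", reference = reference, groups = groups,
      mapping = mapping, geneTrees = list())
}

# small edge table helper
edgeDf <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(domain_protein = m[, 1], class_id = m[, 2],
             target_protein = m[, 3], stringsAsFactors = FALSE)
}

# brute-force global conservation oracle: double loop over edges/orthologs
bruteGlobal <- function(refEdges, othEdges, map, otherSpecies) {
  refSp <- map@reference
  conserved <- lost <- skipped <- 0L
  for (i in seq_len(nrow(refEdges))) {
    d <- refEdges$domain_protein[i]
    cl <- refEdges$class_id[i]
    t <- refEdges$target_protein[i]
    dd <- mappedOrtholog(map, d, otherSpecies)
    tOrth <- orthologsOf(map, t, otherSpecies)
    if (is.na(dd) || length(tOrth) == 0L) {
      skipped <- skipped + 1L
      next
    }
    hit <- FALSE
    for (j in seq_len(nrow(othEdges))) {
      if (othEdges$domain_protein[j] == dd &&
          othEdges$class_id[j] == cl &&
          othEdges$target_protein[j] %in% tOrth) hit <- TRUE
    }
    if (hit) conserved <- conserved + 1L else lost <- lost + 1L
  }
  gained <- 0L
  doms <- unique(refEdges$domain_protein)
  for (j in seq_len(nrow(othEdges))) {
    d2 <- othEdges$domain_protein[j]
    cl <- othEdges$class_id[j]
    t2 <- othEdges$target_protein[j]
    dPre <- doms[!is.na(mappedOrtholog(map, doms, otherSpecies)) &
                   mappedOrtholog(map, doms, otherSpecies) == d2]
    tPre <- orthologsOf(map, t2, refSp)
    if (!length(dPre) || !length(tPre)) next
    hit <- FALSE
    for (i in seq_len(nrow(refEdges))) {
      if (refEdges$domain_protein[i] %in% dPre &&
          refEdges$class_id[i] == cl &&
          refEdges$target_protein[i] %in% tPre) hit <- TRUE
    }
    if (!hit) gained <- gained + 1L
  }
  list(conserved = conserved, gained = gained, lost = lost,
       intChanges = gained + lost, skipped = skipped)
}
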