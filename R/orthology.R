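#' @include AllClasses.R AllGenerics.R
NULL

#' Build a reference-constrained orthology map
#'
#' Constrains orthogroup membership to one-to-one / many-to-one
#' relationships with respect to the reference species: for each reference
#' protein and each other species, the orthogroup member minimizing the
#' gene-tree patristic distance (sum of branch lengths on the connecting
#' path) to the reference protein is selected; distance ties are broken
#' lexicographically by protein id. Reference proteins missing from their
#' orthogroup's gene tree are excluded with a warning.
#'
#' @param groups data.frame with columns `orthogroup_id`, `species`,
#'   `protein_id`.
#' @param geneTrees named list (by orthogroup id) of `ape::phylo` gene trees
#'   whose tip labels are protein ids.
#' @param reference the reference species.
#' @return An [OrthologyMap-class].
#' @export
orthologyMap <- function(groups, geneTrees, reference) {
  stopifnot(all(c("orthogroup_id", "species", "protein_id") %in% names(groups)))
  mapping <- vector("list", 0L)
  dropped <- character()
  for (og in unique(groups$orthogroup_id)) {
    mem <- groups[groups$orthogroup_id == og, , drop = FALSE]
    refs <- mem$protein_id[mem$species == reference]
    if (!length(refs)) next
    others <- mem[mem$species != reference, , drop = FALSE]
    tree <- geneTrees[[og]]
    D <- NULL
    if (!is.null(tree) && length(tree$tip.label) >= 2L)
      D <- ape::cophenetic.phylo(tree)
    for (rp in refs) {
      if (nrow(others) && (is.null(D) || !(rp %in% rownames(D)))) {
        dropped <- c(dropped, rp)
        next
      }
      for (sp in unique(others$species)) {
        cand <- others$protein_id[others$species == sp]
        cand <- cand[cand %in% colnames(D)]
        if (!length(cand)) next
        d <- unname(D[rp, cand])
        bi <- order(d, cand)[1L]
        mapping[[length(mapping) + 1L]] <- data.frame(
          ref_protein = rp, species = sp, ortholog = cand[bi],
          distance = d[bi], stringsAsFactors = FALSE)
      }
      # the reference protein maps to itself at distance 0
      mapping[[length(mapping) + 1L]] <- data.frame(
        ref_protein = rp, species = reference, ortholog = rp,
        distance = 0, stringsAsFactors = FALSE)
    }
  }
  if (length(dropped))
    warning("reference protein(s) absent from their gene tree, excluded: ",
            paste(dropped, collapse = ", "))
  mapping <- if (length(mapping)) do.call(rbind, mapping) else
    data.frame(ref_protein = character(), species = character(),
               ortholog = character(), distance = numeric())
  new("OrthologyMap", reference = reference, groups = groups,
      mapping = mapping, geneTrees = geneTrees)
}

#' One-to-many orthologs of a protein in another species
#'
#' Returns every member of `protein`'s orthogroup(s) belonging to `species`
#' (used by the "global" network comparisons, which accept one-to-many
#' target orthology).
#'
#' @param map an [OrthologyMap-class].
#' @param protein protein id (any species).
#' @param species the species whose members to return.
#' @return character vector (possibly empty).
#' @export
orthologsOf <- function(map, protein, species) {
  g <- map@groups
  ogs <- unique(g$orthogroup_id[g$protein_id == protein])
  if (!length(ogs)) return(character())
  unique(g$protein_id[g$orthogroup_id %in% ogs & g$species == species])
}

#' Constrained ortholog of a reference protein
#'
#' @param map an [OrthologyMap-class].
#' @param refProtein reference-species protein id(s).
#' @param species target species.
#' @return character vector aligned with `refProtein`; `NA` where no
#'   constrained ortholog exists.
#' @export
mappedOrtholog <- function(map, refProtein, species) {
  mp <- map@mapping[map@mapping$species == species, , drop = FALSE]
  mp$ortholog[match(refProtein, mp$ref_protein)]
}

#' Drop orthologs that lost the binding domain
#'
#' Orthologs of reference domain proteins for which domain detection failed
#' (annotation `present = FALSE`) are removed from the constrained mapping,
#' so they no longer take part in network comparison. Proteins absent from
#' the annotation table are kept.
#'
#' @param map an [OrthologyMap-class].
#' @param domainAnnotations data.frame with columns `protein_id`, `present`
#'   (logical).
#' @return The filtered [OrthologyMap-class].
#' @export
filterDomainOrthologs <- function(map, domainAnnotations) {
  absent <- domainAnnotations$protein_id[!domainAnnotations$present]
  keep <- !(map@mapping$ortholog %in% absent)
  map@mapping <- map@mapping[keep, , drop = FALSE]
  rownames(map@mapping) <- NULL
  map
}

#' Construct an aligned family
#'
#' @param msa named character vector (or `Biostrings::AAStringSet`) of
#'   equal-width aligned rows, names = species.
#' @param reference the reference species (must name a row).
#' @param familyId identifier, conventionally the reference protein id.
#' @param proteins optional named character vector species -> protein id.
#' @return An [AlignedFamily-class].
#' @export
alignedFamily <- function(msa, reference, familyId = "family",
                          proteins = character()) {
  nms <- names(msa)
  msa <- as.character(msa)
  names(msa) <- nms
  new("AlignedFamily", familyId = familyId, msa = msa,
      proteins = proteins, reference = reference)
}

#' Map a residue window through a family alignment
#'
#' Takes residue coordinates on one species' row (default the reference),
#' extends them by `flank` residues on each side (clipped to the sequence),
#' converts the window to alignment columns and returns, for every species
#' in the family, the ungapped subsequence under that column span together
#' with its residue coordinates. All coordinates are 0-based half-open.
#'
#' @param family an [AlignedFamily-class].
#' @param start,end residue coordinates on the `species` row.
#' @param flank residues added on each side before mapping (default 10).
#' @param species row on which `start`/`end` live; default the reference.
#' @return data.frame with columns `species`, `start`, `end`, `seq`.
#' @export
mapWindow <- function(family, start, end, flank = 10,
                      species = family@reference) {
  row <- family@msa[[species]]
  chars <- strsplit(row, "", fixed = TRUE)[[1L]]
  resCols <- which(chars != "-")           # column of each residue (1-based)
  L <- length(resCols)
  if (start < 0 || end > L || start >= end)
    stop("window [", start, ", ", end, ") outside the ", species,
         " sequence of length ", L)
  ws <- max(0L, as.integer(start) - as.integer(flank))
  we <- min(L, as.integer(end) + as.integer(flank))
  c1 <- resCols[ws + 1L]
  c2 <- resCols[we]
  out <- lapply(names(family@msa), function(sp) {
    ch <- strsplit(family@msa[[sp]], "", fixed = TRUE)[[1L]]
    nonGap <- ch != "-"
    before <- sum(nonGap[seq_len(c1 - 1L)])
    inside <- which(nonGap[c1:c2])
    if (!length(inside))
      return(data.frame(species = sp, start = before, end = before,
                        seq = "", stringsAsFactors = FALSE))
    data.frame(species = sp, start = before,
               end = before + length(inside),
               seq = paste(ch[c1:c2][ch[c1:c2] != "-"], collapse = ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read / write orthology tables and gene trees
#'
#' The orthology table is a TSV with columns `orthogroup_id`, `species`,
#' `protein_id`; gene trees are newick files named `<orthogroup_id>.nwk` in
#' a directory.
#'
#' @param path TSV path (`readOrthologyTable`) / directory (`readGeneTrees`).
#' @return data.frame / named list of `ape::phylo`.
#' @export
readOrthologyTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname readOrthologyTable
#' @param groups orthology data.frame to write.
#' @export
writeOrthologyTable <- function(groups, path) {
  utils::write.table(groups, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname readOrthologyTable
#' @export
readGeneTrees <- function(path) {
  files <- list.files(path, pattern = "\\.nwk$", full.names = TRUE)
  trees <- lapply(files, ape::read.tree)
  names(trees) <- sub("\\.nwk$", "", basename(files))
  trees
}

#' @rdname readOrthologyTable
#' @param trees named list of `ape::phylo` to write.
#' @export
writeGeneTrees <- function(trees, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (og in names(trees))
    ape::write.tree(trees[[og]], file.path(path, paste0(og, ".nwk")))
  invisible(path)
}
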