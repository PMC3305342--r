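#' @include AllClasses.R AllGenerics.R orthology.R
NULL

#' Binary interaction-profile matrix across species
#'
#' Treats each orthology-mapped interaction as one binary character, as in
#' an alignment column: character identity is (reference domain protein, PWM
#' class, target orthogroup), a species scores 1 if its network contains a
#' corresponding edge (its domain protein being the constrained image of
#' the reference domain protein and its target belonging to the
#' orthogroup), 0 otherwise. Characters are the union over all species;
#' edges that cannot be mapped to the reference frame are ignored.
#'
#' @param networks named list of [SpeciesNetwork-class] objects (the
#'   reference species included).
#' @param map an [OrthologyMap-class].
#' @return binary matrix, rows = species, columns = interaction characters.
#' @export
profileMatrix <- function(networks, map) {
  refSp <- map@reference
  g <- map@groups
  ogOf <- function(prots) g$orthogroup_id[match(prots, g$protein_id)]
  charsOf <- function(sp) {
    ed <- networks[[sp]]@edges
    if (!nrow(ed)) return(character())
    if (sp == refSp) {
      d <- ed$domain_protein
    } else {
      mp <- map@mapping[map@mapping$species == sp, , drop = FALSE]
      d <- mp$ref_protein[match(ed$domain_protein, mp$ortholog)]
    }
    og <- ogOf(ed$target_protein)
    keep <- !is.na(d) & !is.na(og)
    unique(paste(d[keep], ed$class_id[keep], og[keep], sep = "|"))
  }
  perSpecies <- lapply(names(networks), charsOf)
  names(perSpecies) <- names(networks)
  chars <- sort(unique(unlist(perSpecies)))
  mat <- matrix(0L, length(networks), length(chars),
                dimnames = list(names(networks), chars))
  for (sp in names(networks)) mat[sp, perSpecies[[sp]]] <- 1L
  mat
}

#' Normalized Hamming distance between species interaction profiles
#'
#' @param matrix binary profile matrix from [profileMatrix()].
#' @return symmetric species x species distance matrix (fraction of
#'   differing characters), zero diagonal.
#' @export
profileDistance <- function(matrix) {
  if (nrow(matrix) < 2L) stop("need >= 2 species")
  n <- nrow(matrix)
  D <- base::matrix(0, n, n, dimnames = list(rownames(matrix), rownames(matrix)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- mean(matrix[i, ] != matrix[j, ])
    }
  }
  D
}

#' Distance-based tree from an interaction-profile distance matrix
#'
#' Neighbor joining (`ape::nj`); on additive matrices this recovers the
#' generating topology and branch lengths exactly.
#'
#' @param distances symmetric nonnegative distance matrix with zero
#'   diagonal, >= 3 taxa.
#' @return an unrooted `ape::phylo`.
#' @export
buildProfileTree <- function(distances) {
  distances <- as.matrix(distances)
  if (any(distances < 0)) stop("negative distances")
  if (nrow(distances) < 3L) stop("need >= 3 taxa")
  if (any(abs(distances - t(distances)) > 1e-12)) stop("asymmetric matrix")
  ape::nj(stats::as.dist(distances))
}

#' Robinson-Foulds topology distance
#'
#' Number of bipartitions present in exactly one of the two unrooted trees.
#'
#' @param a,b `ape::phylo` trees over the same leaf set.
#' @return integer RF count (0 for identical topologies).
#' @export
treeTopologyDistance <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) stop("leaf sets differ")
  ua <- ape::unroot(a)
  ub <- ape::unroot(b)
  as.numeric(ape::dist.topo(ua, ub, method = "PH85"))
}
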