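#' @import methods
NULL

# The 20 standard amino acids, alphabetical. This ordering is the canonical
# column order for all PWM matrices and the lexicographic tie-break alphabet.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' PWM: a domain binding-specificity class
#'
#' Holds the raw peptide-derived count matrix of one specificity class, the
#' entropy-adjusted probability profile obtained from position-based
#' pseudocounts, the optimal binding score (sum of per-position maxima of the
#' adjusted profile) and the consensus peptide. Rows of both matrices are
#' ligand positions, columns the 20 standard amino acids in alphabetical
#' order. Construct with [buildPWM()].
#'
#' @slot classId character, the specificity class identifier.
#' @slot counts numeric matrix of nonnegative raw counts (positions x 20).
#' @slot profile numeric matrix of adjusted per-position probabilities; every
#'   entry is strictly positive and every row sums to one.
#' @slot optimalScore numeric, the sum over positions of the row maxima of
#'   `profile`; the score a consensus-matching peptide attains before
#'   normalization.
#' @slot consensus character, the argmax peptide (ties broken alphabetically).
#'
#' @aliases PWM-class
#' @exportClass PWM
setClass("PWM",
  slots = c(
    classId = "character",
    counts = "matrix",
    profile = "matrix",
    optimalScore = "numeric",
    consensus = "character"
  )
)

setValidity("PWM", function(object) {
  msg <- character()
  prof <- object@profile
  if (nrow(prof) < 1L) msg <- c(msg, "profile needs >= 1 position")
  if (!identical(colnames(prof), AA20))
    msg <- c(msg, "profile columns must be the 20 standard amino acids")
  if (any(prof <= 0)) msg <- c(msg, "adjusted profile must be strictly positive")
  if (any(abs(rowSums(prof) - 1) > 1e-8))
    msg <- c(msg, "profile rows must each sum to 1")
  if (abs(object@optimalScore - sum(apply(prof, 1L, max))) > 1e-8)
    msg <- c(msg, "optimalScore must equal the sum of per-position maxima")
  if (nchar(object@consensus) != nrow(prof))
    msg <- c(msg, "consensus length must equal the number of positions")
  if (length(msg)) msg else TRUE
})

#' SpeciesNetwork: one species' directed domain-target interaction network
#'
#' Edges are (domain protein, PWM class, target protein) triples; a domain
#' protein carrying several specificity classes contributes one edge per
#' class per target. When the network was assembled from scanned sites
#' ([buildNetwork()]) every edge is backed by at least one accepted
#' [ScoredSite][scanProtein()] row kept in `sites`; networks emitted directly
#' by the simulator carry an empty site table.
#'
#' @slot species character, species identifier.
#' @slot edges data.frame with columns `domain_protein`, `class_id`,
#'   `target_protein`; one row per edge, no duplicates.
#' @slot sites data.frame of accepted sites with the edge columns plus
#'   `start`, `end`, `peptide`, `score`, `accessibility`, `disorder`
#'   (0-based half-open coordinates); possibly 0 rows.
#' @slot domainProteins character, the domain-bearing proteins of the species.
#'
#' @aliases SpeciesNetwork-class
#' @exportClass SpeciesNetwork
setClass("SpeciesNetwork",
  slots = c(
    species = "character",
    edges = "data.frame",
    sites = "data.frame",
    domainProteins = "character"
  )
)

setValidity("SpeciesNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  need <- c("domain_protein", "class_id", "target_protein")
  if (!all(need %in% names(ed)))
    msg <- c(msg, "edges must have domain_protein, class_id, target_protein")
  else {
    key <- paste(ed$domain_protein, ed$class_id, ed$target_protein, sep = "\r")
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
    if (nrow(object@sites) > 0L) {
      skey <- paste(object@sites$domain_protein, object@sites$class_id,
                    object@sites$target_protein, sep = "\r")
      if (!all(key %in% skey))
        msg <- c(msg, "every edge must be backed by >= 1 site")
    }
  }
  if (length(msg)) msg else TRUE
})

#' OrthologyMap: orthogroups, gene trees and a reference-constrained mapping
#'
#' Stores the raw orthogroup membership table (one-to-many orthology), the
#' per-orthogroup gene trees, and the mapping constrained to at most one
#' ortholog per (reference protein, species) chosen by shortest gene-tree
#' patristic distance. Construct with [orthologyMap()].
#'
#' @slot reference character, the reference species.
#' @slot groups data.frame with columns `orthogroup_id`, `species`,
#'   `protein_id` (full membership, paralogs included).
#' @slot mapping data.frame with columns `ref_protein`, `species`, `ortholog`,
#'   `distance` (patristic distance on the orthogroup gene tree).
#' @slot geneTrees named list of `ape::phylo` gene trees, one per orthogroup,
#'   leaf labels = protein ids.
#'
#' @aliases OrthologyMap-class
#' @exportClass OrthologyMap
setClass("OrthologyMap",
  slots = c(
    reference = "character",
    groups = "data.frame",
    mapping = "data.frame",
    geneTrees = "list"
  )
)

setValidity("OrthologyMap", function(object) {
  msg <- character()
  if (!all(c("orthogroup_id", "species", "protein_id") %in% names(object@groups)))
    msg <- c(msg, "groups must have orthogroup_id, species, protein_id")
  mp <- object@mapping
  if (!all(c("ref_protein", "species", "ortholog", "distance") %in% names(mp)))
    msg <- c(msg, "mapping must have ref_protein, species, ortholog, distance")
  else {
    if (anyDuplicated(paste(mp$ref_protein, mp$species, sep = "\r")))
      msg <- c(msg, "mapping must have at most one ortholog per (ref protein, species)")
    if (any(mp$distance < 0)) msg <- c(msg, "distances must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' AlignedFamily: the MSA of a reference protein and its orthologs
#'
#' One aligned row per species (the constrained orthology guarantees at most
#' one member per species). Ungapping the reference row reproduces the
#' reference protein sequence; [mapWindow()] converts residue windows between
#' species through the alignment columns.
#'
#' @slot familyId character, usually the reference protein id.
#' @slot msa named character vector of equal-width aligned sequences
#'   (gap = "-"), names = species.
#' @slot proteins named character vector, species -> member protein id.
#' @slot reference character, the reference species (must name a row).
#'
#' @aliases AlignedFamily-class
#' @exportClass AlignedFamily
setClass("AlignedFamily",
  slots = c(
    familyId = "character",
    msa = "character",
    proteins = "character",
    reference = "character"
  )
)

setValidity("AlignedFamily", function(object) {
  msg <- character()
  if (length(object@msa) < 1L) msg <- c(msg, "empty alignment")
  if (length(unique(nchar(object@msa))) > 1L)
    msg <- c(msg, "aligned rows must share one width")
  if (is.null(names(object@msa)) || anyDuplicated(names(object@msa)))
    msg <- c(msg, "msa rows must be uniquely named by species")
  if (!(object@reference %in% names(object@msa)))
    msg <- c(msg, "reference species must have a row")
  if (length(msg)) msg else TRUE
})

#' EvolvedNetworks: a forward simulation of network evolution
#'
#' The full ground truth of one simulator run (see
#' [simulateNetworkEvolution()]): the species tree, the per-species true
#' networks and binding-site coordinates, the orthology with gene trees, the
#' complete event log, the evolved proteomes with disorder/accessibility
#' tracks, the generating PWMs and the class-to-domain-protein map.
#'
#' @slot config list, the [simulationConfig()] used.
#' @slot tree `ape::phylo`, the species tree (branch lengths in My).
#' @slot mode character, "direct" or "mechanistic".
#' @slot networks named list (by species) of edge data.frames; empty in
#'   mechanistic mode, where networks must be rediscovered by scanning.
#' @slot trueSites named list (by species) of true site tables.
#' @slot orthology [OrthologyMap-class].
#' @slot events data.frame event log (branch, time, type, details).
#' @slot proteomes named list of `Biostrings::AAStringSet`, one per species.
#' @slot tracks named list (by species) of per-residue track tables.
#' @slot pwms named list of [PWM-class] objects.
#' @slot ancestralEdges data.frame, the root network.
#' @slot classMap data.frame, columns `class_id`, `domain_protein`.
#'
#' @aliases EvolvedNetworks-class
#' @exportClass EvolvedNetworks
setClass("EvolvedNetworks",
  slots = c(
    config = "list",
    tree = "ANY",
    mode = "character",
    networks = "list",
    trueSites = "list",
    orthology = "OrthologyMap",
    events = "data.frame",
    proteomes = "list",
    tracks = "list",
    pwms = "list",
    ancestralEdges = "data.frame",
    classMap = "data.frame"
  )
)
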