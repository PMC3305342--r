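#' @include AllClasses.R
NULL

#' Accessors for NetRewire classes
#'
#' Small accessor generics: `classId`, `pwmLength`, `pwmProfile`,
#' `optimalScore`, `consensusSeq` for [PWM-class]; `netSpecies`, `edgeTable`,
#' `siteTable`, `domainProteins` for [SpeciesNetwork-class]; `refSpecies`,
#' `orthoGroups`, `orthoMapping`, `geneTrees` for [OrthologyMap-class];
#' `msaRows`, `familyProteins` for [AlignedFamily-class].
#'
#' @param x an object of the corresponding class.
#' @return The slot contents (matrices, data.frames or character vectors).
#' @name accessors
#' @examples
#' p <- buildPWM(consensusCounts("PXXPXR"), "cls1")
#' classId(p); pwmLength(p); optimalScore(p); consensusSeq(p)
NULL

#' @rdname accessors
#' @export
setGeneric("classId", function(x) standardGeneric("classId"))
#' @rdname accessors
#' @export
setGeneric("pwmLength", function(x) standardGeneric("pwmLength"))
#' @rdname accessors
#' @export
setGeneric("pwmProfile", function(x) standardGeneric("pwmProfile"))
#' @rdname accessors
#' @export
setGeneric("optimalScore", function(x) standardGeneric("optimalScore"))
#' @rdname accessors
#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))
#' @rdname accessors
#' @export
setGeneric("netSpecies", function(x) standardGeneric("netSpecies"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))
#' @rdname accessors
#' @export
setGeneric("domainProteins", function(x) standardGeneric("domainProteins"))
#' @rdname accessors
#' @export
setGeneric("refSpecies", function(x) standardGeneric("refSpecies"))
#' @rdname accessors
#' @export
setGeneric("orthoGroups", function(x) standardGeneric("orthoGroups"))
#' @rdname accessors
#' @export
setGeneric("orthoMapping", function(x) standardGeneric("orthoMapping"))
#' @rdname accessors
#' @export
setGeneric("geneTrees", function(x) standardGeneric("geneTrees"))
#' @rdname accessors
#' @export
setGeneric("msaRows", function(x) standardGeneric("msaRows"))
#' @rdname accessors
#' @export
setGeneric("familyProteins", function(x) standardGeneric("familyProteins"))

setMethod("classId", "PWM", function(x) x@classId)
setMethod("pwmLength", "PWM", function(x) nrow(x@profile))
setMethod("pwmProfile", "PWM", function(x) x@profile)
setMethod("optimalScore", "PWM", function(x) x@optimalScore)
setMethod("consensusSeq", "PWM", function(x) x@consensus)

setMethod("netSpecies", "SpeciesNetwork", function(x) x@species)
setMethod("edgeTable", "SpeciesNetwork", function(x) x@edges)
setMethod("siteTable", "SpeciesNetwork", function(x) x@sites)
setMethod("domainProteins", "SpeciesNetwork", function(x) x@domainProteins)

setMethod("refSpecies", "OrthologyMap", function(x) x@reference)
setMethod("orthoGroups", "OrthologyMap", function(x) x@groups)
setMethod("orthoMapping", "OrthologyMap", function(x) x@mapping)
setMethod("geneTrees", "OrthologyMap", function(x) x@geneTrees)

setMethod("msaRows", "AlignedFamily", function(x) x@msa)
setMethod("familyProteins", "AlignedFamily", function(x) x@proteins)

setMethod("show", "PWM", function(object) {
  cat("PWM class", object@classId, "|", nrow(object@profile), "positions",
      "| consensus", object@consensus,
      sprintf("| S_opt %.3f\n", object@optimalScore))
})

setMethod("show", "SpeciesNetwork", function(object) {
  cat("SpeciesNetwork", object@species, "|", nrow(object@edges), "edges |",
      length(unique(object@edges$target_protein)), "targets |",
      length(object@domainProteins), "domain proteins |",
      nrow(object@sites), "sites\n")
})

setMethod("show", "OrthologyMap", function(object) {
  cat("OrthologyMap | reference", object@reference, "|",
      length(unique(object@groups$orthogroup_id)), "orthogroups |",
      nrow(object@mapping), "constrained ortholog assignments\n")
})

setMethod("show", "AlignedFamily", function(object) {
  cat("AlignedFamily", object@familyId, "|", length(object@msa), "species |",
      "width", nchar(object@msa[[1L]]), "| reference", object@reference, "\n")
})

setMethod("show", "EvolvedNetworks", function(object) {
  cat("EvolvedNetworks (", object@mode, " mode) | ",
      length(object@tree$tip.label), " species | ",
      nrow(object@classMap), " PWM classes | ",
      nrow(object@events), " logged events\n", sep = "")
})
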