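#' Accessors for femnet classes
#'
#' Small accessor generics so that slot access never appears in user code.
#'
#' @param object a femnet S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("betaValues", function(object) standardGeneric("betaValues"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("statTable", function(object) standardGeneric("statTable"))

#' @rdname accessors
#' @export
setGeneric("tInt", function(object) standardGeneric("tInt"))

#' @rdname accessors
#' @export
setGeneric("moduleMembers", function(object) standardGeneric("moduleMembers"))

#' @rdname accessors
#' @export
setGeneric("moduleSeed", function(object) standardGeneric("moduleSeed"))

#' @rdname accessors
#' @export
setGeneric("moduleEnergyValue", function(object) standardGeneric("moduleEnergyValue"))

#' @rdname accessors
#' @export
setGeneric("moduleModularity", function(object) standardGeneric("moduleModularity"))

#' @rdname accessors
#' @export
setGeneric("mcPValue", function(object) standardGeneric("mcPValue"))

#' @rdname accessors
#' @export
setGeneric("memberFlags", function(object) standardGeneric("memberFlags"))

#' @rdname accessors
#' @export
setGeneric("referenceProfiles", function(object) standardGeneric("referenceProfiles"))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(object) standardGeneric("cellTypes"))

#' @rdname accessors
#' @export
setMethod("betaValues", "PromoterMethylation", function(object) object@beta)

#' @rdname accessors
#' @export
setMethod("provenance", "PromoterMethylation", function(object) object@provenance)

#' @rdname accessors
#' @export
setMethod("geneIds", "PromoterMethylation", function(object) rownames(object@beta))

#' @rdname accessors
#' @export
setMethod("geneIds", "GeneStats", function(object) object@stats$gene)

#' @rdname accessors
#' @export
setMethod("statTable", "GeneStats", function(object) object@stats)

#' @rdname accessors
#' @export
setMethod("tInt", "GeneStats", function(object)
  stats::setNames(object@stats$t_int, object@stats$gene))

#' @rdname accessors
#' @export
setMethod("moduleMembers", "FemModule", function(object) object@members)

#' @rdname accessors
#' @export
setMethod("moduleSeed", "FemModule", function(object) object@seed)

#' @rdname accessors
#' @export
setMethod("moduleEnergyValue", "FemModule", function(object) object@energy)

#' @rdname accessors
#' @export
setMethod("moduleModularity", "FemModule", function(object) object@modularity)

#' @rdname accessors
#' @export
setMethod("mcPValue", "FemModule", function(object) object@mcP)

#' @rdname accessors
#' @export
setMethod("memberFlags", "FemModule", function(object) object@flags)

#' @rdname accessors
#' @export
setMethod("referenceProfiles", "ReferenceMatrix", function(object) object@ref)

#' @rdname accessors
#' @export
setMethod("cellTypes", "ReferenceMatrix", function(object) colnames(object@ref))

#' @describeIn accessors number of modules in a set.
#' @export
setMethod("length", "FemModuleSet", function(x) length(x@modules))

#' Extract a module from a FemModuleSet
#' @param x a \linkS4class{FemModuleSet}.
#' @param i index.
#' @export
setMethod("[[", "FemModuleSet", function(x, i) x@modules[[i]])

#' Modules as a plain list
#' @param x a \linkS4class{FemModuleSet}.
#' @param ... ignored.
#' @export
setMethod("as.list", "FemModuleSet", function(x, ...) x@modules)
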