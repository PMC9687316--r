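#' Accessors for boomdock classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `atoms()` returns the atom table, `structureId()` the identifier,
#' `nAtoms()`/`nResidues()`/`chainIds()` basic sizes, `residueTable()` one
#' row per residue, `nFrames()` and `frameCoords()` ensemble access,
#' `clusters()` and `clusterSizes()` clustering results, `contactPairs()`
#' and `contactCounts()` contact tables.
#'
#' @param x an object of the documented class.
#' @param i frame index for `frameCoords`.
#' @return see the individual methods.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname accessors
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname accessors
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' @rdname accessors
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))

setMethod("atoms", "ProteinStructure", function(x) x@atoms)
setMethod("structureId", "ProteinStructure", function(x) x@id)
setMethod("nAtoms", "ProteinStructure", function(x) nrow(x@atoms))
setMethod("chainIds", "ProteinStructure",
          function(x) unique(x@atoms$chain))

.residue_key <- function(a) paste(a$chain, a$resno, a$icode, sep = "\r")

setMethod("residueTable", "ProteinStructure", function(x) {
  a <- x@atoms
  first <- !duplicated(.residue_key(a))
  out <- a[first, c("chain", "resno", "icode", "resname")]
  rownames(out) <- NULL
  out
})

setMethod("nResidues", "ProteinStructure",
          function(x) sum(!duplicated(.residue_key(x@atoms))))

setMethod("nFrames", "PoseEnsemble", function(x) dim(x@coords)[3])
setMethod("nAtoms", "PoseEnsemble", function(x) dim(x@coords)[1])
setMethod("atoms", "PoseEnsemble", function(x) x@topology@atoms)
setMethod("structureId", "PoseEnsemble", function(x) x@id)
setMethod("frameCoords", "PoseEnsemble",
          function(x, i) x@coords[, , i, drop = TRUE])

setMethod("clusters", "ClusterResult", function(x) x@clusters)
setMethod("clusterSizes", "ClusterResult", function(x)
  vapply(x@clusters, function(cl) length(cl$members), integer(1)))

setMethod("contactPairs", "ContactTable", function(x) x@pairs)
setMethod("contactCounts", "ContactTable", function(x) x@counts)

setMethod("show", "ProteinStructure", function(object) {
  cat(sprintf("ProteinStructure '%s': %d chain(s), %d residues, %d atoms\n",
              object@id, length(chainIds(object)), nResidues(object),
              nAtoms(object)))
  if (nzchar(object@title)) cat(" ", object@title, "\n")
})

setMethod("show", "PoseEnsemble", function(object) {
  cat(sprintf("PoseEnsemble '%s': %d frames of %d atoms\n",
              object@id, nFrames(object), nAtoms(object)))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory '%s': %d frames of %d atoms, dt = %g ps (%g ps total)\n",
    object@id, nFrames(object), nAtoms(object), object@dt,
    object@dt * (nFrames(object) - 1)))
})

setMethod("show", "ClusterResult", function(object) {
  sizes <- clusterSizes(object)
  cat(sprintf("ClusterResult: %d poses, %d cluster(s) at cutoff %.2f nm\n",
              object@n, length(sizes), object@cutoff))
  cat("  sizes:", paste(sizes, collapse = ", "), "\n")
  if (length(object@ties))
    cat("  size ties among clusters:",
        paste(vapply(object@ties, paste, "", collapse = "="),
              collapse = "; "), "\n")
})

setMethod("show", "ContactTable", function(object) {
  cat(sprintf("ContactTable: %d contact pair(s) at <= %.1f A\n",
              nrow(object@pairs), object@threshold))
  print(object@counts)
})

setMethod("show", "InterfaceReport", function(object) {
  cat(sprintf("InterfaceReport '%s'\n", object@id))
  cat(sprintf("  interface residues (dSASA > 0): %d\n",
              sum(object@deltaSASA$interface)))
  cat(sprintf("  contacts: %d (threshold %.1f A)\n",
              nrow(object@contacts@pairs), object@contacts@threshold))
  cat(sprintf("  dG = %.1f kcal/mol, Kd = %.1e M at %.2f K\n",
              object@dG, object@kd, object@temperature))
})
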