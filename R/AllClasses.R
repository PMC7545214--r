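#' @import methods
NULL

## Pigment class vocabulary used throughout the package.  "other_pigment"
## collects parsed-but-ignored cofactors (quinones, lipids, ...); it is
## excluded from census totals and from the EET network.
.PIGMENT_CLASSES <- c("chl_a", "chl_c", "fucoxanthin", "diadinoxanthin",
                      "beta_carotene", "other_pigment")
.CHL_CLASSES <- c("chl_a", "chl_c")
.CENSUS_CLASSES <- setdiff(.PIGMENT_CLASSES, "other_pigment")
.CHAIN_ROLES <- c("core", "antenna", "other")

#' PigmentComplex: a parsed pigment-protein supercomplex
#'
#' Container for the atoms, chain annotations and classified pigment
#' records of one coordinate model.  Chlorophyll records carry the Mg
#' position as their representative point; carotenoids carry the
#' unweighted heavy-atom centroid.
#'
#' @slot atoms data.frame of atom records (chain, resname, resno, atom,
#'   element, x, y, z, occupancy, altloc).
#' @slot chains data.frame of chain annotations (chain, subunit, role,
#'   core_letter, antenna_number).
#' @slot pigments data.frame of pigment records (chain, resno, resname,
#'   class, subunit, site, x, y, z, leaflet, near_midplane).
#' @slot sourceId character scalar identifying the input.
#'
#' @export
setClass("PigmentComplex",
         slots = c(atoms = "data.frame",
                   chains = "data.frame",
                   pigments = "data.frame",
                   sourceId = "character"))

setValidity("PigmentComplex", function(object) {
  msgs <- character()
  pg <- object@pigments
  ch <- object@chains
  need <- c("chain", "resno", "class", "subunit", "site",
            "x", "y", "z", "leaflet")
  if (!all(need %in% names(pg)))
    msgs <- c(msgs, paste("pigments lacks columns:",
                          paste(setdiff(need, names(pg)), collapse = ", ")))
  else {
    if (nrow(pg) && !all(pg$chain %in% ch$chain))
      msgs <- c(msgs, "pigment chain ids missing from chain annotations")
    if (nrow(pg) && !all(pg$class %in% .PIGMENT_CLASSES))
      msgs <- c(msgs, "unknown pigment class")
    if (nrow(pg) && !all(is.finite(pg$x) & is.finite(pg$y) & is.finite(pg$z)))
      msgs <- c(msgs, "non-finite pigment coordinates")
    bad_site <- !is.na(pg$site) & (pg$site < 300 | pg$site > 499)
    if (any(bad_site))
      msgs <- c(msgs, "site numbers must lie in [300, 499]")
  }
  if (!all(ch$role %in% .CHAIN_ROLES))
    msgs <- c(msgs, "chain role must be core/antenna/other")
  if (length(msgs)) msgs else TRUE
})

#' MembraneFrame: membrane normal and midplane
#'
#' Defines the stromal/lumenal dichotomy: the unit normal points toward
#' the stromal side and the midplane offset is the absolute projection
#' value (coordinate along the normal) separating the two leaflets.
#'
#' @slot normal unit 3-vector pointing stromal.
#' @slot midplaneOffset scalar projection value (Angstrom).
#' @slot origin 3-vector, the chlorophyll centroid (used to orient the
#'   normal toward the stromal reference).
#'
#' @export
setClass("MembraneFrame",
         slots = c(normal = "numeric",
                   midplaneOffset = "numeric",
                   origin = "numeric"))

setValidity("MembraneFrame", function(object) {
  msgs <- character()
  if (length(object@normal) != 3L || any(!is.finite(object@normal)))
    msgs <- c(msgs, "normal must be a finite 3-vector")
  else if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    msgs <- c(msgs, "normal must have unit length")
  if (length(object@origin) != 3L)
    msgs <- c(msgs, "origin must be a 3-vector")
  if (length(object@midplaneOffset) != 1L || !is.finite(object@midplaneOffset))
    msgs <- c(msgs, "midplaneOffset must be a finite scalar")
  if (length(msgs)) msgs else TRUE
})

## ---- generics ----

#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @export
setGeneric("chainAnnotations", function(x) standardGeneric("chainAnnotations"))
#' @export
setGeneric("pigments", function(x) standardGeneric("pigments"))
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @export
setGeneric("membraneNormal", function(x) standardGeneric("membraneNormal"))
#' @export
setGeneric("midplaneOffset", function(x) standardGeneric("midplaneOffset"))

#' @describeIn PigmentComplex atom record table
#' @param x a \code{PigmentComplex}
#' @export
setMethod("atoms", "PigmentComplex", function(x) x@atoms)

#' @describeIn PigmentComplex chain annotation table
#' @export
setMethod("chainAnnotations", "PigmentComplex", function(x) x@chains)

#' @describeIn PigmentComplex pigment record table
#' @export
setMethod("pigments", "PigmentComplex", function(x) x@pigments)

#' @describeIn PigmentComplex identifier of the parsed input
#' @export
setMethod("sourceId", "PigmentComplex", function(x) x@sourceId)

#' @describeIn MembraneFrame the unit membrane normal (stromal-pointing)
#' @param x a \code{MembraneFrame}
#' @export
setMethod("membraneNormal", "MembraneFrame", function(x) x@normal)

#' @describeIn MembraneFrame projection value of the leaflet midplane
#' @export
setMethod("midplaneOffset", "MembraneFrame", function(x) x@midplaneOffset)

setMethod("show", "PigmentComplex", function(object) {
  pg <- object@pigments
  cls <- table(factor(pg$class, levels = .PIGMENT_CLASSES))
  cat("PigmentComplex object '", object@sourceId, "'\n", sep = "")
  cat("  ", nrow(object@atoms), " atoms, ",
      nrow(object@chains), " chains (",
      sum(object@chains$role == "core"), " core / ",
      sum(object@chains$role == "antenna"), " antenna), ",
      nrow(pg), " pigments\n", sep = "")
  cat("  ", paste(names(cls)[cls > 0], cls[cls > 0], sep = ":",
                  collapse = "  "), "\n", sep = "")
  if (nrow(pg) && any(!is.na(pg$leaflet)))
    cat("  leaflets assigned (",
        sum(pg$leaflet %in% "stromal"), " stromal / ",
        sum(pg$leaflet %in% "lumenal"), " lumenal)\n", sep = "")
  invisible(NULL)
})

setMethod("show", "MembraneFrame", function(object) {
  cat(sprintf("MembraneFrame: normal = (%.4f, %.4f, %.4f), midplane = %.2f A\n",
              object@normal[1], object@normal[2], object@normal[3],
              object@midplaneOffset))
  invisible(NULL)
})

## internal constructor used by the parser and the generator
.newPigmentComplex <- function(atoms, chains, pigments, sourceId) {
  new("PigmentComplex", atoms = atoms, chains = chains,
      pigments = pigments, sourceId = sourceId)
}
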