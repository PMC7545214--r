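#' Estimate the membrane frame from the chlorophyll cloud
#'
#' The membrane plane is taken as the plane of maximal chlorophyll
#' spread: the normal is the eigenvector of the chlorophyll-Mg
#' covariance matrix with the smallest eigenvalue.  Projections of the
#' Mg positions onto the normal are split into two leaflet clusters by
#' deterministic 1-D 2-means (centers initialised at the 25th/75th
#' percentiles and iterated to convergence); the midplane offset is the
#' midpoint of the two cluster centers.  The normal's sign is chosen so
#' that the stromal reference point projects positive.
#'
#' @param model a \code{PigmentComplex} with at least 10 chlorophylls.
#' @param stromalReference optional 3-vector on the stromal side.  When
#'   missing, the centroid of iron-sulfur cluster atoms (residue name
#'   SF4/F3S/FES), which sit on the stromal side of photosystem I, is
#'   used; if none are present an error asks for an explicit reference.
#' @return A \code{\linkS4class{MembraneFrame}}.
#' @export
estimateFrame <- function(model, stromalReference = NULL) {
  stopifnot(is(model, "PigmentComplex"))
  chl <- pigments(model)
  chl <- chl[chl$class %in% .CHL_CLASSES, , drop = FALSE]
  if (nrow(chl) < 10L)
    .stopf("insufficient data: %d chlorophylls (need >= 10)", nrow(chl))
  X <- .coordMatrix(chl)
  origin <- colMeans(X)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  normal <- ev$vectors[, which.min(ev$values)]
  normal <- normal / sqrt(sum(normal^2))
  ## projections are absolute coordinates along the normal, so the
  ## midplane offset is directly comparable to pigment projections
  proj <- as.numeric(X %*% normal)
  km <- .twoMeans1d(proj)
  if (abs(diff(km$centers)) < 5)
    .stopf(paste("degenerate leaflets: projection cluster centers %.2f A",
                 "apart (< 5 A); chlorophylls do not split into two",
                 "leaflet planes"), abs(diff(km$centers)))
  offset <- mean(km$centers)
  if (is.null(stromalReference)) {
    at <- atoms(model)
    fes <- at[at$resname %in% c("SF4", "F3S", "FES"), , drop = FALSE]
    if (!nrow(fes))
      .stopf(paste("no stromal reference: supply stromalReference or a",
                   "model containing iron-sulfur cluster residues"))
    stromalReference <- colMeans(.coordMatrix(fes))
  }
  if (sum((stromalReference - origin) * normal) < 0) {
    normal <- -normal
    offset <- -offset
  }
  new("MembraneFrame", normal = normal, midplaneOffset = offset,
      origin = origin)
}

## deterministic 1-D 2-means, centers initialised at the quartiles
.twoMeans1d <- function(x, maxIter = 200L) {
  ctr <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  if (ctr[1] == ctr[2]) ctr <- ctr + c(-1e-9, 1e-9)
  assign_old <- rep(-1L, length(x))
  for (i in seq_len(maxIter)) {
    assign_new <- ifelse(abs(x - ctr[1]) <= abs(x - ctr[2]), 1L, 2L)
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    for (k in 1:2)
      if (any(assign_new == k)) ctr[k] <- mean(x[assign_new == k])
  }
  list(centers = sort(ctr), cluster = assign_old)
}

#' Assign every pigment to a membrane leaflet
#'
#' Chlorophylls are stromal iff their Mg projection onto the membrane
#' normal exceeds the midplane offset, lumenal otherwise.  Carotenoids
#' (and any other classified pigments) inherit the leaflet of their
#' nearest chlorophyll.  Chlorophylls whose projection falls within
#' \code{flagWithin} of the midplane are flagged (\code{near_midplane})
#' rather than silently forced: intermediate, cross-leaflet pigments
#' straddle the midplane in real antenna systems.
#'
#' @param model a \code{PigmentComplex}.
#' @param frame a \code{MembraneFrame}.
#' @param flagWithin distance (A) from the midplane below which a
#'   chlorophyll is flagged as near-midplane (default 3).
#' @return The model with \code{leaflet} (and \code{near_midplane}) set
#'   on every pigment.
#' @export
assignLeaflets <- function(model, frame, flagWithin = 3) {
  stopifnot(is(model, "PigmentComplex"), is(frame, "MembraneFrame"))
  pg <- pigments(model)
  if (!nrow(pg)) return(model)
  proj <- as.numeric(.coordMatrix(pg) %*% frame@normal)
  is_chl <- pg$class %in% .CHL_CLASSES
  pg$leaflet[is_chl] <- ifelse(proj[is_chl] > frame@midplaneOffset,
                               "stromal", "lumenal")
  pg$near_midplane[is_chl] <-
    abs(proj[is_chl] - frame@midplaneOffset) < flagWithin
  if (any(!is_chl)) {
    if (!any(is_chl))
      .stopf("cannot assign leaflets: no chlorophylls in model")
    Xc <- .coordMatrix(pg[is_chl, , drop = FALSE])
    Xo <- .coordMatrix(pg[!is_chl, , drop = FALSE])
    nn <- apply(Xo, 1, function(p)
      which.min(colSums((t(Xc) - p)^2)))
    pg$leaflet[!is_chl] <- pg$leaflet[is_chl][nn]
    pg$near_midplane[!is_chl] <- FALSE
  }
  model@pigments <- pg
  validObject(model)
  model
}
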