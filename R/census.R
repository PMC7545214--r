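#' Pigment census of a parsed supercomplex
#'
#' Exact integer counts per pigment class, split into core-bound and
#' antenna-bound (by chain role), plus a per-subunit table and, when the
#' counts allow it, the derived stoichiometry ratios.  The class
#' "other_pigment" is excluded from totals.
#'
#' @param model a \code{PigmentComplex} with annotated chains.
#' @return list of class \code{CensusReport}: \code{counts} (data.frame
#'   class x total/core/antenna), \code{per_subunit} (data.frame),
#'   \code{total_pigments}, \code{n_antennas}, and \code{ratios} (from
#'   \code{\link{ratioReport}}, or NULL when a denominator is zero).
#' @export
pigmentCensus <- function(model) {
  stopifnot(is(model, "PigmentComplex"))
  pg <- pigments(model)
  ch <- chainAnnotations(model)
  pg <- pg[pg$class %in% .CENSUS_CLASSES, , drop = FALSE]
  role <- ch$role[match(pg$chain, ch$chain)]
  cl <- factor(pg$class, levels = .CENSUS_CLASSES)
  counts <- data.frame(
    class = .CENSUS_CLASSES,
    total = as.integer(table(cl)),
    core = as.integer(table(cl[role == "core"])),
    antenna = as.integer(table(cl[role == "antenna"])),
    stringsAsFactors = FALSE)
  per_subunit <- as.data.frame.matrix(
    table(pg$subunit, cl), stringsAsFactors = FALSE)
  per_subunit <- cbind(subunit = rownames(per_subunit), per_subunit,
                       stringsAsFactors = FALSE)
  rownames(per_subunit) <- NULL
  n_antennas <- sum(ch$role == "antenna")
  cnt <- stats::setNames(counts$total, counts$class)
  core <- stats::setNames(counts$core, counts$class)
  ratios <- NULL
  if (n_antennas > 0 && cnt["chl_c"] > 0 &&
      (cnt["fucoxanthin"] + cnt["diadinoxanthin"]) > 0) {
    ratios <- ratioReport(chlATotal = cnt[["chl_a"]],
                          chlACore = core[["chl_a"]],
                          chlCTotal = cnt[["chl_c"]],
                          fxTotal = cnt[["fucoxanthin"]],
                          ddxTotal = cnt[["diadinoxanthin"]],
                          nAntennas = n_antennas)
  }
  structure(list(counts = counts, per_subunit = per_subunit,
                 total_pigments = sum(counts$total),
                 n_antennas = n_antennas, ratios = ratios),
            class = "CensusReport")
}

#' @export
print.CensusReport <- function(x, ...) {
  cat("Pigment census:", x$total_pigments, "pigments,",
      x$n_antennas, "antenna subunits\n")
  print(x$counts, row.names = FALSE)
  if (!is.null(x$ratios)) {
    cat(sprintf("Chl a/c (antenna-bound) = %.2f; Chl c per antenna = %.1f; Chl/Car = %.2f\n",
                x$ratios$chl_a_to_c, x$ratios$avg_chl_c_per_antenna,
                x$ratios$chl_to_car))
  }
  invisible(x)
}

#' Stoichiometry ratios from census counts
#'
#' The published arithmetic: the antenna chlorophyll-a pool is the total
#' minus the core-bound count; Chl a/c divides it by the chlorophyll-c
#' total (2 d.p., half-up); the average Chl c per antenna divides the
#' chlorophyll-c total by the number of antenna subunits (1 d.p.); the
#' Chl/Car ratio divides all antenna chlorophylls (a + c) by all
#' fucoxanthins plus diadinoxanthins, including the few core-bound ones
#' (2 d.p.) - this denominator choice reproduces the published value.
#'
#' @param chlATotal,chlACore,chlCTotal,fxTotal,ddxTotal non-negative
#'   integer counts.
#' @param nAntennas number of antenna subunits (> 0).
#' @return list(chl_a_to_c, avg_chl_c_per_antenna, chl_to_car), rounded
#'   half-up at the printed precision; full-precision values under
#'   \code{raw}.
#' @export
ratioReport <- function(chlATotal, chlACore, chlCTotal, fxTotal, ddxTotal,
                        nAntennas) {
  v <- c(chlATotal = chlATotal, chlACore = chlACore, chlCTotal = chlCTotal,
         fxTotal = fxTotal, ddxTotal = ddxTotal, nAntennas = nAntennas)
  if (any(v < 0)) .stopf("census counts must be non-negative")
  if (chlACore > chlATotal) .stopf("core chlorophyll a exceeds total")
  if (chlCTotal == 0) .stopf("division by zero: chlCTotal")
  if (nAntennas <= 0) .stopf("division by zero: nAntennas")
  if (fxTotal + ddxTotal == 0) .stopf("division by zero: fxTotal + ddxTotal")
  a_antenna <- chlATotal - chlACore
  raw <- list(chl_a_to_c = a_antenna / chlCTotal,
              avg_chl_c_per_antenna = chlCTotal / nAntennas,
              chl_to_car = (a_antenna + chlCTotal) / (fxTotal + ddxTotal))
  list(chl_a_to_c = .roundHalfUp(raw$chl_a_to_c, 2),
       avg_chl_c_per_antenna = .roundHalfUp(raw$avg_chl_c_per_antenna, 1),
       chl_to_car = .roundHalfUp(raw$chl_to_car, 2),
       raw = raw)
}

#' Census arithmetic from a printed counts table
#'
#' Pure-arithmetic mode: consumes per-class counts (no structure needed)
#' and returns the total pigment count and the stoichiometry ratios.
#'
#' @param counts named numeric vector or list with entries chl_a, chl_c,
#'   fucoxanthin, diadinoxanthin, beta_carotene.
#' @param chlACore core-bound chlorophyll-a count.
#' @param nAntennas number of antenna subunits.
#' @return list(total_pigments, ratios).
#' @export
censusFromCounts <- function(counts, chlACore, nAntennas) {
  counts <- unlist(counts)
  need <- .CENSUS_CLASSES
  if (!all(need %in% names(counts)))
    .stopf("counts lacks entries: %s",
           paste(setdiff(need, names(counts)), collapse = ", "))
  list(total_pigments = sum(counts[need]),
       ratios = ratioReport(chlATotal = counts[["chl_a"]],
                            chlACore = chlACore,
                            chlCTotal = counts[["chl_c"]],
                            fxTotal = counts[["fucoxanthin"]],
                            ddxTotal = counts[["diadinoxanthin"]],
                            nAntennas = nAntennas))
}
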