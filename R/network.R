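#' Mg-Mg distance between two chlorophylls
#'
#' Euclidean distance between the central Mg atoms, the standard
#' proximity proxy for excitation-transfer coupling strength.  Reported
#' tables round to 0.1 A; the full-precision value is returned here.
#'
#' @param p,q single pigment-record rows (from \code{pigments(x)}), both
#'   of chlorophyll class (their representative point is then the Mg
#'   position).
#' @return distance in Angstrom.
#' @export
mgMgDistance <- function(p, q) {
  stopifnot(is.data.frame(p), nrow(p) == 1L, is.data.frame(q), nrow(q) == 1L)
  if (!(p$class %in% .CHL_CLASSES) || !(q$class %in% .CHL_CLASSES))
    .stopf("mgMgDistance is defined for chlorophylls only (got %s, %s)",
           p$class, q$class)
  sqrt((p$x - q$x)^2 + (p$y - q$y)^2 + (p$z - q$z)^2)
}

#' Find coupled chlorophyll pairs
#'
#' All unordered pairs of chlorophylls (of the requested classes) whose
#' Mg-Mg distance is at most \code{pairCutoff}, annotated with their
#' leaflet and whether both partners sit in the same subunit.  Pairs are
#' stored canonically (lexicographically smaller pigment id first) and
#' sorted, so the result is deterministic and order-independent.
#'
#' @param model a \code{PigmentComplex} (leaflets should be assigned).
#' @param pairCutoff Mg-Mg cutoff in Angstrom (> 0); 12 A by default,
#'   bracketing published coupled-pair distances (9.5-11 A).
#' @param classes chlorophyll classes to consider.
#' @return data.frame with one row per pair: chain/resno/site of both
#'   partners, subunits, distance, leaflet ("mixed" if the partners
#'   disagree), same_subunit.
#' @export
findCoupledPairs <- function(model, pairCutoff = 12,
                             classes = c("chl_a", "chl_c")) {
  stopifnot(is(model, "PigmentComplex"))
  if (pairCutoff <= 0) .stopf("pairCutoff must be > 0")
  bad <- setdiff(classes, .CHL_CLASSES)
  if (length(bad))
    .stopf("coupled pairs are defined for chlorophylls (got %s)",
           paste(bad, collapse = ", "))
  pg <- pigments(model)
  pg <- pg[pg$class %in% classes, , drop = FALSE]
  empty <- data.frame(chain_a = character(), resno_a = integer(),
                      chain_b = character(), resno_b = integer(),
                      subunit_a = character(), subunit_b = character(),
                      class_a = character(), class_b = character(),
                      distance = numeric(), leaflet = character(),
                      same_subunit = logical(), stringsAsFactors = FALSE)
  if (nrow(pg) < 2L) return(empty)
  X <- .coordMatrix(pg)
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  hits <- which(upper.tri(d2) & d2 <= pairCutoff^2, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  id <- paste(pg$chain, formatC(pg$resno, width = 6, flag = "0"))
  rows <- lapply(seq_len(nrow(hits)), function(k) {
    i <- hits[k, 1]; j <- hits[k, 2]
    if (id[j] < id[i]) { tmp <- i; i <- j; j <- tmp }
    lf <- if (!is.na(pg$leaflet[i]) && identical(pg$leaflet[i], pg$leaflet[j]))
      pg$leaflet[i] else if (any(is.na(pg$leaflet[c(i, j)])))
        NA_character_ else "mixed"
    data.frame(chain_a = pg$chain[i], resno_a = pg$resno[i],
               chain_b = pg$chain[j], resno_b = pg$resno[j],
               subunit_a = pg$subunit[i], subunit_b = pg$subunit[j],
               class_a = pg$class[i], class_b = pg$class[j],
               distance = sqrt(d2[hits[k, 1], hits[k, 2]]),
               leaflet = lf,
               same_subunit = identical(pg$subunit[i], pg$subunit[j]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chain_a, out$resno_a, out$chain_b, out$resno_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive inter-subunit EET steps from Mg-Mg distances
#'
#' For every ordered subunit pair whose donor shell index is strictly
#' larger than the acceptor's (outer antenna toward inner antenna or
#' core) and for each leaflet, the single minimal chlorophyll-a Mg-Mg
#' distance is emitted as a directed excitation-energy-transfer step if
#' it does not exceed \code{stepCutoff}.  Steps longer than 20 A are
#' flagged as not efficient.
#'
#' @param model a \code{PigmentComplex} with leaflets assigned.
#' @param shells named shell-index vector from \code{\link{assignLayers}}.
#' @param stepCutoff Mg-Mg cutoff in Angstrom; the 26 A default brackets
#'   the largest published antenna-to-core step (25.7 A).
#' @return data.frame of steps: donor/acceptor subunit, chain, resno
#'   (site label), distance, leaflet, efficient.
#' @export
deriveEETSteps <- function(model, shells, stepCutoff = 26) {
  stopifnot(is(model, "PigmentComplex"))
  if (stepCutoff <= 0) .stopf("stepCutoff must be > 0")
  pg <- pigments(model)
  pg <- pg[pg$class == "chl_a" & !is.na(pg$leaflet), , drop = FALSE]
  empty <- data.frame(donor_subunit = character(), donor_chain = character(),
                      donor_site = integer(), acceptor_subunit = character(),
                      acceptor_chain = character(), acceptor_site = integer(),
                      distance = numeric(), leaflet = character(),
                      efficient = logical(), stringsAsFactors = FALSE)
  if (!nrow(pg)) return(empty)
  pg <- pg[pg$subunit %in% names(shells)[is.finite(shells)], , drop = FALSE]
  if (!nrow(pg)) return(empty)
  subs <- unique(pg$subunit)
  sh <- shells[subs]
  rows <- list()
  for (don in subs) {
    for (acc in subs) {
      if (!(sh[don] > sh[acc])) next
      for (lf in c("stromal", "lumenal")) {
        dpg <- pg[pg$subunit == don & pg$leaflet == lf, , drop = FALSE]
        apg <- pg[pg$subunit == acc & pg$leaflet == lf, , drop = FALSE]
        if (!nrow(dpg) || !nrow(apg)) next
        md <- .minCrossDist(.coordMatrix(dpg), .coordMatrix(apg))
        if (md$dist > stepCutoff) next
        rows[[length(rows) + 1L]] <- data.frame(
          donor_subunit = don, donor_chain = dpg$chain[md$i],
          donor_site = dpg$resno[md$i],
          acceptor_subunit = acc, acceptor_chain = apg$chain[md$j],
          acceptor_site = apg$resno[md$j],
          distance = md$dist, leaflet = lf,
          efficient = md$dist <= 20, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$leaflet, out$donor_subunit, out$acceptor_subunit), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a step edge list
#'
#' Reads the flat TSV encoding of EET steps (columns donor_subunit,
#' donor_site, acceptor_subunit, acceptor_site, distance_A, leaflet), the
#' format used by the packaged pathway-table fixture.
#'
#' @param path TSV file with header.
#' @return data.frame of steps with an \code{efficient} flag added.
#' @export
readStepEdges <- function(path) {
  if (!file.exists(path)) .stopf("edge-list file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("donor_subunit", "donor_site", "acceptor_subunit",
            "acceptor_site", "distance_A", "leaflet")
  if (!all(need %in% names(df)))
    .stopf("edge list %s lacks columns: %s", path,
           paste(setdiff(need, names(df)), collapse = ", "))
  data.frame(donor_subunit = df$donor_subunit,
             donor_site = as.integer(df$donor_site),
             acceptor_subunit = df$acceptor_subunit,
             acceptor_site = as.integer(df$acceptor_site),
             distance = as.numeric(df$distance_A),
             leaflet = tolower(df$leaflet),
             efficient = as.numeric(df$distance_A) <= 20,
             stringsAsFactors = FALSE)
}

.subunitAnnotation <- function(subunits, annotations = NULL) {
  if (!is.null(annotations)) {
    m <- match(subunits, annotations$subunit)
    if (any(is.na(m)))
      .stopf("subunit(s) missing from annotations: %s",
             paste(subunits[is.na(m)], collapse = ", "))
    data.frame(subunit = subunits, role = annotations$role[m],
               core_letter = annotations$core_letter[m],
               antenna_number = annotations$antenna_number[m],
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(subunits, function(s) {
      a <- labelAnnotation(s)
      data.frame(subunit = s, role = a$role, core_letter = a$core_letter,
                 antenna_number = a$antenna_number, stringsAsFactors = FALSE)
    }))
  }
}

#' Canonical pathway code
#'
#' Encodes an ordered subunit chain ending at a core subunit: antenna
#' numbers in donor order joined by dashes, then the core subunit's
#' single code letter, then "S" (stromal) or "L" (lumenal).  For
#' example, FCPI-18 -> FCPI-17 -> FCPI-6 -> PsaA on the lumenal side is
#' "18-17-6-AL".
#'
#' @param subunits character vector, the chain of subunit labels from
#'   source to core terminal.
#' @param leaflet "stromal" or "lumenal".
#' @param annotations optional annotation data.frame (subunit, role,
#'   core_letter, antenna_number); by default annotations are inferred
#'   from the labels (\code{\link{labelAnnotation}}).
#' @return character code.
#' @export
pathwayCode <- function(subunits, leaflet, annotations = NULL) {
  if (!length(subunits)) .stopf("empty pathway")
  leaflet <- match.arg(leaflet, c("stromal", "lumenal"))
  ann <- .subunitAnnotation(subunits, annotations)
  n <- nrow(ann)
  if (ann$role[n] != "core" || is.na(ann$core_letter[n]))
    .stopf("pathway must end at a core subunit with a code letter (got %s)",
           ann$subunit[n])
  if (n > 1L && any(ann$role[-n] != "antenna" | is.na(ann$antenna_number[-n])))
    .stopf("non-terminal pathway members must be numbered antennas")
  paste0(paste(c(ann$antenna_number[-n],
                 ann$core_letter[n]), collapse = "-"),
         if (leaflet == "stromal") "S" else "L")
}

#' Assemble EET pathways from a step collection
#'
#' Per leaflet, the directed step graph must be acyclic (shell indices
#' strictly decrease along steps except for the terminal core hop).
#' Sources are subunits with at least one outgoing and no incoming step;
#' pathways are all maximal simple chains followed from a source until a
#' core subunit is reached.  A branching source yields one pathway per
#' branch, and chains converging on a shared inner step each count
#' separately.  Chains that dead-end before reaching a core are emitted
#' with \code{complete = FALSE} plus a warning and are excluded from the
#' headline pathway count.
#'
#' @param steps step data.frame (\code{\link{deriveEETSteps}} or
#'   \code{\link{readStepEdges}}).
#' @param annotations optional subunit annotation table; defaults to
#'   label inference.
#' @return data.frame with one row per step of each pathway: pathway_id,
#'   code, complete, step (index within pathway), the step columns, and
#'   leaflet.  The attribute \code{codes} holds the distinct codes of
#'   complete pathways.
#' @export
assemblePathways <- function(steps, annotations = NULL) {
  cols <- c("pathway_id", "code", "complete", "step", "donor_subunit",
            "donor_site", "acceptor_subunit", "acceptor_site", "distance",
            "leaflet", "efficient")
  if (is.null(steps) || !nrow(steps)) {
    out <- data.frame(pathway_id = integer(), code = character(),
                      complete = logical(), step = integer(),
                      donor_subunit = character(), donor_site = integer(),
                      acceptor_subunit = character(),
                      acceptor_site = integer(), distance = numeric(),
                      leaflet = character(), efficient = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "codes") <- character()
    return(out)
  }
  if (!"efficient" %in% names(steps)) steps$efficient <- steps$distance <= 20
  if (!"donor_site" %in% names(steps)) steps$donor_site <- NA_integer_
  if (!"acceptor_site" %in% names(steps)) steps$acceptor_site <- NA_integer_
  ## drop duplicate edges (a step shared by two pathways is one edge)
  key <- paste(steps$donor_subunit, steps$acceptor_subunit, steps$leaflet)
  steps <- steps[!duplicated(key), , drop = FALSE]
  ann <- .subunitAnnotation(unique(c(steps$donor_subunit,
                                     steps$acceptor_subunit)), annotations)
  paths <- list(); pid <- 0L
  for (lf in unique(steps$leaflet)) {
    st <- steps[steps$leaflet == lf, , drop = FALSE]
    .checkAcyclic(st, lf)
    incoming <- unique(st$acceptor_subunit)
    sources <- setdiff(unique(st$donor_subunit), incoming)
    core_of <- stats::setNames(ann$role, ann$subunit)
    walk <- function(node, idx_trail, visited) {
      out_edges <- which(st$donor_subunit == node)
      if (core_of[node] == "core" || !length(out_edges)) {
        pid <<- pid + 1L
        chain <- c(st$donor_subunit[idx_trail],
                   st$acceptor_subunit[idx_trail[length(idx_trail)]])
        complete <- core_of[node] == "core"
        code <- if (complete) pathwayCode(chain, lf, annotations) else
          NA_character_
        seg <- st[idx_trail, , drop = FALSE]
        seg$pathway_id <- pid
        seg$code <- code
        seg$complete <- complete
        seg$step <- seq_along(idx_trail)
        paths[[length(paths) + 1L]] <<- seg
        return(invisible(NULL))
      }
      for (e in out_edges) {
        nxt <- st$acceptor_subunit[e]
        if (nxt %in% visited) next  # guarded by acyclicity check anyway
        walk(nxt, c(idx_trail, e), c(visited, nxt))
      }
      invisible(NULL)
    }
    for (s in sources) {
      for (e in which(st$donor_subunit == s)) {
        walk(st$acceptor_subunit[e], e, c(s, st$acceptor_subunit[e]))
      }
    }
  }
  out <- do.call(rbind, paths)
  out <- out[, cols, drop = FALSE]
  rownames(out) <- NULL
  if (any(!out$complete))
    warning(sprintf("%d chain(s) end at a non-core subunit; excluded from %s",
                    length(unique(out$pathway_id[!out$complete])),
                    "the pathway count"), call. = FALSE)
  attr(out, "codes") <- unique(out$code[out$complete & out$step == 1L])
  out
}

.checkAcyclic <- function(st, leaflet) {
  g <- igraph::graph_from_data_frame(
    st[, c("donor_subunit", "acceptor_subunit")], directed = TRUE)
  if (!igraph::is_dag(g)) {
    ## peel sources/sinks; what remains lies on a cycle
    repeat {
      deg_in <- igraph::degree(g, mode = "in")
      deg_out <- igraph::degree(g, mode = "out")
      drop <- names(which(deg_in == 0 | deg_out == 0))
      if (!length(drop)) break
      g <- igraph::delete_vertices(g, drop)
    }
    .stopf("cycle detected in %s step graph involving: %s", leaflet,
           paste(igraph::V(g)$name, collapse = ", "))
  }
  invisible(TRUE)
}

#' Distinct codes of assembled complete pathways
#'
#' @param paths result of \code{\link{assemblePathways}}.
#' @return character vector of codes.
#' @export
pathwayCodes <- function(paths) {
  cd <- attr(paths, "codes")
  if (!is.null(cd)) return(cd)
  unique(paths$code[paths$complete & paths$step == 1L])
}

#' Pathway report table
#'
#' One row per step, grouped by pathway code, mirroring the published
#' table layout: code, hop ("FCPI-18 -> FCPI-17"), pigment pair, Mg-Mg
#' distance rounded half-up to 0.1 A, leaflet location, and the
#' efficiency flag (steps above 20 A are marked not efficient).
#'
#' @param paths result of \code{\link{assemblePathways}}.
#' @param includeIncomplete also list chains that did not reach a core
#'   subunit (default FALSE).
#' @return data.frame.
#' @export
pathwayReport <- function(paths, includeIncomplete = FALSE) {
  keep <- if (includeIncomplete) rep(TRUE, nrow(paths)) else paths$complete
  p <- paths[keep, , drop = FALSE]
  if (!nrow(p))
    return(data.frame(code = character(), step = integer(),
                      pathway = character(), pigments = character(),
                      distance_A = numeric(), location = character(),
                      efficient = logical(), stringsAsFactors = FALSE))
  out <- data.frame(
    code = ifelse(is.na(p$code), "(incomplete)", p$code),
    step = p$step,
    pathway = paste0(p$donor_subunit, "→", p$acceptor_subunit),
    pigments = paste0("a", p$donor_site, "–a", p$acceptor_site),
    distance_A = .roundHalfUp(p$distance, 1),
    location = ifelse(p$leaflet == "stromal", "Stromal", "Lumenal"),
    efficient = p$efficient,
    stringsAsFactors = FALSE)
  out[order(match(out$code, unique(out$code)), out$step), , drop = FALSE]
}

#' Packaged encoding of the published PSI-FCPI pathway table
#'
#' Returns the packaged edge list of the 34 distinct donor-to-acceptor
#' EET steps underlying the 18 published antenna-to-core pathways of the
#' diatom PSI-FCPI supercomplex (the printed table lists 36 step rows;
#' two inner steps are each shared by two pathways and appear once
#' here).
#'
#' @return step data.frame as from \code{\link{readStepEdges}}.
#' @export
publishedStepTable <- function() {
  readStepEdges(system.file("extdata", "psi_fcpi_steps.tsv",
                            package = "pigmentNet", mustWork = TRUE))
}
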