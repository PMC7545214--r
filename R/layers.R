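#' Build the subunit contact graph
#'
#' Two annotated subunits (role core or antenna) share an edge iff any
#' pair of heavy atoms between their chains lies within
#' \code{contactCutoff}; the edge weight is that minimal distance.  The
#' 4 A default is the standard crystallographic heavy-atom contact
#' criterion.
#'
#' @param model a \code{PigmentComplex} with at least two annotated
#'   (core/antenna) chains.
#' @param contactCutoff heavy-atom distance cutoff in Angstrom (> 0).
#' @return An undirected \pkg{igraph} graph whose vertices carry
#'   \code{name} (subunit label) and \code{role} attributes and whose
#'   edges carry the minimal inter-chain distance as \code{weight}.
#' @export
buildContactGraph <- function(model, contactCutoff = 4) {
  stopifnot(is(model, "PigmentComplex"))
  if (contactCutoff <= 0) .stopf("contactCutoff must be > 0")
  ch <- chainAnnotations(model)
  ch <- ch[ch$role %in% c("core", "antenna"), , drop = FALSE]
  if (nrow(ch) < 2L) .stopf("need >= 2 annotated (core/antenna) chains")
  at <- atoms(model)
  at <- at[toupper(at$element) != "H", , drop = FALSE]
  coords <- lapply(ch$chain, function(cid)
    .coordMatrix(at[at$chain == cid, , drop = FALSE]))
  names(coords) <- ch$subunit
  ## bounding-box prefilter before exact all-pairs distance
  lo <- t(vapply(coords, function(m) apply(m, 2, min), numeric(3)))
  hi <- t(vapply(coords, function(m) apply(m, 2, max), numeric(3)))
  n <- nrow(ch)
  edges <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      gap <- pmax(lo[i, ] - hi[j, ], lo[j, ] - hi[i, ], 0)
      if (sqrt(sum(gap^2)) > contactCutoff) next
      md <- .minCrossDist(coords[[i]], coords[[j]])
      if (md$dist <= contactCutoff)
        edges[[length(edges) + 1L]] <-
          data.frame(from = ch$subunit[i], to = ch$subunit[j],
                     weight = md$dist, stringsAsFactors = FALSE)
    }
  }
  el <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), weight = numeric())
  g <- igraph::graph_from_data_frame(
    el, directed = FALSE,
    vertices = data.frame(name = ch$subunit, role = ch$role,
                          stringsAsFactors = FALSE))
  g
}

#' Classify antenna subunits into concentric layers
#'
#' The shell index of a subunit is its breadth-first (unweighted
#' shortest-path) distance in the contact graph from the set of core
#' subunits, expanded from all core nodes simultaneously: 0 = core,
#' 1 = innermost antenna layer, 2 = middle, 3 = outermost.  Antennas
#' disconnected from the core get index \code{Inf} with a warning, and
#' indices above 3 are reported as-is with a warning.
#'
#' @param graph contact graph from \code{\link{buildContactGraph}}.
#' @param annotations optional chain annotation data.frame; when given,
#'   its subunit -> role mapping overrides the graph's role attribute.
#' @return Named numeric vector of shell indices (name = subunit label).
#' @export
assignLayers <- function(graph, annotations = NULL) {
  roles <- igraph::vertex_attr(graph, "role")
  nodes <- igraph::vertex_attr(graph, "name")
  if (!is.null(annotations)) {
    m <- match(nodes, annotations$subunit)
    roles <- ifelse(is.na(m), roles, annotations$role[m])
  }
  core <- nodes[roles == "core"]
  if (!length(core)) .stopf("contact graph contains no core subunit")
  d <- igraph::distances(graph, v = core, to = igraph::V(graph),
                         weights = NA)
  shell <- apply(d, 2, min)
  names(shell) <- nodes
  shell[roles == "core"] <- 0
  if (any(is.infinite(shell)))
    warning(sprintf("antenna subunit(s) disconnected from core: %s",
                    paste(names(shell)[is.infinite(shell)], collapse = ", ")),
            call. = FALSE)
  if (any(is.finite(shell) & shell > 3))
    warning(sprintf("shell index > 3 for: %s",
                    paste(names(shell)[is.finite(shell) & shell > 3],
                          collapse = ", ")),
            call. = FALSE)
  shell
}

#' Layer table
#'
#' Convenience TSV-ready summary of a layer assignment: one row per
#' subunit with its shell index and contact degree.
#'
#' @param graph contact graph.
#' @param shells result of \code{\link{assignLayers}}.
#' @return data.frame (subunit, role, shell, n_contacts).
#' @export
layerTable <- function(graph, shells) {
  nodes <- igraph::vertex_attr(graph, "name")
  data.frame(subunit = nodes,
             role = igraph::vertex_attr(graph, "role"),
             shell = unname(shells[nodes]),
             n_contacts = unname(igraph::degree(graph)),
             stringsAsFactors = FALSE)
}
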