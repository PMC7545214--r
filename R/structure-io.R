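#' Pigment class map
#'
#' Maps chemical-component codes (mmCIF/PDB residue names) to pigment
#' classes.  The packaged default covers the codes used in
#' fucoxanthin-chlorophyll protein depositions: CLA (chlorophyll a),
#' KC1/KC2 (chlorophyll c1/c2), A86 (fucoxanthin), DD6 (diadinoxanthin)
#' and BCR (beta-carotene).  Component codes vary across depositions, so
#' the map ships as an editable YAML config rather than being
#' hard-coded.
#'
#' @param path YAML file with a top-level \code{classes} mapping
#'   (component code -> class) and an optional logical \code{strict}.
#' @return A list with elements \code{classes} (named character vector)
#'   and \code{strict} (logical; in strict mode a chlorophyll residue
#'   without an Mg atom is an error instead of a skipped warning).
#' @export
readClassMap <- function(path) {
  if (!file.exists(path)) .stopf("class map file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$classes)) .stopf("class map %s lacks a 'classes' block", path)
  cl <- vapply(y$classes, as.character, character(1))
  .validateClassMap(cl)
  list(classes = cl, strict = isTRUE(y$strict))
}

#' @rdname readClassMap
#' @export
defaultClassMap <- function() {
  readClassMap(system.file("extdata", "pigment_classes.yaml",
                           package = "pigmentNet", mustWork = TRUE))
}

.validateClassMap <- function(cl) {
  bad <- setdiff(unique(cl), .PIGMENT_CLASSES)
  if (length(bad))
    .stopf("unknown pigment class(es) in map: %s", paste(bad, collapse = ", "))
  if (anyDuplicated(names(cl)))
    .stopf("component code mapped to two classes: %s",
           paste(names(cl)[duplicated(names(cl))], collapse = ", "))
  invisible(cl)
}

#' Chain annotation config
#'
#' Maps chain identifiers to subunit labels and roles.  Entries may be a
#' bare subunit label (role, core letter and antenna number are then
#' inferred from the label: \code{Psa<X>} is a core subunit with code
#' letter \code{X}; \code{FCPI-<n>} is antenna number \code{n}) or a map
#' with explicit \code{subunit}, \code{role}, \code{core_letter},
#' \code{antenna_number} fields.
#'
#' @param path YAML file with a top-level \code{chains} mapping.
#' @return data.frame with columns chain, subunit, role, core_letter,
#'   antenna_number.
#' @export
readChainConfig <- function(path) {
  if (!file.exists(path)) .stopf("chain config file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$chains)) .stopf("chain config %s lacks a 'chains' block", path)
  rows <- lapply(names(y$chains), function(ch) {
    e <- y$chains[[ch]]
    if (is.character(e) && length(e) == 1L) {
      ann <- labelAnnotation(e)
    } else {
      ann <- labelAnnotation(e$subunit)
      if (!is.null(e$role)) ann$role <- e$role
      if (!is.null(e$core_letter)) ann$core_letter <- e$core_letter
      if (!is.null(e$antenna_number))
        ann$antenna_number <- as.integer(e$antenna_number)
    }
    data.frame(chain = ch, subunit = ann$subunit, role = ann$role,
               core_letter = ann$core_letter,
               antenna_number = ann$antenna_number,
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  .validateChainAnnotations(ann)
}

.validateChainAnnotations <- function(ann) {
  if (anyDuplicated(ann$chain))
    .stopf("duplicate chain id in config: %s",
           paste(unique(ann$chain[duplicated(ann$chain)]), collapse = ", "))
  if (!all(ann$role %in% .CHAIN_ROLES))
    .stopf("chain role must be one of %s", paste(.CHAIN_ROLES, collapse = "/"))
  if (any(ann$role == "core" & is.na(ann$core_letter)))
    .stopf("core chains need a core_letter: %s",
           paste(ann$chain[ann$role == "core" & is.na(ann$core_letter)],
                 collapse = ", "))
  if (any(ann$role != "core" & !is.na(ann$core_letter)))
    .stopf("core_letter set on non-core chain")
  if (any(ann$role == "antenna" & is.na(ann$antenna_number)))
    .stopf("antenna chains need an antenna_number")
  if (any(ann$role != "antenna" & !is.na(ann$antenna_number)))
    .stopf("antenna_number set on non-antenna chain")
  nn <- ann$antenna_number[!is.na(ann$antenna_number)]
  if (anyDuplicated(nn))
    .stopf("antenna_number must be unique among antennas")
  ann
}

#' Infer an annotation from a subunit label
#'
#' \code{Psa<X>} labels are core subunits with pathway-code letter
#' \code{X}; \code{FCPI-<n>} labels are antennas numbered \code{n};
#' anything else is role "other".
#'
#' @param subunit character label, e.g. "PsaA" or "FCPI-8".
#' @return list(subunit, role, core_letter, antenna_number)
#' @export
labelAnnotation <- function(subunit) {
  stopifnot(is.character(subunit), length(subunit) == 1L)
  if (grepl("^Psa[A-Z]$", subunit)) {
    list(subunit = subunit, role = "core",
         core_letter = sub("^Psa", "", subunit), antenna_number = NA_integer_)
  } else if (grepl("^FCPI-[0-9]+$", subunit)) {
    list(subunit = subunit, role = "antenna", core_letter = NA_character_,
         antenna_number = as.integer(sub("^FCPI-", "", subunit)))
  } else {
    list(subunit = subunit, role = "other", core_letter = NA_character_,
         antenna_number = NA_integer_)
  }
}

#' Parse a coordinate file and extract classified pigment records
#'
#' Reads an mmCIF (preferred) or legacy PDB file, annotates chains from
#' the chain config, and builds one pigment record per residue whose
#' chemical-component code appears in the class map.  Chlorophyll
#' records take the Mg atom position as their representative point;
#' carotenoids (and other classes) take the unweighted heavy-atom
#' centroid.  Where a residue has alternate-location conformers only the
#' highest-occupancy conformer of each atom is kept (ties broken by
#' altloc letter, so parsing is deterministic).
#'
#' @param path coordinate file; extension .cif/.mmcif selects the mmCIF
#'   reader, anything else the PDB reader.
#' @param classMap list as returned by \code{\link{readClassMap}}.
#' @param chainConfig chain annotation data.frame
#'   (\code{\link{readChainConfig}}) or path to a YAML config.  Chains
#'   absent from the config are annotated with role "other".
#' @return A \code{\linkS4class{PigmentComplex}}.
#' @export
parseStructure <- function(path, classMap = defaultClassMap(),
                           chainConfig = NULL) {
  if (!file.exists(path)) .stopf("coordinate file not found: %s", path)
  if (is.character(chainConfig)) chainConfig <- readChainConfig(chainConfig)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  parsed <- tryCatch(
    suppressWarnings(
      ## rm.alt = FALSE: alternate conformers are resolved here by
      ## occupancy, not by the reader's keep-"A" policy
      if (is_cif) bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
      else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    ),
    error = function(e)
      .stopf("parse error in '%s': %s", path, conditionMessage(e)))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L)
    .stopf("parse error in '%s': no atom records", path)
  ## integrity: every ATOM/HETATM line of the file must be represented
  ## and, for mmCIF, carry the full declared field count; a file
  ## truncated mid-record must not yield a silent partial model
  lines <- readLines(path, warn = FALSE)
  atom_lines <- grep("^(ATOM|HETATM)", lines, value = TRUE)
  if (length(atom_lines) != nrow(at))
    .stopf("parse error in '%s': %d atom lines but %d parsed records (truncated or malformed file?)",
           path, length(atom_lines), nrow(at))
  if (is_cif) {
    n_fields <- sum(grepl("^_atom_site\\.", lines))
    got <- lengths(strsplit(trimws(atom_lines), "[ \t]+"))
    if (n_fields > 0L && any(got != n_fields))
      .stopf("parse error in '%s': atom record with %d of %d fields (truncated mid-record?)",
             path, min(got), n_fields)
  }
  atoms <- data.frame(chain = as.character(at$chain),
                      resname = as.character(at$resid),
                      resno = as.integer(at$resno),
                      atom = as.character(at$elety),
                      element = as.character(at$elesy),
                      x = at$x, y = at$y, z = at$z,
                      occupancy = ifelse(is.na(at$o), 1, at$o),
                      altloc = ifelse(is.na(at$alt) | at$alt == "",
                                      "", as.character(at$alt)),
                      stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    .stopf("parse error in '%s': non-finite coordinates", path)
  atoms <- .resolveAltloc(atoms)
  chains <- .annotateChains(unique(atoms$chain), chainConfig)
  pigments <- .extractPigments(atoms, chains, classMap)
  .newPigmentComplex(atoms, chains, pigments, basename(path))
}

## keep, per (chain, resno, atom name), the highest-occupancy conformer
.resolveAltloc <- function(atoms) {
  has_alt <- atoms$altloc != ""
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$resname, atoms$atom, sep = "\r")
  idx <- seq_len(nrow(atoms))
  ## order: occupancy descending, altloc ascending -> first per key wins
  o <- order(key, -atoms$occupancy, atoms$altloc)
  keep <- o[!duplicated(key[o])]
  atoms <- atoms[sort(keep), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

.annotateChains <- function(chain_ids, chainConfig) {
  if (is.null(chainConfig)) {
    chainConfig <- data.frame(chain = character(), subunit = character(),
                              role = character(), core_letter = character(),
                              antenna_number = integer(),
                              stringsAsFactors = FALSE)
  }
  known <- chainConfig[chainConfig$chain %in% chain_ids, , drop = FALSE]
  missing <- setdiff(chain_ids, chainConfig$chain)
  if (length(missing)) {
    known <- rbind(known,
                   data.frame(chain = missing, subunit = missing,
                              role = "other", core_letter = NA_character_,
                              antenna_number = NA_integer_,
                              stringsAsFactors = FALSE))
  }
  known[match(chain_ids, known$chain), , drop = FALSE]
}

.extractPigments <- function(atoms, chains, classMap) {
  cl <- classMap$classes
  sel <- atoms$resname %in% names(cl)
  empty <- data.frame(chain = character(), resno = integer(),
                      resname = character(), class = character(),
                      subunit = character(), site = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      leaflet = character(), near_midplane = logical(),
                      stringsAsFactors = FALSE)
  if (!any(sel)) return(empty)
  pa <- atoms[sel, , drop = FALSE]
  key <- paste(pa$chain, pa$resno, pa$resname, sep = "\r")
  rows <- lapply(split(seq_len(nrow(pa)), key), function(idx) {
    res <- pa[idx, , drop = FALSE]
    klass <- unname(cl[res$resname[1]])
    if (klass %in% .CHL_CLASSES) {
      mg <- which(toupper(res$element) == "MG" | toupper(res$atom) == "MG")
      if (!length(mg)) {
        msg <- sprintf("chlorophyll residue %s %d (chain %s) lacks an Mg atom",
                       res$resname[1], res$resno[1], res$chain[1])
        if (classMap$strict) .stopf("%s", msg)
        warning(msg, ", skipped", call. = FALSE)
        return(NULL)
      }
      pt <- c(res$x[mg[1]], res$y[mg[1]], res$z[mg[1]])
    } else {
      heavy <- toupper(res$element) != "H"
      pt <- c(mean(res$x[heavy]), mean(res$y[heavy]), mean(res$z[heavy]))
    }
    data.frame(chain = res$chain[1], resno = res$resno[1],
               resname = res$resname[1], class = klass,
               subunit = NA_character_,
               site = .siteNumber(res$resno[1], klass),
               x = pt[1], y = pt[2], z = pt[3],
               leaflet = NA_character_, near_midplane = NA,
               stringsAsFactors = FALSE)
  })
  pg <- do.call(rbind, rows)
  if (is.null(pg)) return(empty)
  pg$subunit <- chains$subunit[match(pg$chain, chains$chain)]
  pg <- pg[order(pg$chain, pg$resno), , drop = FALSE]
  rownames(pg) <- NULL
  pg
}

.siteNumber <- function(resno, klass) {
  if (klass %in% .CHL_CLASSES && resno >= 400 && resno <= 423)
    return(as.integer(resno))
  if (!(klass %in% .CHL_CLASSES) && klass != "other_pigment" &&
      resno >= 301 && resno <= 307)
    return(as.integer(resno))
  NA_integer_
}

#' Site number of a pigment record
#'
#' Returns the author residue number when it lies in the conventional
#' antenna site ranges (chlorophyll sites 400-423, carotenoid sites
#' 301-307), otherwise \code{NA}.  Core pigments carry deposition
#' numbering outside these ranges and so have no site number.
#'
#' @param record one row of \code{pigments(x)}.
#' @return integer site number or \code{NA}.
#' @export
extractSiteNumber <- function(record) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  .siteNumber(record$resno, record$class)
}

#' Tabulate pigment records
#'
#' One row per pigment with its subunit, class, site and representative
#' coordinates; suitable for writing as TSV.
#'
#' @param model a \code{PigmentComplex}.
#' @return data.frame with columns chain, subunit, class, site, x, y, z,
#'   leaflet.
#' @export
pigmentTable <- function(model) {
  stopifnot(is(model, "PigmentComplex"))
  pg <- pigments(model)
  pg[, c("chain", "subunit", "class", "site", "x", "y", "z", "leaflet"),
     drop = FALSE]
}
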