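## Geometry constants of the synthetic supercomplex (Angstrom).  The toy
## emulates the published architecture: a compact core cluster encircled
## by concentric antenna rings, chlorophylls split between two parallel
## leaflet planes, carotenoid rods, and designated "bridge" chlorophylls
## that make the intended minimal inter-subunit steps unique by a clear
## margin.
.SYN_CORE_RADIUS <- 12    # core subunit centers sit on this circle
.SYN_ACCEPTOR_PROTRUSION <- 5.5   # acceptor bridge Chl, toward the donor
.SYN_BRIDGE_DIST <- 11    # intended minimal Mg-Mg step distance
.SYN_STEP_CUTOFF <- 16    # step cutoff the ground truth is built for
.SYN_SCATTER_MAX <- 3.5   # in-plane radius of non-bridge chlorophylls

#' Specification of a synthetic supercomplex
#'
#' Defines a toy pigment-protein supercomplex with known ground truth:
#' \code{nCore} core subunits clustered around the origin and
#' \code{nRings} concentric rings of \code{antennasPerRing} antenna
#' subunits.  Each subunit carries chlorophylls split between two
#' leaflet planes \code{leafletGap} apart (with Gaussian jitter
#' \code{jitterSd}), plus chlorophyll c (antennas, stromal plane) and
#' carotenoid rods.  One seeded pseudo-random stream drives all
#' randomness.
#'
#' @param nCore,nRings,antennasPerRing architecture counts.
#' @param chlAPerSubunit,chlCPerSubunit,carPerSubunit pigments per
#'   subunit; part of the chlorophyll-a budget is reserved for bridge
#'   chlorophylls that realise the intended EET steps.
#' @param leafletGap distance between the two leaflet planes (A); must
#'   be at least \code{2*jitterSd + 6} so the leaflets stay separable.
#' @param ringSpacing radial distance between consecutive shells (A).
#' @param jitterSd Gaussian jitter of chlorophyll plane positions (A).
#' @param seed integer seed fixing all randomness.
#' @return validated list of class \code{SyntheticSpec}.
#' @export
syntheticSpec <- function(nCore = 4, nRings = 2, antennasPerRing = 6,
                          chlAPerSubunit = 8, chlCPerSubunit = 1,
                          carPerSubunit = 2, leafletGap = 14,
                          ringSpacing = 28, jitterSd = 0.6, seed = 1) {
  spec <- list(nCore = as.integer(nCore), nRings = as.integer(nRings),
               antennasPerRing = as.integer(antennasPerRing),
               chlAPerSubunit = as.integer(chlAPerSubunit),
               chlCPerSubunit = as.integer(chlCPerSubunit),
               carPerSubunit = as.integer(carPerSubunit),
               leafletGap = leafletGap, ringSpacing = ringSpacing,
               jitterSd = jitterSd, seed = as.integer(seed))
  counts <- unlist(spec[c("nCore", "nRings", "antennasPerRing",
                          "chlAPerSubunit", "chlCPerSubunit",
                          "carPerSubunit")])
  if (any(counts < 0)) .stopf("synthetic spec counts must be >= 0")
  if (spec$nCore < 1) .stopf("need at least one core subunit")
  if (spec$leafletGap < 2 * spec$jitterSd + 6)
    .stopf("leafletGap must be >= 2*jitterSd + 6 = %.2f",
           2 * spec$jitterSd + 6)
  if (spec$ringSpacing < 24)
    .stopf("ringSpacing below 24 A crowds the bridge geometry")
  if (spec$chlAPerSubunit + spec$chlCPerSubunit > 24)
    .stopf("chlorophyll sites per subunit limited to 24 (400-423)")
  if (spec$carPerSubunit > 7)
    .stopf("carotenoid sites per subunit limited to 7 (301-307)")
  ## bridge budget: every antenna donates (2 tips, one per leaflet);
  ## inner antennas and cores accept (2 tips per incoming edge)
  if (spec$nRings > 0) {
    if (spec$antennasPerRing < 1) .stopf("antennasPerRing must be >= 1")
    layout <- .synLayout(spec)
    need <- 2L + vapply(layout$subunits$label, function(lb) {
      2L * sum(layout$eet$donor == lb) + 2L * sum(layout$eet$acceptor == lb)
    }, integer(1))
    if (any(need > spec$chlAPerSubunit))
      .stopf(paste("chlAPerSubunit = %d too small for bridge chlorophylls",
                   "(subunit %s needs %d)"), spec$chlAPerSubunit,
             layout$subunits$label[which.max(need)], max(need))
  }
  class(spec) <- "SyntheticSpec"
  spec
}

## subunit centers, chain ids, declared adjacency and intended EET edges
.synLayout <- function(spec) {
  pool <- c(LETTERS, letters, as.vector(outer(LETTERS, 0:9, paste0)))
  subs <- data.frame(label = character(), chain = character(),
                     role = character(), shell = integer(),
                     cx = numeric(), cy = numeric(), stringsAsFactors = FALSE)
  for (m in seq_len(spec$nCore)) {
    th <- 2 * pi * (m - 1) / spec$nCore
    subs <- rbind(subs, data.frame(
      label = paste0("Psa", LETTERS[m]), chain = pool[m], role = "core",
      shell = 0L, cx = .SYN_CORE_RADIUS * cos(th),
      cy = .SYN_CORE_RADIUS * sin(th), stringsAsFactors = FALSE))
  }
  if (spec$nRings > 0) {
    for (k in seq_len(spec$nRings)) {
      r <- .SYN_CORE_RADIUS + k * spec$ringSpacing
      for (j in seq_len(spec$antennasPerRing)) {
        n <- (k - 1L) * spec$antennasPerRing + j
        th <- 2 * pi * (j - 1) / spec$antennasPerRing
        subs <- rbind(subs, data.frame(
          label = paste0("FCPI-", n), chain = pool[spec$nCore + n],
          role = "antenna", shell = k, cx = r * cos(th), cy = r * sin(th),
          stringsAsFactors = FALSE))
      }
    }
  }
  ## adjacency: core clique, ring-1 antenna to nearest core, ring-k
  ## antenna to the ring-(k-1) antenna of the same column
  adj <- list()
  core <- subs[subs$role == "core", , drop = FALSE]
  if (nrow(core) > 1L)
    for (i in seq_len(nrow(core) - 1L))
      for (j in seq(i + 1L, nrow(core)))
        adj[[length(adj) + 1L]] <- c(core$label[i], core$label[j])
  eet <- list()
  if (spec$nRings > 0) {
    for (k in seq_len(spec$nRings)) {
      for (j in seq_len(spec$antennasPerRing)) {
        n <- (k - 1L) * spec$antennasPerRing + j
        don <- paste0("FCPI-", n)
        acc <- if (k == 1L) {
          di <- subs[subs$label == don, ]
          core$label[which.min((core$cx - di$cx)^2 + (core$cy - di$cy)^2)]
        } else paste0("FCPI-", n - spec$antennasPerRing)
        adj[[length(adj) + 1L]] <- c(don, acc)
        eet[[length(eet) + 1L]] <- c(don, acc)
      }
    }
  }
  list(subunits = subs,
       adjacency = if (length(adj))
         data.frame(subunit_a = vapply(adj, `[`, "", 1),
                    subunit_b = vapply(adj, `[`, "", 2),
                    stringsAsFactors = FALSE)
       else data.frame(subunit_a = character(), subunit_b = character()),
       eet = if (length(eet))
         data.frame(donor = vapply(eet, `[`, "", 1),
                    acceptor = vapply(eet, `[`, "", 2),
                    stringsAsFactors = FALSE)
       else data.frame(donor = character(), acceptor = character()))
}

#' Generate a synthetic supercomplex with ground truth
#'
#' Writes a legal mmCIF coordinate file realising the spec and returns
#' (and optionally writes) the ground truth: per-subunit shell indices,
#' per-chlorophyll leaflets, the intended minimal-step edge list with
#' the step cutoff it was built for, the expected pathway codes, the
#' expected census, the declared chain adjacency and the chain
#' annotation table.  Bridge chlorophylls are placed so the intended
#' minimal steps are unique by a >= 2 A margin, which the generator
#' verifies before writing anything.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param cifPath output mmCIF path.
#' @param truthPath optional path for the ground-truth JSON.
#' @param chainConfigPath optional path for a chain-config YAML matching
#'   the generated file.
#' @return invisible list(cif, truth) where truth is the ground-truth
#'   list.
#' @export
generateSynthetic <- function(spec, cifPath, truthPath = NULL,
                              chainConfigPath = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  layout <- .synLayout(spec)
  built <- withr::with_seed(spec$seed, .synBuild(spec, layout))
  .synCheckMargins(spec, layout, built)
  .writeMmcif(built$atoms, cifPath, "synthetic_supercomplex")
  truth <- .synTruth(spec, layout, built)
  if (!is.null(truthPath))
    jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  if (!is.null(chainConfigPath)) .writeChainConfig(layout, chainConfigPath)
  invisible(list(cif = cifPath, truth = truth))
}

## place all atoms; returns list(atoms, pigment bookkeeping)
.synBuild <- function(spec, layout) {
  subs <- layout$subunits
  zL <- 0; zS <- spec$leafletGap; zM <- spec$leafletGap / 2
  atoms <- list(); pig <- list()
  addAtom <- function(chain, resname, resno, atom, element, x, y, z) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      chain = chain, resname = resname, resno = resno, atom = atom,
      element = element, x = x, y = y, z = z, stringsAsFactors = FALSE)
  }
  addChl <- function(chain, label, resname, resno, x, y, z, leaflet, bridge) {
    addAtom(chain, resname, resno, "MG", "MG", x, y, z)
    for (i in 1:4) {
      th <- pi / 2 * (i - 1)
      addAtom(chain, resname, resno, paste0("N", LETTERS[i]), "N",
              x + 1.6 * cos(th), y + 1.6 * sin(th), z)
    }
    pig[[length(pig) + 1L]] <<- data.frame(
      chain = chain, subunit = label, resname = resname, resno = resno,
      x = x, y = y, z = z, leaflet = leaflet, bridge = bridge,
      stringsAsFactors = FALSE)
  }
  ## reserve bridge chlorophyll slots per subunit
  nextRes <- stats::setNames(rep(400L, nrow(subs)), subs$label)
  take <- function(label) {
    r <- nextRes[[label]]; nextRes[[label]] <<- r + 1L; r
  }
  chainOf <- stats::setNames(subs$chain, subs$label)
  centerOf <- function(label) {
    i <- match(label, subs$label); c(subs$cx[i], subs$cy[i])
  }
  ## anchors: one center chlorophyll per leaflet per subunit
  for (i in seq_len(nrow(subs))) {
    addChl(subs$chain[i], subs$label[i], "CLA", take(subs$label[i]),
           subs$cx[i], subs$cy[i], zS, "stromal", FALSE)
    addChl(subs$chain[i], subs$label[i], "CLA", take(subs$label[i]),
           subs$cx[i], subs$cy[i], zL, "lumenal", FALSE)
  }
  ## bridge chlorophylls along each intended EET edge, both leaflets
  steps <- list()
  if (nrow(layout$eet)) {
    for (e in seq_len(nrow(layout$eet))) {
      don <- layout$eet$donor[e]; acc <- layout$eet$acceptor[e]
      cD <- centerOf(don); cA <- centerOf(acc)
      u <- (cD - cA) / sqrt(sum((cD - cA)^2))
      tA <- cA + .SYN_ACCEPTOR_PROTRUSION * u
      tD <- cA + (.SYN_ACCEPTOR_PROTRUSION + .SYN_BRIDGE_DIST) * u
      for (lf in c("stromal", "lumenal")) {
        z <- if (lf == "stromal") zS else zL
        rA <- take(acc); rD <- take(don)
        addChl(chainOf[[acc]], acc, "CLA", rA, tA[1], tA[2], z, lf, TRUE)
        addChl(chainOf[[don]], don, "CLA", rD, tD[1], tD[2], z, lf, TRUE)
        steps[[length(steps) + 1L]] <- data.frame(
          donor_subunit = don, donor_site = rD, acceptor_subunit = acc,
          acceptor_site = rA, distance = .SYN_BRIDGE_DIST, leaflet = lf,
          stringsAsFactors = FALSE)
      }
    }
  }
  ## scattered chlorophyll a filling the per-subunit budget
  for (i in seq_len(nrow(subs))) {
    lb <- subs$label[i]
    while (nextRes[[lb]] - 400L < spec$chlAPerSubunit) {
      r <- take(lb)
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 1.0, .SYN_SCATTER_MAX)
      lf <- if ((r %% 2L) == 0L) "stromal" else "lumenal"
      z <- (if (lf == "stromal") zS else zL) + stats::rnorm(1, 0, spec$jitterSd)
      addChl(subs$chain[i], lb, "CLA", r,
             subs$cx[i] + rad * cos(ang), subs$cy[i] + rad * sin(ang), z,
             lf, FALSE)
    }
    ## chlorophyll c: antennas only, stromal plane
    if (subs$role[i] == "antenna") {
      for (q in seq_len(spec$chlCPerSubunit)) {
        r <- take(lb)
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 1.0, .SYN_SCATTER_MAX)
        addChl(subs$chain[i], lb, "KC2", r,
               subs$cx[i] + rad * cos(ang), subs$cy[i] + rad * sin(ang),
               zS + stats::rnorm(1, 0, spec$jitterSd), "stromal", FALSE)
      }
    }
    ## carotenoid rods (5 carbons, 2.5 A spacing), mid-membrane
    carCode <- if (subs$role[i] == "core") "BCR" else "A86"
    for (q in seq_len(spec$carPerSubunit)) {
      ang <- stats::runif(1, 0, 2 * pi)
      dx <- cos(ang) * 2.5; dy <- sin(ang) * 2.5
      for (t in -2:2)
        addAtom(subs$chain[i], carCode, 300L + q,
                paste0("C", t + 3), "C",
                subs$cx[i] + t * dx, subs$cy[i] + t * dy, zM)
    }
    ## one backbone marker atom per chain
    addAtom(subs$chain[i], "GLY", 1L, "CA", "C", subs$cx[i], subs$cy[i], zM)
  }
  ## contact connector atoms realising the declared adjacency (3.0 A)
  if (nrow(layout$adjacency)) {
    for (e in seq_len(nrow(layout$adjacency))) {
      a <- layout$adjacency$subunit_a[e]; b <- layout$adjacency$subunit_b[e]
      cA <- centerOf(a); cB <- centerOf(b)
      u <- (cB - cA) / sqrt(sum((cB - cA)^2))
      mid <- (cA + cB) / 2
      addAtom(chainOf[[a]], "GLY", 1L + e, "CA", "C",
              mid[1] - 1.5 * u[1], mid[2] - 1.5 * u[2], zM)
      addAtom(chainOf[[b]], "GLY", 1L + e, "CA", "C",
              mid[1] + 1.5 * u[1], mid[2] + 1.5 * u[2], zM)
    }
  }
  ## iron-sulfur cluster on the stromal side of the first core chain
  sf <- c(1.1, -1.1)
  for (i in 1:4)
    addAtom(subs$chain[1], "SF4", 901L, paste0("FE", i), "FE",
            sf[1 + i %% 2], sf[1 + (i %/% 2) %% 2], zS + 8 + (i %% 2))
  for (i in 1:4)
    addAtom(subs$chain[1], "SF4", 901L, paste0("S", i), "S",
            -sf[1 + i %% 2], sf[1 + (i %/% 2) %% 2], zS + 9 + (i %% 2))
  list(atoms = do.call(rbind, atoms),
       pigments = do.call(rbind, pig),
       steps = if (length(steps)) do.call(rbind, steps) else
         data.frame(donor_subunit = character(), donor_site = integer(),
                    acceptor_subunit = character(),
                    acceptor_site = integer(), distance = numeric(),
                    leaflet = character(), stringsAsFactors = FALSE))
}

## verify that intended minimal steps are unique and unintended subunit
## pairs stay clearly beyond the ground-truth step cutoff
.synCheckMargins <- function(spec, layout, built) {
  pg <- built$pigments[built$pigments$resname == "CLA", , drop = FALSE]
  subs <- layout$subunits
  shell <- stats::setNames(subs$shell, subs$label)
  intended <- paste(built$steps$donor_subunit, built$steps$acceptor_subunit,
                    built$steps$leaflet)
  for (don in subs$label) for (acc in subs$label) {
    if (!(shell[[don]] > shell[[acc]])) next
    for (lf in c("stromal", "lumenal")) {
      dp <- pg[pg$subunit == don & pg$leaflet == lf, , drop = FALSE]
      ap <- pg[pg$subunit == acc & pg$leaflet == lf, , drop = FALSE]
      if (!nrow(dp) || !nrow(ap)) next
      d <- sqrt(outer(rowSums(.coordMatrix(dp)^2),
                      rowSums(.coordMatrix(ap)^2), "+") -
                  2 * tcrossprod(.coordMatrix(dp), .coordMatrix(ap)))
      ds <- sort(as.vector(d))
      if (paste(don, acc, lf) %in% intended) {
        if (ds[1] > .SYN_STEP_CUTOFF - 2 ||
            (length(ds) > 1L && ds[2] < ds[1] + 2))
          .stopf("synthetic geometry violation: intended step %s -> %s not
unique by margin", don, acc)
      } else if (ds[1] <= .SYN_STEP_CUTOFF + 2) {
        .stopf("synthetic geometry violation: unintended pair %s -> %s at
%.1f A", don, acc, ds[1])
      }
    }
  }
  invisible(TRUE)
}

.synTruth <- function(spec, layout, built) {
  subs <- layout$subunits
  a <- spec$antennasPerRing
  codes <- character()
  if (spec$nRings > 0) {
    coreLetterOf <- function(lb) sub("^Psa", "", lb)
    for (j in seq_len(a)) {
      nums <- vapply(rev(seq_len(spec$nRings)),
                     function(k) (k - 1L) * a + j, integer(1))
      acc1 <- layout$eet$acceptor[layout$eet$donor == paste0("FCPI-", j)]
      for (lf in c("S", "L"))
        codes <- c(codes, paste0(paste(nums, collapse = "-"), "-",
                                 coreLetterOf(acc1), lf))
    }
  }
  nAnt <- sum(subs$role == "antenna")
  census <- list(
    chl_a = nrow(subs) * spec$chlAPerSubunit,
    chl_c = nAnt * spec$chlCPerSubunit,
    fucoxanthin = nAnt * spec$carPerSubunit,
    diadinoxanthin = 0L,
    beta_carotene = spec$nCore * spec$carPerSubunit,
    chl_a_core = spec$nCore * spec$chlAPerSubunit)
  list(shells = as.list(stats::setNames(subs$shell, subs$label)),
       chlorophylls = built$pigments[, c("chain", "resno", "resname",
                                         "x", "y", "z", "leaflet")],
       steps = built$steps,
       step_cutoff = .SYN_STEP_CUTOFF,
       pathway_codes = codes,
       census = census,
       adjacency = layout$adjacency,
       chain_config = .synChainConfig(layout))
}

.synChainConfig <- function(layout) {
  subs <- layout$subunits
  do.call(rbind, lapply(seq_len(nrow(subs)), function(i) {
    ann <- labelAnnotation(subs$label[i])
    data.frame(chain = subs$chain[i], subunit = ann$subunit,
               role = ann$role, core_letter = ann$core_letter,
               antenna_number = ann$antenna_number, stringsAsFactors = FALSE)
  }))
}

.writeChainConfig <- function(layout, path) {
  cfg <- .synChainConfig(layout)
  ## keys quoted: bare Y/N/y/n would parse as YAML booleans
  lines <- c("chains:",
             sprintf('  "%s": "%s"', cfg$chain, cfg$subunit))
  writeLines(lines, path)
  invisible(path)
}

## minimal mmCIF atom_site writer (fixed formats -> byte-stable output)
.writeMmcif <- function(atoms, path, dataId) {
  hdr <- c(paste0("data_", dataId), "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                    "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  grp <- ifelse(atoms$resname == "GLY", "ATOM", "HETATM")
  ent <- match(atoms$chain, unique(atoms$chain))
  recs <- sprintf(
    "%s %d %s %s . %s %s %d %d ? %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
    grp, seq_len(nrow(atoms)), atoms$element, atoms$atom, atoms$resname,
    atoms$chain, ent, atoms$resno, atoms$x, atoms$y, atoms$z, 1, 30,
    atoms$resno, atoms$resname, atoms$chain, atoms$atom)
  con <- file(path, open = "wb")  # fixed newline across platforms
  on.exit(close(con))
  writeLines(c(hdr, recs, "#"), con, sep = "\n")
  invisible(path)
}
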