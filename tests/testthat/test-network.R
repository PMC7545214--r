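# exhaustive minimal chl-a pair per (donor, acceptor, leaflet): the
# brute-force oracle for deriveEETSteps
brute_min_steps <- function(model, shells, cutoff) {
  pg <- pigments(model)
  pg <- pg[pg$class == "chl_a" & !is.na(pg$leaflet), ]
  out <- list()
  for (d in unique(pg$subunit)) for (a in unique(pg$subunit)) {
    if (!(shells[d] > shells[a])) next
    for (lf in c("stromal", "lumenal")) {
      dp <- pg[pg$subunit == d & pg$leaflet == lf, ]
      ap <- pg[pg$subunit == a & pg$leaflet == lf, ]
      if (!nrow(dp) || !nrow(ap)) next
      best <- Inf; bi <- NULL
      for (i in seq_len(nrow(dp))) for (j in seq_len(nrow(ap))) {
        dd <- sqrt(sum((c(dp$x[i], dp$y[i], dp$z[i]) -
                          c(ap$x[j], ap$y[j], ap$z[j]))^2))
        if (dd < best) { best <- dd; bi <- c(i, j) }
      }
      if (best <= cutoff)
        out[[length(out) + 1L]] <- data.frame(
          donor_subunit = d, donor_site = dp$resno[bi[1]],
          acceptor_subunit = a, acceptor_site = ap$resno[bi[2]],
          distance = best, leaflet = lf, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

test_that("Mg-Mg distance is Euclidean, symmetric and chlorophyll-only", {
  m <- toy_model(rbind(chl_atoms("A", 401L, 0, 0, 0),
                       chl_atoms("A", 402L, 3, 4, 0),
                       car_atoms("A", 301L, 8, 0, 0)),
                 chain_table("A", "FCPI-1"))
  pg <- pigments(m)
  p <- pg[pg$resno == 401L, ]; q <- pg[pg$resno == 402L, ]
  expect_equal(mgMgDistance(p, p), 0)
  expect_equal(mgMgDistance(p, q), 5)
  expect_equal(mgMgDistance(q, p), 5)
  expect_error(mgMgDistance(p, pg[pg$resno == 301L, ]), "chlorophylls only")
})

test_that("reported distances satisfy symmetry and the triangle inequality", {
  spec <- syntheticSpec(nCore = 2, nRings = 1, antennasPerRing = 3, seed = 21)
  path <- tempfile(fileext = ".cif")
  g <- generateSynthetic(spec, path)
  m <- parseStructure(path, chainConfig = g$truth$chain_config)
  pg <- pigments(m)
  chl <- pg[pg$class == "chl_a", ][1:6, ]
  D <- outer(seq_len(6), seq_len(6), Vectorize(function(i, j)
    mgMgDistance(chl[i, ], chl[j, ])))
  expect_equal(D, t(D))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
})

test_that("coupled pairs respect the cutoff, canonical order and subunit flags", {
  at <- rbind(chl_atoms("A", 403L, 0, 0, 0),
              chl_atoms("A", 406L, 9, 0, 0),      # 9.0 A, same subunit
              chl_atoms("B", 401L, 0, 30, 0),     # beyond cutoff from all
              chl_atoms("B", 402L, 9, 9, 0))      # 9 A from A/406
  m <- toy_model(at, chain_table(c("A", "B"), c("FCPI-1", "FCPI-2")))
  pr <- findCoupledPairs(m, pairCutoff = 12)
  expect_equal(nrow(pr), 2L)                      # far pair excluded
  expect_true(all(paste(pr$chain_a, pr$resno_a) <=
                    paste(pr$chain_b, pr$resno_b)))
  same <- pr[pr$chain_a == "A" & pr$chain_b == "A", ]
  expect_true(same$same_subunit)
  expect_equal(same$distance, 9)
  cross <- pr[pr$chain_a != pr$chain_b, ]
  expect_false(cross$same_subunit)
  expect_error(findCoupledPairs(m, 0), "pairCutoff")
  # empty model
  m0 <- toy_model(protein_atom("A", 1L, 0, 0, 0), chain_table("A", "PsaA"))
  expect_equal(nrow(findCoupledPairs(m0)), 0L)
})

test_that("coupled-pair output is invariant to pigment input order", {
  spec <- syntheticSpec(nCore = 2, nRings = 1, antennasPerRing = 3, seed = 14)
  path <- tempfile(fileext = ".cif")
  g <- generateSynthetic(spec, path)
  m <- parseStructure(path, chainConfig = g$truth$chain_config)
  a <- findCoupledPairs(m, 12)
  mp <- m
  mp@pigments <- pigments(m)[rev(seq_len(nrow(pigments(m)))), ]
  b <- findCoupledPairs(mp, 12)
  expect_equal(a, b)
})

test_that("minimal-step selection equals the brute-force all-pairs oracle", {
  # deliberate small fixture: 3 candidate pairs between two subunits
  at <- rbind(chl_atoms("A", 401L, 0, 0, 0),
              chl_atoms("A", 402L, 0, 6, 0),
              chl_atoms("B", 401L, 14, 0, 0),    # 14.0 from A/401
              chl_atoms("B", 402L, 13, 6, 0))    # 13.0 from A/402
  m <- toy_model(at, chain_table(c("A", "B"), c("PsaA", "FCPI-1")))
  pg <- pigments(m); pg$leaflet <- "stromal"; m@pigments <- pg
  shells <- c("PsaA" = 0, "FCPI-1" = 1)
  st <- deriveEETSteps(m, shells, stepCutoff = 26)
  expect_equal(nrow(st), 1L)
  expect_equal(st$donor_site, 402L)
  expect_equal(st$acceptor_site, 402L)
  expect_equal(st$distance, 13)
  # randomized fixtures against the oracle
  for (seed in c(5, 23)) {
    spec <- syntheticSpec(nCore = 3, nRings = 2, antennasPerRing = 4,
                          seed = seed)
    path <- tempfile(fileext = ".cif")
    g <- generateSynthetic(spec, path)
    mm <- parseStructure(path, chainConfig = g$truth$chain_config)
    mm <- assignLeaflets(mm, estimateFrame(mm))
    sh <- assignLayers(buildContactGraph(mm, 4))
    got <- deriveEETSteps(mm, sh, stepCutoff = 18)
    want <- brute_min_steps(mm, sh, 18)
    ord <- function(x) {
      x <- x[order(x$leaflet, x$donor_subunit, x$acceptor_subunit), ]
      rownames(x) <- NULL
      x[, c("donor_subunit", "donor_site", "acceptor_subunit",
            "acceptor_site", "distance", "leaflet")]
    }
    expect_equal(ord(got), ord(want))
  }
})

test_that("no step is emitted without chlorophyll a in the donor leaflet", {
  at <- rbind(chl_atoms("A", 401L, 0, 0, 0),
              chl_atoms("B", 405L, 12, 0, 20))   # other leaflet only
  m <- toy_model(at, chain_table(c("A", "B"), c("PsaA", "FCPI-1")))
  pg <- pigments(m)
  pg$leaflet <- c("lumenal", "stromal")
  m@pigments <- pg
  st <- deriveEETSteps(m, c("PsaA" = 0, "FCPI-1" = 1), 26)
  expect_equal(nrow(st), 0L)
})

test_that("pathway codes follow the number-letter-leaflet grammar", {
  expect_equal(pathwayCode(c("FCPI-18", "FCPI-17", "FCPI-6", "PsaA"),
                           "lumenal"), "18-17-6-AL")
  expect_equal(pathwayCode(c("FCPI-2", "PsaL"), "stromal"), "2-LS")
  expect_equal(pathwayCode("PsaB", "lumenal"), "BL")
  expect_error(pathwayCode(character(), "stromal"), "empty")
  expect_error(pathwayCode(c("FCPI-1", "FCPI-2"), "stromal"), "core")
})

test_that("assembly walks sources to core terminals, branching and converging", {
  st <- data.frame(
    donor_subunit = c("FCPI-3", "FCPI-3", "FCPI-1", "FCPI-2", "FCPI-4"),
    acceptor_subunit = c("FCPI-1", "FCPI-2", "PsaA", "PsaA", "FCPI-2"),
    distance = c(10, 11, 12, 13, 9),
    leaflet = "stromal", stringsAsFactors = FALSE)
  p <- assemblePathways(st)
  # 3 branches: 3-1-A, 3-2-A, 4-2-A
  expect_setequal(pathwayCodes(p), c("3-1-AS", "3-2-AS", "4-2-AS"))
  # single-step pathway
  single <- assemblePathways(data.frame(
    donor_subunit = "FCPI-11", acceptor_subunit = "PsaB", distance = 22.2,
    leaflet = "lumenal", stringsAsFactors = FALSE))
  expect_equal(pathwayCodes(single), "11-BL")
  expect_false(single$efficient)
  # empty collection
  p0 <- assemblePathways(NULL)
  expect_equal(nrow(p0), 0L)
  expect_length(pathwayCodes(p0), 0L)
})

test_that("cycles are reported by name and dead ends excluded with warning", {
  cyc <- data.frame(
    donor_subunit = c("FCPI-1", "FCPI-2", "FCPI-3"),
    acceptor_subunit = c("FCPI-2", "FCPI-3", "FCPI-1"),
    distance = 10, leaflet = "stromal", stringsAsFactors = FALSE)
  expect_error(assemblePathways(cyc), "cycle.*FCPI-1")
  dead <- data.frame(
    donor_subunit = c("FCPI-5", "FCPI-6"),
    acceptor_subunit = c("FCPI-6", "FCPI-7"),  # FCPI-7 has no outgoing
    distance = 10, leaflet = "lumenal", stringsAsFactors = FALSE)
  expect_warning(p <- assemblePathways(dead), "non-core")
  expect_length(pathwayCodes(p), 0L)
  expect_true(all(!p$complete))
})

test_that("pathway counts match brute-force simple-chain enumeration on random DAGs", {
  for (seed in c(2, 7, 19)) {
    edges <- withr::with_seed(seed, {
      ant <- paste0("FCPI-", 1:7); core <- c("PsaA", "PsaB")
      lvl <- stats::setNames(c(sample(1:3, 7, TRUE), 0, 0), c(ant, core))
      out <- list()
      for (d in ant) {
        lower <- names(lvl)[lvl < lvl[d]]
        for (a in sample(lower, min(length(lower), 1 + seed %% 2)))
          out[[length(out) + 1L]] <- data.frame(
            donor_subunit = d, acceptor_subunit = a,
            distance = runif(1, 8, 24), leaflet = "stromal",
            stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    })
    p <- suppressWarnings(assemblePathways(edges))
    n_got <- length(unique(p$pathway_id[p$complete]))
    # oracle: igraph simple paths from each source to a core with no
    # intermediate core
    g <- igraph::graph_from_data_frame(
      edges[, c("donor_subunit", "acceptor_subunit")], directed = TRUE)
    nodes <- igraph::V(g)$name
    cores <- nodes[grepl("^Psa", nodes)]
    srcs <- setdiff(unique(edges$donor_subunit),
                    unique(edges$acceptor_subunit))
    n_want <- 0L
    for (s in srcs) for (co in intersect(cores, nodes)) {
      sp <- igraph::all_simple_paths(g, from = s, to = co, mode = "out")
      for (pp in sp) {
        mid <- names(pp)[-c(1, length(pp))]
        if (!any(mid %in% cores)) n_want <- n_want + 1L
      }
    }
    expect_equal(n_got, n_want)
  }
})

test_that("the pathway report groups steps by code with half-up rounded distances", {
  p <- assemblePathways(publishedStepTable())
  rep <- pathwayReport(p)
  expect_equal(length(unique(rep$code)), 18L)
  expect_equal(nrow(rep), 36L)  # 18 pathways, shared steps listed per pathway
  b22 <- rep[rep$code == "11-BL", ]
  expect_false(b22$efficient)
  expect_equal(b22$distance_A, 22.2)
  expect_equal(unique(rep$location[grepl("S$", rep$code)]), "Stromal")
  # half-up rounding at 0.1 A
  p2 <- assemblePathways(data.frame(
    donor_subunit = "FCPI-1", acceptor_subunit = "PsaA",
    distance = 14.25, leaflet = "stromal", stringsAsFactors = FALSE))
  expect_equal(pathwayReport(p2)$distance_A, 14.3)
  # empty report keeps the header
  rep0 <- pathwayReport(assemblePathways(NULL))
  expect_equal(nrow(rep0), 0L)
  expect_true(all(c("code", "pigments", "distance_A", "location") %in%
                    names(rep0)))
})

test_that("the packaged step fixture encodes the published table", {
  st <- publishedStepTable()
  expect_equal(nrow(st), 34L)      # 36 printed rows, 2 shared steps deduped
  expect_equal(sum(st$leaflet == "lumenal"), 19L)
  lum910 <- st[st$donor_subunit == "FCPI-9" & st$acceptor_subunit == "FCPI-10", ]
  expect_equal(lum910$distance, 9.5)
  expect_equal(lum910$leaflet, "lumenal")
  str219 <- st[st$donor_subunit == "FCPI-21" & st$acceptor_subunit == "FCPI-9" &
                 st$leaflet == "stromal", ]
  expect_equal(str219$distance, 9.8)
  expect_equal(sum(!st$efficient), 7L)  # steps above the 20 A rule
})
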