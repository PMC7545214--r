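test_that("a minimal mmCIF with one chlorophyll yields one chl_a record", {
  m <- toy_model(chl_atoms("A", 401L, 1.25, -2.5, 3.75),
                 chain_table("A", "PsaA"))
  pg <- pigments(m)
  expect_equal(nrow(pg), 1L)
  expect_equal(pg$class, "chl_a")
  # representative point is the Mg position, echoed exactly
  expect_equal(c(pg$x, pg$y, pg$z), c(1.25, -2.5, 3.75))
  tab <- pigmentTable(m)
  expect_equal(nrow(tab), 1L)
  expect_named(tab, c("chain", "subunit", "class", "site", "x", "y", "z",
                      "leaflet"))
})

test_that("carotenoids get the unweighted heavy-atom centroid", {
  m <- toy_model(car_atoms("A", 301L, 10, 5, 2), chain_table("A", "FCPI-1"))
  pg <- pigments(m)
  expect_equal(pg$class, "fucoxanthin")
  expect_equal(c(pg$x, pg$y, pg$z), c(10, 5, 2))
  expect_equal(pg$site, 301L)
})

test_that("a file truncated mid-record raises a parse error, no partial model", {
  at <- rbind(chl_atoms("A", 401L, 0, 0, 0), chl_atoms("A", 402L, 9, 0, 0))
  path <- tempfile(fileext = ".cif")
  pigmentNet:::.writeMmcif(at, path, "toy")
  txt <- readChar(path, file.size(path))
  cut <- substr(txt, 1, nchar(txt) - 80)  # cut inside the last records
  writeLines(cut, path, sep = "")
  expect_error(parseStructure(path, defaultClassMap()), "parse error")
  expect_error(parseStructure(tempfile(), defaultClassMap()), "not found")
})

test_that("altloc duplicates keep the highest-occupancy conformer, deterministically", {
  at <- chl_atoms("A", 401L, 0, 0, 0)
  path <- tempfile(fileext = ".cif")
  # hand-write two MG conformers: altloc A occ 0.40 at x=0, B occ 0.60 at x=2
  pigmentNet:::.writeMmcif(at, path, "toy")
  lines <- readLines(path)
  mg <- grep("MG MG", lines)[1]
  rec_a <- sub("MG \\. CLA", "MG A CLA", lines[mg])
  rec_a <- sub("1.00 30.00", "0.40 30.00", rec_a)
  rec_b <- sub("MG \\. CLA", "MG B CLA", lines[mg])
  rec_b <- sub("0\\.000 0\\.000 0\\.000", "2.000 0.000 0.000", rec_b)
  rec_b <- sub("1.00 30.00", "0.60 30.00", rec_b)
  lines <- c(lines[seq_len(mg - 1L)], rec_a, rec_b,
             lines[seq(mg + 1L, length(lines))])
  writeLines(lines, path)
  m1 <- parseStructure(path, defaultClassMap(), chain_table("A", "PsaA"))
  expect_equal(pigments(m1)$x, 2)          # occupancy 0.60 conformer wins
  m2 <- parseStructure(path, defaultClassMap(), chain_table("A", "PsaA"))
  expect_identical(pigments(m1), pigments(m2))
})

test_that("chlorophylls without Mg are skipped with a warning, or error in strict mode", {
  at <- chl_atoms("A", 401L, 0, 0, 0)
  at <- at[at$atom != "MG", ]                       # drop the Mg
  at <- rbind(at, chl_atoms("A", 402L, 9, 0, 0))
  path <- tempfile(fileext = ".cif")
  pigmentNet:::.writeMmcif(at, path, "toy")
  cm <- defaultClassMap()
  expect_warning(m <- parseStructure(path, cm, chain_table("A", "PsaA")),
                 "lacks an Mg")
  expect_equal(nrow(pigments(m)), 1L)               # the intact one remains
  cm$strict <- TRUE
  expect_error(suppressWarnings(parseStructure(path, cm)), "lacks an Mg")
})

test_that("unannotated chains get role 'other' and pigments keep flowing", {
  at <- rbind(chl_atoms("A", 401L, 0, 0, 0), chl_atoms("Z", 402L, 30, 0, 0))
  m <- toy_model(at, chain_table("A", "PsaA"))
  ch <- chainAnnotations(m)
  expect_equal(ch$role[ch$chain == "Z"], "other")
  expect_equal(nrow(pigments(m)), 2L)
})

test_that("site numbers come only from the antenna site ranges", {
  m <- toy_model(rbind(chl_atoms("A", 406L, 0, 0, 0),
                       chl_atoms("A", 1203L, 10, 0, 0),
                       car_atoms("A", 305L, 20, 0, 0),
                       car_atoms("A", 310L, 30, 0, 0)),
                 chain_table("A", "FCPI-8"))
  pg <- pigments(m)
  expect_equal(extractSiteNumber(pg[pg$resno == 406L, ]), 406L)
  expect_true(is.na(extractSiteNumber(pg[pg$resno == 1203L, ])))
  expect_equal(extractSiteNumber(pg[pg$resno == 305L, ]), 305L)
  expect_true(is.na(extractSiteNumber(pg[pg$resno == 310L, ])))
})

test_that("round trip through the generator preserves counts, classes and points", {
  for (seed in c(2, 11)) {
    spec <- syntheticSpec(nCore = 2, nRings = 1, antennasPerRing = 3,
                          seed = seed)
    path <- tempfile(fileext = ".cif")
    g <- generateSynthetic(spec, path)
    m <- parseStructure(path, chainConfig = g$truth$chain_config)
    pg <- pigments(m)
    truth_chl <- g$truth$chlorophylls
    chl <- pg[pg$class %in% c("chl_a", "chl_c"), ]
    expect_equal(nrow(chl), nrow(truth_chl))
    # per-class conservation: class counts sum to the pigment total
    expect_equal(sum(table(pg$class)), nrow(pg))
    # representative points match the generated coordinates within 1e-3
    i <- match(paste(chl$chain, chl$resno),
               paste(truth_chl$chain, truth_chl$resno))
    expect_false(anyNA(i))
    expect_lt(max(abs(as.matrix(chl[, c("x", "y", "z")]) -
                        as.matrix(truth_chl[i, c("x", "y", "z")]))), 1e-3)
    # chlorophyll classes survive the round trip
    expect_equal(chl$class == "chl_c", truth_chl$resname[i] == "KC2")
  }
})

test_that("parsing the same file twice yields identical models", {
  spec <- syntheticSpec(nCore = 2, nRings = 1, antennasPerRing = 3, seed = 5)
  path <- tempfile(fileext = ".cif")
  g <- generateSynthetic(spec, path)
  m1 <- parseStructure(path, chainConfig = g$truth$chain_config)
  m2 <- parseStructure(path, chainConfig = g$truth$chain_config)
  expect_identical(atoms(m1), atoms(m2))
  expect_identical(pigments(m1), pigments(m2))
})
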