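# Shared fixture builders: all models are constructed in code, written
# through the package's mmCIF writer and re-read through the public
# parser, so every test exercises the real I/O path.

# atom rows for one minimal chlorophyll (Mg + 4 N placeholders)
chl_atoms <- function(chain, resno, x, y, z, resname = "CLA") {
  rbind(
    data.frame(chain = chain, resname = resname, resno = resno,
               atom = "MG", element = "MG", x = x, y = y, z = z,
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(1:4, function(i) {
      th <- pi / 2 * (i - 1)
      data.frame(chain = chain, resname = resname, resno = resno,
                 atom = paste0("N", LETTERS[i]), element = "N",
                 x = x + 1.6 * cos(th), y = y + 1.6 * sin(th), z = z,
                 stringsAsFactors = FALSE)
    })))
}

# carotenoid rod (5 carbons along +x)
car_atoms <- function(chain, resno, x, y, z, resname = "A86") {
  do.call(rbind, lapply(-2:2, function(t)
    data.frame(chain = chain, resname = resname, resno = resno,
               atom = paste0("C", t + 3), element = "C",
               x = x + 2.5 * t, y = y, z = z, stringsAsFactors = FALSE)))
}

sf4_atoms <- function(chain, x, y, z) {
  do.call(rbind, lapply(1:4, function(i)
    data.frame(chain = chain, resname = "SF4", resno = 901L,
               atom = paste0("FE", i), element = "FE",
               x = x + 0.8 * (i %% 2), y = y + 0.8 * (i %/% 2 %% 2),
               z = z + 0.5 * i, stringsAsFactors = FALSE)))
}

protein_atom <- function(chain, resno, x, y, z) {
  data.frame(chain = chain, resname = "GLY", resno = resno, atom = "CA",
             element = "C", x = x, y = y, z = z, stringsAsFactors = FALSE)
}

# annotation table from subunit labels (chain ids = labels' chains)
chain_table <- function(chains, subunits) {
  do.call(rbind, Map(function(ch, su) {
    a <- labelAnnotation(su)
    data.frame(chain = ch, subunit = su, role = a$role,
               core_letter = a$core_letter, antenna_number = a$antenna_number,
               stringsAsFactors = FALSE)
  }, chains, subunits))
}

# write atom rows as mmCIF and parse back into a PigmentComplex
toy_model <- function(atoms, chainConfig = NULL, classMap = NULL,
                      path = tempfile(fileext = ".cif")) {
  atoms$occupancy <- NULL
  pigmentNet:::.writeMmcif(atoms, path, "toy")
  if (is.null(classMap)) classMap <- defaultClassMap()
  parseStructure(path, classMap, chainConfig)
}

# a model with chlorophylls on two parallel planes z = 0 and z = gap
# (in-plane radius wide enough that the gap is the thin axis), plus an
# iron-sulfur cluster above the top plane (stromal side)
two_plane_model <- function(n_per_plane = 8, gap = 20, jitter = 0,
                            seed = 42, chain = "A", subunit = "PsaA",
                            radius = 35) {
  at <- withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_per_plane)) {
      th <- 2 * pi * i / n_per_plane
      for (z0 in c(0, gap)) {
        rows[[length(rows) + 1L]] <- chl_atoms(
          chain, 400L + i + ifelse(z0 > 0, 100L, 0L),
          radius * cos(th), radius * sin(th), z0 + stats::rnorm(1, 0, jitter))
      }
    }
    rows[[length(rows) + 1L]] <- sf4_atoms(chain, 0, 0, gap + 10)
    do.call(rbind, rows)
  })
  toy_model(at, chain_table(chain, subunit))
}

# chlorophylls on a circle at both leaflet planes (deterministic)
circle_chl_atoms <- function(chain = "A", n = 6, radius = 25, gap = 16) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    th <- 2 * pi * i / n
    rbind(chl_atoms(chain, 400L + i, radius * cos(th), radius * sin(th), 0),
          chl_atoms(chain, 450L + i, radius * cos(th), radius * sin(th), gap))
  }))
}

# proper rotation matrix from a seed
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

# apply a rigid motion to atom rows
transform_atoms <- function(atoms, R = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

# rigid motion applied in memory (atoms and pigment points), avoiding
# file-writer coordinate rounding
transform_model <- function(m, R = diag(3), shift = c(0, 0, 0)) {
  m@atoms <- transform_atoms(atoms(m), R, shift)
  m@pigments <- transform_atoms(pigments(m), R, shift)
  m
}

published_codes <- c(
  "18-17-6-AL", "18-7-JL", "19-8-BL", "20-8-BL", "21-9-10-BL", "11-BL",
  "1-IL", "2-IL", "13-3-IL", "24-15-4-AL", "21-9-8-RS", "11-BS", "2-LS",
  "12-3-AS", "13-4-AS", "14-4-AS", "22-15-5-AS", "16-6-AS")
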