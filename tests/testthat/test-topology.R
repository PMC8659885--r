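# Topology construction: particle sets, side-chain mapping, constraints.

BEAD_COUNTS <- c(G = 0L, A = 0L, V = 1L, L = 1L, I = 1L, P = 1L, M = 1L,
                 C = 1L, S = 1L, T = 1L, N = 1L, Q = 1L, D = 1L, E = 1L,
                 K = 2L, R = 2L, H = 3L, F = 3L, Y = 3L, W = 4L)

test_that("backbone particle sets follow the residue chemistry", {
  tG <- build_topology("G")
  expect_equal(nrow(tG$atoms), 5L)
  expect_setequal(tG$atoms$kind, c("N", "H", "CA", "C", "O"))

  tW <- build_topology("W")
  expect_equal(nrow(tW$atoms), 9L)
  expect_equal(sum(grepl("^SC", tW$atoms$kind)), 4L)

  tP <- build_topology("P")
  expect_false("H" %in% tP$atoms$kind)

  expect_error(build_topology("AZA"), "position 2")
})

test_that("side-chain bead counts match the published mapping table", {
  seq20 <- paste(names(BEAD_COUNTS), collapse = "")
  expect_equal(sidechain_bead_counts(seq20), unname(BEAD_COUNTS))
  topo <- build_topology(seq20)
  expect_equal(sum(grepl("^SC", topo$atoms$kind)), sum(BEAD_COUNTS))
  expect_true(all(topo$atoms$mass > 0))
  expect_true(all(topo$atoms$radius > 0))
})

test_that("a 40-residue chain has the particle count implied by the mapping", {
  topo <- build_topology(AB40_SEQ)
  letters1 <- strsplit(AB40_SEQ, "")[[1]]
  n_bb <- 5L * 40L - sum(letters1 == "P")
  expect_equal(nrow(topo$atoms), n_bb + sum(BEAD_COUNTS[letters1]))
  expect_equal(max(topo$atoms$resno), 40L)
  expect_equal(unique(topo$atoms$chain), "A")
})

test_that("topology construction is deterministic", {
  a <- build_topology("ACDEFGHIKLMNPQRSTVWY")
  b <- build_topology("ACDEFGHIKLMNPQRSTVWY")
  expect_identical(a, b)
})

test_that("constraints are valid ranges between nearby residues", {
  topo <- build_topology("MKVLAW")
  con <- topo$constraints
  expect_true(all(con$dmin > 0))
  expect_true(all(con$dmin < con$dmax))
  expect_true(all(con$i != con$j))
  expect_true(all(con$i %in% topo$atoms$index & con$j %in% topo$atoms$index))
  cov <- con[con$role == "covalent", ]
  dr <- abs(topo$atoms$resno[cov$i] - topo$atoms$resno[cov$j])
  expect_true(all(dr <= 1L))
})

test_that("merging topologies concatenates and re-indexes", {
  a <- build_topology("MKVL", chain_id = "A")
  b <- build_topology("WGG", chain_id = "B")
  m <- merge_topologies(a, b)
  expect_equal(nrow(m$atoms), nrow(a$atoms) + nrow(b$atoms))
  expect_equal(nrow(m$constraints), nrow(a$constraints) + nrow(b$constraints))
  # chain B constraints offset by |A|
  conB <- m$constraints[(nrow(a$constraints) + 1L):nrow(m$constraints), ]
  expect_equal(conB$i, b$constraints$i + nrow(a$atoms))
  expect_equal(conB$j, b$constraints$j + nrow(a$atoms))
  # no inter-chain bonded constraints
  ch <- m$atoms$chain
  expect_true(all(ch[m$constraints$i] == ch[m$constraints$j]))
  expect_error(merge_topologies(a, build_topology("GG", chain_id = "A")),
               "duplicate")
})

test_that("mapping a structure copies the backbone and centroids the beads", {
  st <- ideal_helix("MKVLAW")
  f <- tempfile(fileext = ".pdb")
  write_pdb(st$xyz, st$topology, f)
  pdb <- read_pdb(f)
  # rename bead records so the PDB looks atomistic enough to remap: instead,
  # map a true atomistic fixture built by hand below for leucine; here check
  # the backbone passthrough on a synthetic atomistic file
  at <- st$topology$atoms
  bb <- at$kind %in% c("N", "H", "CA", "C", "O")
  atoms <- data.frame(name = at$kind[bb], resid = at$resid[bb],
                      resno = at$resno[bb], chain = at$chain[bb],
                      x = st$xyz[bb, 1], y = st$xyz[bb, 2], z = st$xyz[bb, 3])
  # add side-chain heavy atoms for each LEU/VAL etc. at the bead position so
  # the centroid reproduces the bead
  map <- read_sidechain_map()
  for (r in unique(at$resno)) {
    res3 <- at$resid[at$resno == r][1]
    for (b in map[[res3]]) {
      pos <- st$xyz[at$resno == r & at$kind == b$name, ]
      for (nm in b$atoms)
        atoms <- rbind(atoms, data.frame(name = nm, resid = res3, resno = r,
                                         chain = "A", x = pos[1], y = pos[2],
                                         z = pos[3]))
    }
  }
  xyz <- map_structure(list(atoms = atoms), st$topology)
  expect_equal(xyz, st$xyz, tolerance = 1e-12)
})

test_that("a leucine side-chain bead lands on the heavy-atom centroid", {
  topo <- build_topology("L")
  # tetrahedron corners centered on the origin for CB CG CD1 CD2
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  st <- extended_chain("L")
  at <- topo$atoms
  bb <- at$kind %in% c("N", "H", "CA", "C", "O")
  atoms <- data.frame(name = at$kind[bb], resid = "LEU", resno = 1L,
                      chain = "A", x = st$xyz[bb, 1], y = st$xyz[bb, 2],
                      z = st$xyz[bb, 3])
  for (k in seq_len(4))
    atoms <- rbind(atoms, data.frame(name = c("CB", "CG", "CD1", "CD2")[k],
                                     resid = "LEU", resno = 1L, chain = "A",
                                     x = tet[k, 1], y = tet[k, 2], z = tet[k, 3]))
  xyz <- map_structure(list(atoms = atoms), topo)
  expect_equal(unname(xyz[at$kind == "SC1", ]), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(xyz[at$kind == "CA", ], st$xyz[at$kind == "CA", ],
               tolerance = 1e-12)
})

test_that("missing backbone atoms are rejected by name, missing bead atoms warn", {
  topo <- build_topology("L")
  st <- extended_chain("L")
  at <- topo$atoms
  bb <- at$kind %in% c("N", "H", "CA", "C", "O")
  base <- data.frame(name = at$kind[bb], resid = "LEU", resno = 1L,
                     chain = "A", x = st$xyz[bb, 1], y = st$xyz[bb, 2],
                     z = st$xyz[bb, 3])
  sc <- data.frame(name = "CB", resid = "LEU", resno = 1L, chain = "A",
                   x = 1, y = 0, z = 0)
  expect_warning(map_structure(list(atoms = rbind(base, sc)), topo),
                 "3/4|only 1/4")
  no_ca <- rbind(base[base$name != "CA", ], sc)
  expect_error(map_structure(list(atoms = no_ca), topo), "CA")
})
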