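# Coarse-grained topology construction: atomistic backbone (N, H, CA, C, O;
# no amide H for proline) plus MARTINI-mapped side-chain beads, with all
# bonded geometry encoded as distance-range constraints (the event-driven
# engine has no continuous forces, so bonds, angles and dihedral freedom are
# all expressed as [dmin, dmax] ranges acting as reflecting walls).

BACKBONE_KINDS <- c("N", "H", "CA", "C", "O")

#' Read the side-chain coarse-graining map
#'
#' Parses the plain-text mapping table (one row per amino acid: code, bead
#' count, per-bead heavy-atom lists with a nominal link distance).
#'
#' @param path path to the mapping file; defaults to the table shipped with
#'   the package
#' @return named list, one entry per residue, each a list of beads with
#'   `name`, `atoms`, `link` fields
#' @export
read_sidechain_map <- function(path = system.file("extdata", "sidechain_map.txt",
                                                  package = "pacsab")) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    code <- tok[1]
    nb <- as.integer(tok[2])
    beads <- list()
    if (nb > 0L) {
      for (k in seq_len(nb)) {
        fld <- tok[2L + k]
        nm <- sub("=.*$", "", fld)
        rest <- sub("^[^=]*=", "", fld)
        link <- as.numeric(sub("^.*@", "", rest))
        atoms <- strsplit(sub("@.*$", "", rest), ",")[[1]]
        beads[[k]] <- list(name = nm, atoms = atoms, link = link)
      }
    }
    out[[code]] <- beads
  }
  out
}

sidechain_bead_mass <- function(atoms) {
  sum(ELEMENT_MASS[atom_element(atoms)])
}

#' Build a coarse-grained topology from an amino-acid sequence
#'
#' Each residue carries backbone particles N, H, CA, C, O (the amide H is
#' omitted for proline) and 0-4 side-chain beads following the MARTINI-style
#' mapping table.  Bonded geometry is generated as distance-range
#' constraints: covalent bonds as narrow ranges around ideal lengths, bond
#' angles as 1-3 ranges, the trans peptide and backbone dihedral freedom as
#' 1-4 ranges wide enough to admit both helical and extended conformations,
#' and side-chain links as loose pseudo-bonds.
#'
#' @param sequence one-letter amino-acid string (standard 20-residue alphabet)
#' @param chain_id single-character chain label
#' @param map side-chain mapping table from [read_sidechain_map()]
#' @param params force-field parameter list from [ff_params()] (only the
#'   particle masses/radii tables are used here)
#' @param geom ideal peptide geometry table
#' @return an object of class `pacsab_topology` with components `atoms`
#'   (data.frame: index, kind, resno, resid, chain, mass, radius, type),
#'   `constraints` (data.frame: i, j, dmin, dmax, role) and `sequence`
#'   (named per chain)
#' @export
build_topology <- function(sequence, chain_id = "A",
                           map = read_sidechain_map(),
                           params = ff_params(),
                           geom = load_peptide_geometry()) {
  resid3 <- seq_to_resid(sequence)
  n <- length(resid3)
  kinds <- params$kinds
  del <- geom$delta

  rows <- vector("list", n)
  idx <- 0L
  for (i in seq_len(n)) {
    rk <- BACKBONE_KINDS
    if (resid3[i] == "PRO") rk <- setdiff(rk, "H")
    beads <- map[[resid3[i]]]
    if (is.null(beads)) stop("no mapping entry for residue ", resid3[i])
    bead_names <- vapply(beads, `[[`, "", "name")
    kind <- c(rk, bead_names)
    mass <- c(vapply(rk, function(k) kinds[[k]]$mass, 0),
              vapply(beads, function(b) sidechain_bead_mass(b$atoms), 0))
    radius <- c(vapply(rk, function(k) kinds[[k]]$radius, 0),
                vapply(beads, function(b) {
                  params$sidechain$radius_base +
                    params$sidechain$radius_per_atom * length(b$atoms)
                }, 0))
    type <- c(rk, if (length(bead_names)) paste0(resid3[i], ".", bead_names))
    rows[[i]] <- data.frame(index = idx + seq_along(kind), kind = kind,
                            resno = i, resid = resid3[i], chain = chain_id,
                            mass = mass, radius = radius, type = type,
                            stringsAsFactors = FALSE)
    idx <- idx + length(kind)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL

  constraints <- build_constraints(atoms, map, geom)
  structure(list(atoms = atoms, constraints = constraints,
                 sequence = setNames(sequence, chain_id)),
            class = "pacsab_topology")
}

# index of a particle by residue number and kind (NA if absent)
atom_index <- function(atoms, resno, kind, chain = NULL) {
  sel <- atoms$resno == resno & atoms$kind == kind
  if (!is.null(chain)) sel <- sel & atoms$chain == chain
  i <- atoms$index[sel]
  if (length(i) == 0L) NA_integer_ else i[1]
}

build_constraints <- function(atoms, map, geom) {
  bl <- geom$bonds; an <- geom$angles; del <- geom$delta
  n <- max(atoms$resno)
  ai <- function(r, k) atom_index(atoms, r, k)
  res3 <- vapply(seq_len(n), function(r) atoms$resid[atoms$resno == r][1], "")

  cov <- function(i, j, d0, delta = del$covalent)
    data.frame(i = i, j = j, dmin = d0 * (1 - delta), dmax = d0 * (1 + delta),
               role = "covalent")
  ang <- function(i, j, d0, delta = del$angle)
    data.frame(i = i, j = j, dmin = d0 * (1 - delta), dmax = d0 * (1 + delta),
               role = "angle")

  out <- list()
  add <- function(x) out[[length(out) + 1L]] <<- x

  hx <- geom$conformations$helix; ex <- geom$conformations$extended
  # 1-4 distances at the helical and extended reference dihedrals
  d14_phi <- c(dist14(bl$C_N, bl$N_CA, bl$CA_C, an$C_N_CA, an$N_CA_C, hx$phi),
               dist14(bl$C_N, bl$N_CA, bl$CA_C, an$C_N_CA, an$N_CA_C, ex$phi))
  d14_psi <- c(dist14(bl$N_CA, bl$CA_C, bl$C_N, an$N_CA_C, an$CA_C_N, hx$psi),
               dist14(bl$N_CA, bl$CA_C, bl$C_N, an$N_CA_C, an$CA_C_N, ex$psi))
  d14_omega <- dist14(bl$CA_C, bl$C_N, bl$N_CA, an$CA_C_N, an$C_N_CA, geom$omega)

  for (r in seq_len(n)) {
    N <- ai(r, "N"); H <- ai(r, "H"); CA <- ai(r, "CA")
    C <- ai(r, "C"); O <- ai(r, "O")
    add(cov(N, CA, bl$N_CA))
    add(cov(CA, C, bl$CA_C))
    add(cov(C, O, bl$C_O))
    add(ang(N, C, dist13(bl$N_CA, bl$CA_C, an$N_CA_C)))
    add(ang(CA, O, dist13(bl$CA_C, bl$C_O, an$CA_C_O)))
    if (!is.na(H)) {
      add(cov(N, H, bl$N_H))
      add(ang(H, CA, dist13(bl$N_H, bl$N_CA, an$H_N_CA)))
    }
    if (r < n) {
      N2 <- ai(r + 1L, "N"); CA2 <- ai(r + 1L, "CA"); H2 <- ai(r + 1L, "H")
      add(cov(C, N2, bl$C_N))
      add(ang(CA, N2, dist13(bl$CA_C, bl$C_N, an$CA_C_N)))
      add(ang(O, N2, dist13(bl$C_O, bl$C_N, an$O_C_N)))
      add(ang(C, CA2, dist13(bl$C_N, bl$N_CA, an$C_N_CA)))
      if (!is.na(H2)) add(ang(C, H2, dist13(bl$C_N, bl$N_H, an$C_N_H)))
      # trans peptide bond: CA(i)-CA(i+1) held near the omega = 180 distance
      add(data.frame(i = CA, j = CA2,
                     dmin = d14_omega * (1 - del$angle),
                     dmax = d14_omega * (1 + del$angle),
                     role = "dihedral_range"))
      # psi freedom: N(i)-N(i+1) between the helical and extended values
      add(data.frame(i = N, j = N2,
                     dmin = min(d14_psi) * (1 - del$dihedral),
                     dmax = max(d14_psi) * (1 + del$dihedral),
                     role = "dihedral_range"))
      # phi freedom: C(i)-C(i+1) between the helical and extended values
      C2 <- ai(r + 1L, "C")
      add(data.frame(i = C, j = C2,
                     dmin = min(d14_phi) * (1 - del$dihedral),
                     dmax = max(d14_phi) * (1 + del$dihedral),
                     role = "dihedral_range"))
    }
    # side-chain links: CA - SC1 - SC2 - ...
    beads <- map[[res3[r]]]
    if (length(beads)) {
      prev <- CA
      for (b in beads) {
        sc <- ai(r, b$name)
        add(cov(prev, sc, b$link, del$sidechain_link))
        prev <- sc
      }
    }
  }
  constraints <- do.call(rbind, out)
  rownames(constraints) <- NULL
  constraints
}

#' @export
print.pacsab_topology <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat("pacsab_topology:", nrow(x$atoms), "particles,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues,",
      length(ch), if (length(ch) == 1L) "chain" else "chains",
      paste0("(", paste(ch, collapse = ", "), "),"),
      nrow(x$constraints), "constraints\n")
  invisible(x)
}

#' Number of side-chain beads per residue of a sequence
#' @param sequence one-letter sequence
#' @param map mapping table
#' @return integer vector
#' @export
sidechain_bead_counts <- function(sequence, map = read_sidechain_map()) {
  vapply(seq_to_resid(sequence), function(r) length(map[[r]]), 0L,
         USE.NAMES = FALSE)
}

#' Merge two topologies into a multi-chain system
#'
#' Concatenates the particle tables and re-indexes the constraints of the
#' second topology; no inter-chain bonded constraints are added.
#'
#' @param a,b `pacsab_topology` objects with distinct chain labels
#' @return merged `pacsab_topology`
#' @export
merge_topologies <- function(a, b) {
  stopifnot(inherits(a, "pacsab_topology"), inherits(b, "pacsab_topology"))
  if (length(intersect(unique(a$atoms$chain), unique(b$atoms$chain))))
    stop("duplicate chain label; relabel one topology before merging")
  off <- nrow(a$atoms)
  atoms_b <- b$atoms
  atoms_b$index <- atoms_b$index + off
  con_b <- b$constraints
  con_b$i <- con_b$i + off
  con_b$j <- con_b$j + off
  atoms <- rbind(a$atoms, atoms_b)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 constraints = rbind(a$constraints, con_b),
                 sequence = c(a$sequence, b$sequence)),
            class = "pacsab_topology")
}

#' Relabel the chain of a single-chain topology or structure
#' @param topology a `pacsab_topology` or `pacsab_structure`
#' @param chain_id new label
#' @return relabelled object
#' @export
set_chain <- function(topology, chain_id) {
  if (inherits(topology, "pacsab_structure")) {
    topology$topology <- set_chain(topology$topology, chain_id)
    return(topology)
  }
  old <- unique(topology$atoms$chain)
  stopifnot(length(old) == 1L)
  topology$atoms$chain <- chain_id
  names(topology$sequence) <- chain_id
  topology
}

#' Map an atomistic structure onto a coarse-grained topology
#'
#' Backbone particle coordinates are copied from the corresponding atoms and
#' each side-chain bead is placed at the unweighted centroid of its mapped
#' heavy atoms.  A missing amide H (absent from most experimental files) is
#' rebuilt from the C(i-1)/N/CA geometry; any other missing backbone atom is
#' an error.  Beads with some atoms missing fall back to the centroid of the
#' available ones, with a warning.
#'
#' @param structure atomistic structure from [read_pdb()]
#' @param topology matching `pacsab_topology`
#' @param map side-chain mapping table
#' @param geom ideal peptide geometry (for H reconstruction)
#' @return numeric matrix (n_particles x 3) aligned with `topology$atoms`
#' @export
map_structure <- function(structure, topology, map = read_sidechain_map(),
                          geom = load_peptide_geometry()) {
  at <- structure$atoms
  top <- topology$atoms
  xyz <- matrix(NA_real_, nrow(top), 3)
  chains <- unique(top$chain)
  for (ch in chains) {
    tch <- top[top$chain == ch, ]
    sch <- at[at$chain == ch, ]
    resnos <- sort(unique(tch$resno))
    sresnos <- sort(unique(sch$resno))
    if (length(sresnos) != length(resnos))
      stop("chain ", ch, ": structure has ", length(sresnos),
           " residues but topology expects ", length(resnos))
    for (k in seq_along(resnos)) {
      r <- resnos[k]
      ratoms <- sch[sch$resno == sresnos[k], ]
      res3 <- tch$resid[tch$resno == r][1]
      if (ratoms$resid[1] != res3)
        stop("chain ", ch, " residue ", r, ": structure has ",
             ratoms$resid[1], " where topology expects ", res3)
      get_atom <- function(nm) {
        m <- ratoms[ratoms$name == nm, , drop = FALSE]
        if (nrow(m) == 0L) return(NULL)
        as.numeric(m[1, c("x", "y", "z")])
      }
      for (bk in intersect(BACKBONE_KINDS, tch$kind[tch$resno == r])) {
        p <- get_atom(bk)
        if (is.null(p) && bk == "H") {
          # rebuild the amide H from local geometry
          Np <- get_atom("N"); CAp <- get_atom("CA")
          Cprev <- if (k > 1L) {
            pr <- sch[sch$resno == sresnos[k - 1L] & sch$name == "C", , drop = FALSE]
            if (nrow(pr)) as.numeric(pr[1, c("x", "y", "z")]) else NULL
          } else NULL
          p <- if (!is.null(Cprev)) {
            u <- unitv(unitv(Np - Cprev) + unitv(Np - CAp))
            Np + geom$bonds$N_H * u
          } else {
            Cp <- get_atom("C")
            nerf_place(Cp, CAp, Np, geom$bonds$N_H, geom$angles$H_N_CA, 180)
          }
        }
        if (is.null(p))
          stop("chain ", ch, " residue ", r, ": missing backbone atom ", bk)
        xyz[top$chain == ch & top$resno == r & top$kind == bk, ] <- p
      }
      for (b in map[[res3]]) {
        have <- ratoms[ratoms$name %in% b$atoms, c("x", "y", "z"), drop = FALSE]
        if (nrow(have) == 0L)
          stop("chain ", ch, " residue ", r, ": no atoms for bead ", b$name)
        if (nrow(have) < length(b$atoms))
          warning("chain ", ch, " residue ", r, " bead ", b$name,
                  ": only ", nrow(have), "/", length(b$atoms),
                  " atoms present; using centroid of available atoms")
        xyz[top$chain == ch & top$resno == r & top$kind == b$name, ] <-
          colMeans(have)
      }
    }
  }
  xyz
}
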