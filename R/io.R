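# File formats: PDB structures, multi-model PDB and binary trajectories,
# structured run configuration, provenance records.

#' Read an atomistic structure from a PDB file
#'
#' ATOM records of the first MODEL, altloc 'A' or blank; insertion codes are
#' preserved in the residue labels.
#'
#' @param path file path
#' @return a `pacsab_pdb` list with an `atoms` data.frame (name, resid,
#'   resno, label, chain, x, y, z)
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  insert <- ifelse(is.na(at$insert), "", at$insert)
  atoms <- data.frame(name = at$elety, resid = at$resid, resno = at$resno,
                      label = paste0(at$resno, insert), chain = chain,
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, path = path), class = "pacsab_pdb")
}

pdb_atom_line <- function(serial, name, resid, chain, resno, xyz) {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  el <- substr(name, 1L, 1L)
  if (el == "S" && nchar(name) > 1L) el <- "C"   # side-chain beads are carbon-ish
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, resid, chain, resno, xyz[1], xyz[2], xyz[3], 1, 0, el)
}

pdb_model_lines <- function(xyz, atoms) {
  vapply(seq_len(nrow(atoms)), function(k)
    pdb_atom_line(k, atoms$kind[k], atoms$resid[k], atoms$chain[k],
                  atoms$resno[k], xyz[k, ]), "")
}

#' Write a coarse-grained structure as PDB
#'
#' @param xyz coordinates (n x 3)
#' @param topology matching topology
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pdb <- function(xyz, topology, path) {
  lines <- c(pdb_model_lines(xyz, topology$atoms), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory
#'
#' `pdb_models` writes a multi-model PDB (interoperable, 1e-3 Angstrom
#' precision); `binary` writes a fixed-layout binary file (magic "PCSB",
#' int32 version/particle count/frame count, float64 box side and snapshot
#' interval, then float64 coordinate frames).
#'
#' @param traj a `pacsab_trajectory` (or list with `frames`, `times`,
#'   `system`)
#' @param path output path
#' @param format `"pdb_models"` or `"binary"`
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path, format = c("pdb_models", "binary")) {
  format <- match.arg(format)
  frames <- traj$frames
  nf <- if (length(dim(frames)) == 3L) dim(frames)[3] else 0L
  atoms <- traj$system$topology$atoms
  if (format == "pdb_models") {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", k), con)
      writeLines(pdb_model_lines(frames[, , k], atoms), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar("PCSB", con, nchars = 4L, eos = NULL)
    writeBin(c(1L, nrow(atoms), nf), con, size = 4L)
    dt <- if (nf > 1L) traj$times[2] - traj$times[1] else 0
    writeBin(c(traj$system$box_L, dt), con, size = 8L)
    for (k in seq_len(nf))
      writeBin(as.numeric(frames[, , k]), con, size = 8L)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path input path
#' @param format `"auto"` (by magic bytes), `"pdb_models"` or `"binary"`
#' @return list with `frames` (n x 3 x F array), `times` (binary format
#'   only), `box_L` (binary only)
#' @export
read_trajectory <- function(path, format = c("auto", "pdb_models", "binary")) {
  format <- match.arg(format)
  if (format == "auto") {
    magic <- readBin(path, "raw", 4L)
    format <- if (rawToChar(magic) == "PCSB") "binary" else "pdb_models"
  }
  if (format == "binary") {
    con <- file(path, "rb")
    on.exit(close(con))
    readChar(con, 4L, useBytes = TRUE)
    hdr <- readBin(con, "integer", 3L, size = 4L)
    box <- readBin(con, "numeric", 2L, size = 8L)
    n <- hdr[2]; nf <- hdr[3]
    frames <- array(readBin(con, "numeric", n * 3L * nf, size = 8L),
                    dim = c(n, 3L, nf))
    list(frames = frames, times = (seq_len(nf) - 1L) * box[2], box_L = box[1])
  } else {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    nf <- nrow(xyz)
    n <- ncol(xyz) / 3L
    frames <- array(0, dim = c(n, 3L, nf))
    for (k in seq_len(nf))
      frames[, , k] <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
    list(frames = frames, times = NULL, box_L = NULL)
  }
}

CONFIG_SCHEMA <- list(
  system = c("sequences", "pdb"),
  box = c("n_molecules", "concentration", "box_L_nm", "box_L_A"),
  plan = c("n_replicas", "seeds", "t_end", "initial_mode", "preset"),
  restraints = c("mode", "chain", "from", "to"),
  thermostat = c("ghost_rate", "kT"),
  output = c("dir", "format", "snapshot_interval"),
  seed = NULL)

#' Read and validate a run configuration
#'
#' Structured YAML with blocks `system` (sequences and/or PDB paths), `box`
#' (molecule count plus concentration in mol/L, or an explicit side length),
#' `plan` (replicas, seeds, t_end, preset), optional `restraints`
#' (mode + 1-based inclusive residue range), `thermostat` and `output`.
#' Unknown keys are rejected, not silently ignored.
#'
#' @param path YAML file
#' @return validated config list with attribute `md5` (provenance hash)
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(CONFIG_SCHEMA))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  for (blk in names(CONFIG_SCHEMA)) {
    if (is.null(cfg[[blk]]) || is.null(CONFIG_SCHEMA[[blk]])) next
    bad <- setdiff(names(cfg[[blk]]), CONFIG_SCHEMA[[blk]])
    if (length(bad))
      stop("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", "))
  }
  if (is.null(cfg$system) || (is.null(cfg$system$sequences) && is.null(cfg$system$pdb)))
    stop("config needs a 'system' block with 'sequences' or 'pdb'")
  if (is.null(cfg$plan) || is.null(cfg$plan$t_end))
    stop("config needs a 'plan' block with 't_end'")
  if (is.null(cfg$box)) stop("config needs a 'box' block")
  attr(cfg, "md5") <- unname(tools::md5sum(path))
  cfg
}

config_box_A <- function(cfg) {
  bx <- cfg$box
  if (!is.null(bx$box_L_A)) return(bx$box_L_A)
  if (!is.null(bx$box_L_nm)) return(10 * bx$box_L_nm)
  if (is.null(bx$n_molecules) || is.null(bx$concentration))
    stop("box block needs box_L_A, box_L_nm, or n_molecules + concentration")
  10 * box_for_concentration(bx$n_molecules, bx$concentration)
}

write_provenance <- function(path, cfg, seed) {
  yaml::write_yaml(list(config_md5 = attr(cfg, "md5"), seed = seed,
                        package = "pacsab",
                        version = as.character(utils::packageVersion("pacsab"))),
                   paste0(path, ".provenance.yaml"))
}

#' Run a replica campaign from a configuration
#'
#' Builds the molecules (extended conformers from sequences and/or mapped PDB
#' structures), places them in the box with each replica's seed, applies any
#' configured restraints, runs the replicas, and writes trajectories plus
#' provenance records (config hash, seed, package version).
#'
#' @param cfg config from [read_run_config()]
#' @param write write trajectory files to `cfg$output$dir`
#' @return list of `pacsab_trajectory`
#' @export
run_campaign <- function(cfg, write = !is.null(cfg$output$dir)) {
  preset <- if (!is.null(cfg$plan$preset)) cfg$plan$preset else "original"
  params <- ff_params(preset)
  mols <- list()
  chains <- LETTERS
  ci <- 1L
  for (s in cfg$system$sequences) {
    mols[[ci]] <- extended_chain(s, chain_id = chains[ci], params = params)
    ci <- ci + 1L
  }
  for (p in cfg$system$pdb) {
    pdb <- read_pdb(p)
    ch <- unique(pdb$atoms$chain)[1]
    sq <- paste(AA3[pdb$atoms$resid[pdb$atoms$name == "CA" &
                                      pdb$atoms$chain == ch]], collapse = "")
    topo <- build_topology(sq, chains[ci], params = params)
    xyz <- map_structure(list(atoms = pdb$atoms[pdb$atoms$chain == ch, ]), topo)
    mols[[ci]] <- structure(list(topology = topo, xyz = xyz),
                            class = "pacsab_structure")
    ci <- ci + 1L
  }
  box_A <- config_box_A(cfg)
  seeds <- if (!is.null(cfg$plan$seeds)) cfg$plan$seeds else seq_len(cfg$plan$n_replicas)
  ghost <- if (!is.null(cfg$thermostat$ghost_rate)) cfg$thermostat$ghost_rate else 0.1
  snap <- if (!is.null(cfg$output$snapshot_interval))
    cfg$output$snapshot_interval else cfg$plan$t_end / 100
  fmt <- if (!is.null(cfg$output$format)) cfg$output$format else "pdb_models"
  out <- list()
  for (s in seeds) {
    st <- place_replicas(mols, box_A, seed = s)
    restr <- NULL
    if (!is.null(cfg$restraints)) {
      rc <- cfg$restraints
      sel <- if (!is.null(rc$chain))
        list(chain = rc$chain, from = rc$from, to = rc$to) else NULL
      restr <- make_restraints(st$xyz, st$topology, sel, mode = rc$mode)
    }
    sys <- build_system(st, params, box_L = box_A, restraints = restr)
    tr <- run_dmd(sys, t_end = cfg$plan$t_end, snapshot_interval = snap,
                  ghost_rate = ghost, seed = s)
    if (write) {
      dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
      fn <- file.path(cfg$output$dir,
                      sprintf("replica_%03d.%s", s,
                              if (fmt == "binary") "trj" else "pdb"))
      write_trajectory(tr, fn, format = fmt)
      write_provenance(fn, cfg, s)
    }
    out[[length(out) + 1L]] <- tr
  }
  out
}

#' Write an event log as tab-separated text
#' @param traj trajectory run with `log_events = TRUE`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_event_log <- function(traj, path) {
  if (is.null(traj$event_log)) stop("trajectory has no event log")
  lg <- as.data.frame(traj$event_log)
  lg$kind <- c("shell_cross", "bond_bounce", "hbond", "ghost",
               "resync")[lg$kind + 1L]
  write.table(lg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
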