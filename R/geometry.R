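# Internal-coordinate geometry: NeRF atom placement, backbone construction
# from (phi, psi) dihedrals, and measurement helpers.

deg2rad <- function(x) x * pi / 180

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) v / vnorm(v)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D given positions of A, B, C, the bond length C-D, the angle
# B-C-D and the dihedral A-B-C-D (degrees): the standard NeRF construction.
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  th <- deg2rad(angle)
  ph <- -deg2rad(dihedral)   # so that dihedral_deg(a, b, c, result) == dihedral
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

load_peptide_geometry <- function(path = system.file("extdata", "peptide_geometry.yaml",
                                                     package = "pacsab")) {
  yaml::read_yaml(path)
}

# Backbone coordinates for a chain built at the given (phi, psi) angles.
# Returns a list per residue with named 3-vectors N, H (may be NULL for PRO),
# CA, C, O.  Deterministic.
build_backbone <- function(resid3, phi, psi, geom = load_peptide_geometry()) {
  n <- length(resid3)
  stopifnot(length(phi) == n, length(psi) == n)
  bl <- geom$bonds; an <- geom$angles; omega <- geom$omega
  out <- vector("list", n)
  # seed first residue in a canonical frame
  N1 <- c(0, 0, 0)
  CA1 <- c(bl$N_CA, 0, 0)
  thN <- deg2rad(an$N_CA_C)
  C1 <- CA1 + bl$CA_C * c(-cos(thN), sin(thN), 0)
  res <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n)) {
    if (i > 1L) {
      prev <- out[[i - 1L]]
      Ni <- nerf_place(prev$N, prev$CA, prev$C, bl$C_N, an$CA_C_N, psi[i - 1L])
      CAi <- nerf_place(prev$CA, prev$C, Ni, bl$N_CA, an$C_N_CA, omega)
      Ci <- nerf_place(prev$C, Ni, CAi, bl$CA_C, an$N_CA_C, phi[i])
      res <- list(N = Ni, CA = CAi, C = Ci)
    } else {
      res <- list(N = N1, CA = CA1, C = C1)
    }
    # carbonyl O: anti to the next N, i.e. dihedral N-CA-C-O = psi + 180
    res$O <- nerf_place(res$N, res$CA, res$C, bl$C_O, an$CA_C_O, psi[i] + 180)
    # amide H in the peptide plane, anti to the carbonyl of the previous
    # residue (trans to CA(i) across C(i-1)-N(i))
    if (resid3[i] != "PRO") {
      if (i > 1L) {
        prev <- out[[i - 1L]]
        res$H <- nerf_place(prev$CA, prev$C, res$N, bl$N_H, an$C_N_H, 0)
      } else {
        res$H <- nerf_place(res$C, res$CA, res$N, bl$N_H, an$H_N_CA, 180)
      }
    }
    out[[i]] <- res
  }
  out
}

# 1-3 distance from two bond lengths and the enclosed angle (degrees)
dist13 <- function(a, b, theta) sqrt(a^2 + b^2 - 2 * a * b * cos(deg2rad(theta)))

# 1-4 distance from three bond lengths, two angles and the dihedral (degrees)
dist14 <- function(b1, b2, b3, ang123, ang234, dihedral) {
  p1 <- c(0, 0, 0); p2 <- c(b1, 0, 0)
  th <- deg2rad(ang123)
  p3 <- p2 + b2 * c(-cos(th), sin(th), 0)
  p4 <- nerf_place(p1, p2, p3, b3, ang234, dihedral)
  vnorm(p4 - p1)
}

# Uniform random rotation matrix from a random unit quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
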