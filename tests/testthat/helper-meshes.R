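# Shared fixtures: a spherical-shell mesh builder (validation oracles), a
# memoised store of expensive tonometry runs, and small numeric utilities.

# Hemispherical shell (inner radius r_in, outer r_out), pole on the axis,
# equatorial cut restrained axially: same structured layout as the eye mesh.
shell_mesh <- function(r_in, r_out, nm = 24, nt = 2) {
  nm <- as.integer(nm); nt <- as.integer(nt)
  ncol_ <- 2L * nm + 1L; nrow_ <- 2L * nt + 1L
  phi <- seq(0, pi / 2, length.out = ncol_)
  zeta <- seq(0, 1, length.out = nrow_)
  th <- r_out - r_in
  nodes <- matrix(0, ncol_ * nrow_, 2)
  idx <- function(k, l) (l - 1L) * ncol_ + k
  for (l in seq_len(nrow_)) {
    rad <- r_out - zeta[l] * th
    nodes[idx(seq_len(ncol_), l), 1] <- rad * sin(phi)
    nodes[idx(seq_len(ncol_), l), 2] <- -rad * cos(phi)
  }
  nodes[idx(1L, seq_len(nrow_)), 1] <- 0
  ne <- nm * nt
  elems <- matrix(0L, ne, 9); e <- 0L
  for (j in seq_len(nt)) for (i in seq_len(nm)) {
    e <- e + 1L; loc <- 1L
    for (j0 in 0:2) for (i0 in 0:2) {
      elems[e, loc] <- idx(2L * (i - 1L) + i0 + 1L, 2L * (j - 1L) + j0 + 1L)
      loc <- loc + 1L
    }
  }
  edge_row <- function(l) t(vapply(seq_len(nm), function(i)
    idx(c(2L * i - 1L, 2L * i, 2L * i + 1L), l), integer(3)))
  tags <- list(anterior = idx(seq_len(ncol_), 1L),
               posterior = idx(seq_len(ncol_), nrow_),
               axis = idx(1L, seq_len(nrow_)),
               scleral_base = idx(ncol_, seq_len(nrow_)))
  structure(list(nodes = nodes, elems = elems, region = rep(1L, ne),
                 region_labels = "shell",
                 edges_interior = edge_row(nrow_),
                 edges_anterior = edge_row(1L),
                 tags = tags,
                 fixed_dofs = sort(unique(c(2L * tags$axis - 1L,
                                            2L * tags$scleral_base))),
                 nm = c(shell = nm), nt = nt, geometry = NULL),
            class = "meridian_mesh")
}

neo_hookean <- function(C10 = 0.05)
  gho_params(C10 = C10, k1 = 0, k2 = 1, kappa = 0)

# memoised expensive runs, shared across test files in one session
.run_store <- new.env(parent = emptyenv())

std_run <- function(material = "C", iop = 19, cct = 585, ...) {
  key <- paste(material, iop, cct, ..., sep = "|")
  if (is.null(.run_store[[key]])) {
    .run_store[[key]] <- simulate_tonometry(
      geometry = geometry_preset("baseline", cct = cct),
      material = material, iop_mmhg = iop, ...)
  }
  .run_store[[key]]
}

# random rotation matrix (seeded by the caller)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random near-identity deformation gradient, mostly isochoric
random_F <- function(sd = 0.03) {
  F <- diag(3) + matrix(rnorm(9, sd = sd), 3, 3)
  F <- F / det(F)^(1 / 3)
  F * (1 + rnorm(1, sd = 0.002))^(1 / 3)
}

# max principal Cauchy stress per row of a field table (axisymmetric:
# in-plane 2x2 eigenvalue vs hoop)
principal_stress <- function(ft) {
  tr <- ft$s_rr + ft$s_zz
  dd <- sqrt(((ft$s_rr - ft$s_zz) / 2)^2 + ft$s_rz^2)
  pmax(tr / 2 + dd, ft$s_tt)
}

# independent energy evaluation of the fiber-reinforced model for a
# diagonal isochoric stretch along the first fiber (oracle used against
# the kernel implementation)
gho_energy_oracle <- function(lam, p) {
  I1b <- lam^2 + 2 / lam
  I4 <- c(lam^2, 1 / lam)
  E <- p$kappa * (I1b - 3) + (1 - 3 * p$kappa) * (I4 - 1)
  Epos <- pmax(E, 0)
  p$C10 * (I1b - 3) + p$k1 / (2 * p$k2) * sum(exp(p$k2 * Epos^2) - 1)
}
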