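# Deterministic fixture generators: every input the analyses and tests need
# is produced by code, no external files.

.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Born ion fixture
#'
#' A single spherical ion: charge `q`, cavity radius `R`, at the centre of a
#' cubic box of edge `L` (or at the origin if nonperiodic). The analytic
#' nonperiodic solvation free energy is the Born expression
#' `-f q^2 / (2 R) * (1 - 1/eps_out)`.
#'
#' @param q Charge in e.
#' @param R Cavity radius in nm (> 0).
#' @param L Cubic box edge in nm, or `NULL` for nonperiodic.
#' @return A [charge_system()] with one atom.
#' @export
born_ion <- function(q = 1, R = 0.2, L = NULL) {
  stopifnot(R > 0)
  ctr <- if (is.null(L)) c(0, 0, 0) else rep(L / 2, 3)
  charge_system(matrix(ctr, 1, 3), charges = q, radii = R,
                names = "ION", box_edge = L)
}

#' Analytic Born solvation free energy
#'
#' @param q Charge in e.
#' @param R Cavity radius in nm.
#' @param eps_out Solvent relative permittivity.
#' @param eps_in Cavity relative permittivity (default 1).
#' @return Energy in kJ/mol.
#' @export
born_energy <- function(q, R, eps_out, eps_in = 1) {
  -.F_COULOMB * q^2 / (2 * R) * (1 / eps_in - 1 / eps_out)
}

#' Rock-salt lattice fixture (Madelung oracle)
#'
#' Alternating +1/-1 charges on a cubic lattice with lattice constant `a`
#' (nearest-neighbour distance `a/2`), `n_cells` conventional cells per axis,
#' periodic box edge `n_cells * a`. Neutral overall; 8 atoms per cell.
#'
#' @param a Lattice constant in nm.
#' @param n_cells Conventional cells per axis (>= 1).
#' @return A [charge_system()].
#' @export
rocksalt_cell <- function(a = 0.564, n_cells = 1) {
  stopifnot(a > 0, n_cells >= 1)
  m <- 2 * n_cells
  g <- as.matrix(expand.grid(0:(m - 1), 0:(m - 1), 0:(m - 1)))
  q <- (-1)^rowSums(g)
  charge_system(g * a / 2, charges = q,
                names = ifelse(q > 0, "NA+", "CL-"),
                box_edge = n_cells * a)
}

# torsion-driven atom placement (natural extension reference frame): appends D
# to chain A-B-C with bond |CD| = r, angle B-C-D = theta, torsion
# A-B-C-D = phi (degrees)
.place_atom <- function(A, B, C, r, theta, phi) {
  theta <- theta * pi / 180
  phi <- -phi * pi / 180  # sign fixes the IUPAC torsion convention
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + r * (-cos(theta) * bc + sin(theta) * (cos(phi) * m + sin(phi) * n))
}

#' Torsion angle of four points
#'
#' @param A,B,C,D Numeric 3-vectors.
#' @return Torsion angle in degrees in (-180, 180].
#' @export
torsion_angle <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Ideal helical alanine octapeptide fixture
#'
#' An 8-residue alanine peptide built with standard backbone geometry and
#' ideal alpha-helical dihedrals (phi = -57, psi = -47, omega = 180 degrees),
#' zwitterionic termini (protonated N-terminus with three amine hydrogens,
#' deprotonated C-terminal carboxylate), polar amide hydrogens, and
#' united-atom style side chains (a single CB pseudo-atom per residue, no
#' aliphatic hydrogens). Bond lengths and angles follow textbook peptide
#' values.
#'
#' @param L Optional cubic box edge in nm; when given, the peptide centroid is
#'   placed at the box centre and the system is periodic.
#' @param phi,psi Backbone dihedrals in degrees (defaults -57, -47).
#' @return A [charge_system()] with attributes `n_index` (nitrogen of the
#'   first residue) and `c_index` (carboxyl carbon of the last residue).
#' @export
ideal_helix_octapeptide <- function(L = NULL, phi = -57, psi = -47) {
  n_res <- 8
  # bond lengths (nm) and angles (deg)
  b_NCA <- 0.1458; b_CAC <- 0.1525; b_CN <- 0.1329; b_CO <- 0.1231
  b_CACB <- 0.1521; b_NH <- 0.100; b_COO <- 0.125
  a_CNCA <- 121.7; a_NCAC <- 111.2; a_CACN <- 116.2; a_CACO <- 120.8
  a_NCACB <- 110.4; a_CNH <- 119.3; a_CANH <- 109.5; a_CACOO <- 117.0
  omega <- 180

  pos <- list(); nm <- character(0); res <- integer(0)
  add <- function(p, name, r) {
    pos[[length(pos) + 1]] <<- p
    nm <<- c(nm, name)
    res <<- c(res, r)
    length(pos)
  }
  # seed: virtual previous carbonyl carbon fixes the torsion reference frame
  C_prev <- c(-b_CN * cos((180 - a_CNCA) * pi / 180),
              b_CN * sin((180 - a_CNCA) * pi / 180), 0)
  N <- c(0, 0, 0)
  CA <- c(b_NCA, 0, 0)
  i_N1 <- add(N, "N", 1L)
  add(CA, "CA", 1L)
  CA_prev <- NULL
  idx_C <- NA_integer_
  for (r in seq_len(n_res)) {
    C <- .place_atom(C_prev, N, CA, b_CAC, a_NCAC, phi)
    # side chain and carbonyl oxygen hang off the same N-CA / CA-C frames
    CB <- .place_atom(C_prev, N, CA, b_CACB, a_NCACB, phi + 122.6)
    add(CB, "CB", r)
    idx_C <- add(C, "C", r)
    if (r == 1) {
      # protonated N-terminus: three tetrahedral amine hydrogens
      for (t in c(60, 180, 300))
        add(.place_atom(C, CA, N, b_NH, a_CANH, t),
            paste0("H", (t + 60) / 120), 1L)
    }
    if (r < n_res) {
      add(.place_atom(N, CA, C, b_CO, a_CACO, psi + 180), "O", r)
      N_next <- .place_atom(N, CA, C, b_CN, a_CACN, psi)
      CA_next <- .place_atom(CA, C, N_next, b_NCA, a_CNCA, omega)
      add(N_next, "N", r + 1L)
      # amide hydrogen roughly anti to the incoming CA
      add(.place_atom(CA, C, N_next, b_NH, a_CNH, 0), "H", r + 1L)
      add(CA_next, "CA", r + 1L)
      C_prev <- C; N <- N_next; CA <- CA_next
    } else {
      # deprotonated carboxylate terminus
      add(.place_atom(N, CA, C, b_COO, a_CACOO, psi + 180), "O1", r)
      add(.place_atom(N, CA, C, b_COO, a_CACOO, psi), "O2", r)
    }
  }
  P <- do.call(rbind, pos)
  # align the helix axis (first to last CA) with +z, as builders orient
  # an ideal secondary-structure element along a box axis
  ca1 <- P[which(res == 1L & nm == "CA")[1], ]
  ca8 <- P[which(res == n_res & nm == "CA")[1], ]
  ax1 <- ca8 - ca1; ax1 <- ax1 / sqrt(sum(ax1^2))
  ez <- c(0, 0, 1)
  v <- c(ax1[2] * ez[3] - ax1[3] * ez[2],
         ax1[3] * ez[1] - ax1[1] * ez[3],
         ax1[1] * ez[2] - ax1[2] * ez[1])
  cth <- sum(ax1 * ez)
  if (sum(v^2) > 1e-16) {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    Rm <- diag(3) + vx + vx %*% vx / (1 + cth)
    P <- P %*% t(Rm)
  } else if (cth < 0) {
    P <- P %*% diag(c(1, -1, -1))
  }
  P <- sweep(P, 2, colMeans(P))
  if (!is.null(L)) P <- P + L / 2
  q <- numeric(nrow(P))
  q[nm %in% c("H1", "H2", "H3")] <- 0.248
  q[res == 1 & nm == "N"] <- 0.129
  q[res == 1 & nm == "CA"] <- 0.127
  q[nm %in% c("O1", "O2")] <- -0.635
  q[res == n_res & nm == "C"] <- 0.27
  rad <- ifelse(startsWith(nm, "H"), 0.05, 0.17)
  out <- charge_system(P, charges = q, radii = rad, names = nm, box_edge = L)
  attr(out, "resid") <- res
  attr(out, "n_index") <- i_N1
  attr(out, "c_index") <- idx_C
  out
}

#' Two-state distance sampler
#'
#' Gaussian-mixture end-to-end distance samples emulating a two-basin
#' conformational equilibrium: basin A (weight `p_A`, mean `mu_A`) and basin B
#' (weight `1 - p_A`, mean `mu_B`), common width `sigma`. Reproducible under a
#' fixed seed.
#'
#' @param p_A Probability of basin A (0 < p_A < 1); default 0.2.
#' @param mu_A,mu_B Basin means in nm (defaults 0.65 and 2.2, inside the
#'   default windows of [basin_delta_g()]).
#' @param sigma Gaussian width in nm (default 0.1).
#' @param n_frames Samples per replica.
#' @param n_replicas Number of replicas.
#' @param seed Random seed.
#' @return Data frame with columns `replica`, `frame`, `value_nm`.
#' @export
two_state_distance_sampler <- function(p_A = 0.2, mu_A = 0.65, mu_B = 2.2,
                                       sigma = 0.1, n_frames = 1000,
                                       n_replicas = 5, seed = 1) {
  stopifnot(p_A > 0, p_A < 1, sigma > 0)
  .with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_replicas), function(r) {
      inA <- runif(n_frames) < p_A
      data.frame(replica = r, frame = seq_len(n_frames),
                 value_nm = rnorm(n_frames, ifelse(inA, mu_A, mu_B), sigma))
    }))
  })
}

#' Orientation ensemble sampler
#'
#' Unit vectors on the sphere: `"isotropic"` draws uniformly; `"six-face"`
#' draws from an equal-weight von Mises-Fisher mixture centred on the six
#' cube-face directions (+x, -x, +y, -y, +z, -z) with the given
#' concentration, emulating the orientational trapping of an elongated solute
#' along the box axes. Concentration 0 degenerates to isotropic.
#'
#' @param mode `"isotropic"` or `"six-face"`.
#' @param concentration von Mises-Fisher concentration parameter (six-face
#'   mode; default 20).
#' @param n Number of vectors.
#' @param seed Random seed.
#' @return An n x 3 matrix of unit vectors.
#' @export
orientation_sampler <- function(mode = c("isotropic", "six-face"),
                                concentration = 20, n = 1000, seed = 1) {
  mode <- match.arg(mode)
  .with_seed(seed, {
    if (mode == "isotropic" || concentration < 1e-8) {
      v <- matrix(rnorm(3 * n), n, 3)
      return(v / sqrt(rowSums(v^2)))
    }
    axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    mu <- axes[sample.int(6, n, replace = TRUE), , drop = FALSE]
    k <- concentration
    u <- runif(n)
    w <- 1 + log(u + (1 - u) * exp(-2 * k)) / k
    ang <- runif(n, 0, 2 * pi)
    s <- sqrt(pmax(1 - w^2, 0))
    t(vapply(seq_len(n), function(i) {
      # tangent-plane basis at mu[i]
      a <- if (abs(mu[i, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- a - sum(a * mu[i, ]) * mu[i, ]
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(mu[i, 2] * e1[3] - mu[i, 3] * e1[2],
              mu[i, 3] * e1[1] - mu[i, 1] * e1[3],
              mu[i, 1] * e1[2] - mu[i, 2] * e1[1])
      w[i] * mu[i, ] + s[i] * (cos(ang[i]) * e1 + sin(ang[i]) * e2)
    }, numeric(3)))
  })
}

#' Random neutral charge cloud
#'
#' `n_pairs` (+1, -1) point charges placed uniformly in a cubic box with all
#' minimum-image pairwise separations at least `min_sep`. Net charge 0;
#' reproducible under a fixed seed. Used as input for the lattice-sum oracle
#' checks.
#'
#' @param n_pairs Number of +/- charge pairs.
#' @param L Cubic box edge in nm.
#' @param min_sep Minimum pairwise (minimum-image) separation in nm.
#' @param seed Random seed.
#' @return A periodic [charge_system()].
#' @export
random_neutral_cloud <- function(n_pairs = 4, L = 3, min_sep = 0.3, seed = 1) {
  stopifnot(n_pairs >= 1, min_sep > 0, min_sep < L / 2)
  n <- 2 * n_pairs
  .with_seed(seed, {
    pts <- matrix(NA_real_, n, 3)
    placed <- 0
    for (attempt in seq_len(20000)) {
      p <- runif(3, 0, L)
      ok <- TRUE
      if (placed > 0) {
        d <- sweep(pts[seq_len(placed), , drop = FALSE], 2, p, `-`)
        d <- d - L * round(d / L)
        ok <- min(sqrt(rowSums(d^2))) >= min_sep
      }
      if (ok) {
        placed <- placed + 1
        pts[placed, ] <- p
        if (placed == n) break
      }
    }
    if (placed < n)
      stop("could not place ", n, " charges with min_sep = ", min_sep)
    charge_system(pts, charges = rep(c(1, -1), n_pairs),
                  names = rep(c("P", "M"), n_pairs), box_edge = L)
  })
}
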