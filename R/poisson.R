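#' Grid specification for the finite-difference Poisson solvers
#'
#' @param spacing Grid spacing h in nm (default 0.05).
#' @param eps_in Relative permittivity inside the solute cavity (default 1).
#' @param eps_out Relative permittivity of the solvent continuum; default
#'   taken from [fs_constants()] (66.6, the SPC-like water model value).
#' @param kappa Inverse Debye screening length in nm^-1 (default 0; a nonzero
#'   value adds the linearized screening term in the solvent region only).
#' @param sor_tol Relative residual tolerance of the relaxation solver
#'   (default 1e-6).
#' @param max_iter Iteration cap for the relaxation solver.
#' @param padding Nonperiodic grids span `padding` times the solute extent
#'   (default 3), so the Coulomb-Dirichlet boundary sits well away from the
#'   cavity.
#' @param min_dims Minimum grid points per axis (default 16).
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(spacing = 0.05, eps_in = 1, eps_out = NULL,
                      kappa = 0, sor_tol = 1e-6, max_iter = 50000,
                      padding = 3, min_dims = 16) {
  if (is.null(eps_out)) eps_out <- fs_constants()$eps_solvent
  stopifnot(spacing > 0, eps_in >= 1, eps_out >= 1, kappa >= 0,
            sor_tol > 0, padding >= 1, min_dims >= 4)
  structure(list(spacing = spacing, eps_in = eps_in, eps_out = eps_out,
                 kappa = kappa, sor_tol = sor_tol, max_iter = max_iter,
                 padding = padding, min_dims = min_dims),
            class = "grid_spec")
}

# grid geometry: origin = coordinates of node [1,1,1]; nodes along axis a are
# origin[a] + (0:(dims[a]-1)) * h. Periodic grids tile the box (h = L/N).
.make_grid <- function(origin, h, dims, periodic) {
  list(origin = origin, h = h, dims = as.integer(dims), periodic = periodic)
}

.grid_for <- function(system, spec, boundary) {
  if (boundary == "periodic") {
    L <- system$box_edge
    if (is.null(L)) stop("periodic Poisson solve requires a periodic system")
    n <- max(spec$min_dims, round(L / spec$spacing))
    if (n %% 2 == 1) n <- n + 1  # red-black coloring needs even periodic dims
    .make_grid(c(0, 0, 0), L / n, c(n, n, n), TRUE)
  } else {
    pos <- system$positions
    r <- system$radii
    ext <- max(apply(pos + r, 2, max) - apply(pos - r, 2, min))
    if (ext <= 0) ext <- 8 * spec$spacing
    edge <- max(spec$padding * ext, (spec$min_dims - 1) * spec$spacing)
    n <- max(spec$min_dims, ceiling(edge / spec$spacing) + 1)
    ctr <- (apply(pos + r, 2, max) + apply(pos - r, 2, min)) / 2
    h <- spec$spacing
    .make_grid(ctr - (n - 1) * h / 2, h, c(n, n, n), FALSE)
  }
}

.grid_axes <- function(grid) {
  lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$dims[a]) - 1) * grid$h)
}

# merge a set of [lo, hi] intervals and return total covered length
.union_length <- function(lo, hi) {
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  tot <- 0; cl <- lo[1]; ch <- hi[1]
  for (t in seq_along(lo)[-1]) {
    if (lo[t] > ch) { tot <- tot + (ch - cl); cl <- lo[t]; ch <- hi[t] }
    else ch <- max(ch, hi[t])
  }
  tot + (ch - cl)
}

# atoms (and, when periodic, their relevant images) whose cavity spheres can
# touch the grid
.cavity_atoms <- function(system, grid) {
  pos <- system$positions
  r <- system$radii
  keep <- r > 0
  pos <- pos[keep, , drop = FALSE]
  r <- r[keep]
  if (length(r) == 0) return(list(pos = pos, r = r))
  if (grid$periodic) {
    L <- system$box_edge
    pos <- pos %% L
    sh <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) * L
    allpos <- do.call(rbind, lapply(seq_len(nrow(sh)), function(s)
      sweep(pos, 2, sh[s, ], `+`)))
    allr <- rep(r, nrow(sh))
    lo <- grid$origin - max(allr) - grid$h
    hi <- grid$origin + (grid$dims - 1) * grid$h + max(allr) + grid$h
    keep2 <- allpos[, 1] >= lo[1] & allpos[, 1] <= hi[1] &
      allpos[, 2] >= lo[2] & allpos[, 2] <= hi[2] &
      allpos[, 3] >= lo[3] & allpos[, 3] <= hi[3]
    list(pos = allpos[keep2, , drop = FALSE], r = allr[keep2])
  } else {
    # the Dirichlet boundary assumes solvent there: keep cavities at least
    # one cell inside the grid
    gmin <- grid$origin + grid$h
    gmax <- grid$origin + (grid$dims - 2) * grid$h
    if (any(sweep(pos - r, 2, gmin, `<`)) || any(sweep(pos + r, 2, gmax, `>`)))
      stop("grid too small: an atom cavity sphere exceeds the nonperiodic ",
           "grid bounds (increase padding)")
    list(pos = pos, r = r)
  }
}

#' Build the dielectric permittivity field on grid edges
#'
#' The cavity model is sharp: permittivity is `eps_in` inside any atom sphere
#' (distance to the atom centre at most its radius) and `eps_out` outside.
#' Each grid edge gets the harmonic average of the permittivity along it,
#' weighted by the exact fraction of the edge inside the cavity union:
#' `1/eps_edge = f_in/eps_in + (1 - f_in)/eps_out`. The harmonic (series)
#' average is the standard flux-conserving discretization for an interface
#' crossing an edge.
#'
#' @param system A [charge_system()] with radii.
#' @param spec A [grid_spec()].
#' @param boundary `"periodic"` (grid tiles the box) or `"nonperiodic"`
#'   (padded grid around the solute).
#' @param grid Internal override of the grid geometry.
#' @return List with edge arrays `epsx`, `epsy`, `epsz` (permittivity on the
#'   edge leaving each node in +x/+y/+z), the logical node array
#'   `node_inside`, and attribute `grid`.
#' @export
build_dielectric_grid <- function(system, spec = grid_spec(),
                                  boundary = c("periodic", "nonperiodic"),
                                  grid = NULL) {
  boundary <- match.arg(boundary)
  if (is.null(grid)) grid <- .grid_for(system, spec, boundary)
  ax <- .grid_axes(grid)
  nd <- grid$dims
  h <- grid$h
  ca <- .cavity_atoms(system, grid)
  eps <- lapply(1:3, function(d) array(spec$eps_out, nd))
  node_inside <- array(FALSE, nd)
  if (length(ca$r) > 0) {
    # nodes inside the cavity union
    for (a in seq_along(ca$r)) {
      c0 <- ca$pos[a, ]; R <- ca$r[a]
      ix <- which(abs(ax[[1]] - c0[1]) <= R)
      iy <- which(abs(ax[[2]] - c0[2]) <= R)
      iz <- which(abs(ax[[3]] - c0[3]) <= R)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx2 <- (ax[[1]][ix] - c0[1])^2
      dy2 <- (ax[[2]][iy] - c0[2])^2
      dz2 <- (ax[[3]][iz] - c0[3])^2
      d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
      sel <- which(d2 <= R^2, arr.ind = TRUE)
      if (nrow(sel)) {
        idx <- cbind(ix[sel[, 1]], iy[sel[, 2]], iz[sel[, 3]])
        node_inside[idx] <- TRUE
      }
    }
    # fraction of each edge inside the union, per direction
    for (d in 1:3) {
      p1 <- (d %% 3) + 1; p2 <- ((d + 1) %% 3) + 1
      ids <- integer(0); los <- numeric(0); his <- numeric(0)
      for (a in seq_along(ca$r)) {
        c0 <- ca$pos[a, ]; R <- ca$r[a]
        i_d <- which(ax[[d]] <= c0[d] + R & ax[[d]] + h >= c0[d] - R)
        i_1 <- which(abs(ax[[p1]] - c0[p1]) < R)
        i_2 <- which(abs(ax[[p2]] - c0[p2]) < R)
        if (!length(i_d) || !length(i_1) || !length(i_2)) next
        perp2 <- outer((ax[[p1]][i_1] - c0[p1])^2,
                       (ax[[p2]][i_2] - c0[p2])^2, `+`)
        sel <- which(perp2 < R^2, arr.ind = TRUE)
        if (!nrow(sel)) next
        s <- sqrt(R^2 - perp2[sel])
        for (m in seq_len(nrow(sel))) {
          tlo <- pmax(0, (c0[d] - s[m] - ax[[d]][i_d]) / h)
          thi <- pmin(1, (c0[d] + s[m] - ax[[d]][i_d]) / h)
          ok <- thi > tlo
          if (!any(ok)) next
          sub <- cbind(i_d[ok], i_1[sel[m, 1]], i_2[sel[m, 2]])
          cols <- integer(3)
          cols[c(d, p1, p2)] <- 1:3
          sub <- sub[, cols, drop = FALSE]
          lin <- sub[, 1] + nd[1] * (sub[, 2] - 1 + nd[2] * (sub[, 3] - 1))
          ids <- c(ids, lin); los <- c(los, tlo[ok]); his <- c(his, thi[ok])
        }
      }
      if (length(ids)) {
        fin <- vapply(split(seq_along(ids), ids), function(ii)
          .union_length(los[ii], his[ii]), numeric(1))
        fin <- pmin(fin, 1)
        lin <- as.integer(names(fin))
        eps[[d]][lin] <- 1 / (fin / spec$eps_in + (1 - fin) / spec$eps_out)
      }
    }
  }
  if (!grid$periodic) {
    # edges leaving the last node along each axis are outside the grid
    eps[[1]][nd[1], , ] <- 0
    eps[[2]][, nd[2], ] <- 0
    eps[[3]][, , nd[3]] <- 0
  }
  structure(list(epsx = eps[[1]], epsy = eps[[2]], epsz = eps[[3]],
                 node_inside = node_inside),
            grid = grid, spec = spec, class = "dielectric_grid")
}

#' Spread point charges onto the grid
#'
#' Trilinear (cloud-in-cell) assignment of each point charge to its eight
#' surrounding nodes; the grid total equals the net charge exactly.
#'
#' @inheritParams build_dielectric_grid
#' @return 3-d array of charge (e) per node, attribute `grid`.
#' @export
spread_charges <- function(system, spec = grid_spec(),
                           boundary = c("periodic", "nonperiodic"),
                           grid = NULL) {
  boundary <- match.arg(boundary)
  if (is.null(grid)) grid <- .grid_for(system, spec, boundary)
  nd <- grid$dims
  rho <- array(0, nd)
  pos <- system$positions
  q <- system$charges
  for (a in seq_len(nrow(pos))) {
    if (q[a] == 0) next
    u <- (pos[a, ] - grid$origin) / grid$h
    i0 <- floor(u)
    fr <- u - i0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- prod(ifelse(c(cx, cy, cz) == 1, fr, 1 - fr))
      if (w == 0) next
      ii <- i0 + c(cx, cy, cz)
      if (grid$periodic) {
        ii <- ii %% nd
      } else if (any(ii < 0) || any(ii > nd - 1)) {
        stop("atom ", a, " lies outside the nonperiodic grid")
      }
      idx <- cbind(ii[1] + 1, ii[2] + 1, ii[3] + 1)
      rho[idx] <- rho[idx] + q[a] * w
    }
  }
  structure(rho, grid = grid)
}

.interp_trilinear <- function(values, grid, points) {
  nd <- grid$dims
  out <- numeric(nrow(points))
  for (a in seq_len(nrow(points))) {
    u <- (points[a, ] - grid$origin) / grid$h
    i0 <- floor(u)
    fr <- u - i0
    v <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- prod(ifelse(c(cx, cy, cz) == 1, fr, 1 - fr))
      if (w == 0) next
      ii <- i0 + c(cx, cy, cz)
      if (grid$periodic) ii <- ii %% nd
      else ii <- pmin(pmax(ii, 0), nd - 1)
      v <- v + w * values[ii[1] + 1, ii[2] + 1, ii[3] + 1]
    }
    out[a] <- v
  }
  out
}

# Coulomb potential of the system's charges at the grid boundary nodes,
# screened by a uniform permittivity eps
.coulomb_boundary <- function(system, grid, eps) {
  nd <- grid$dims
  ax <- .grid_axes(grid)
  vals <- array(0, nd)
  bnd <- array(FALSE, nd)
  bnd[c(1, nd[1]), , ] <- TRUE
  bnd[, c(1, nd[2]), ] <- TRUE
  bnd[, , c(1, nd[3])] <- TRUE
  sel <- which(bnd, arr.ind = TRUE)
  px <- ax[[1]][sel[, 1]]; py <- ax[[2]][sel[, 2]]; pz <- ax[[3]][sel[, 3]]
  phi <- numeric(nrow(sel))
  pos <- system$positions; q <- system$charges
  for (a in seq_len(nrow(pos))) {
    if (q[a] == 0) next
    r <- sqrt((px - pos[a, 1])^2 + (py - pos[a, 2])^2 + (pz - pos[a, 3])^2)
    phi <- phi + .F_COULOMB * q[a] / (eps * pmax(r, 1e-9))
  }
  vals[sel] <- phi
  vals
}

#' Solve the finite-difference Poisson equation
#'
#' Solves `div(eps grad phi) - eps_out*kappa^2*phi*(solvent mask) =
#' -4*pi*f*rho` on the grid by red-black successive over-relaxation with a
#' 7-point stencil, to the relative residual `spec$sor_tol`. Periodic
#' solutions are gauge-fixed to zero mean; a periodic net charge is
#' compensated by a uniform background (the mean source is subtracted).
#' In `"coulomb-dirichlet"` mode the boundary nodes are fixed at the analytic
#' Coulomb potential of the charges screened by `eps_boundary`.
#'
#' @param rho Charge array from [spread_charges()] (attribute `grid`
#'   required).
#' @param eps A `dielectric_grid` from [build_dielectric_grid()], or `NULL`
#'   for a uniform permittivity of `eps_uniform`.
#' @param spec A [grid_spec()].
#' @param boundary `"periodic"` or `"coulomb-dirichlet"`.
#' @param system Required for `"coulomb-dirichlet"`: source of the boundary
#'   potential.
#' @param eps_uniform Uniform permittivity used when `eps` is `NULL`.
#' @param eps_boundary Permittivity screening the Dirichlet boundary values
#'   (defaults to `eps_uniform` for uniform solves, else `spec$eps_out`).
#' @return A `potential_grid`: list with `values` (kJ mol^-1 e^-1 per node),
#'   `grid`, `boundary`, `iterations`, `residual`.
#' @export
solve_poisson_fd <- function(rho, eps = NULL, spec = grid_spec(),
                             boundary = c("periodic", "coulomb-dirichlet"),
                             system = NULL, eps_uniform = spec$eps_out,
                             eps_boundary = NULL) {
  boundary <- match.arg(boundary)
  grid <- attr(rho, "grid")
  if (is.null(grid)) stop("rho must carry a `grid` attribute (spread_charges)")
  nd <- grid$dims
  if (is.null(eps)) {
    e1 <- array(eps_uniform, nd); e2 <- e1; e3 <- e1
    if (!grid$periodic) {
      e1[nd[1], , ] <- 0; e2[, nd[2], ] <- 0; e3[, , nd[3]] <- 0
    }
    node_inside <- array(FALSE, nd)
    if (is.null(eps_boundary)) eps_boundary <- eps_uniform
  } else {
    e1 <- eps$epsx; e2 <- eps$epsy; e3 <- eps$epsz
    node_inside <- eps$node_inside
    if (is.null(eps_boundary)) eps_boundary <- spec$eps_out
  }
  b <- 4 * pi * .F_COULOMB * as.vector(rho) / grid$h
  periodic <- boundary == "periodic"
  if (periodic) {
    if (!grid$periodic) stop("periodic solve on a nonperiodic grid")
    b <- b - mean(b)  # neutralizing background for net-charge systems
    phi0 <- numeric(length(b))
  } else {
    if (is.null(system))
      stop("coulomb-dirichlet boundary requires `system` for boundary values")
    phi0 <- as.vector(.coulomb_boundary(system, grid, eps_boundary))
  }
  kterm <- as.vector(spec$eps_out * spec$kappa^2 * grid$h^2 *
                       (!node_inside))
  omega <- 2 / (1 + sin(pi / max(nd)))
  res <- sor_solve_cpp(phi0, b, as.vector(e1), as.vector(e2), as.vector(e3),
                       kterm, nd, periodic, omega, spec$sor_tol,
                       spec$max_iter)
  if (res$residual > spec$sor_tol)
    stop(sprintf("Poisson solver did not converge in %d iterations ",
                 spec$max_iter),
         sprintf("(relative residual %.3g > %.3g)", res$residual,
                 spec$sor_tol))
  phi <- array(res$phi, nd)
  if (periodic) phi <- phi - mean(phi)  # zero-mean gauge
  structure(list(values = phi, grid = grid,
                 boundary = if (periodic) "periodic" else "coulomb-dirichlet",
                 iterations = res$iterations, residual = res$residual),
            class = "potential_grid")
}

#' Solve the periodic Poisson equation spectrally (uniform permittivity)
#'
#' Inverts exactly the same discrete 7-point operator as [solve_poisson_fd()]
#' by FFT; valid only for uniform permittivity and periodic boundaries. The
#' k = 0 mode is set to zero (neutralizing background / zero-mean gauge).
#'
#' @param rho Charge array from [spread_charges()] on a periodic grid.
#' @param spec A [grid_spec()].
#' @param eps_uniform The uniform relative permittivity (default
#'   `spec$eps_out`).
#' @return A `potential_grid`.
#' @export
solve_poisson_fft <- function(rho, spec = grid_spec(),
                              eps_uniform = spec$eps_out) {
  grid <- attr(rho, "grid")
  if (is.null(grid) || !grid$periodic)
    stop("solve_poisson_fft requires a periodic grid")
  if (length(eps_uniform) != 1)
    stop("solve_poisson_fft requires a uniform (scalar) permittivity")
  if (spec$kappa != 0)
    stop("spectral solve does not support the masked screening term")
  nd <- grid$dims
  b <- 4 * pi * .F_COULOMB * rho / grid$h
  lam <- function(n) 2 * (cos(2 * pi * (0:(n - 1)) / n) - 1)
  eig <- outer(outer(lam(nd[1]), lam(nd[2]), `+`), lam(nd[3]), `+`)
  bhat <- fft(b)
  phihat <- array(0i, nd)
  nz <- eig != 0
  phihat[nz] <- bhat[nz] / (-eps_uniform * eig[nz])
  phi <- Re(fft(phihat, inverse = TRUE)) / prod(nd)
  phi <- phi - mean(phi)
  structure(list(values = phi, grid = grid, boundary = "periodic",
                 iterations = 0L, residual = 0),
            class = "potential_grid")
}

#' Continuum-electrostatics solvation free energy on a grid
#'
#' Charging free energy of the solute cavity in the dielectric continuum:
#' \deqn{\Delta G_{solv} = \tfrac12 \sum_i q_i\,[\phi_{het}(r_i) -
#'   \phi_{vac}(r_i)]}
#' where the heterogeneous solve uses the cavity dielectric model and the
#' vacuum solve repeats the identical grid computation with permittivity
#' `eps_in` everywhere, so the grid self-energy of the spread charges cancels
#' exactly by construction. Potentials are interpolated trilinearly at the
#' atom centres.
#'
#' Under `"periodic"` boundaries the result includes the periodicity-induced
#' (Wigner-type) artifacts of the lattice-sum setup being modelled; under
#' `"nonperiodic"` boundaries it approximates the ideal infinite-dilution
#' value with Coulomb-Dirichlet boundary conditions on a padded grid.
#'
#' @param system A [charge_system()] with radii.
#' @param spec A [grid_spec()].
#' @param boundary `"nonperiodic"` (default) or `"periodic"`.
#' @return Solvation free energy in kJ/mol, with attributes `eps_out`,
#'   `spacing`, `iterations`.
#' @export
solvation_free_energy <- function(system, spec = grid_spec(),
                                  boundary = c("nonperiodic", "periodic")) {
  boundary <- match.arg(boundary)
  if (all(system$charges == 0))
    return(structure(0, eps_out = spec$eps_out, spacing = spec$spacing,
                     iterations = c(het = 0L, vac = 0L)))
  grid <- .grid_for(system, spec, boundary)
  eps <- build_dielectric_grid(system, spec, boundary, grid = grid)
  rho <- spread_charges(system, spec, boundary, grid = grid)
  if (boundary == "periodic") {
    het <- solve_poisson_fd(rho, eps, spec, "periodic")
    spec0 <- spec
    spec0$kappa <- 0  # no screening in the vacuum reference
    vac <- solve_poisson_fft(rho, spec0, eps_uniform = spec$eps_in)
  } else {
    het <- solve_poisson_fd(rho, eps, spec, "coulomb-dirichlet",
                            system = system, eps_boundary = spec$eps_out)
    vac <- solve_poisson_fd(rho, NULL, spec, "coulomb-dirichlet",
                            system = system, eps_uniform = spec$eps_in,
                            eps_boundary = spec$eps_in)
  }
  dphi <- .interp_trilinear(het$values, grid, system$positions) -
    .interp_trilinear(vac$values, grid, system$positions)
  structure(sum(0.5 * system$charges * dphi),
            eps_out = spec$eps_out, spacing = spec$spacing,
            iterations = c(het = het$iterations, vac = vac$iterations))
}

#' Polarization correction for lattice-sum artifacts
#'
#' For each snapshot and end state, compares the continuum solvation free
#' energy of the perturbed group under nonperiodic boundaries with the
#' periodic solve in the simulation box:
#' \deqn{\Delta G_{pol} = \langle \Delta G_{solv}^{NPBC} -
#'   \Delta G_{solv}^{PBC} \rangle_B - \langle \cdot \rangle_A.}
#' The corrected free energy is `raw + dG_pol`. The default solvent
#' permittivity (66.6) is echoed in the result; choosing 78 instead shifts the
#' correction by a box-size-independent offset.
#'
#' @inheritParams delta_g_dir
#' @param spec A [grid_spec()].
#' @return A `finsize_correction` (see [delta_g_dir()]) with `term = "pol"`
#'   and attribute `eps_out`.
#' @export
delta_g_pol <- function(frames_A, frames_B, topology, spec = grid_spec()) {
  .check_frames(frames_A, frames_B)
  qa <- state_charges(topology, "A")
  qb <- state_charges(topology, "B")
  one <- function(frames, qstate) vapply(frames, function(fr) {
    grp <- solute_group(fr)
    if (length(qstate) != n_atoms(grp))
      stop("state charge vector length does not match the perturbed group")
    grp$charges <- qstate
    as.numeric(solvation_free_energy(grp, spec, "nonperiodic")) -
      as.numeric(solvation_free_energy(grp, spec, "periodic"))
  }, numeric(1))
  out <- .correction_fragment("pol", one(frames_A, qa), one(frames_B, qb))
  attr(out, "eps_out") <- spec$eps_out
  out
}
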