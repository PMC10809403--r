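#' Construct a charge system
#'
#' A `charge_system` is the central container: atom positions (nm), partial
#' charges (e), cavity radii (nm), atom names, an optional cubic periodic box
#' edge `L` (nm), and per-atom group tags partitioning the atoms into
#' `host`, `solute`, `coion`, `solvent`, or `salt`.
#'
#' @param positions Numeric matrix with 3 columns (x, y, z in nm), one row per
#'   atom.
#' @param charges Numeric vector of per-atom charges in e.
#' @param radii Numeric vector of per-atom cavity radii in nm (default 0).
#' @param names Character vector of atom labels.
#' @param box_edge Cubic box edge length L in nm, or `NULL` for a nonperiodic
#'   system.
#' @param group_tags Character vector of group memberships; defaults to
#'   `"solute"` for every atom.
#' @return An object of class `charge_system`.
#' @examples
#' cs <- charge_system(matrix(c(0, 0, 0), 1, 3), charges = 1,
#'                     radii = 0.2, names = "ION", box_edge = 3)
#' net_charge(cs)
#' @export
charge_system <- function(positions, charges, radii = NULL, names = NULL,
                          box_edge = NULL, group_tags = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3)
    stop("`positions` must have 3 columns (x, y, z in nm)")
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  charges <- as.numeric(charges)
  if (length(charges) == 1) charges <- rep(charges, n)
  if (is.null(radii)) radii <- rep(0, n)
  radii <- as.numeric(radii)
  if (length(radii) == 1) radii <- rep(radii, n)
  if (is.null(names)) names <- sprintf("AT%d", seq_len(n))
  if (is.null(group_tags)) group_tags <- rep("solute", n)
  if (length(charges) != n || length(radii) != n || length(names) != n ||
      length(group_tags) != n)
    stop("per-atom fields must all have length nrow(positions)")
  if (!all(is.finite(positions))) stop("all coordinates must be finite")
  if (!all(is.finite(charges))) stop("all charges must be finite")
  if (any(radii < 0)) stop("radii must be >= 0")
  if (!is.null(box_edge)) {
    if (length(box_edge) == 3) {
      if (max(abs(diff(box_edge))) > 1e-9)
        stop("unsupported geometry: only cubic boxes are supported")
      box_edge <- box_edge[1]
    }
    box_edge <- as.numeric(box_edge)
    if (!is.finite(box_edge) || box_edge <= 0)
      stop("box_edge must be a positive length in nm")
  }
  tags_ok <- group_tags %in% c("host", "solute", "coion", "solvent", "salt")
  if (!all(tags_ok))
    stop("unknown group tag(s): ", paste(unique(group_tags[!tags_ok]),
                                         collapse = ", "))
  structure(
    list(positions = positions, charges = charges, radii = radii,
         names = as.character(names), box_edge = box_edge,
         group_tags = as.character(group_tags)),
    class = "charge_system"
  )
}

#' Net charge of a system
#'
#' @param system A [charge_system()].
#' @return Sum of per-atom charges in e.
#' @export
net_charge <- function(system) {
  stopifnot(inherits(system, "charge_system"))
  sum(system$charges)
}

#' Number of atoms in a system
#' @param system A [charge_system()].
#' @return Integer atom count.
#' @export
n_atoms <- function(system) nrow(system$positions)

#' @export
print.charge_system <- function(x, ...) {
  cat(sprintf("charge_system: %d atoms, net charge %+g e, %s\n",
              n_atoms(x), net_charge(x),
              if (is.null(x$box_edge)) "nonperiodic"
              else sprintf("cubic box L = %g nm", x$box_edge)))
  invisible(x)
}

#' Assemble a charge system from coordinates and a charge/radius table
#'
#' Joins a coordinate set (e.g. from [read_gro()] or [read_pdb()]) with a
#' per-atom-name charge and radius table. Every atom name must be resolvable
#' in the table.
#'
#' @param coordinates Data frame with columns `name`, `x`, `y`, `z`
#'   (nm) and optionally `group`.
#' @param charge_table Data frame with columns `name`, `charge_e`,
#'   `radius_nm`, e.g. from [read_charge_table()].
#' @param box_edge Cubic box edge in nm or `NULL`. If the coordinate set
#'   carries a `box_edge` attribute it is used as the default.
#' @return A [charge_system()]; the net charge is reported via `message()`.
#' @examples
#' coords <- data.frame(name = c("C", "O1", "O2"),
#'                      x = c(0, 0.12, -0.12), y = 0, z = 0)
#' tab <- data.frame(name = c("C", "O1", "O2"),
#'                   charge_e = c(0.27, -0.635, -0.635),
#'                   radius_nm = c(0.2, 0.15, 0.15))
#' cs <- make_charge_system(coords, tab)
#' net_charge(cs)  # -1
#' @export
make_charge_system <- function(coordinates, charge_table, box_edge = NULL) {
  req <- c("name", "x", "y", "z")
  if (!all(req %in% names(coordinates)))
    stop("`coordinates` needs columns name, x, y, z")
  if (!all(c("name", "charge_e", "radius_nm") %in% names(charge_table)))
    stop("`charge_table` needs columns name, charge_e, radius_nm")
  idx <- match(coordinates$name, charge_table$name)
  if (anyNA(idx)) {
    missing <- unique(coordinates$name[is.na(idx)])
    stop("atom name(s) not in charge table: ", paste(missing, collapse = ", "))
  }
  if (is.null(box_edge)) box_edge <- attr(coordinates, "box_edge")
  tags <- if ("group" %in% names(coordinates)) coordinates$group else NULL
  cs <- charge_system(
    positions = cbind(coordinates$x, coordinates$y, coordinates$z),
    charges = charge_table$charge_e[idx],
    radii = charge_table$radius_nm[idx],
    names = coordinates$name,
    box_edge = box_edge,
    group_tags = tags
  )
  message(sprintf("net charge: %+g e over %d atoms", net_charge(cs),
                  n_atoms(cs)))
  cs
}

#' Extract the solute group of a system
#'
#' The perturbed group used by the direct-interaction correction: all atoms
#' tagged `host`, `solute`, or `coion`.
#'
#' @param system A [charge_system()].
#' @return A [charge_system()] restricted to the solute group (the box edge is
#'   retained).
#' @export
solute_group <- function(system) {
  keep <- system$group_tags %in% c("host", "solute", "coion")
  if (!any(keep)) stop("system has no host/solute/coion atoms")
  charge_system(system$positions[keep, , drop = FALSE],
                system$charges[keep], system$radii[keep],
                system$names[keep], system$box_edge,
                system$group_tags[keep])
}
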