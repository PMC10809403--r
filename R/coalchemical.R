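#' Perturbation topology (end-state charge bookkeeping)
#'
#' Low-level constructor for the charge bookkeeping of an alchemical
#' perturbation in which a solute charge change is compensated by a
#' coalchemical ion. Scalar end-state charges are mandatory; per-atom charge
#' vectors for the perturbed group (used by [delta_g_pol()] and
#' [delta_g_dir()]) are optional.
#'
#' @param q_solute_A,q_solute_B Net solute charge at the end states (e).
#' @param q_ion_A,q_ion_B Coalchemical ion charge at the end states (e).
#' @param q_host Net charge of the host (e), 0 if none.
#' @param q_environment Net charge of everything else in the box (solvent,
#'   static counter-ions, salt); 0 for neutral environments.
#' @param per_atom_A,per_atom_B Optional per-atom charge vectors for the
#'   perturbed group at each state; their sums must equal
#'   `q_host + q_solute + q_ion` at the respective state.
#' @param n_lambda Number of equidistant lambda windows (default 11).
#' @param mode `"neutral-box"` or `"constant-charge"` (metadata).
#' @param ion_species Optional label (e.g. `"NA+"`); metadata only, the
#'   energetics modules see only charges.
#' @return A list of class `perturbation_topology` with the fields above plus
#'   `q_overall_A`, `q_overall_B` and the lambda schedule.
#' @export
perturbation_topology <- function(q_solute_A, q_solute_B, q_ion_A, q_ion_B,
                                  q_host = 0, q_environment = 0,
                                  per_atom_A = NULL, per_atom_B = NULL,
                                  n_lambda = 11, mode = "neutral-box",
                                  ion_species = NULL) {
  stopifnot(n_lambda >= 2)
  qoA <- q_host + q_solute_A + q_ion_A + q_environment
  qoB <- q_host + q_solute_B + q_ion_B + q_environment
  chk <- function(v, q, state) {
    if (!is.null(v) && abs(sum(v) - (q_host + q)) > 1e-9)
      stop("per_atom_", state, " sums to ", sum(v),
           " but the perturbed group should carry ", q_host + q, " e")
  }
  chk(per_atom_A, q_solute_A + q_ion_A, "A")
  chk(per_atom_B, q_solute_B + q_ion_B, "B")
  structure(
    list(q_solute_A = q_solute_A, q_solute_B = q_solute_B,
         q_ion_A = q_ion_A, q_ion_B = q_ion_B,
         q_host = q_host, q_environment = q_environment,
         q_overall_A = qoA, q_overall_B = qoB,
         per_atom_A = per_atom_A, per_atom_B = per_atom_B,
         n_lambda = as.integer(n_lambda),
         lambdas = seq(0, 1, length.out = n_lambda),
         mode = mode, ion_species = ion_species),
    class = "perturbation_topology")
}

#' Per-atom charges of the perturbed group at an end state
#'
#' @param topology A [perturbation_topology()].
#' @param state `"A"` or `"B"`.
#' @return Numeric charge vector.
#' @export
state_charges <- function(topology, state = c("A", "B")) {
  state <- match.arg(state)
  v <- topology[[paste0("per_atom_", state)]]
  if (is.null(v))
    stop("topology has no per-atom charge vector for state ", state,
         "; supply per_atom_A / per_atom_B")
  v
}

#' @export
print.perturbation_topology <- function(x, ...) {
  cat(sprintf("perturbation (%s): solute %+g -> %+g, ion %+g -> %+g\n",
              x$mode, x$q_solute_A, x$q_solute_B, x$q_ion_A, x$q_ion_B))
  cat(sprintf("  host %+g, environment %+g, overall %+g -> %+g, %d lambdas\n",
              x$q_host, x$q_environment, x$q_overall_A, x$q_overall_B,
              x$n_lambda))
  invisible(x)
}

#' Build a coalchemical ion perturbation
#'
#' Constructs the charge bookkeeping for perturbing a solute from
#' `solute_dq[1]` to `solute_dq[2]` inside a host of charge `host_charge`,
#' while a coalchemical ion absorbs the opposite charge change so the box
#' charge is conserved:
#' `q_ion_B = q_ion_A - (q_solute_B - q_solute_A)`.
#'
#' In `"neutral-box"` mode the box must additionally be exactly neutral at
#' state A (hence, by linear charge interpolation, at every lambda). If
#' `host_charge + q_solute_A + ion_start` is nonzero, the required complement
#' of static counter-ions is reported in `counter_ions_to_add` (one elementary
#' charge per ion) rather than silently inserted; an error is raised only if
#' no integer complement can neutralize state A.
#'
#' In `"constant-charge"` mode the overall charge is conserved but the box is
#' not necessarily neutral (the lattice-sum neutralizing background then
#' compensates it; the legacy setup this package's corrections address).
#'
#' @param host_charge Net host charge in e (0 for a free solute).
#' @param solute_dq Length-2 numeric, solute net charge at states A and B.
#' @param ion_start Coalchemical ion charge at state A (e).
#' @param mode `"neutral-box"` (default) or `"constant-charge"`.
#' @param n_lambda Number of lambda windows (default 11).
#' @param ion_species Optional metadata label.
#' @return A [perturbation_topology()]; in neutral-box mode
#'   `q_environment` holds the counter-ion complement and the attribute
#'   `counter_ions_to_add` lists it explicitly.
#' @examples
#' # solute 0 -> -1 inside a host of charge -1, ion starting at +1:
#' top <- build_coalchemical_perturbation(-1, c(0, -1), +1)
#' top$q_ion_B       # +2
#' top$q_overall_A   # 0
#' @export
build_coalchemical_perturbation <- function(host_charge, solute_dq, ion_start,
                                            mode = c("neutral-box",
                                                     "constant-charge"),
                                            n_lambda = 11,
                                            ion_species = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(solute_dq) == 2, length(ion_start) == 1,
            length(host_charge) == 1)
  q_sA <- solute_dq[1]
  q_sB <- solute_dq[2]
  q_iA <- ion_start
  q_iB <- q_iA - (q_sB - q_sA)  # charge-conserving compensation
  env <- 0
  counter <- numeric(0)
  if (mode == "neutral-box") {
    need <- -(host_charge + q_sA + q_iA)  # complement zeroing state A
    if (need == 0) need <- 0              # normalize signed zero
    if (abs(need - round(need)) > 1e-9)
      stop("infeasible setup: state A cannot be neutralized with integer ",
           "counter-ions; required complement is ", need, " e")
    env <- need
    if (abs(need) > 1e-9)
      counter <- rep(sign(need), abs(round(need)))
  }
  top <- perturbation_topology(q_sA, q_sB, q_iA, q_iB,
                               q_host = host_charge, q_environment = env,
                               n_lambda = n_lambda, mode = mode,
                               ion_species = ion_species)
  attr(top, "counter_ions_to_add") <- counter
  top
}

#' Net box charge along the lambda schedule
#'
#' Reports the overall box charge at each lambda window under linear charge
#' interpolation between the end states, and flags any nonzero value - the
#' failure mode of setups that conserve charge without neutralizing the box.
#'
#' @param topology A [perturbation_topology()].
#' @param n_lambda Number of equidistant lambda windows; defaults to the
#'   topology's schedule.
#' @return Data frame with columns `lambda`, `net_charge`, `neutral`.
#' @export
validate_neutrality <- function(topology, n_lambda = NULL) {
  if (is.null(n_lambda)) n_lambda <- topology$n_lambda
  lam <- seq(0, 1, length.out = n_lambda)
  qnet <- (1 - lam) * topology$q_overall_A + lam * topology$q_overall_B
  out <- data.frame(lambda = lam, net_charge = qnet,
                    neutral = abs(qnet) < 1e-9)
  if (any(!out$neutral)) {
    worst <- which.max(abs(out$net_charge))
    attr(out, "flag") <- sprintf(
      "box is NOT neutral: |q| up to %g e (at lambda = %.2f)",
      out$net_charge[worst], out$lambda[worst])
  }
  out
}

#' Coalchemical ion distance restraint
#'
#' The restraint keeping the coalchemical ion at a fixed reference distance
#' from its solute anchor (the nitrogen for a methylammonium-like solute, the
#' carboxyl carbon for an acetate-like one): harmonic, r0 = 2.25 nm, k = 1000
#' kJ mol^-1 nm^-2.
#'
#' @param solute_anchor,ion Distinct atom indices.
#' @param r0 Reference distance in nm (default 2.25).
#' @param k Force constant in kJ mol^-1 nm^-2 (default 1000).
#' @return A list of class `restraint_spec`.
#' @export
make_restraint <- function(solute_anchor, ion, r0 = 2.25, k = 1000) {
  if (solute_anchor == ion)
    stop("solute_anchor and ion must be distinct atoms")
  stopifnot(r0 > 0, k >= 0)
  structure(list(atom_i = as.integer(solute_anchor), atom_j = as.integer(ion),
                 r0 = r0, k = k),
            class = "restraint_spec")
}

#' Harmonic restraint energy
#'
#' @param restraint A [make_restraint()] spec.
#' @param r Distance in nm (vectorized).
#' @return Energy `0.5 * k * (r - r0)^2` in kJ/mol.
#' @export
restraint_energy <- function(restraint, r) {
  0.5 * restraint$k * (r - restraint$r0)^2
}

#' Read / write a perturbation topology as YAML
#'
#' Schema: `{host_charge, solute: {qA, qB}, coion: {qA, qB}, mode, n_lambda,
#' environment_charge}` with optional per-atom vectors under
#' `solute: atoms_qA/atoms_qB`.
#'
#' @param topology A [perturbation_topology()].
#' @param path File path.
#' @return For `read_perturbation_yaml`, a [perturbation_topology()].
#' @export
write_perturbation_yaml <- function(topology, path) {
  obj <- list(
    host_charge = topology$q_host,
    solute = list(qA = topology$q_solute_A, qB = topology$q_solute_B),
    coion = list(qA = topology$q_ion_A, qB = topology$q_ion_B),
    environment_charge = topology$q_environment,
    mode = topology$mode,
    n_lambda = topology$n_lambda)
  if (!is.null(topology$per_atom_A))
    obj$per_atom <- list(qA = topology$per_atom_A, qB = topology$per_atom_B)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_perturbation_yaml
#' @export
read_perturbation_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  perturbation_topology(
    q_solute_A = obj$solute$qA, q_solute_B = obj$solute$qB,
    q_ion_A = obj$coion$qA, q_ion_B = obj$coion$qB,
    q_host = obj$host_charge %||% 0,
    q_environment = obj$environment_charge %||% 0,
    per_atom_A = unlist(obj$per_atom$qA), per_atom_B = unlist(obj$per_atom$qB),
    n_lambda = obj$n_lambda %||% 11, mode = obj$mode %||% "neutral-box")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
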