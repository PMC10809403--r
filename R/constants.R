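#' Physical constants and unit system
#'
#' The package works in a fixed unit system throughout: lengths in nanometres,
#' charges in units of the elementary charge \eqn{e}, energies in kJ/mol.
#' In these units the Coulomb energy of two charges is
#' \eqn{E = f \, q_i q_j / r_{ij}} with
#' \eqn{f = 138.935458} kJ mol\eqn{^{-1}} nm e\eqn{^{-2}}.
#'
#' `eps_solvent` defaults to 66.6, the relative permittivity of the SPC-like
#' three-point water model the simulations use; 78 (an experimental-like
#' value) may be requested instead, which shifts polarization corrections by a
#' box-size-independent offset.
#'
#' @param temperature Simulation temperature in K (default 300).
#' @param eps_solvent Relative permittivity of the solvent continuum
#'   (default 66.6).
#' @return A list of class `finsize_constants` with elements `f_coulomb`,
#'   `k_boltzmann`, `temperature`, `eps_solvent`, and `units` (a named
#'   character vector echoed in all reports).
#' @examples
#' fs_constants()
#' fs_constants(eps_solvent = 78)
#' @export
fs_constants <- function(temperature = 300, eps_solvent = 66.6) {
  stopifnot(is.numeric(temperature), temperature > 0,
            is.numeric(eps_solvent), eps_solvent >= 1)
  structure(
    list(
      f_coulomb = 138.935458,
      k_boltzmann = 0.00831446,
      temperature = temperature,
      eps_solvent = eps_solvent,
      units = c(length = "nm", charge = "e", energy = "kJ/mol",
                temperature = "K")
    ),
    class = "finsize_constants"
  )
}

#' @export
print.finsize_constants <- function(x, ...) {
  cat("finsize unit system: nm, e, kJ/mol\n")
  cat(sprintf("  f_coulomb   %.6f kJ mol^-1 nm e^-2\n", x$f_coulomb))
  cat(sprintf("  k_B         %.8f kJ mol^-1 K^-1\n", x$k_boltzmann))
  cat(sprintf("  T           %g K\n", x$temperature))
  cat(sprintf("  eps_solvent %g\n", x$eps_solvent))
  invisible(x)
}

# internal shorthands
.F_COULOMB <- 138.935458
.K_B <- 0.00831446
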