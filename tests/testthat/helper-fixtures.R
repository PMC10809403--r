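# shared helpers: small systems and the in-text system-setup table

F_C <- 138.935458
K_B <- 0.00831446

dimer_system <- function(sep = 0.5, L = NULL) {
  charge_system(rbind(c(0, 0, 0), c(sep, 0, 0)), charges = c(1, -1),
                names = c("P", "M"), box_edge = L)
}

# the 22 published setup rows: source block, host charge, solute qA->qB,
# ion qA->qB, overall qA->qB
setup_table_rows <- function() {
  rows <- rbind(
    # constant-charge block (charge conserved, box not necessarily neutral)
    c("cc", 0, 0, -1, -1, 0, -1, -1),
    c("cc", 0, 0, -1, -1, 0, -1, -1),
    c("cc", 0, 0, -1, -1, 0, -1, -1),
    c("cc", -1, 0, -1, -1, 0, -2, -2),
    c("cc", 1, 0, -1, -1, 0, 0, 0),
    c("cc", 0, 0, 1, 1, 0, 1, 1),
    c("cc", 0, 0, 1, 1, 0, 1, 1),
    c("cc", 0, 0, 1, 1, 0, 1, 1),
    c("cc", -1, 0, 1, 1, 0, 0, 0),
    c("cc", 1, 0, 1, 1, 0, 2, 2),
    # neutral-box block
    c("nb", 0, 0, -1, 0, 1, 0, 0),
    c("nb", 0, 0, -1, 0, 1, 0, 0),
    c("nb", 0, 0, -1, 0, 1, 0, 0),
    c("nb", -1, 0, -1, 1, 2, 0, 0),
    c("nb", 1, 0, -1, -1, 0, 0, 0),
    c("nb", 0, 0, 1, 0, -1, 0, 0),
    c("nb", 0, 0, 1, 0, -1, 0, 0),
    c("nb", 0, 0, 1, 0, -1, 0, 0),
    c("nb", -1, 0, 1, 1, 0, 0, 0),
    c("nb", 1, 0, 1, -1, -2, 0, 0),
    # salt variants (neutral-box topologies used with added salt)
    c("nb", -1, 0, -1, 0, 1, 0, 0),
    c("nb", 1, 0, 1, 0, -1, 0, 0)
  )
  data.frame(mode = ifelse(rows[, 1] == "cc", "constant-charge",
                           "neutral-box"),
             host = as.numeric(rows[, 2]),
             q_sA = as.numeric(rows[, 3]), q_sB = as.numeric(rows[, 4]),
             q_iA = as.numeric(rows[, 5]), q_iB = as.numeric(rows[, 6]),
             q_oA = as.numeric(rows[, 7]), q_oB = as.numeric(rows[, 8]))
}

# identity-charge topology over n atoms (A == B)
identity_topology <- function(charges) {
  perturbation_topology(sum(charges), sum(charges), 0, 0,
                        per_atom_A = charges, per_atom_B = charges)
}
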