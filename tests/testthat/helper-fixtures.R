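# Shared fixture builders; everything is generated in code.

toy_residue_plan <- function() {
  data.frame(
    residue_id = 1:6,
    amino_acid = c("K", "L", "Y", "A", "V", "R"),
    ligand_role = c("catalytic", "allosteric", "none", "none", "none",
                    "allosteric"),
    target_distance = c(4.0, 5.0, NA, NA, NA, 3.5),
    exposure = c("exposed", "exposed", "exposed", "buried", "exposed",
                 "exposed"),
    stringsAsFactors = FALSE)
}

two_class_msa_spec <- function(n_sequences = 50, n_cols = 50, seed = 1) {
  msa_spec(n_sequences, list(
    list(label = "conserved", n_columns = n_cols, rate = 0.05),
    list(label = "variable", n_columns = n_cols, rate = 0.8)),
    seed = seed)
}

# Minimal structure_model built directly from an atom table (for geometric
# oracles that need exact atom placement).
bare_model <- function(atoms, ligand_roles = c()) {
  structure(list(atoms = atoms, ligand_roles = ligand_roles),
            class = "structure_model")
}

atom_row <- function(type, chain, resno, resid, elety, element, x, y, z) {
  data.frame(type = type, chain = chain, resno = resno, resid = resid,
             elety = elety, element = element, x = x, y = y, z = z,
             o = 1, alt = "", stringsAsFactors = FALSE)
}

noise_free_data <- function(ki = 20, km = 50, h = 2, vmax = 1) {
  des <- kinetic_design(
    exp(seq(log(0.2 * km), log(5 * km), length.out = 8)),
    c(0, exp(seq(log(0.2 * ki), log(5 * ki), length.out = 7))),
    list(V_max = vmax, K_m = km, H = h, K_i = ki),
    noise_cv = 0, n_replicates = 1, seed = 1)
  gen_kinetic_data(des, model = "eq2")
}

# Independent two-sided Mann-Whitney oracle: full enumeration of label
# assignments, U counted directly, doubled smaller tail capped at 1.
mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  combos <- utils::combn(n, length(x))
  us <- apply(combos, 2, function(ix)
    sum(outer(pooled[ix], pooled[-ix], ">")) +
      0.5 * sum(outer(pooled[ix], pooled[-ix], "==")))
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Independent two-sided Fisher oracle: hypergeometric enumeration with the
# point-probability convention.
fisher_exact_oracle <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  support <- max(0, k - nn):min(k, m)
  probs <- dhyper(support, m, nn, k)
  sum(probs[probs <= dhyper(a, m, nn, k) * (1 + 1e-7)])
}
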