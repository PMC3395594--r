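# Synthetic-data generators: alignments with rate classes, toy structures
# with ligands at controlled distances, and velocity tables from the kinetic
# models. Every generator takes an explicit integer seed and leaves the
# global RNG state untouched.

#' Specify a synthetic multiple sequence alignment
#'
#' Columns are partitioned into rate classes mirroring the
#' conserved-versus-variable contrast between catalytic and allosteric
#' sites: a class with substitution rate 0 yields invariant columns, a high
#' rate yields variable ones.
#'
#' @param n_sequences Number of rows, including the query.
#' @param column_classes List of classes, each a list with elements
#'   `label`, `n_columns`, `rate` (per-row probability in `[0,1]` of drawing
#'   from the class equilibrium instead of copying the query), and optional
#'   `freqs` (length-20 equilibrium frequencies over [AA_ALPHABET1];
#'   default uniform).
#' @param seed Integer seed.
#' @return Object of class `msa_spec`.
#' @export
msa_spec <- function(n_sequences, column_classes, seed = 1L) {
  n_sequences <- as.integer(n_sequences)
  if (is.na(n_sequences) || n_sequences < 1L)
    stop("invalid spec: n_sequences must be >= 1")
  if (length(column_classes) == 0L)
    stop("invalid spec: at least one column class required")
  column_classes <- lapply(column_classes, function(cl) {
    stopifnot(!is.null(cl$label), !is.null(cl$n_columns), !is.null(cl$rate))
    cl$n_columns <- as.integer(cl$n_columns)
    if (cl$n_columns < 1L) stop("invalid spec: n_columns must be >= 1")
    if (cl$rate < 0 || cl$rate > 1)
      stop("invalid spec: substitution rate must lie in [0,1]")
    if (is.null(cl$freqs)) cl$freqs <- rep(1 / 20, 20)
    if (length(cl$freqs) != 20L || any(cl$freqs < 0))
      stop("invalid spec: freqs must be 20 non-negative values")
    s <- sum(cl$freqs)
    if (abs(s - 1) > 1e-6) stop("invalid spec: freqs must sum to 1")
    cl$freqs <- stats::setNames(cl$freqs / s, AA_ALPHABET1)
    cl
  })
  structure(list(n_sequences = n_sequences,
                 column_classes = column_classes,
                 seed = as.integer(seed)),
            class = "msa_spec")
}

#' Generate a synthetic alignment from a spec
#'
#' Per column, each non-query row draws from the class equilibrium
#' frequencies with probability `rate`, otherwise it copies the query
#' residue; rate 0 therefore forces the column identical to the query.
#' Reproducible for a fixed spec and seed.
#'
#' @param spec An [msa_spec].
#' @return An [msa] with attribute `column_class` (label per column).
#' @export
gen_msa <- function(spec) {
  stopifnot(inherits(spec, "msa_spec"))
  labels <- unlist(lapply(spec$column_classes,
                          function(cl) rep(cl$label, cl$n_columns)))
  ncol_total <- length(labels)
  n <- spec$n_sequences
  mat <- withr::with_seed(spec$seed, {
    m <- matrix("", nrow = n, ncol = ncol_total)
    j <- 0L
    for (cl in spec$column_classes) {
      for (k in seq_len(cl$n_columns)) {
        j <- j + 1L
        q <- sample(AA_ALPHABET1, 1L, prob = cl$freqs)
        col <- rep(q, n)
        if (n > 1L && cl$rate > 0) {
          hit <- stats::runif(n - 1L) < cl$rate
          if (any(hit))
            col[-1L][hit] <- sample(AA_ALPHABET1, sum(hit),
                                    replace = TRUE, prob = cl$freqs)
        }
        m[, j] <- col
      }
    }
    m
  })
  ids <- c("query", sprintf("hom_%03d", seq_len(n - 1L)))[seq_len(n)]
  out <- msa(mat, ids = ids, query_index = 1L)
  attr(out, "column_class") <- labels
  out
}

#' Specify a toy ligand-bound structure
#'
#' Residues are laid out on a straight backbone with wide spacing; each
#' residue with a ligand role gets a dedicated ligand heavy atom placed at a
#' controlled distance from its side-chain atom, and residues planned as
#' buried are enclosed in an occluding cage of non-protein atoms. Only
#' inter-atomic distances and solvent accessibility matter downstream.
#'
#' @param residues Data frame with columns `residue_id` (unique integers),
#'   `amino_acid` (one-letter), `ligand_role`
#'   (`"catalytic"|"allosteric"|"none"`), `target_distance` (Angstrom, `NA`
#'   when role is none), and `exposure` (`"exposed"|"buried"`).
#' @param seed Integer seed (kept for interface symmetry; generation is
#'   deterministic).
#' @return Object of class `toy_structure_spec`.
#' @export
toy_structure_spec <- function(residues, seed = 1L) {
  req <- c("residue_id", "amino_acid", "ligand_role", "target_distance",
           "exposure")
  if (!all(req %in% names(residues)))
    stop("residues must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(residues$residue_id))
    stop("invalid spec: residue_ids must be unique")
  if (!all(residues$ligand_role %in% c("catalytic", "allosteric", "none")))
    stop("invalid spec: unknown ligand_role")
  has_role <- residues$ligand_role != "none"
  d <- residues$target_distance[has_role]
  if (anyNA(d) || any(d < 1.0))
    stop("invalid spec: target distances must be >= 1.0 Angstrom")
  structure(list(residues = residues, seed = as.integer(seed)),
            class = "toy_structure_spec")
}

# Deterministic sphere points (golden-spiral), also used by the SASA engine.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = cos(theta) * sin(phi),
        y = sin(theta) * sin(phi),
        z = cos(phi))
}

#' Generate a toy structure from a spec
#'
#' @param spec A [toy_structure_spec].
#' @param path Optional file: when given, the model is also written in PDB
#'   format (ligands as HETATM with residue names `SUB` / `EFF`).
#' @return A `structure_model` (see [read_structure]) whose ligand role map
#'   is `c(SUB = "catalytic_substrate", EFF = "allosteric_effector")`.
#' @export
gen_toy_structure <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "toy_structure_spec"))
  res <- spec$residues
  spacing <- 20
  rows <- list()
  add <- function(chain, resno, resid, elety, element, xyz, type) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, chain = chain, resno = resno, resid = resid,
      elety = elety, element = element,
      x = xyz[1], y = xyz[2], z = xyz[3],
      o = 1, alt = "", stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(res))) {
    x0 <- (i - 1) * spacing
    aa3 <- aa_three_letter(res$amino_acid[i])
    rn <- res$residue_id[i]
    add("A", rn, aa3, "N",  "N", c(x0 - 1.2, 0.8, 0), "ATOM")
    add("A", rn, aa3, "CA", "C", c(x0, 0, 0), "ATOM")
    add("A", rn, aa3, "C",  "C", c(x0 + 1.2, 0.8, 0), "ATOM")
    add("A", rn, aa3, "O",  "O", c(x0 + 1.8, 1.9, 0), "ATOM")
    side <- c(x0, -1.5, 0)
    if (res$amino_acid[i] != "G") add("A", rn, aa3, "CB", "C", side, "ATOM")
    anchor <- if (res$amino_acid[i] != "G") side else c(x0, 0, 0)
    role <- res$ligand_role[i]
    if (role != "none") {
      d <- res$target_distance[i]
      # ligand modelled as a phosphorus-like heavy atom; clash check against
      # the sum of van der Waals radii of the contact pair
      rsum <- .VDW_RADII[["P"]] +
        .VDW_RADII[[if (res$amino_acid[i] != "G") "C" else "C"]]
      if (d < rsum)
        stop(sprintf(
          "infeasible geometry for residue %d: distance %.2f < vdW sum %.2f",
          rn, d, rsum))
      lig <- c(anchor[1], anchor[2] - d, anchor[3])
      nm <- if (role == "catalytic") "SUB" else "EFF"
      add("L", if (role == "catalytic") 900 + i else 950 + i, nm,
          "P1", "P", lig, "HETATM")
    }
    if (res$exposure[i] == "buried") {
      cage <- sphere_points(50) * 4.6
      for (k in seq_len(nrow(cage)))
        add("X", 800 + i, "CAG", sprintf("C%d", k), "C",
            c(x0, -0.7, 0) + cage[k, ], "HETATM")
    }
  }
  atoms <- do.call(rbind, rows)
  model <- structure(list(
    atoms = atoms,
    ligand_roles = c(SUB = "catalytic_substrate", EFF = "allosteric_effector")),
    class = "structure_model")
  # verify realized geometry against the plan
  for (i in seq_len(nrow(res))) {
    if (res$ligand_role[i] == "none") next
    nm <- if (res$ligand_role[i] == "catalytic") "SUB" else "EFF"
    ra <- atoms[atoms$chain == "A" & atoms$resno == res$residue_id[i], ]
    la <- atoms[atoms$resid == nm & atoms$resno %in% c(900 + i, 950 + i), ]
    dmin <- min(sqrt(outer(ra$x, la$x, "-")^2 +
                     outer(ra$y, la$y, "-")^2 +
                     outer(ra$z, la$z, "-")^2))
    if (abs(dmin - res$target_distance[i]) > 0.1)
      stop(sprintf("generation error: residue %d realized distance %.2f",
                   res$residue_id[i], dmin))
  }
  if (!is.null(path)) write_structure_pdb(model, path)
  model
}

#' Specify a kinetic simulation design
#'
#' @param substrate_concs Substrate concentrations (uM), all `>= 0`.
#' @param inhibitor_concs Inhibitor concentrations (uM), all `>= 0`;
#'   use `0` for uninhibited designs.
#' @param true_params Named list/vector with `V_max`, `K_m` (uM), `H`, and
#'   (for the inhibition model) `K_i` (uM).
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   noise (`>= 0`).
#' @param n_replicates Replicates per concentration pair (`>= 1`).
#' @param seed Integer seed.
#' @return Object of class `kinetic_design`.
#' @export
kinetic_design <- function(substrate_concs, inhibitor_concs = 0,
                           true_params, noise_cv = 0.05,
                           n_replicates = 3L, seed = 1L) {
  if (any(substrate_concs < 0) || any(inhibitor_concs < 0))
    stop("invalid design: concentrations must be >= 0")
  if (noise_cv < 0) stop("invalid design: noise_cv must be >= 0")
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("invalid design: n_replicates must be >= 1")
  tp <- as.list(true_params)
  for (p in c("V_max", "K_m", "H"))
    if (is.null(tp[[p]])) stop("true_params must include ", p)
  structure(list(substrate_concs = substrate_concs,
                 inhibitor_concs = inhibitor_concs,
                 true_params = tp, noise_cv = noise_cv,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "kinetic_design")
}

#' Simulate a velocity dataset from the Hill or noncompetitive model
#'
#' Velocities are the closed-form model value times `(1 + eps)` with
#' `eps ~ Normal(0, noise_cv)`, truncated below at zero. `model = "eq1"` is
#' the Hill equation; `model = "eq2"` adds the noncompetitive inhibition
#' term (and requires `K_i` in the design plus, for downstream
#' identifiability, at least two distinct inhibitor levels).
#'
#' @param design A [kinetic_design].
#' @param model `"eq1"` or `"eq2"`.
#' @return Data frame with columns `substrate_uM`, `inhibitor_uM`,
#'   `replicate`, `velocity`.
#' @export
gen_kinetic_data <- function(design, model = c("eq2", "eq1")) {
  stopifnot(inherits(design, "kinetic_design"))
  model <- match.arg(model)
  tp <- design$true_params
  if (model == "eq2") {
    if (is.null(tp$K_i)) stop("eq2 requires K_i in true_params")
    if (length(unique(design$inhibitor_concs)) < 2L)
      stop("eq2 requires at least two distinct inhibitor concentrations")
  }
  grid <- expand.grid(substrate_uM = design$substrate_concs,
                      inhibitor_uM = if (model == "eq1") 0
                                     else design$inhibitor_concs,
                      replicate = seq_len(design$n_replicates),
                      KEEP.OUT.ATTRS = FALSE)
  mu <- if (model == "eq1")
    hill_velocity(grid$substrate_uM, tp$V_max, tp$K_m, tp$H)
  else
    inhibition_velocity(grid$substrate_uM, grid$inhibitor_uM,
                        tp$V_max, tp$K_m, tp$H, tp$K_i)
  v <- withr::with_seed(design$seed, {
    eps <- if (design$noise_cv > 0)
      stats::rnorm(nrow(grid), 0, design$noise_cv) else 0
    pmax(mu * (1 + eps), 0)
  })
  data.frame(grid[c("substrate_uM", "inhibitor_uM", "replicate")],
             velocity = v)
}
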