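# Structure parsing, ligand-proximity site classification, Shrake-Rupley
# solvent accessibility, and residue-ligand contact areas.

.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

.element_from_atom <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    if (all(nzchar(e))) return(e)
  }
  e <- gsub("[0-9']", "", toupper(trimws(elety)))
  two <- c("SE", "CL", "BR", "MG", "ZN", "MN", "FE", "NA", "CA")
  out <- substr(e, 1, 1)
  # two-letter element symbols only when the whole name matches (avoids
  # reading calcium out of a CA alpha-carbon)
  out[e %in% setdiff(two, "CA")] <- e[e %in% setdiff(two, "CA")]
  out
}

#' Read a ligand-bound structure in PDB format
#'
#' Parses a PDB file (via bio3d), strips waters and hydrogens, keeps the
#' highest-occupancy alternate location per atom, and attaches a
#' ligand-role map assigning HETATM residue names to
#' `"catalytic_substrate"` or `"allosteric_effector"`.
#'
#' @param path PDB file.
#' @param ligand_roles Named character vector mapping ligand residue names
#'   to roles, e.g. `c(FBP = "catalytic_substrate",
#'   AMP = "allosteric_effector", G6P = "allosteric_effector")`.
#' @return Object of class `structure_model`: list with `atoms` (data frame
#'   `type`, `chain`, `resno`, `resid`, `elety`, `element`, `x`, `y`, `z`,
#'   `o`, `alt`) and `ligand_roles`.
#' @export
read_structure <- function(path, ligand_roles = c()) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("format error reading '", path, "': ",
                         conditionMessage(e)))
  a <- pdb$atom
  a$element <- .element_from_atom(a$elety, a$elesy)
  a <- a[!(a$resid %in% .WATER_NAMES), ]
  a <- a[!(a$element %in% c("H", "D")), ]
  # highest-occupancy altloc per atom site
  if (any(!is.na(a$alt) & nzchar(a$alt) & a$alt != " ")) {
    a$o[is.na(a$o)] <- 1
    key <- paste(a$chain, a$resno, a$insert, a$elety)
    a <- a[order(key, -a$o), ]
    a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety)), ]
    a <- a[order(as.integer(rownames(a))), ]
  }
  atoms <- data.frame(type = a$type, chain = a$chain, resno = a$resno,
                      resid = a$resid, elety = a$elety, element = a$element,
                      x = a$x, y = a$y, z = a$z,
                      o = ifelse(is.na(a$o), 1, a$o),
                      alt = ifelse(is.na(a$alt), "", a$alt),
                      stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("format error: non-finite coordinates in ", path)
  missing <- setdiff(names(ligand_roles), atoms$resid)
  if (length(missing) > 0L)
    stop("missing ligand: residue name(s) ",
         paste(missing, collapse = ", "), " not present in ", path)
  structure(list(atoms = atoms, ligand_roles = ligand_roles),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  prot <- x$atoms[x$atoms$type == "ATOM", ]
  cat(sprintf(
    "structure_model: %d atoms, %d protein residues, ligand roles: %s\n",
    nrow(x$atoms),
    nrow(unique(prot[c("chain", "resno")])),
    if (length(x$ligand_roles)) paste(names(x$ligand_roles),
                                      x$ligand_roles, sep = "=",
                                      collapse = ", ") else "none"))
  invisible(x)
}

#' Write a structure model in PDB format
#'
#' @param model A `structure_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  a <- model$atoms
  xyz <- as.vector(t(as.matrix(a[c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = a$type,
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, o = a$o, b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' Protein chain sequence of a structure model
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier (default: first protein chain).
#' @return One-letter sequence string, in residue-number order.
#' @export
structure_chain_sequence <- function(model, chain = NULL) {
  prot <- model$atoms[model$atoms$type == "ATOM", ]
  if (is.null(chain)) chain <- prot$chain[1]
  prot <- prot[prot$chain == chain, ]
  res <- unique(prot[c("resno", "resid")])
  res <- res[order(res$resno), ]
  paste(aa_one_letter(res$resid), collapse = "")
}

.ligand_atoms <- function(model, role) {
  nm <- names(model$ligand_roles)[model$ligand_roles == role]
  if (length(nm) == 0L)
    stop("missing ligand: no ligand with role '", role, "' in model")
  la <- model$atoms[model$atoms$resid %in% nm, ]
  if (nrow(la) == 0L)
    stop("missing ligand: no atoms for ligand role '", role, "'")
  la
}

#' Residues proximal to a ligand role
#'
#' Returns protein residues whose minimum heavy-atom distance to any heavy
#' atom of a ligand with the given role is at most `cutoff` (inclusive);
#' the binding-site definition used throughout: residues within 6 Angstrom
#' of the bound ligand.
#'
#' @param model A `structure_model`.
#' @param role `"catalytic_substrate"` or `"allosteric_effector"`.
#' @param cutoff Distance cutoff in Angstrom (default 6.0, inclusive).
#' @param chain Optional chain restriction (single-subunit analyses).
#' @return Data frame `chain`, `resno`, `resid`, `min_dist` for residues
#'   within the cutoff.
#' @export
ligand_proximal_residues <- function(model, role, cutoff = 6.0,
                                     chain = NULL) {
  la <- .ligand_atoms(model, role)
  prot <- model$atoms[model$atoms$type == "ATOM", ]
  if (!is.null(chain)) prot <- prot[prot$chain %in% chain, ]
  if (nrow(prot) == 0L) stop("no protein atoms in selection")
  d2 <- outer(prot$x, la$x, "-")^2 + outer(prot$y, la$y, "-")^2 +
    outer(prot$z, la$z, "-")^2
  dmin_atom <- sqrt(apply(d2, 1, min))
  key <- paste(prot$chain, prot$resno)
  dmin <- tapply(dmin_atom, key, min)
  info <- unique(prot[c("chain", "resno", "resid")])
  info$min_dist <- as.numeric(dmin[paste(info$chain, info$resno)])
  out <- info[info$min_dist <= cutoff, ]
  out <- out[order(out$chain, out$resno), ]
  rownames(out) <- NULL
  out
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA with a deterministic golden-spiral point set on each
#' atom's probe-expanded sphere. Heavy atoms only; van der Waals radii from
#' a standard element table (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80
#' Angstrom, ...).
#'
#' @param model A `structure_model` (all atoms occlude).
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param n_points Points per atom sphere (default 960).
#' @param subset Optional logical/integer index of atoms for which SASA is
#'   evaluated (all atoms still occlude).
#' @return List with `atom_sasa` (numeric, per evaluated atom, Angstrom^2)
#'   and `residue_sasa` (data frame `chain`, `resno`, `resid`, `sasa`).
#' @export
compute_sasa <- function(model, probe = 1.4, n_points = 960, subset = NULL) {
  a <- model$atoms
  unknown <- setdiff(unique(a$element), names(.VDW_RADII))
  if (length(unknown) > 0L) {
    bad <- a[a$element %in% unknown, ][1, ]
    stop(sprintf("unknown element '%s' (atom %s %s%d %s)",
                 unknown[1], bad$elety, bad$chain, bad$resno, bad$resid))
  }
  xyz <- as.matrix(a[c("x", "y", "z")])
  r <- .VDW_RADII[a$element] + probe
  pts <- sphere_points(n_points)
  idx <- if (is.null(subset)) seq_len(nrow(a)) else seq_len(nrow(a))[subset]
  sasa <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r + r[i])^2 & d2 > 1e-12)
    if (length(nb) == 0L) {
      sasa[k] <- 4 * pi * r[i]^2
      next
    }
    sp <- pts * r[i]
    sp[, 1] <- sp[, 1] + xyz[i, 1]
    sp[, 2] <- sp[, 2] + xyz[i, 2]
    sp[, 3] <- sp[, 3] + xyz[i, 3]
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dd <- (sp[acc, 1] - xyz[j, 1])^2 + (sp[acc, 2] - xyz[j, 2])^2 +
        (sp[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dd > r[j]^2
    }
    sasa[k] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  sel <- a[idx, ]
  key <- paste(sel$chain, sel$resno)
  rs <- tapply(sasa, key, sum)
  info <- unique(sel[c("chain", "resno", "resid")])
  info$sasa <- as.numeric(rs[paste(info$chain, info$resno)])
  rownames(info) <- NULL
  list(atom_sasa = sasa, residue_sasa = info)
}

#' Relative solvent accessibility per residue
#'
#' Residue SASA divided by its theoretical maximum in an extended
#' Gly-X-Gly context. Values can slightly exceed 1 for unusually exposed
#' residues.
#'
#' @param residue_sasa `residue_sasa` component of [compute_sasa].
#' @return Input data frame with an added `rsasa` column (`NA` for
#'   non-standard residues).
#' @export
relative_sasa <- function(residue_sasa) {
  aa1 <- aa_one_letter(residue_sasa$resid)
  ref <- .AA_MAX_ASA[aa1]
  residue_sasa$rsasa <- residue_sasa$sasa / as.numeric(ref)
  residue_sasa
}

#' Classify residues as catalytic, allosteric, surface, or other
#'
#' Applies the structure-derived site definitions: catalytic = within
#' `cutoff` of a catalytic-substrate ligand; allosteric = within `cutoff`
#' of an allosteric effector and not catalytic (catalytic precedence on
#' dual contact, flagged); surface = neither site, with relative solvent
#' accessibility above `rsasa_cutoff`; other = remainder.
#'
#' @param model A `structure_model` whose ligand-role map names at least
#'   one ligand.
#' @param cutoff Ligand-proximity cutoff in Angstrom (default 6.0).
#' @param rsasa_cutoff Surface rSASA threshold (default 0.50).
#' @param chain Optional chain restriction (per-subunit analysis).
#' @param n_points SASA point count (default 960).
#' @return Data frame (one row per protein residue): `chain`, `resno`,
#'   `aa`, `class`, `min_dist_catalytic`, `min_dist_allosteric`, `sasa`,
#'   `rsasa`, `dual_contact`, `provenance`.
#' @export
classify_sites <- function(model, cutoff = 6.0, rsasa_cutoff = 0.50,
                           chain = NULL, n_points = 960) {
  prot <- model$atoms[model$atoms$type == "ATOM", ]
  if (!is.null(chain)) prot <- prot[prot$chain %in% chain, ]
  res <- unique(prot[c("chain", "resno", "resid")])
  res <- res[order(res$chain, res$resno), ]
  key <- paste(res$chain, res$resno)

  dist_for <- function(role) {
    has <- any(model$ligand_roles == role)
    if (!has) return(rep(NA_real_, nrow(res)))
    la <- .ligand_atoms(model, role)
    d2 <- outer(prot$x, la$x, "-")^2 + outer(prot$y, la$y, "-")^2 +
      outer(prot$z, la$z, "-")^2
    dmin_atom <- sqrt(apply(d2, 1, min))
    dmin <- tapply(dmin_atom, paste(prot$chain, prot$resno), min)
    as.numeric(dmin[key])
  }
  d_cat <- dist_for("catalytic_substrate")
  d_all <- dist_for("allosteric_effector")

  sas <- compute_sasa(model, n_points = n_points,
                      subset = model$atoms$type == "ATOM" &
                        (if (is.null(chain)) TRUE
                         else model$atoms$chain %in% chain))
  rs <- relative_sasa(sas$residue_sasa)
  m <- match(key, paste(rs$chain, rs$resno))

  is_cat <- !is.na(d_cat) & d_cat <= cutoff
  is_all <- !is.na(d_all) & d_all <= cutoff & !is_cat
  rsasa <- rs$rsasa[m]
  cls <- ifelse(is_cat, "catalytic",
                ifelse(is_all, "allosteric",
                       ifelse(!is.na(rsasa) & rsasa > rsasa_cutoff,
                              "surface", "other")))
  data.frame(chain = res$chain, resno = res$resno,
             aa = aa_one_letter(res$resid), class = cls,
             min_dist_catalytic = d_cat, min_dist_allosteric = d_all,
             sasa = rs$sasa[m], rsasa = rsasa,
             dual_contact = is_cat & !is.na(d_all) & d_all <= cutoff,
             provenance = "derived",
             stringsAsFactors = FALSE)
}

#' Residue-ligand contact area
#'
#' Solvent-accessible area of a residue that the ligand buries:
#' SASA of the residue with the ligand removed minus SASA with the ligand
#' present (non-negative up to numerical tolerance).
#'
#' @param model A `structure_model`.
#' @param chain,resno Residue identifier.
#' @param ligand Ligand residue name (e.g. `"G6P"`).
#' @param n_points SASA point count (default 960).
#' @return Contact area in Angstrom^2.
#' @export
residue_ligand_contact_area <- function(model, chain, resno, ligand,
                                        n_points = 960) {
  a <- model$atoms
  ridx <- a$chain == chain & a$resno == resno & a$type == "ATOM"
  if (!any(ridx)) stop("lookup error: residue ", chain, resno,
                       " not in model")
  lidx <- a$resid == ligand
  if (!any(lidx)) stop("lookup error: ligand '", ligand, "' not in model")
  with_lig <- compute_sasa(model, n_points = n_points, subset = ridx)
  model_no <- model
  model_no$atoms <- a[!lidx, ]
  without_lig <- compute_sasa(model_no, n_points = n_points,
                              subset = ridx[!lidx])
  sum(without_lig$atom_sasa) - sum(with_lig$atom_sasa)
}

#' Write a site-annotation table
#'
#' @param annotation Output of [classify_sites].
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
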