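## surface: solvent accessibility and side-chain orientation — the
## eligibility gate ("on the surface, R-group facing outward") for all
## structure-based site detection and design.

## van der Waals radii (Angstrom) by element, Bondi-style values.
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

#' @noRd
.atom_element <- function(elety) {
  e <- substr(sub("^[0-9]*", "", toupper(elety)), 1L, 1L)
  e
}

#' @noRd
.atom_radius <- function(elety) {
  r <- .VDW[.atom_element(elety)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Deterministic golden-spiral point set on the unit sphere
#'
#' @param n Number of points (> 0).
#' @return An `n x 3` matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n_points must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  theta <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA with a deterministic golden-spiral point set, so
#' results are exactly reproducible for fixed `n_points`. Per-residue area
#' is the sum over the residue's atoms. Unmodeled residues (no atoms)
#' contribute zero and are flagged.
#'
#' @param model An `hs_structure` with at least one modeled residue.
#' @param probe_radius Solvent probe radius in Angstroms (default 1.4, a
#'   water molecule).
#' @param n_points Sampling points per atom (default 960).
#' @return Data frame with columns `chain`, `resno`, `aa`, `sasa` (Angstrom
#'   squared) and `flag` (`"no_atoms"` for residues without coordinates).
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 1) {
    stop("n_points must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(probe_radius) || probe_radius < 0) {
    stop("probe_radius must be non-negative", call. = FALSE)
  }
  atoms <- model$atoms
  if (!nrow(atoms)) stop("model has no atoms", call. = FALSE)
  pts <- golden_spiral_points(n_points)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- .atom_radius(atoms$elety) + probe_radius
  n <- nrow(xyz)
  area <- numeric(n)
  ## Neighbour lists from the full distance matrix; fixtures and single
  ## domains stay well under a few thousand atoms.
  d <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n)) {
    ri <- rad[i]
    nb <- which(d[, i] < (ri + rad) & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * ri^2
      next
    }
    sp <- pts * ri
    sp <- sweep(sp, 2, xyz[i, ], "+")
    covered <- rep(FALSE, nrow(sp))
    for (j in nb) {
      if (all(covered)) break
      dj <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      ## boundary ties (points exactly on a neighbour's surface, as with
      ## fully coincident atoms) are awarded to the earlier atom, so a
      ## duplicated sphere contributes its area exactly once
      eps <- 1e-6
      covered <- covered |
        if (j < i) dj < rad[j]^2 + eps else dj < rad[j]^2 - eps
    }
    area[i] <- 4 * pi * ri^2 * sum(!covered) / nrow(sp)
  }
  per_res <- rowsum(area, group = paste(atoms$chain, atoms$resno))
  res <- model$residues
  key <- paste(res$chain, res$resno)
  sasa <- as.numeric(per_res[match(key, rownames(per_res)), 1])
  flag <- ifelse(is.na(sasa), "no_atoms", "")
  sasa[is.na(sasa)] <- 0
  data.frame(chain = res$chain, resno = res$resno, aa = res$aa,
             sasa = sasa, flag = flag, stringsAsFactors = FALSE)
}

#' Reference maximal solvent accessibility per residue type
#'
#' Theoretical maximum accessible surface areas (Angstrom squared) for a
#' residue X in an extended Gly-X-Gly tripeptide, from Tien et al. (2013,
#' PLoS ONE 8:e80635). Used as the denominator of relative SASA.
#'
#' @return Named numeric vector over the 20 standard one-letter codes.
#' @export
default_max_sasa <- function() {
  c(A = 129, R = 274, N = 195, D = 193, C = 167,
    Q = 225, E = 223, G = 104, H = 224, I = 197,
    L = 201, K = 236, M = 224, F = 240, P = 159,
    S = 155, T = 172, W = 285, Y = 263, V = 174)
}

#' Relative solvent accessibility
#'
#' @param abs_sasa Numeric vector of absolute per-residue SASA, or the data
#'   frame returned by [compute_sasa()].
#' @param aa One-letter codes (ignored when `abs_sasa` is a data frame).
#' @param reference Named per-residue maximal SASA table covering the 20
#'   standard amino acids; default [default_max_sasa()]. Residues coded `X`
#'   get relative SASA 0.
#' @return Numeric vector of fractions (values > 1 can occur for distorted
#'   geometries and are clamped to 1.2).
#' @export
relative_sasa <- function(abs_sasa, aa = NULL,
                          reference = default_max_sasa()) {
  if (is.data.frame(abs_sasa)) {
    aa <- abs_sasa$aa
    abs_sasa <- abs_sasa$sasa
  }
  missing_aa <- setdiff(setdiff(unique(toupper(aa)), "X"), names(reference))
  if (length(missing_aa)) {
    stop("reference table lacks: ", paste(missing_aa, collapse = ", "),
         call. = FALSE)
  }
  denom <- reference[toupper(aa)]
  rel <- ifelse(toupper(aa) == "X", 0, abs_sasa / denom)
  pmin(unname(rel), 1.2)
}

## Representative side-chain point for orientation: charged-group centroid
## for basic residues, otherwise the centroid of all non-backbone atoms.
#' @noRd
.sidechain_tip <- function(res_atoms, aa) {
  if (is_basic_aa(aa)) {
    cg <- try(charged_group_centroid(res_atoms, aa), silent = TRUE)
    if (!inherits(cg, "try-error")) return(cg$coord)
  }
  bb <- c("N", "CA", "C", "O", "OXT")
  sc <- res_atoms[!(res_atoms$elety %in% bb), , drop = FALSE]
  if (!nrow(sc)) return(NULL)
  colMeans(sc[, c("x", "y", "z")])
}

#' Is a residue's side chain facing outward?
#'
#' True when the angle between the vector from the alpha carbon to the
#' side-chain tip and the vector from the protein centroid to the alpha
#' carbon is below 90 degrees, i.e. the side chain points away from the
#' body of the protein. Glycine (no side chain) defaults to `TRUE`; a
#' residue without an alpha carbon is reported `FALSE` with a flag.
#'
#' @param model An `hs_structure`.
#' @param chain,resno Residue to test.
#' @param centroid Optional precomputed all-atom centroid.
#' @return Logical scalar with attribute `flag` (`""` or `"no_ca"`).
#' @export
outward_orientation <- function(model, chain, resno, centroid = NULL) {
  ra <- residue_atoms(model, chain, resno)
  aa <- model$residues$aa[model$residues$chain == chain &
                            model$residues$resno == resno]
  ca <- atom_xyz(ra, "CA")
  if (is.null(ca)) {
    return(structure(FALSE, flag = "no_ca"))
  }
  tip <- .sidechain_tip(ra, aa)
  if (is.null(tip)) {
    return(structure(TRUE, flag = ""))  # Gly / no side-chain atoms
  }
  if (is.null(centroid)) {
    centroid <- colMeans(model$atoms[, c("x", "y", "z")])
  }
  v_out <- tip - ca
  v_rad <- ca - centroid
  if (sqrt(sum(v_out^2)) < 1e-9 || sqrt(sum(v_rad^2)) < 1e-9) {
    return(structure(TRUE, flag = "degenerate"))
  }
  structure(sum(v_out * v_rad) > 0, flag = "")
}

#' Per-residue surface profile
#'
#' Combines absolute and relative SASA, side-chain orientation and the
#' exposure verdict that gates all structure-based detection and design:
#' a residue is exposed when its relative SASA reaches `threshold` and its
#' side chain faces outward — or when it is unmodeled, in which case it is
#' assumed disordered and surface-located.
#'
#' @inheritParams compute_sasa
#' @param threshold Relative-SASA exposure threshold (default 0.20).
#' @param reference Maximal-SASA table, see [relative_sasa()].
#' @return Data frame of class `hs_surface` with columns `chain`, `resno`,
#'   `aa`, `modeled`, `sasa`, `rel_sasa`, `outward`, `exposed`, `tip_x`,
#'   `tip_y`, `tip_z` (side-chain tip; `NA` when unmodeled or absent) and
#'   `flag`.
#' @export
surface_profile <- function(model, probe_radius = 1.4, n_points = 960,
                            threshold = 0.20,
                            reference = default_max_sasa()) {
  sa <- compute_sasa(model, probe_radius = probe_radius,
                     n_points = n_points)
  rel <- relative_sasa(sa, reference = reference)
  res <- model$residues
  centroid <- colMeans(model$atoms[, c("x", "y", "z")])
  n <- nrow(res)
  outward <- logical(n)
  tips <- matrix(NA_real_, n, 3)
  flags <- sa$flag
  for (i in seq_len(n)) {
    if (!res$modeled[i]) {
      outward[i] <- NA
      next
    }
    o <- outward_orientation(model, res$chain[i], res$resno[i],
                             centroid = centroid)
    outward[i] <- as.logical(o)
    fl <- attr(o, "flag")
    if (nzchar(fl)) flags[i] <- trimws(paste(flags[i], fl))
    tip <- .sidechain_tip(residue_atoms(model, res$chain[i], res$resno[i]),
                          res$aa[i])
    if (!is.null(tip)) tips[i, ] <- tip
  }
  exposed <- ifelse(res$modeled,
                    rel >= threshold & outward %in% TRUE,
                    TRUE)
  out <- data.frame(
    chain = res$chain, resno = res$resno, aa = res$aa,
    modeled = res$modeled, sasa = sa$sasa, rel_sasa = rel,
    outward = outward, exposed = exposed,
    tip_x = tips[, 1], tip_y = tips[, 2], tip_z = tips[, 3],
    flag = flags, stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- threshold
  attr(out, "n_points") <- n_points
  attr(out, "probe_radius") <- probe_radius
  class(out) <- c("hs_surface", "data.frame")
  out
}
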