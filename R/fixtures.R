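## fixtures: synthetic structures with planted HS-binding geometry, so the
## whole pipeline is testable without external downloads. Side chains are
## minimal (CB plus a correctly named charged-group pseudo-atom); that is
## sufficient for every operation in the package, though not a physically
## realistic protein model.

## Loose plausibility bound on how far a planted side-chain tip may sit
## from its own alpha carbon (Angstroms). Requests that need more are
## rejected as infeasible.
.MAX_TIP_REACH <- 12

#' @noRd
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## Per-residue local frames for each geometry: ca (position), r (outward
## normal), t (chain direction), s (second tangent).
#' @noRd
.fixture_frames <- function(n, geometry) {
  if (geometry == "line") {
    ca <- cbind(3.8 * (seq_len(n) - 1), 0, 0)
    r <- matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE)
    t <- matrix(rep(c(1, 0, 0), n), ncol = 3, byrow = TRUE)
    s <- matrix(rep(c(0, 1, 0), n), ncol = 3, byrow = TRUE)
  } else if (geometry == "helix") {
    i <- seq_len(n)
    ang <- i * 100 * pi / 180
    ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
    r <- cbind(cos(ang), sin(ang), 0)
    t <- rbind(diff(ca), c(0, 0, 1))
    t <- t / sqrt(rowSums(t^2))
    s <- cbind(r[, 2] * t[, 3] - r[, 3] * t[, 2],
               r[, 3] * t[, 1] - r[, 1] * t[, 3],
               r[, 1] * t[, 2] - r[, 2] * t[, 1])
    s <- s / sqrt(rowSums(s^2))
  } else {  # sphere_shell
    R <- max(3.8 * sqrt(n / (4 * pi)), 6)
    u <- golden_spiral_points(n)
    ca <- u * R
    r <- u
    t <- rbind(diff(ca), ca[1, , drop = FALSE] * 0 + c(1, 0, 0))
    ## orthogonalise the chain direction against the normal
    t <- t - r * rowSums(t * r)
    nz <- sqrt(rowSums(t^2)) < 1e-6
    t[nz, ] <- matrix(rep(c(1, 0, 0), sum(nz)), ncol = 3, byrow = TRUE)
    t <- t / sqrt(rowSums(t^2))
    s <- cbind(r[, 2] * t[, 3] - r[, 3] * t[, 2],
               r[, 3] * t[, 1] - r[, 1] * t[, 3],
               r[, 1] * t[, 2] - r[, 2] * t[, 1])
    s <- s / sqrt(rowSums(s^2))
  }
  list(ca = ca, r = r, t = t, s = s)
}

## Minimal residue atoms in a local frame. tip = explicit charged-group
## coordinate for basic residues (NULL = default radial placement).
#' @noRd
.residue_atoms_fixture <- function(aa, ca, r, t, s, tip = NULL) {
  at <- rbind(
    data.frame(elety = "N", x = ca[1] - 1.2 * t[1] - 0.4 * r[1],
               y = ca[2] - 1.2 * t[2] - 0.4 * r[2],
               z = ca[3] - 1.2 * t[3] - 0.4 * r[3]),
    data.frame(elety = "CA", x = ca[1], y = ca[2], z = ca[3]),
    data.frame(elety = "C", x = ca[1] + 1.2 * t[1] - 0.4 * r[1],
               y = ca[2] + 1.2 * t[2] - 0.4 * r[2],
               z = ca[3] + 1.2 * t[3] - 0.4 * r[3]),
    data.frame(elety = "O", x = ca[1] + 1.2 * t[1] + 1.23 * s[1],
               y = ca[2] + 1.2 * t[2] + 1.23 * s[2],
               z = ca[3] + 1.2 * t[3] + 1.23 * s[3])
  )
  if (aa != "G") {
    cb_dir <- if (!is.null(tip)) .unit(tip - ca) else r
    cb <- ca + 1.53 * cb_dir
    at <- rbind(at, data.frame(elety = "CB", x = cb[1], y = cb[2],
                               z = cb[3]))
  }
  if (is_basic_aa(aa)) {
    tp <- if (!is.null(tip)) tip else ca + 4.6 * r
    tip_names <- switch(aa, K = "NZ", R = c("NH1", "NH2", "NE"),
                        H = c("ND1", "NE2"))
    at <- rbind(at, data.frame(elety = tip_names, x = tp[1], y = tp[2],
                               z = tp[3]))
  }
  at
}

## Solve planted tip positions: anchors T1, T2 with |T1-T2| = pair_dist and
## |Ti - P| = di, in the frame (t, s) centred on the candidate's projected
## tip P. Errors when the triangle is unrealisable.
#' @noRd
.solve_anchor_tips <- function(P, t, s, d1, d2, pair_dist) {
  if (pair_dist <= 0 || d1 <= 0 || d2 <= 0) {
    stop("infeasible fixture spec: distances must be positive",
         call. = FALSE)
  }
  a <- (d2^2 - d1^2) / (2 * pair_dist)
  b2 <- d1^2 - (a - pair_dist / 2)^2
  if (b2 < 0) {
    stop("infeasible fixture spec: requested distances violate the ",
         "triangle inequality", call. = FALSE)
  }
  b <- sqrt(b2)
  list(T1 = P + (a - pair_dist / 2) * t + b * s,
       T2 = P + (a + pair_dist / 2) * t + b * s)
}

#' @noRd
.random_rotation <- function() {
  ang <- stats::runif(3, 0, 2 * pi)
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

#' Generate a synthetic structure with planted HS-binding geometry
#'
#' Lays out a minimal backbone on the chosen geometry and (optionally)
#' plants a pair of basic residues whose charged-group tips sit at a
#' controlled distance, plus a candidate residue whose *projected* mutant
#' tip (see [project_mutant_tip()]) sits at controlled distances from both
#' anchors — i.e. a cluster one point mutation away from completion.
#' Filler residues are highly hydrophobic (Leu by default) so the planted
#' candidate is the only introduction-eligible position. Planted
#' distances are realised within 0.1 Angstroms (verified by
#' recomputation); unrealisable requests raise an infeasible-spec error.
#' The same seed always produces byte-identical output.
#'
#' @param n_residues Number of residues in the main chain (default 24).
#' @param geometry `"sphere_shell"` (default), `"line"` or `"helix"`.
#' @param pair_aa Amino acids of the planted basic pair (default K, K), or
#'   `NULL` for no planting.
#' @param pair_distance Tip-tip distance of the planted pair (default 6).
#' @param candidate_aa Residue type of the completion candidate (default
#'   `"S"`; set `"L"` for a hydrophobic-candidate variant, `NULL` for
#'   none).
#' @param candidate_distances Distances from the candidate's projected tip
#'   to the two anchors (default `c(6.5, 7)`; `NA` entries are drawn
#'   uniformly from 5.8-8.2 under the seed).
#' @param candidate_buried Surround the candidate with an occluding shell
#'   of cage pseudo-residues (chain `"Z"`) so it fails the exposure gate.
#' @param masked When `TRUE`, the ground truth includes a mask range
#'   covering the candidate.
#' @param filler_aa Residue type of unplanted positions (default `"L"`).
#' @param seed Integer seed controlling jitter (candidate placement,
#'   sampled distances, rigid-body pose).
#' @return List with `model` (an `hs_structure`) and `truth` (planted
#'   ground truth: candidate, anchors, requested and realised distances,
#'   expected top mutation, mask).
#' @export
generate_fixture <- function(n_residues = 24,
                             geometry = c("sphere_shell", "line", "helix"),
                             pair_aa = c("K", "K"), pair_distance = 6,
                             candidate_aa = "S",
                             candidate_distances = c(6.5, 7),
                             candidate_buried = FALSE, masked = FALSE,
                             filler_aa = "L", seed = 1) {
  geometry <- match.arg(geometry)
  .with_seed(seed, {
    n <- as.integer(n_residues)
    if (n < 8) stop("need at least 8 residues", call. = FALSE)
    fr <- .fixture_frames(n, geometry)
    aa <- rep(filler_aa, n)
    tips <- vector("list", n)
    truth <- list(seed = seed, geometry = geometry)
    if (!is.null(pair_aa)) {
      ## candidate index jittered around the middle of the chain
      ci <- sample(seq(max(4L, n %/% 2 - 3L), min(n - 3L, n %/% 2 + 3L)), 1)
      d12 <- candidate_distances
      if (length(d12) != 2) stop("candidate_distances must have length 2",
                                 call. = FALSE)
      d12[is.na(d12)] <- stats::runif(sum(is.na(d12)), 5.8, 8.2)
      P <- fr$ca[ci, ] + 5.5 * fr$r[ci, ]
      tt <- .solve_anchor_tips(P, fr$t[ci, ], fr$s[ci, ], d12[1], d12[2],
                               pair_distance)
      ## anchors: the residues whose backbone sits nearest each planted tip
      reach1 <- .dist3(fr$ca, matrix(tt$T1, n, 3, byrow = TRUE))
      reach2 <- .dist3(fr$ca, matrix(tt$T2, n, 3, byrow = TRUE))
      reach1[ci] <- Inf; reach2[ci] <- Inf
      a1 <- which.min(reach1)
      reach2[a1] <- Inf
      a2 <- which.min(reach2)
      if (reach1[a1] > .MAX_TIP_REACH || reach2[a2] > .MAX_TIP_REACH) {
        stop("infeasible fixture spec: planted tips out of side-chain ",
             "reach for this geometry", call. = FALSE)
      }
      aa[a1] <- pair_aa[1]; aa[a2] <- pair_aa[2]
      tips[[a1]] <- tt$T1; tips[[a2]] <- tt$T2
      if (!is.null(candidate_aa)) aa[ci] <- candidate_aa
      truth$candidate <- list(chain = "A", resno = ci,
                              aa = if (is.null(candidate_aa)) NA else
                                candidate_aa)
      truth$anchors <- data.frame(
        chain = "A", resno = c(a1, a2), aa = pair_aa,
        dist_requested = d12, stringsAsFactors = FALSE)
      truth$pair_distance <- pair_distance
      truth$buried <- candidate_buried
      if (!is.null(candidate_aa)) {
        truth$expected_mutation <- format_mutation(candidate_aa, ci, "K")
      }
      if (masked) {
        truth$mask <- mask_ranges("A", ci - 1L, ci + 1L, "planted_mask")
      }
    }
    atoms <- list()
    for (i in seq_len(n)) {
      at <- .residue_atoms_fixture(aa[i], fr$ca[i, ], fr$r[i, ],
                                   fr$t[i, ], fr$s[i, ], tip = tips[[i]])
      at$chain <- "A"; at$resno <- i
      atoms[[i]] <- at
    }
    residues <- data.frame(chain = "A", resno = seq_len(n), aa = aa,
                           modeled = TRUE, stringsAsFactors = FALSE)
    if (candidate_buried && !is.null(pair_aa)) {
      ci <- truth$candidate$resno
      centre <- fr$ca[ci, ] + 0.7 * fr$r[ci, ]
      cage <- golden_spiral_points(100) * 3.4
      cage <- sweep(cage, 2, centre, "+")
      atoms[[length(atoms) + 1L]] <- data.frame(
        elety = "CA", x = cage[, 1], y = cage[, 2], z = cage[, 3],
        chain = "Z", resno = seq_len(nrow(cage)))
      residues <- rbind(residues, data.frame(
        chain = "Z", resno = seq_len(nrow(cage)), aa = "G",
        modeled = TRUE, stringsAsFactors = FALSE))
    }
    atoms <- do.call(rbind, atoms)
    ## random rigid-body pose: planted distances are invariant
    rot <- .random_rotation()
    shift <- stats::runif(3, -20, 20)
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
    xyz <- sweep(xyz, 2, shift, "+")
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
    model <- hs_structure(residues,
                          atoms[, c("chain", "resno", "elety",
                                    "x", "y", "z")],
                          provenance = list(generator = "generate_fixture",
                                            seed = seed,
                                            geometry = geometry))
    ## verify planted geometry by recomputation
    if (!is.null(pair_aa)) {
      t1 <- charged_group_centroid(model, chain = "A",
                                   resno = truth$anchors$resno[1])$coord
      t2 <- charged_group_centroid(model, chain = "A",
                                   resno = truth$anchors$resno[2])$coord
      realised <- c(pair = as.numeric(.dist3(t1, t2)))
      if (!is.null(candidate_aa)) {
        Pr <- project_mutant_tip(model, "A", truth$candidate$resno, "K")
        realised <- c(realised, d1 = as.numeric(.dist3(Pr, t1)),
                      d2 = as.numeric(.dist3(Pr, t2)))
      }
      want <- c(pair = pair_distance,
                if (!is.null(candidate_aa)) {
                  c(d1 = truth$anchors$dist_requested[1],
                    d2 = truth$anchors$dist_requested[2])
                })
      if (any(abs(realised - want) > 0.1)) {
        stop("infeasible fixture spec: planted distances not realised ",
             "within 0.1 Angstrom", call. = FALSE)
      }
      truth$realised <- realised
    }
    list(model = model, truth = truth)
  })
}

#' Write a fixture model as a PDB file
#'
#' Standards-conformant ATOM records, re-readable by [read_structure()]
#' with zero loss (to the format's 0.001 Angstrom precision).
#'
#' @param model An `hs_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture_pdb <- function(model, path) {
  atoms <- model$atoms
  if (nrow(atoms) > 9999) {
    stop("atom serial overflow: PDB format caps at 9999 atoms",
         call. = FALSE)
  }
  aa <- model$residues$aa[match(paste(atoms$chain, atoms$resno),
                                paste(model$residues$chain,
                                      model$residues$resno))]
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    resno = atoms$resno, chain = atoms$chain,
    resid = aa1to3(aa), elety = atoms$elety,
    eleno = seq_len(nrow(atoms))
  )
  invisible(path)
}

#' Benchmark fixture: a removable cluster and a removable linear motif
#'
#' A two-strand hairpin-sheet mimic of a small folded domain carrying the
#' two classic removal situations: (i) a spatial cluster formed by a
#' sequence-adjacent basic pair (K42/K43) plus a sequence-distant anchor
#' (K239) brought in range by the fold, and (ii) a linear B-XXX-B-B motif
#' on residues 239/243/244 whose final residue (R244) lies on a disordered
#' C-terminal tail absent from the coordinates and supplied only through
#' the full-length sequence. A ballast chain (`"B"`) of core pseudo-atoms
#' below the sheet gives the centroid-based orientation test an interior
#' to point away from. K239 belongs to both sites; excluding it from
#' mutation (it anchors the cluster being kept in the canonical use of
#' this fixture) forces the minimal motif-removal set to `{K243Q, R244Q}`.
#'
#' @param seed Integer seed (rigid-body pose jitter only; topology and all
#'   planted distances are fixed).
#' @return List with `model` (reconciled `hs_structure`, 246 residues of
#'   which 244-246 are unmodeled), `full_sequence`, and `truth`
#'   (cluster members, motif description, canonical exclusion, expected
#'   per-site and minimal removal sets).
#' @export
fixture_cluster_motif_removal <- function(seed = 1) {
  .with_seed(seed, {
    n_mod <- 243L
    sep <- 8  # strand separation, sets the 8.0 / 8.86 A cluster edges
    x42 <- 3.8 * 42
    x0 <- x42 + 3.8 * (239 - 131)
    aa <- rep("A", n_mod)
    aa[c(42, 43, 239, 243)] <- "K"
    atoms <- list()
    for (i in seq_len(n_mod)) {
      if (i <= 130) {
        ca <- c(3.8 * i, 0, 0); tv <- c(1, 0, 0)
      } else {
        ca <- c(x0 - 3.8 * (i - 131), sep, 0); tv <- c(-1, 0, 0)
      }
      rv <- c(0, 0, 1); sv <- c(0, 1, 0)
      tip <- if (is_basic_aa(aa[i])) ca + c(0, 0, 4) else NULL
      at <- .residue_atoms_fixture(aa[i], ca, rv, tv, sv, tip = tip)
      at$chain <- "A"; at$resno <- i
      atoms[[i]] <- at
    }
    ## ballast core below the sheet
    bx <- seq(0, x0, by = 3.8)
    atoms[[length(atoms) + 1L]] <- data.frame(
      elety = "CA", x = bx, y = sep / 2, z = -8,
      chain = "B", resno = seq_along(bx))
    residues <- rbind(
      data.frame(chain = "A", resno = seq_len(n_mod), aa = aa,
                 modeled = TRUE, stringsAsFactors = FALSE),
      data.frame(chain = "B", resno = seq_along(bx), aa = "G",
                 modeled = TRUE, stringsAsFactors = FALSE))
    atoms <- do.call(rbind, atoms)
    rot <- .random_rotation()
    shift <- stats::runif(3, -10, 10)
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
    xyz <- sweep(xyz, 2, shift, "+")
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
    model <- hs_structure(
      residues, atoms[, c("chain", "resno", "elety", "x", "y", "z")],
      provenance = list(generator = "fixture_cluster_motif_removal",
                        seed = seed))
    full <- paste0(paste(aa, collapse = ""), "RAA")  # 244 R + tail
    model <- reconcile_sequence(model, c(A = full))
    truth <- list(
      cluster_members = c(42L, 43L, 239L),
      adjacent_pair = c(42L, 43L),
      motif = list(pattern = "BXXXBB", start = 239L,
                   basic_positions = c(239L, 243L, 244L)),
      exclude = 239L,
      expected_per_site_cluster = c("K42Q", "K43Q"),
      expected_minimal_motif = c("K243Q", "R244Q"),
      expected_full_removal = c("K42Q", "K43Q", "K243Q", "R244Q"))
    list(model = model, full_sequence = c(A = full), truth = truth)
  })
}
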