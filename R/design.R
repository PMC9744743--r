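## design: propose single point mutations that introduce HS-binding
## clusters (neutral -> Lys) or remove existing motifs/clusters
## (basic -> Gln), under mask / exposure / hydrophobicity constraints.

#' Design constraints
#'
#' @param masks `hs_masks` ranges that must not be mutated (e.g. antibody
#'   variable regions), or `NULL`.
#' @param bands Distance bands, see [distance_bands()].
#' @param rel_sasa_threshold Exposure threshold (default 0.20).
#' @param min_anchors Anchors an introduction must gain (default 2, the
#'   strict reading of "a third basic residue completes a pair"; set 1 to
#'   admit single-anchor sites).
#' @param forbidden_from_aas Residues never mutated *into* a charged
#'   residue; default the highly hydrophobic set I, V, L, F, M, W
#'   (hydrophobicity is a dominant folding force, so charged<->hydrophobic
#'   swaps risk destabilisation). The reverse rule is enforced too:
#'   charged residues are never mutated to a member of this set.
#' @param removal_to_aa Replacement for removals (default `"Q"`,
#'   polar-neutral; `"N"` is the usual alternative). Must be non-basic and
#'   non-acidic.
#' @param introduce_to_aa Residue introduced (default `"K"`; `"R"` is the
#'   usual alternative). Must be basic.
#' @param max_proposals Cap on returned introduction proposals.
#' @param use_long_band Use the ~20 Angstrom band for design
#'   (default `FALSE`).
#' @param use_histidine Count His as basic (default `TRUE`; His anchors are
#'   down-weighted in ranking since His is mostly neutral at pH 7.4).
#' @return List of class `hs_constraints`.
#' @export
design_constraints <- function(masks = NULL,
                               bands = distance_bands(),
                               rel_sasa_threshold = 0.20,
                               min_anchors = 2,
                               forbidden_from_aas = c("I", "V", "L", "F",
                                                      "M", "W"),
                               removal_to_aa = "Q",
                               introduce_to_aa = "K",
                               max_proposals = Inf,
                               use_long_band = FALSE,
                               use_histidine = TRUE) {
  if (!is_basic_aa(introduce_to_aa)) {
    stop("introduce_to_aa must be basic (R, K or H)", call. = FALSE)
  }
  if (is_basic_aa(removal_to_aa) || removal_to_aa %in% .ACIDIC_AA) {
    stop("removal_to_aa must be non-basic and non-acidic", call. = FALSE)
  }
  if (toupper(removal_to_aa) %in% toupper(forbidden_from_aas)) {
    stop("removal_to_aa may not be in the hydrophobic set ",
         "(charged residues are never mutated to hydrophobics)",
         call. = FALSE)
  }
  structure(list(
    masks = masks, bands = bands,
    rel_sasa_threshold = rel_sasa_threshold,
    min_anchors = min_anchors,
    forbidden_from_aas = toupper(forbidden_from_aas),
    removal_to_aa = toupper(removal_to_aa),
    introduce_to_aa = toupper(introduce_to_aa),
    max_proposals = max_proposals,
    use_long_band = use_long_band,
    use_histidine = use_histidine
  ), class = "hs_constraints")
}

#' Project the charged-group tip of a not-yet-existing side chain
#'
#' Places a pseudo-tip along the CA->CB unit vector at 5.5 Angstroms from
#' the alpha carbon — the approximate CA-NZ extension of an extended
#' lysine side chain. For glycine a beta-carbon direction is synthesised
#' from ideal backbone geometry (N, CA, C).
#'
#' @param model An `hs_structure`.
#' @param chain,resno Residue to mutate.
#' @param to_aa Target residue type (basic; default `"K"`).
#' @return Length-3 numeric coordinate.
#' @export
project_mutant_tip <- function(model, chain, resno, to_aa = "K") {
  ra <- residue_atoms(model, chain, resno)
  ca <- atom_xyz(ra, "CA")
  if (is.null(ca)) {
    stop("cannot project tip: residue ", chain, ":", resno, " has no CA",
         call. = FALSE)
  }
  cb <- atom_xyz(ra, "CB")
  if (is.null(cb)) {
    cb <- .ideal_cb(ra, ca)
  }
  v <- cb - ca
  if (sqrt(sum(v^2)) < 1e-9) {
    stop("cannot project tip: CA and CB coincide at ", chain, ":", resno,
         call. = FALSE)
  }
  ca + 5.5 * .unit(v)
}

## Ideal beta-carbon direction from backbone N, CA, C (tetrahedral carbon).
#' @noRd
.ideal_cb <- function(res_atoms, ca) {
  n <- atom_xyz(res_atoms, "N")
  c_ <- atom_xyz(res_atoms, "C")
  if (is.null(n) || is.null(c_)) {
    stop("cannot synthesise CB: backbone N/C missing", call. = FALSE)
  }
  u <- .unit(ca - n)
  v <- .unit(ca - c_)
  bis <- .unit(u + v)
  perp <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  perp <- .unit(perp)
  ang <- 54.75 * pi / 180  # tilt out of the N-CA-C bisector plane
  ca + 1.53 * (cos(ang) * bis + sin(ang) * perp)
}

#' @noRd
.empty_proposals <- function() {
  out <- data.frame(
    chain = character(), position = integer(), from_aa = character(),
    to_aa = character(), mutation = character(), kind = character(),
    n_anchors = integer(), anchor_detail = character(),
    affected_sites = character(), score = numeric(), flags = character(),
    stringsAsFactors = FALSE
  )
  out$anchors <- I(list())
  class(out) <- c("hs_proposals", "data.frame")
  out
}

#' Propose introductions of HS-binding clusters
#'
#' For every exposed, modeled, unmasked, non-basic position outside the
#' hydrophobic set, the mutant side-chain tip is projected and exposed
#' basic anchors within a distance band are collected; positions reaching
#' `min_anchors` anchors become proposals, scored and ranked with
#' [rank_proposals()]. Proline sites are allowed but flagged
#' (`"proline_site"`): the substitution also changes backbone flexibility.
#'
#' @param model An `hs_structure`.
#' @param surface An `hs_surface` profile.
#' @param constraints An `hs_constraints` object.
#' @return An `hs_proposals` data frame (ranked; at most `max_proposals`
#'   rows) with an `audit` attribute listing skipped candidates and the
#'   constraint that excluded them.
#' @export
propose_introductions <- function(model, surface,
                                  constraints = design_constraints()) {
  b_alpha <- if (constraints$use_histidine) c("R", "K", "H") else c("R", "K")
  targets <- find_completion_targets(
    model, surface, bands = constraints$bands,
    min_anchors = constraints$min_anchors,
    use_long = constraints$use_long_band,
    to_aa = constraints$introduce_to_aa,
    b_alphabet = b_alpha
  )
  audit <- list()
  rows <- .empty_proposals()
  for (i in seq_len(nrow(targets))) {
    ch <- targets$chain[i]; pos <- targets$resno[i]; aa <- targets$aa[i]
    if (in_mask(constraints$masks, ch, pos)) {
      audit[[length(audit) + 1L]] <- data.frame(
        chain = ch, position = pos, from_aa = aa, reason = "masked",
        stringsAsFactors = FALSE)
      next
    }
    if (aa %in% constraints$forbidden_from_aas) {
      audit[[length(audit) + 1L]] <- data.frame(
        chain = ch, position = pos, from_aa = aa,
        reason = "hydrophobic", stringsAsFactors = FALSE)
      next
    }
    anchors <- targets$anchors[[i]]
    anchor_w <- sum(ifelse(anchors$aa == "H", 0.5, 1))
    pairs_created <- nrow(anchors) + .inband_anchor_pairs(
      model, anchors, constraints$bands, constraints$use_long_band)
    score <- anchor_w + 0.1 * targets$rel_sasa[i] + 0.05 * pairs_created
    flags <- character(0)
    if (aa == "P") flags <- c(flags, "proline_site")
    row <- data.frame(
      chain = ch, position = pos, from_aa = aa,
      to_aa = constraints$introduce_to_aa,
      mutation = format_mutation(aa, pos, constraints$introduce_to_aa),
      kind = "introduce", n_anchors = nrow(anchors),
      anchor_detail = targets$anchor_detail[i],
      affected_sites = "", score = score,
      flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE
    )
    row$anchors <- I(list(anchors))
    rows <- rbind(rows, row)
  }
  rows <- rank_proposals(rows)
  if (is.finite(constraints$max_proposals)) {
    rows <- utils::head(rows, constraints$max_proposals)
  }
  attr(rows, "audit") <- if (length(audit)) do.call(rbind, audit) else NULL
  class(rows) <- c("hs_proposals", "data.frame")
  rows
}

## In-band pairs among the anchors themselves (edges the completed cluster
## already contains).
#' @noRd
.inband_anchor_pairs <- function(model, anchors, bands, use_long) {
  if (nrow(anchors) < 2) return(0L)
  tips <- t(vapply(seq_len(nrow(anchors)), function(k) {
    charged_group_centroid(model, chain = anchors$chain[k],
                           resno = anchors$resno[k])$coord
  }, numeric(3)))
  d <- stats::dist(tips)
  sum(!is.na(.band_class(as.numeric(d), bands, use_long = use_long)))
}

#' Rank mutation proposals
#'
#' Orders by decreasing score; ties broken by ascending author number
#' (then chain). Stable and deterministic. The score of an introduction is
#' the anchor count (His anchors weighted 0.5) plus 0.1 times the
#' relative SASA plus 0.05 times the number of in-band pairs the mutation
#' creates.
#'
#' @param proposals An `hs_proposals` data frame.
#' @return The same data frame, reordered.
#' @export
rank_proposals <- function(proposals) {
  if (!nrow(proposals)) return(proposals)
  ord <- order(-proposals$score, proposals$position, proposals$chain)
  out <- proposals[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Normalise targeted sites from motif hits / cluster objects into a list
## of site records: list(id, type, chain, members = data.frame(resno, aa)).
#' @noRd
.collect_sites <- function(model, motifs, clusters) {
  sites <- list()
  if (!is.null(motifs) && nrow(motifs)) {
    for (i in seq_len(nrow(motifs))) {
      pos <- as.integer(strsplit(motifs$basic_positions[i], ",")[[1]])
      ch <- if ("chain" %in% names(motifs)) motifs$chain[i] else
        unique(model$residues$chain)[1]
      aa <- model$residues$aa[match(paste(ch, pos),
                                    paste(model$residues$chain,
                                          model$residues$resno))]
      sites[[length(sites) + 1L]] <- list(
        id = sprintf("motif:%s@%d", motifs$pattern_id[i], motifs$start[i]),
        type = "motif", chain = ch,
        members = data.frame(resno = pos, aa = aa,
                             stringsAsFactors = FALSE),
        pattern = motifs$pattern_id[i], start = motifs$start[i]
      )
    }
  }
  if (!is.null(clusters) && length(clusters$clusters)) {
    for (cl in clusters$clusters) {
      sites[[length(sites) + 1L]] <- list(
        id = sprintf("cluster:%s", cl$id), type = "cluster",
        chain = cl$members$chain[1],
        members = data.frame(resno = cl$members$resno,
                             aa = cl$members$aa, stringsAsFactors = FALSE)
      )
    }
  }
  sites
}

#' Propose removals of HS-binding motifs and clusters
#'
#' Removal mutates basic residues to a polar-neutral residue (Gln by
#' default, matching the usual K->Q / R->Q practice). Two modes:
#'
#' * `per_site`: every basic member of every targeted site (outside masks
#'   and not excluded) is proposed.
#' * `minimal_set`: the smallest mutation set that neutralises every
#'   targeted site. A site is neutralised when at most one of its basic
#'   members remains basic — one lone basic residue cannot form an
#'   HS-binding site, since every motif and cluster requires at least two.
#'   Exact subset search for up to 20 candidate residues; greedy beyond,
#'   with an audit flag.
#'
#' @param model An `hs_structure`.
#' @param motifs `hs_motif_hits` rows to target (or `NULL`).
#' @param clusters `hs_clusters` object to target (or `NULL`).
#' @param constraints An `hs_constraints` object.
#' @param mode `"per_site"` or `"minimal_set"`.
#' @param exclude Integer author positions (or `"K239"`-style names via
#'   `"chain:resno"`, see Details) that must not be mutated even though
#'   they belong to a site — e.g. a basic residue that also anchors a
#'   cluster being kept. Plain integers apply to all chains.
#' @return An `hs_proposals` data frame; sites that cannot be neutralised
#'   (all members masked or excluded) are reported in the `unresolvable`
#'   attribute.
#' @export
propose_removals <- function(model, motifs = NULL, clusters = NULL,
                             constraints = design_constraints(),
                             mode = c("per_site", "minimal_set"),
                             exclude = NULL) {
  mode <- match.arg(mode)
  sites <- .collect_sites(model, motifs, clusters)
  if (!length(sites)) {
    stop("no targeted sites: supply motifs and/or clusters", call. = FALSE)
  }
  excl <- as.integer(exclude %||% integer(0))
  blocked <- function(ch, pos) {
    pos %in% excl | in_mask(constraints$masks, ch, pos)
  }
  to_aa <- constraints$removal_to_aa
  unresolvable <- character(0)
  mk_row <- function(ch, pos, aa, site_ids) {
    row <- data.frame(
      chain = ch, position = pos, from_aa = aa, to_aa = to_aa,
      mutation = format_mutation(aa, pos, to_aa), kind = "remove",
      n_anchors = 0L, anchor_detail = "",
      affected_sites = paste(site_ids, collapse = ";"),
      score = 0, flags = "", stringsAsFactors = FALSE
    )
    row$anchors <- I(list(NULL))
    row
  }
  rows <- .empty_proposals()
  if (mode == "per_site") {
    seen <- character(0)
    for (s in sites) {
      memb <- s$members[is_basic_aa(s$members$aa), , drop = FALSE]
      ok <- !blocked(s$chain, memb$resno)
      if (!any(ok)) {
        unresolvable <- c(unresolvable, s$id)
        next
      }
      for (k in which(ok)) {
        key <- paste(s$chain, memb$resno[k])
        if (key %in% seen) {
          prev <- rows$chain == s$chain & rows$position == memb$resno[k]
          rows$affected_sites[prev] <-
            paste(rows$affected_sites[prev], s$id, sep = ";")
          next
        }
        seen <- c(seen, key)
        rows <- rbind(rows, mk_row(s$chain, memb$resno[k], memb$aa[k],
                                   s$id))
      }
    }
  } else {
    cand <- unique(do.call(rbind, lapply(sites, function(s) {
      m <- s$members[is_basic_aa(s$members$aa), , drop = FALSE]
      data.frame(chain = s$chain, resno = m$resno, aa = m$aa,
                 stringsAsFactors = FALSE)
    })))
    cand <- cand[!blocked(cand$chain, cand$resno), , drop = FALSE]
    cand <- cand[order(cand$chain, cand$resno), , drop = FALSE]
    neutralised <- function(s, chosen) {
      m <- s$members[is_basic_aa(s$members$aa), , drop = FALSE]
      remaining <- !(paste(s$chain, m$resno) %in% chosen)
      sum(remaining) <= 1
    }
    all_ok <- function(chosen) all(vapply(sites, neutralised,
                                          logical(1), chosen = chosen))
    keys <- paste(cand$chain, cand$resno)
    chosen <- NULL
    flags_extra <- ""
    if (all_ok(character(0))) {
      chosen <- integer(0)
    } else if (length(keys) <= 20) {
      for (sz in seq_along(keys)) {
        combos <- utils::combn(seq_along(keys), sz, simplify = FALSE)
        feas <- Filter(function(ix) all_ok(keys[ix]), combos)
        if (length(feas)) { chosen <- feas[[1]]; break }
      }
    } else {
      ## greedy: repeatedly mutate the residue appearing in most
      ## not-yet-neutralised sites
      chosen <- integer(0)
      flags_extra <- "greedy"
      repeat {
        open <- Filter(function(s) !neutralised(s, keys[chosen]), sites)
        if (!length(open)) break
        cover <- vapply(seq_along(keys), function(ix) {
          sum(vapply(open, function(s) {
            paste(s$chain, keys[ix]) ; any(paste(s$chain, s$members$resno)
                                           == keys[ix])
          }, logical(1)))
        }, numeric(1))
        cover[chosen] <- -1
        nxt <- which.max(cover)
        if (cover[nxt] <= 0) break
        chosen <- c(chosen, nxt)
      }
    }
    if (is.null(chosen) || !all_ok(keys[chosen])) {
      unresolvable <- vapply(
        Filter(function(s) !neutralised(s, keys[chosen %||% integer(0)]),
               sites),
        function(s) s$id, character(1))
    }
    for (ix in sort(chosen %||% integer(0))) {
      affected <- vapply(Filter(function(s) {
        any(paste(s$chain, s$members$resno) == keys[ix])
      }, sites), function(s) s$id, character(1))
      row <- mk_row(cand$chain[ix], cand$resno[ix], cand$aa[ix], affected)
      row$flags <- flags_extra
      rows <- rbind(rows, row)
    }
  }
  rows <- rows[order(rows$chain, rows$position), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "unresolvable") <- unresolvable
  class(rows) <- c("hs_proposals", "data.frame")
  rows
}

#' Apply mutation proposals to a structure model
#'
#' Returns a mutated copy: residue identities are updated; removals drop
#' the charged-group atoms of the original side chain (the beta carbon is
#' kept); introductions place named charged-group atoms at the projected
#' mutant tip so that distance-based re-scanning sees the new side chain.
#' A proposal whose `from_aa` no longer matches raises a stale-proposal
#' error. Coordinates of untouched residues are never altered.
#'
#' @param model An `hs_structure`.
#' @param proposals An `hs_proposals` data frame.
#' @return The mutated `hs_structure`.
#' @export
apply_proposals <- function(model, proposals) {
  if (!nrow(proposals)) return(model)
  res <- model$residues
  atoms <- model$atoms
  charged_atoms <- c("NZ", "NH1", "NH2", "NE", "ND1", "NE2")
  for (i in seq_len(nrow(proposals))) {
    ch <- proposals$chain[i]; pos <- proposals$position[i]
    j <- which(res$chain == ch & res$resno == pos)
    if (!length(j)) {
      stop("proposal position ", ch, ":", pos, " not in model",
           call. = FALSE)
    }
    if (res$aa[j] != proposals$from_aa[i]) {
      stop("stale proposal ", proposals$mutation[i], ": current residue is ",
           res$aa[j], call. = FALSE)
    }
    if (proposals$kind[i] == "remove") {
      res$aa[j] <- proposals$to_aa[i]
      drop <- atoms$chain == ch & atoms$resno == pos &
        atoms$elety %in% charged_atoms
      atoms <- atoms[!drop, , drop = FALSE]
    } else {
      res$aa[j] <- proposals$to_aa[i]
      if (res$modeled[j]) {
        tip <- project_mutant_tip(model, ch, pos,
                                  to_aa = proposals$to_aa[i])
        tip_names <- switch(proposals$to_aa[i],
                            K = "NZ", R = c("NH1", "NH2", "NE"),
                            H = c("ND1", "NE2"))
        add <- data.frame(chain = ch, resno = pos, elety = tip_names,
                          x = tip[1], y = tip[2], z = tip[3],
                          stringsAsFactors = FALSE)
        atoms <- rbind(atoms, add)
      }
    }
  }
  hs_structure(res, atoms, model$provenance)
}

#' Verify a design by re-scanning the mutant
#'
#' Applies the proposals to a copy of the model, recomputes the surface
#' profile and checks: introductions must now sit in a detected spatial
#' cluster with at least `min_anchors` in-band partners (an introduction
#' whose only partners are histidines is unverified when histidine is
#' disabled); removals must leave every targeted site neutralised (at most
#' one basic member remaining) with no surviving motif match at the site.
#' The net-charge delta of the proposal set is reported.
#'
#' @param model The original `hs_structure`.
#' @param proposals An `hs_proposals` data frame.
#' @param constraints An `hs_constraints` object.
#' @param motifs,clusters The targeted sites (for removal verification).
#' @param n_points,probe_radius SASA parameters for the re-profile.
#' @return List of class `hs_verification`: `report` data frame
#'   (`mutation`, `kind`, `verified`, `note`), `charge_delta`, `ok`.
#' @export
verify_design <- function(model, proposals,
                          constraints = design_constraints(),
                          motifs = NULL, clusters = NULL,
                          n_points = 960, probe_radius = 1.4) {
  mutant <- apply_proposals(model, proposals)
  notes <- character(nrow(proposals))
  verified <- logical(nrow(proposals))
  if (nrow(proposals)) {
    msurf <- surface_profile(mutant, probe_radius = probe_radius,
                             n_points = n_points,
                             threshold = constraints$rel_sasa_threshold)
    b_alpha <- if (constraints$use_histidine) c("R", "K", "H") else
      c("R", "K")
    mclust <- find_spatial_clusters(mutant, msurf,
                                    bands = constraints$bands,
                                    use_long = constraints$use_long_band,
                                    b_alphabet = b_alpha)
    sites <- .collect_sites(model, motifs, clusters)
    for (i in seq_len(nrow(proposals))) {
      if (proposals$kind[i] == "introduce") {
        hit <- FALSE
        for (cl in mclust$clusters) {
          k <- cl$members$chain == proposals$chain[i] &
            cl$members$resno == proposals$position[i]
          if (any(k)) {
            partners <- sum(cl$pairs$resno_i == proposals$position[i] |
                              cl$pairs$resno_j == proposals$position[i])
            hit <- partners >= constraints$min_anchors
            if (hit) {
              notes[i] <- sprintf("in %s (%d members)", cl$id,
                                  nrow(cl$members))
            }
          }
        }
        verified[i] <- hit
        if (!hit && !nzchar(notes[i])) {
          notes[i] <- "no cluster formed at mutant position"
        }
      } else {
        seqs <- model_sequence(mutant)
        own_sites <- Filter(function(s) {
          any(s$members$resno == proposals$position[i]) &&
            s$chain == proposals$chain[i]
        }, sites)
        okv <- vapply(own_sites, function(s) {
          m <- s$members
          mu <- mutant$residues[mutant$residues$chain == s$chain, ]
          aa_now <- mu$aa[match(m$resno, mu$resno)]
          still_basic <- sum(is_basic_aa(aa_now))
          if (still_basic > 1) return(FALSE)
          if (s$type == "motif") {
            rn <- mu$resno
            hits <- scan_linear_motifs(
              paste(mu$aa, collapse = ""),
              patterns = motif_patterns(s$pattern, s$pattern))
            if (nrow(hits)) {
              starts <- rn[hits$start]
              if (any(starts == s$start)) return(FALSE)
            }
          }
          TRUE
        }, logical(1))
        verified[i] <- all(okv)
        notes[i] <- if (verified[i]) "site neutralised" else
          "targeted site still present"
      }
    }
  }
  delta <- mutation_charge_delta(proposals$mutation)
  report <- data.frame(mutation = proposals$mutation,
                       kind = proposals$kind, verified = verified,
                       note = notes, stringsAsFactors = FALSE)
  structure(list(report = report, charge_delta = delta,
                 ok = all(verified)),
            class = "hs_verification")
}

#' @export
print.hs_verification <- function(x, ...) {
  cat("hs_verification:", if (x$ok) "all proposals verified" else
    "UNVERIFIED proposals present",
    sprintf("(net charge delta %+.2f)\n", x$charge_delta))
  print(x$report)
  invisible(x)
}
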