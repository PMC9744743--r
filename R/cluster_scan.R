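## cluster_scan: spatial HS-binding clusters — surface-exposed basic
## residues whose charged groups fall within the characteristic distance
## bands — plus "incomplete" clusters one mutation away from completion.

#' Distance bands for charged-group spacing
#'
#' HS-binding sites place basic charged groups roughly 5-10 Angstroms
#' apart, with a secondary ~20 Angstrom spacing reported for extended
#' sites. The long band is used for detection reports but disabled for
#' design by default (both literature exemplar designs use the short
#' range).
#'
#' @param short Numeric `c(lo, hi)` in Angstroms (default `c(5, 10)`).
#' @param long Numeric `c(lo, hi)` (default `c(18, 22)`).
#' @return List of class `hs_bands`.
#' @export
distance_bands <- function(short = c(5, 10), long = c(18, 22)) {
  for (b in list(short, long)) {
    if (length(b) != 2 || b[1] >= b[2]) {
      stop("each band must be c(lo, hi) with lo < hi", call. = FALSE)
    }
  }
  if (max(short[1], long[1]) < min(short[2], long[2])) {
    stop("bands may not overlap", call. = FALSE)
  }
  structure(list(short = as.numeric(short), long = as.numeric(long)),
            class = "hs_bands")
}

#' @noRd
.band_class <- function(d, bands, use_long = TRUE) {
  out <- rep(NA_character_, length(d))
  out[d >= bands$short[1] & d <= bands$short[2]] <- "short"
  if (use_long) out[d >= bands$long[1] & d <= bands$long[2]] <- "long"
  out
}

#' Charged-group centroid of a basic residue
#'
#' The point between which HS-relevant distances are measured: Lys uses
#' the terminal amine NZ; Arg the mean of the guanidinium atoms NH1, NH2,
#' NE; His the mean of the imidazole nitrogens ND1, NE2. When side-chain
#' atoms are missing the beta carbon is used as fallback (then the alpha
#' carbon), with a flag.
#'
#' @param res_atoms Atom data frame of one residue (see internal layout of
#'   [hs_structure()]), or an `hs_structure` together with `chain`/`resno`.
#' @param aa One-letter code of the residue (must be basic).
#' @param chain,resno Residue selector when `res_atoms` is an
#'   `hs_structure`.
#' @return List with `coord` (length-3 numeric) and `flag` (`""`,
#'   `"cb_fallback"` or `"ca_fallback"`).
#' @export
charged_group_centroid <- function(res_atoms, aa, chain = NULL,
                                   resno = NULL) {
  if (inherits(res_atoms, "hs_structure")) {
    model <- res_atoms
    aa <- model$residues$aa[model$residues$chain == chain &
                              model$residues$resno == resno]
    res_atoms <- residue_atoms(model, chain, resno)
  }
  if (!is_basic_aa(aa)) {
    stop("charged_group_centroid: residue is not basic (", aa, ")",
         call. = FALSE)
  }
  want <- switch(toupper(aa),
                 K = "NZ",
                 R = c("NH1", "NH2", "NE"),
                 H = c("ND1", "NE2"))
  have <- res_atoms[res_atoms$elety %in% want, , drop = FALSE]
  if (nrow(have) == length(want)) {
    return(list(coord = colMeans(have[, c("x", "y", "z"), drop = FALSE]),
                flag = ""))
  }
  cb <- atom_xyz(res_atoms, "CB")
  if (!is.null(cb)) return(list(coord = cb, flag = "cb_fallback"))
  ca <- atom_xyz(res_atoms, "CA")
  if (!is.null(ca)) return(list(coord = ca, flag = "ca_fallback"))
  stop("residue has no side-chain, CB or CA atoms", call. = FALSE)
}

## Exposed basic sites with charged-group tips, from a surface profile.
## Unmodeled basics are exposed by assumption but have no tip, so they
## never enter distance computations.
#' @noRd
.basic_sites <- function(model, surface, b_alphabet = c("R", "K", "H")) {
  s <- surface[surface$exposed & surface$aa %in% b_alphabet, , drop = FALSE]
  keep <- s$modeled
  s <- s[keep, , drop = FALSE]
  if (!nrow(s)) {
    return(data.frame(chain = character(), resno = integer(),
                      aa = character(), tip_x = numeric(),
                      tip_y = numeric(), tip_z = numeric(),
                      stringsAsFactors = FALSE))
  }
  tips <- t(vapply(seq_len(nrow(s)), function(i) {
    charged_group_centroid(model, chain = s$chain[i],
                           resno = s$resno[i])$coord
  }, numeric(3)))
  data.frame(chain = s$chain, resno = s$resno, aa = s$aa,
             tip_x = tips[, 1], tip_y = tips[, 2], tip_z = tips[, 3],
             stringsAsFactors = FALSE)
}

#' Find spatial HS-binding clusters
#'
#' Builds a graph over exposed basic residues with an edge for every pair
#' whose charged-group distance falls in a declared band; clusters are the
#' connected components with at least two members. A cluster is `complete`
#' when it has at least `min_cluster_size` members (default 3 — a pair is
#' a seed that a single introduced basic residue could complete).
#' Sequence-adjacent member pairs are annotated as `"adjacent pair"` seeds.
#'
#' @param model An `hs_structure`.
#' @param surface An `hs_surface` profile (or any data frame with columns
#'   `chain`, `resno`, `aa`, `modeled`, `exposed`; tips are recomputed from
#'   the model).
#' @param bands An `hs_bands` object; default [distance_bands()].
#' @param min_cluster_size Members needed for a complete cluster
#'   (default 3).
#' @param use_long Include the ~20 Angstrom band (default `TRUE` for
#'   detection).
#' @param b_alphabet Residues counted as basic.
#' @return Object of class `hs_clusters`: a list with `clusters` (each a
#'   list with `id`, `members` data frame, `pairs` data frame of in-band
#'   distances with `band` class, `complete`, `adjacent_pairs`), and
#'   `sites` (all participating basic sites).
#' @export
find_spatial_clusters <- function(model, surface,
                                  bands = distance_bands(),
                                  min_cluster_size = 3,
                                  use_long = TRUE,
                                  b_alphabet = c("R", "K", "H")) {
  sites <- .basic_sites(model, surface, b_alphabet = b_alphabet)
  empty <- structure(list(clusters = list(), sites = sites, bands = bands,
                          min_cluster_size = min_cluster_size),
                     class = "hs_clusters")
  n <- nrow(sites)
  if (n < 2) return(empty)
  tips <- as.matrix(sites[, c("tip_x", "tip_y", "tip_z")])
  d <- as.matrix(stats::dist(tips))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  pd <- d[pairs]
  cls <- .band_class(pd, bands, use_long = use_long)
  keep <- !is.na(cls)
  if (!any(keep)) return(empty)
  ei <- pairs[keep, 1]; ej <- pairs[keep, 2]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(ei, ej))
  comp <- igraph::components(g)
  clusters <- list()
  for (cid in seq_len(comp$no)) {
    mem <- which(comp$membership == cid)
    if (length(mem) < 2) next
    members <- sites[mem, , drop = FALSE]
    rownames(members) <- NULL
    sel <- keep & pairs[, 1] %in% mem & pairs[, 2] %in% mem
    pr <- data.frame(
      chain_i = sites$chain[pairs[sel, 1]],
      resno_i = sites$resno[pairs[sel, 1]],
      chain_j = sites$chain[pairs[sel, 2]],
      resno_j = sites$resno[pairs[sel, 2]],
      dist = d[pairs[sel, , drop = FALSE]],
      band = .band_class(d[pairs[sel, , drop = FALSE]], bands,
                         use_long = use_long),
      stringsAsFactors = FALSE
    )
    adj <- members[order(members$chain, members$resno), , drop = FALSE]
    ad <- which(diff(adj$resno) == 1 & adj$chain[-1] ==
                  adj$chain[-nrow(adj)])
    adjacent <- if (length(ad)) data.frame(
      chain = adj$chain[ad], resno_i = adj$resno[ad],
      resno_j = adj$resno[ad + 1L], stringsAsFactors = FALSE
    ) else data.frame(chain = character(), resno_i = integer(),
                      resno_j = integer(), stringsAsFactors = FALSE)
    clusters[[length(clusters) + 1L]] <- list(
      id = sprintf("C%d", length(clusters) + 1L),
      members = members,
      pairs = pr,
      complete = length(mem) >= min_cluster_size,
      adjacent_pairs = adjacent
    )
  }
  structure(list(clusters = clusters, sites = sites, bands = bands,
                 min_cluster_size = min_cluster_size),
            class = "hs_clusters")
}

#' @export
print.hs_clusters <- function(x, ...) {
  cat("hs_clusters:", length(x$clusters), "cluster(s) over",
      nrow(x$sites), "exposed basic site(s)\n")
  for (cl in x$clusters) {
    cat(sprintf("  %s [%s, %d members]: %s\n", cl$id,
                if (cl$complete) "complete" else "incomplete",
                nrow(cl$members),
                paste0(cl$members$aa, cl$members$resno, collapse = " ")))
  }
  invisible(x)
}

#' Positions where one introduced basic residue would complete a cluster
#'
#' For every exposed, modeled, non-basic residue, projects the tip of a
#' hypothetical introduced side chain (see [project_mutant_tip()]) and
#' collects the exposed basic anchors whose charged groups fall within a
#' band of that tip. Positions with at least `min_anchors` anchors are
#' candidate completion sites. Lowering `min_anchors` to 1 admits
#' single-anchor sites (a lone in-range basic residue).
#'
#' @inheritParams find_spatial_clusters
#' @param min_anchors Minimum anchors required (default 2).
#' @param use_long Include the long band (default `FALSE` for design).
#' @param to_aa Residue type of the hypothetical introduction
#'   (default `"K"`).
#' @return Data frame with one row per candidate: `chain`, `resno`, `aa`,
#'   `rel_sasa`, `n_anchors`, `anchor_detail` (semicolon-joined
#'   `"K12:6.31"` entries) and a list column `anchors` of per-candidate
#'   anchor data frames (`chain`, `resno`, `aa`, `dist`, `band`).
#' @export
find_completion_targets <- function(model, surface,
                                    bands = distance_bands(),
                                    min_anchors = 2,
                                    use_long = FALSE,
                                    to_aa = "K",
                                    b_alphabet = c("R", "K", "H")) {
  sites <- .basic_sites(model, surface, b_alphabet = b_alphabet)
  cand <- surface[surface$exposed & surface$modeled &
                    !(surface$aa %in% b_alphabet) & surface$aa != "X", ,
                  drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    tip <- try(project_mutant_tip(model, cand$chain[i], cand$resno[i],
                                  to_aa = to_aa), silent = TRUE)
    if (inherits(tip, "try-error")) next
    if (!nrow(sites)) next
    dd <- .dist3(as.matrix(sites[, c("tip_x", "tip_y", "tip_z")]),
                 matrix(tip, nrow(sites), 3, byrow = TRUE))
    bc <- .band_class(dd, bands, use_long = use_long)
    sel <- !is.na(bc)
    if (sum(sel) < min_anchors) next
    anchors <- data.frame(chain = sites$chain[sel],
                          resno = sites$resno[sel], aa = sites$aa[sel],
                          dist = dd[sel], band = bc[sel],
                          stringsAsFactors = FALSE)
    anchors <- anchors[order(anchors$dist), , drop = FALSE]
    rownames(anchors) <- NULL
    rel <- if (!is.null(cand$rel_sasa)) cand$rel_sasa[i] else 0
    rows[[length(rows) + 1L]] <- data.frame(
      chain = cand$chain[i], resno = cand$resno[i], aa = cand$aa[i],
      rel_sasa = rel,
      n_anchors = nrow(anchors),
      anchor_detail = paste0(anchors$aa, anchors$resno, ":",
                             sprintf("%.2f", anchors$dist),
                             collapse = ";"),
      stringsAsFactors = FALSE
    )
    rows[[length(rows)]]$anchors <- I(list(anchors))
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    chain = character(), resno = integer(), aa = character(),
    rel_sasa = numeric(), n_anchors = integer(),
    anchor_detail = character(), anchors = I(list()),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
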