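## structure_io: read structures and sequences, reconcile the modeled
## structure with the full-length sequence, and write mutant sequences.
##
## All user-facing coordinates are author residue numbering, as deposited in
## the input file. Internal row indices are never surfaced.

#' Construct a structure model
#'
#' The central container of the package: a light-weight representation of a
#' parsed protein structure holding one row per residue and one row per atom.
#' Residues absent from the coordinates (e.g. termini left out by a homology
#' modelling server) can still be present with `modeled = FALSE`; such
#' residues take part in sequence-level analysis and are treated as
#' surface-exposed, but are excluded from all distance computations.
#'
#' @param residues Data frame with columns `chain` (character), `resno`
#'   (integer author numbering, strictly increasing within a chain), `aa`
#'   (one-letter code, `"X"` for non-standard) and `modeled` (logical).
#' @param atoms Data frame with columns `chain`, `resno`, `elety` (PDB atom
#'   name, e.g. `"CA"`, `"NZ"`), `x`, `y`, `z` (Angstroms). Every atom must
#'   belong to a modeled residue.
#' @param provenance Optional list recording input path and format.
#' @return An object of class `hs_structure`.
#' @seealso [read_structure()], [generate_fixture()]
#' @export
hs_structure <- function(residues, atoms, provenance = list()) {
  req <- c("chain", "resno", "aa", "modeled")
  if (!all(req %in% names(residues))) {
    stop("residues must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  reqa <- c("chain", "resno", "elety", "x", "y", "z")
  if (!all(reqa %in% names(atoms))) {
    stop("atoms must have columns: ", paste(reqa, collapse = ", "),
         call. = FALSE)
  }
  residues$resno <- as.integer(residues$resno)
  residues <- residues[order(residues$chain, residues$resno), , drop = FALSE]
  rownames(residues) <- NULL
  key <- paste(residues$chain, residues$resno)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, resno) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  for (ch in unique(residues$chain)) {
    rn <- residues$resno[residues$chain == ch]
    if (any(diff(rn) <= 0)) {
      stop("residue numbering not strictly increasing in chain ", ch,
           call. = FALSE)
    }
  }
  akey <- paste(atoms$chain, atoms$resno)
  unmod <- key[!residues$modeled]
  if (any(akey %in% unmod)) {
    stop("unmodeled residues must carry no atoms", call. = FALSE)
  }
  if (!all(akey %in% key)) {
    stop("atoms reference residues absent from the residue table",
         call. = FALSE)
  }
  structure(
    list(residues = residues, atoms = atoms, provenance = provenance),
    class = "hs_structure"
  )
}

#' @export
print.hs_structure <- function(x, ...) {
  ch <- unique(x$residues$chain)
  cat("hs_structure:", nrow(x$residues), "residues (",
      sum(x$residues$modeled), "modeled ) in", length(ch), "chain(s):",
      paste(ch, collapse = " "), "\n")
  invisible(x)
}

#' Per-chain one-letter sequence of a model
#'
#' @param model An `hs_structure`.
#' @param chain Optional chain id; default all chains.
#' @return Named character vector, one sequence per chain, covering modeled
#'   and unmodeled residues in author-number order.
#' @export
model_sequence <- function(model, chain = NULL) {
  res <- model$residues
  if (!is.null(chain)) res <- res[res$chain %in% chain, , drop = FALSE]
  vapply(split(res$aa, res$chain), paste, character(1), collapse = "")
}

## Atoms of one residue, as a data.frame (possibly 0-row).
#' @noRd
residue_atoms <- function(model, chain, resno) {
  a <- model$atoms
  a[a$chain == chain & a$resno == resno, , drop = FALSE]
}

#' @noRd
atom_xyz <- function(res_atoms, elety) {
  i <- which(res_atoms$elety == elety)
  if (!length(i)) return(NULL)
  as.numeric(res_atoms[i[1], c("x", "y", "z")])
}

#' Read a protein structure
#'
#' Loads the polymer chains of a PDB or mmCIF file into an [hs_structure()].
#' Only the first model of a multi-model file is used; heteroatoms and
#' waters are excluded; alternate locations are resolved to the highest
#' occupancy, ties broken by the first alternate-location label. Files with
#' insertion codes are rejected (homology models do not carry them).
#' Non-standard residues are mapped to `X`.
#'
#' @param path Path to the structure file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return An `hs_structure` with all residues flagged `modeled = TRUE`.
#' @seealso [reconcile_sequence()] to add unmodeled residues from a
#'   full-length sequence.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) {
      stop("cannot parse ", path, " as ", format, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) {
    stop("no polymer (ATOM) residues in ", path, call. = FALSE)
  }
  ins <- at$insert
  if (!is.null(ins) && any(!is.na(ins) & ins != "" & ins != " ")) {
    stop("insertion codes are not supported: ", path, call. = FALSE)
  }
  ## Resolve altlocs: keep highest occupancy, ties by first alt label.
  alt <- at$alt
  if (!is.null(alt) && any(!is.na(alt) & alt != "" & alt != " ")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    altlab <- ifelse(is.na(alt) | alt == "" | alt == " ", "A", alt)
    grp <- paste(at$chain, at$resno, at$elety)
    ord <- order(grp, -occ, altlab)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(grp[ord]), , drop = FALSE]
  }
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  atoms <- data.frame(
    chain = chain, resno = as.integer(at$resno), elety = at$elety,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE
  )
  rkey <- !duplicated(paste(atoms$chain, atoms$resno))
  residues <- data.frame(
    chain = atoms$chain[rkey],
    resno = atoms$resno[rkey],
    aa = aa3to1(at$resid[rkey]),
    modeled = TRUE,
    stringsAsFactors = FALSE
  )
  hs_structure(residues, atoms,
               provenance = list(path = path, format = format))
}

#' Reconcile a modeled structure with its full-length sequence
#'
#' Homology models routinely omit terminal residues; those residues still
#' matter for sequence-level motif scanning and for mutation design (they
#' are assumed surface-exposed and disordered). This function extends the
#' residue table so it covers the full sequence, flagging added residues
#' `modeled = FALSE` and extrapolating author numbering consecutively from
#' the nearest modeled residue. Coordinates of modeled residues are never
#' changed.
#'
#' @param model An `hs_structure`.
#' @param fasta_sequence Named character vector of per-chain full-length
#'   sequences (an unnamed single string is taken to belong to the model's
#'   only chain).
#' @return An `hs_structure` whose residue list covers the full sequence.
#' @export
reconcile_sequence <- function(model, fasta_sequence) {
  chains <- unique(model$residues$chain)
  if (is.null(names(fasta_sequence))) {
    if (length(fasta_sequence) == 1L && length(chains) == 1L) {
      names(fasta_sequence) <- chains
    } else {
      stop("fasta_sequence must be named by chain", call. = FALSE)
    }
  }
  res_out <- list()
  for (ch in chains) {
    res <- model$residues[model$residues$chain == ch, , drop = FALSE]
    if (!(ch %in% names(fasta_sequence))) {
      res_out[[ch]] <- res
      next
    }
    full <- toupper(fasta_sequence[[ch]])
    fchars <- strsplit(full, "")[[1]]
    mchars <- res$aa
    mseq <- paste(mchars, collapse = "")
    ## Prefer a contiguous placement; otherwise greedy subsequence embedding.
    map <- integer(length(mchars))   # full-sequence position of residue i
    hit <- regexpr(mseq, full, fixed = TRUE)
    if (length(mchars) && hit > 0) {
      map <- seq.int(hit, length.out = length(mchars))
    } else {
      p <- 1L
      for (i in seq_along(mchars)) {
        while (p <= length(fchars) && fchars[p] != mchars[i]) p <- p + 1L
        if (p > length(fchars)) {
          stop("modeled sequence of chain ", ch,
               " is not a subsequence of the supplied sequence; first ",
               "conflict at modeled position ", i, " (", mchars[i], ")",
               call. = FALSE)
        }
        map[i] <- p
        p <- p + 1L
      }
    }
    ## Author numbering for every full-sequence position: anchored on the
    ## mapped modeled residues, filled consecutively outward/between.
    resno_full <- rep(NA_integer_, length(fchars))
    resno_full[map] <- res$resno
    if (length(map)) {
      for (k in seq_along(resno_full)) {
        if (is.na(resno_full[k]) && k > 1L && !is.na(resno_full[k - 1L])) {
          resno_full[k] <- resno_full[k - 1L] + 1L
        }
      }
      for (k in rev(seq_along(resno_full))) {
        if (is.na(resno_full[k]) && k < length(resno_full) &&
            !is.na(resno_full[k + 1L])) {
          resno_full[k] <- resno_full[k + 1L] - 1L
        }
      }
    } else {
      resno_full <- seq_along(fchars)
    }
    if (any(diff(resno_full) <= 0)) {
      stop("cannot extrapolate a strictly increasing author numbering for ",
           "chain ", ch, call. = FALSE)
    }
    out <- data.frame(
      chain = ch, resno = resno_full, aa = fchars,
      modeled = seq_along(fchars) %in% map, stringsAsFactors = FALSE
    )
    res_out[[ch]] <- out
  }
  residues <- do.call(rbind, res_out)
  rownames(residues) <- NULL
  m <- hs_structure(residues, model$atoms, model$provenance)
  m$full_sequence <- fasta_sequence
  m
}

#' Read a FASTA file as per-record character strings
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Apply point mutations to a sequence string
#'
#' Positions are author residue numbers translated through `resno`; by
#' default positions index the string directly.
#'
#' @param sequence One-letter sequence string.
#' @param mutations Character vector in `"K42Q"` notation.
#' @param resno Integer vector of author numbers, one per sequence position.
#' @return The mutated sequence string.
#' @export
apply_mutations <- function(sequence, mutations,
                            resno = seq_len(nchar(sequence))) {
  if (!length(mutations)) return(sequence)
  chars <- strsplit(toupper(sequence), "")[[1]]
  mt <- parse_mutation(mutations)
  for (i in seq_len(nrow(mt))) {
    j <- match(mt$position[i], resno)
    if (is.na(j)) {
      stop("mutation position ", mt$position[i], " not in sequence",
           call. = FALSE)
    }
    if (chars[j] != mt$from_aa[i]) {
      stop("stale proposal ", format_mutation(mt$from_aa[i], mt$position[i],
                                              mt$to_aa[i]),
           ": current residue is ", chars[j], call. = FALSE)
    }
    chars[j] <- mt$to_aa[i]
  }
  paste(chars, collapse = "")
}

#' Write mutant sequences as FASTA
#'
#' Applies a set of mutation proposals to the model's sequence and writes
#' one FASTA record per chain. Each header carries the applied mutations in
#' `"K42Q"` notation. A proposal whose original amino acid no longer matches
#' the sequence raises a stale-proposal error.
#'
#' @param model An `hs_structure`.
#' @param proposals A proposal data frame (see [propose_introductions()]),
#'   or a character vector of mutations in `"K42Q"` notation (single chain).
#' @param out Output file path.
#' @return Invisibly, the named vector of mutant sequences.
#' @export
write_mutant_fasta <- function(model, proposals, out) {
  seqs <- model_sequence(model)
  muts <- split_proposal_mutations(proposals, names(seqs))
  recs <- character(length(seqs))
  for (i in seq_along(seqs)) {
    ch <- names(seqs)[i]
    rn <- model$residues$resno[model$residues$chain == ch]
    seqs[[i]] <- apply_mutations(seqs[[i]], muts[[ch]], resno = rn)
    tag <- if (length(muts[[ch]])) paste(muts[[ch]], collapse = " ") else ""
    recs[i] <- trimws(paste(ch, tag))
  }
  ss <- Biostrings::AAStringSet(stats::setNames(unname(seqs), recs))
  Biostrings::writeXStringSet(ss, filepath = out)
  invisible(stats::setNames(unname(seqs), names(seqs)))
}

## Normalize proposals (data.frame or "K42Q" strings) into a per-chain list
## of mutation strings.
#' @noRd
split_proposal_mutations <- function(proposals, chains) {
  out <- stats::setNames(vector("list", length(chains)), chains)
  if (is.null(proposals) ||
      (is.data.frame(proposals) && !nrow(proposals)) ||
      (!is.data.frame(proposals) && !length(proposals))) {
    return(out)
  }
  if (is.data.frame(proposals)) {
    for (ch in chains) {
      sel <- proposals$chain == ch
      out[[ch]] <- proposals$mutation[sel]
    }
  } else {
    if (length(chains) != 1L) {
      stop("bare mutation strings need a single-chain model", call. = FALSE)
    }
    out[[chains]] <- as.character(proposals)
  }
  out
}

#' Read a mask file of protected residue ranges
#'
#' Masks name regions that must never be mutated, e.g. the variable regions
#' of an antibody whose receptor binding must be preserved. Plain TSV with
#' columns `chain`, `start`, `end`, `label` (1-based inclusive author
#' numbering; ranges may overlap).
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `hs_masks`.
#' @export
read_masks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  mask_ranges(m$chain, m$start, m$end, m$label %||% "")
}

#' @param chain,start,end,label Vectors defining the ranges.
#' @rdname read_masks
#' @export
mask_ranges <- function(chain, start, end, label = "") {
  m <- data.frame(chain = as.character(chain), start = as.integer(start),
                  end = as.integer(end), label = label,
                  stringsAsFactors = FALSE)
  if (any(m$start > m$end)) stop("mask start > end", call. = FALSE)
  class(m) <- c("hs_masks", "data.frame")
  m
}

#' Test positions against mask ranges
#'
#' @param masks An `hs_masks` data frame (or `NULL` for no masks).
#' @param chain,position Vectors of positions to test (recycled).
#' @return Logical vector: is each position inside any mask range?
#' @export
in_mask <- function(masks, chain, position) {
  n <- max(length(chain), length(position))
  chain <- rep_len(as.character(chain), n)
  position <- rep_len(as.integer(position), n)
  if (is.null(masks) || !nrow(masks)) return(rep(FALSE, n))
  vapply(seq_len(n), function(i) {
    any(masks$chain == chain[i] &
          masks$start <= position[i] & position[i] <= masks$end)
  }, logical(1))
}
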