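## Independent oracles and small construction helpers shared across tests.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa_seq <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

## Motif oracle: classify each residue as B (basic), A (acidic) or N
## (neutral) and find pattern occurrences with the regex engine
## (overlapping matches via a lookahead), independently of the scanner's
## index arithmetic.
oracle_motif_starts <- function(sequence, pattern,
                                b_alphabet = c("R", "K", "H"),
                                x_semantics = "nonbasic") {
  chars <- strsplit(toupper(sequence), "")[[1]]
  sym <- ifelse(chars %in% b_alphabet, "B",
                ifelse(chars %in% c("D", "E"), "A", "N"))
  xcls <- switch(x_semantics, nonbasic = "[AN]", neutral = "[N]",
                 any = "[BAN]")
  rex <- paste0("(?=", gsub("X", xcls, pattern, fixed = TRUE), ")")
  hits <- gregexpr(rex, paste(sym, collapse = ""), perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

## Cluster oracle: brute-force all-pairs in-band test + union-find,
## independent of the igraph route used by the implementation.
oracle_partition <- function(tips, bands, use_long = TRUE) {
  n <- nrow(tips)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  in_band <- function(d) {
    (d >= bands$short[1] & d <= bands$short[2]) ||
      (use_long && d >= bands$long[1] && d <= bands$long[2])
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    d <- sqrt(sum((tips[i, ] - tips[j, ])^2))
    if (in_band(d)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

## Canonical form of a clustering: sorted list of sorted member vectors,
## keeping only groups of >= 2.
canon_groups <- function(membership, ids = seq_along(membership)) {
  gr <- unname(split(ids, membership))
  gr <- Filter(function(g) length(g) >= 2, gr)
  gr <- lapply(gr, sort)
  unname(gr[order(vapply(gr, function(g) g[1], numeric(1)))])
}

## A sequence-only model (no coordinates): all residues unmodeled.
seq_model <- function(sequence, chain = "A", start = 1L) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  hs_structure(
    residues = data.frame(chain = chain,
                          resno = seq.int(start,
                                          length.out = length(chars)),
                          aa = chars, modeled = FALSE,
                          stringsAsFactors = FALSE),
    atoms = data.frame(chain = character(), resno = integer(),
                       elety = character(), x = numeric(), y = numeric(),
                       z = numeric(), stringsAsFactors = FALSE)
  )
}

## A cloud of Lys "sites": one residue per point, NZ at the point.
## Paired with a hand-built surface table, this drives cluster_scan
## without needing a SASA pass.
site_cloud <- function(tips, aa = "K", resno = seq_len(nrow(tips))) {
  n <- nrow(tips)
  aa <- rep_len(aa, n)
  tipnames <- list(K = "NZ", R = c("NH1", "NH2", "NE"),
                   H = c("ND1", "NE2"))
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    nm <- c("CA", tipnames[[aa[i]]])
    data.frame(chain = "A", resno = resno[i], elety = nm,
               x = tips[i, 1], y = tips[i, 2], z = tips[i, 3],
               stringsAsFactors = FALSE)
  }))
  model <- hs_structure(
    residues = data.frame(chain = "A", resno = resno, aa = aa,
                          modeled = TRUE, stringsAsFactors = FALSE),
    atoms = atoms)
  surface <- data.frame(chain = "A", resno = resno, aa = aa,
                        modeled = TRUE, exposed = TRUE, rel_sasa = 1,
                        stringsAsFactors = FALSE)
  list(model = model, surface = surface)
}

## Fixed-width PDB ATOM/HETATM line writer for hand-built edge-case files.
pdb_line <- function(record = "ATOM", serial, name, resname, chain,
                     resno, x, y, z, occ = 1, alt = " ", icode = " ") {
  sprintf("%-6s%5d %-4s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, name, alt, resname, chain, resno, icode,
          x, y, z, occ, 0)
}
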