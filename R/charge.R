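## charge: Henderson-Hasselbalch net-charge and composition accounting for
## sequences and mutation sets (the cationization bookkeeping behind
## charge-grafting designs).

#' Default side-chain and termini pKa values
#'
#' Standard (Lehninger) pKa table: Asp 3.65, Glu 4.25, Cys 8.18, Tyr
#' 10.07, His 6.00, Lys 10.54, Arg 12.48; N-terminus 9.0, C-terminus 2.3.
#'
#' @return Named numeric vector (one-letter codes plus `Nterm`, `Cterm`).
#' @export
default_pka <- function() {
  c(D = 3.65, E = 4.25, C = 8.18, Y = 10.07,
    H = 6.00, K = 10.54, R = 12.48,
    Nterm = 9.0, Cterm = 2.3)
}

## Fractional side-chain charge of a single residue type at a given pH.
#' @noRd
.sidechain_charge <- function(aa, pH, pka = default_pka()) {
  aa <- toupper(aa)
  vapply(aa, function(a) {
    if (a %in% c("R", "K", "H")) {
      1 / (1 + 10^(pH - pka[[a]]))
    } else if (a %in% c("D", "E", "C", "Y")) {
      -1 / (1 + 10^(pka[[a]] - pH))
    } else 0
  }, numeric(1), USE.NAMES = FALSE)
}

#' Net charge of a sequence
#'
#' Henderson-Hasselbalch sum over ionizable groups: Asp, Glu, Cys, Tyr
#' contribute negatively; Arg, Lys, His positively; termini optionally.
#' `X` contributes zero.
#'
#' @param sequence One-letter amino-acid string.
#' @param pH pH in `[0, 14]` (default 7).
#' @param pka pKa table, see [default_pka()].
#' @param include_termini Add the free N-/C-terminus (default `FALSE`:
#'   point mutations never change the termini, and side-chain-only charges
#'   compare directly across mutants).
#' @return Net charge in elementary charges (numeric scalar).
#' @examples
#' net_charge("KKKKK")  # ~ +5 at pH 7
#' @export
net_charge <- function(sequence, pH = 7, pka = default_pka(),
                       include_termini = FALSE) {
  if (!is.numeric(pH) || pH < 0 || pH > 14) {
    stop("pH must lie in [0, 14]", call. = FALSE)
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  q <- sum(.sidechain_charge(chars, pH, pka))
  if (include_termini) {
    q <- q + 1 / (1 + 10^(pH - pka[["Nterm"]])) -
      1 / (1 + 10^(pka[["Cterm"]] - pH))
  }
  q
}

#' Charge delta of a mutation set
#'
#' Sum over mutations of (side-chain charge of the new residue minus
#' side-chain charge of the original) at the given pH. Additive over
#' disjoint mutation sets, and equal (to numerical precision) to the
#' difference of full-sequence [net_charge()] before and after applying
#' the mutations.
#'
#' @param mutations Character vector in `"K42Q"` notation (may be empty).
#' @param pH pH (default 7).
#' @param pka pKa table.
#' @return Numeric scalar.
#' @examples
#' mutation_charge_delta(c("S75K", "P176K"))                    # ~ +2
#' mutation_charge_delta(c("K42Q", "K43Q", "K243Q", "R244Q"))   # ~ -4
#' @export
mutation_charge_delta <- function(mutations, pH = 7, pka = default_pka()) {
  if (!length(mutations)) return(0)
  mt <- parse_mutation(mutations)
  sum(.sidechain_charge(mt$to_aa, pH, pka) -
        .sidechain_charge(mt$from_aa, pH, pka))
}

#' Charge profile of a sequence
#'
#' @inheritParams net_charge
#' @param mutations Optional mutation set in `"K42Q"` notation; per-mutation
#'   deltas are reported.
#' @return List of class `hs_charge`: `pH`, `net_charge`, `basic_count`
#'   (R+K+H), `acidic_count` (D+E), and when mutations are given `delta`
#'   plus `per_mutation` deltas.
#' @export
charge_profile <- function(sequence, pH = 7, mutations = NULL,
                           pka = default_pka(), include_termini = FALSE) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  out <- list(
    pH = pH,
    net_charge = net_charge(sequence, pH, pka, include_termini),
    basic_count = sum(chars %in% .BASIC_AA),
    acidic_count = sum(chars %in% .ACIDIC_AA),
    length = length(chars)
  )
  if (!is.null(mutations) && length(mutations)) {
    per <- vapply(mutations, mutation_charge_delta, numeric(1),
                  pH = pH, pka = pka)
    out$per_mutation <- per
    out$delta <- sum(per)
  }
  structure(out, class = "hs_charge")
}

#' @export
print.hs_charge <- function(x, ...) {
  cat(sprintf("net charge %+.2f at pH %.1f (%d basic, %d acidic of %d)\n",
              x$net_charge, x$pH, x$basic_count, x$acidic_count, x$length))
  if (!is.null(x$delta)) {
    cat(sprintf("mutation set delta %+.2f\n", x$delta))
  }
  invisible(x)
}
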