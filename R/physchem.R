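#' Average residue-mass table
#'
#' Average (isotope-abundance-weighted) masses of the 20 amino-acid residues
#' in Da, plus the mass of one water molecule. A free amino acid weighs its
#' residue mass plus one water, e.g. leucine 113.1594 + 18.0153 = 131.17 Da
#' and glutamine 128.1307 + 18.0153 = 146.15 Da, so every L -> Q
#' substitution adds 14.97 Da.
#'
#' @param set Table name; only `"average"` is provided (monoisotopic masses
#'   are out of scope for whole-protein MW reporting).
#' @return Named numeric vector of residue masses with attribute `water`.
#' @export
residue_masses <- function(set = "average") {
  set <- match.arg(set)
  m <- c(
    A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
  )
  attr(m, "water") <- 18.01524
  attr(m, "set") <- set
  m
}

seq_chars <- function(sequence) strsplit(sequence, "")[[1]]

#' Molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water (Expasy Compute pI/MW
#' convention).
#'
#' @param sequence One-letter sequence.
#' @param masses Residue-mass table from [residue_masses()].
#' @return Mass in Da.
#' @export
#' @examples
#' molecular_weight("MKLLIVFAGW")
molecular_weight <- function(sequence, masses = residue_masses()) {
  chars <- seq_chars(sequence)
  bad <- which(!(chars %in% names(masses)))
  if (length(bad) > 0) {
    abort(sprintf(
      "residue '%s' at position %d has no entry in the mass table",
      chars[bad[1]], bad[1]
    ))
  }
  sum(masses[chars]) + attr(masses, "water")
}

#' Side-chain and terminal pKa tables
#'
#' `"expasy"` is the Bjellqvist set used by Expasy's Compute pI/MW, with
#' residue-specific N-terminal pKa values; `"emboss"` is the simpler EMBOSS
#' iep set. Positive groups: N-terminus, K, R, H; negative groups:
#' C-terminus, D, E, C, Y.
#'
#' @param set `"expasy"` (default) or `"emboss"`.
#' @return A list with `side` (named pKa vector), `nterm` (default value),
#'   `nterm_by_residue` (residue-specific overrides), `cterm`, and the
#'   group polarities.
#' @export
pka_table <- function(set = c("expasy", "emboss")) {
  set <- match.arg(set)
  if (set == "expasy") {
    list(
      name = "expasy",
      side = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0, H = 5.98, K = 10.0, R = 12.0),
      nterm = 7.5,
      nterm_by_residue = c(A = 7.59, E = 7.70, M = 7.00, P = 8.36,
                           S = 6.93, T = 6.82, V = 7.44),
      cterm = 3.55,
      positive = c("NTERM", "K", "R", "H"),
      negative = c("CTERM", "D", "E", "C", "Y")
    )
  } else {
    list(
      name = "emboss",
      side = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1, H = 6.5, K = 10.8, R = 12.5),
      nterm = 8.6,
      nterm_by_residue = c(),
      cterm = 3.6,
      positive = c("NTERM", "K", "R", "H"),
      negative = c("CTERM", "D", "E", "C", "Y")
    )
  }
}

ionizable_groups <- function(sequence, pka = pka_table()) {
  chars <- seq_chars(sequence)
  bad <- which(!(chars %in% AA1))
  if (length(bad) > 0) {
    abort(sprintf(
      "residue '%s' at position %d is not a standard amino acid",
      chars[bad[1]], bad[1]
    ))
  }
  nt <- chars[1]
  nt_pka <- if (nt %in% names(pka$nterm_by_residue)) {
    pka$nterm_by_residue[[nt]]
  } else {
    pka$nterm
  }
  side <- chars[chars %in% names(pka$side)]
  sign <- c(1, -1, ifelse(side %in% pka$positive, 1, -1))
  tibble(
    group = c("NTERM", "CTERM", side),
    pka = c(nt_pka, pka$cterm, unname(pka$side[side])),
    sign = sign
  )
}

#' Henderson-Hasselbalch net charge of a peptide
#'
#' Net charge in elementary units at a given pH: each positive group
#' (N-terminus, K, R, H) contributes `1 / (1 + 10^(pH - pKa))`, each
#' negative group (C-terminus, D, E, C, Y) contributes
#' `-1 / (1 + 10^(pKa - pH))`. The sum is strictly decreasing in pH, which
#' guarantees a unique isoelectric point.
#'
#' @param sequence One-letter sequence (free termini assumed).
#' @param pH pH value(s) in (0, 14); vectorized.
#' @param pka pKa table from [pka_table()].
#' @return Numeric net charge, one value per `pH`.
#' @export
net_charge <- function(sequence, pH, pka = pka_table()) {
  stopifnot(all(pH > 0), all(pH < 14))
  g <- ionizable_groups(sequence, pka)
  vapply(pH, function(p) {
    pos <- g$pka[g$sign > 0]
    neg <- g$pka[g$sign < 0]
    sum(1 / (1 + 10^(p - pos))) - sum(1 / (1 + 10^(neg - p)))
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which [net_charge()] is zero by bisection on (0, 14).
#' Because the charge curve is strictly decreasing the root is unique.
#'
#' @inheritParams net_charge
#' @param tol Bisection tolerance in pH units (default 1e-4).
#' @return The pI in pH units.
#' @export
#' @examples
#' isoelectric_point("MKLLIVFAGW")
isoelectric_point <- function(sequence, pka = pka_table(), tol = 1e-4) {
  lo <- 1e-6
  hi <- 14 - 1e-6
  f_lo <- net_charge(sequence, lo, pka)
  f_hi <- net_charge(sequence, hi, pka)
  if (f_lo < 0) return(lo)
  if (f_hi > 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector of per-residue hydropathy scores.
#' @export
kyte_doolittle <- function() {
  c(
    A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
    L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
  )
}

#' Sliding-window hydropathy profile
#'
#' Arithmetic mean of per-residue hydropathy scores over an odd sliding
#' window. With the default 19-residue window, sustained stretches above
#' ~1.6 are the classic signature of membrane-spanning segments. Note that
#' every QTY target residue (Q, T, Y) scores lower than its source
#' (L, I, V, F), so a QTY analog's profile lies at or below the native
#' profile at every position.
#'
#' @param sequence One-letter sequence.
#' @param scale Scale name; only `"kyte-doolittle"` is shipped.
#' @param window Odd window length `<= nchar(sequence)` (default 19).
#' @return A tibble of class `qty_hydropathy` with columns `position`
#'   (window center, 1-based) and `score`.
#' @export
hydropathy_profile <- function(sequence, scale = "kyte-doolittle", window = 19) {
  scale <- match.arg(scale)
  n <- nchar(sequence)
  if (window %% 2 == 0) abort("window must be odd")
  if (window > n) abort("window exceeds sequence length")
  kd <- kyte_doolittle()
  chars <- seq_chars(sequence)
  bad <- which(!(chars %in% names(kd)))
  if (length(bad) > 0) {
    abort(sprintf("residue '%s' at position %d has no hydropathy score",
                  chars[bad[1]], bad[1]))
  }
  scores <- unname(kd[chars])
  half <- (window - 1) / 2
  cs <- c(0, cumsum(scores))
  centers <- seq(half + 1, n - half)
  prof <- (cs[centers + half + 1] - cs[centers - half]) / window
  out <- tibble(position = centers, score = prof)
  class(out) <- c("qty_hydropathy", class(out))
  attr(out, "window") <- window
  attr(out, "scale") <- scale
  out
}

#' Residue composition of a sequence
#'
#' @param sequence One-letter sequence.
#' @return A tibble with columns `residue` and `count` covering all 20
#'   standard residues (zero counts included); counts sum to the length.
#' @export
residue_composition <- function(sequence) {
  validate_sequence(sequence)
  chars <- seq_chars(sequence)
  tibble(
    residue = AA1,
    count = unname(vapply(AA1, function(a) sum(chars == a), integer(1)))
  )
}

#' Physicochemical characterization of QTY designs
#'
#' The machine-readable twin of a design-summary table: for each record in a
#' [qty_apply()] result, molecular weight and isoelectric point of native
#' and analog plus the variation percentages. QTY substitutions add only
#' neutral residues (the tyrosine phenol, pKa ~10, is the one new ionizable
#' group), so pI shifts are small, and each substitution adds at most
#' a few tens of Da.
#'
#' @param qty A `qty_tbl` from [qty_apply()].
#' @param pka pKa table; default Expasy-compatible.
#' @return A tibble: `id`, `mw_native`, `mw_analog`, `pi_native`,
#'   `pi_analog`, `tm_pct`, `overall_pct`.
#' @export
qty_characterize <- function(qty, pka = pka_table()) {
  stopifnot(inherits(qty, "qty_tbl"))
  qty %>%
    as_tibble() %>%
    mutate(
      mw_native = purrr::map_dbl(.data$native, molecular_weight),
      mw_analog = purrr::map_dbl(.data$analog, molecular_weight),
      pi_native = purrr::map_dbl(.data$native, isoelectric_point, pka = pka),
      pi_analog = purrr::map_dbl(.data$analog, isoelectric_point, pka = pka)
    ) %>%
    select("id", "mw_native", "mw_analog", "pi_native", "pi_analog",
           "tm_pct", "overall_pct")
}
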