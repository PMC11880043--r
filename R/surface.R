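#' Heavy-atom van der Waals radii
#'
#' Bondi-style van der Waals radii in Angstrom for the elements found in
#' protein structures and common cofactors. Hydrogens are never modeled
#' (heavy-atom convention throughout).
#'
#' @param set Radii-set name; `"bondi"` is provided.
#' @return Named numeric vector, element symbol to radius.
#' @export
vdw_radii <- function(set = "bondi") {
  set <- match.arg(set)
  r <- c(
    C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.31, `NA` = 2.27, K = 2.75,
    MN = 2.00, CU = 1.40, NI = 1.63, CO = 2.00, SE = 1.90
  )
  attr(r, "set") <- set
  r
}

# Deterministic quasi-uniform points on the unit sphere: golden-section
# spiral (no RNG, bit-reproducible areas)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

# Canonical molecule frame: principal axes of the coordinates with a
# covariant sign convention (each axis points toward the atom with the
# largest absolute projection). Expressing the sampling spiral in this
# frame makes the computed areas invariant under rigid motion of the
# molecule, not just deterministic. Exact point-group symmetries (equal
# covariance eigenvalues) can still reorder the axes; generic molecules
# are unaffected.
canonical_frame <- function(xyz) {
  xc <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  f <- ev$vectors
  for (k in 1:2) {
    proj <- xc %*% f[, k]
    j <- which.max(abs(proj))
    if (length(j) > 0 && proj[j] < 0) f[, k] <- -f[, k]
  }
  f[, 3] <- c(
    f[2, 1] * f[3, 2] - f[3, 1] * f[2, 2],
    f[3, 1] * f[1, 2] - f[1, 1] * f[3, 2],
    f[1, 1] * f[2, 2] - f[2, 1] * f[1, 2]
  )
  f
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Computes per-atom SASA by sampling a deterministic golden-spiral point
#' set on each atom's solvent-accessible sphere (radius = vdW radius +
#' probe radius) and counting the points not buried inside any neighboring
#' atom's accessible sphere; the accessible fraction times the sphere area
#' gives the atom's SASA. Per-residue areas are per-atom sums.
#'
#' @param struct A `qty_structure` (heavy atoms).
#' @param probe Probe (water) radius in Angstrom, default 1.4.
#' @param n_points Sample points per atom, default 960; accuracy knob
#'   (isolated-sphere error < 0.5 percent at the default).
#' @param radii Radii set from [vdw_radii()].
#' @param fallback_radius Radius used (with a warning) for elements missing
#'   from the radii table; `NULL` (default) makes unknown elements an error.
#' @return An object of class `qty_sasa`: list with `atoms` (per-atom areas
#'   in A^2), `residues` (per-residue areas), `total_area`, and `params`.
#' @export
shrake_rupley <- function(struct, probe = 1.4, n_points = 960,
                          radii = vdw_radii(), fallback_radius = NULL) {
  stopifnot(inherits(struct, "qty_structure"), probe >= 0, n_points >= 12)
  if (nrow(struct) < 1) abort("empty model: no atoms to compute SASA for")
  tab <- as_tibble(struct)
  r <- radii[tab$element]
  unk <- which(is.na(r))
  if (length(unk) > 0) {
    if (is.null(fallback_radius)) {
      abort(sprintf(
        "no van der Waals radius for element '%s' (atom %s %s%d/%s)",
        tab$element[unk[1]], tab$atom[unk[1]], tab$chain[unk[1]],
        tab$resno[unk[1]], tab$resname[unk[1]]
      ))
    }
    warn(sprintf("using fallback radius %.2f A for %d atom(s)",
                 fallback_radius, length(unk)))
    r[unk] <- fallback_radius
  }
  r <- unname(r) + probe
  xyz <- coords(tab)
  n <- nrow(xyz)
  pts <- sphere_points(n_points) %*% t(canonical_frame(xyz))
  # neighbor lists from one squared-distance pass
  d2 <- crossdist2(xyz, xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    cut <- (r[i] + r)^2
    nb <- which(d2[i, ] < cut & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dx <- p[acc, 1] - xyz[j, 1]
      dy <- p[acc, 2] - xyz[j, 2]
      dz <- p[acc, 3] - xyz[j, 3]
      acc[acc] <- dx * dx + dy * dy + dz * dz > r[j]^2
    }
    area[i] <- mean(acc) * 4 * pi * r[i]^2
  }
  atoms <- tab %>%
    mutate(radius = r - probe, area = area)
  residues <- atoms %>%
    group_by(.data$chain, .data$resno, .data$icode, .data$resname,
             .data$is_polymer) %>%
    summarise(area = sum(.data$area), n_atoms = dplyr::n(), .groups = "drop")
  res <- list(
    atoms = atoms,
    residues = residues,
    total_area = sum(area),
    params = list(
      probe = probe, n_points = n_points,
      radii_set = attr(radii, "set") %||% "custom"
    )
  )
  class(res) <- "qty_sasa"
  res
}

#' Default hydrophobic residue set
#'
#' The nonpolar residues whose lipid-facing surface defines the hydrophobic
#' patches of a membrane protein: Leu, Ile, Val, Phe, Met, Trp, Ala.
#' Proline is deliberately not included by default; pass a custom set to
#' add it.
#'
#' @return Character vector of one-letter codes.
#' @export
hydrophobic_set <- function() {
  c("L", "I", "V", "F", "M", "W", "A")
}

#' Hydrophobic fraction of a solvent-accessible surface
#'
#' SASA contributed by residues in a hydrophobic set divided by total SASA.
#' QTY substitution turns surface L/I/V/F into Q/T/T/Y, so on identical
#' coordinates the analog's fraction is strictly lower whenever at least
#' one exposed residue was substituted — the quantitative counterpart of
#' "reduced hydrophobic surface patches".
#'
#' @param sasa A `qty_sasa` from [shrake_rupley()].
#' @param set One-letter hydrophobic residue codes; default
#'   [hydrophobic_set()].
#' @return Fraction in `[0, 1]`.
#' @export
hydrophobic_fraction <- function(sasa, set = hydrophobic_set()) {
  stopifnot(inherits(sasa, "qty_sasa"))
  res <- sasa$residues
  if (nrow(res) == 0 || sasa$total_area <= 0) {
    abort("model has no surface area")
  }
  aa1 <- aa_three_to_one(res$resname)
  sum(res$area[aa1 %in% set]) / sasa$total_area
}

#' Compare native and analog surfaces
#'
#' Per-residue and global SASA deltas between two models computed with
#' identical parameters (typically a native structure and its QTY analog on
#' matched coordinates), flagging residues whose hydrophobic class changed.
#'
#' @param native_sasa,analog_sasa `qty_sasa` objects from
#'   [shrake_rupley()] runs with equal parameters.
#' @param set Hydrophobic residue set.
#' @return An object of class `qty_surface_delta`: list with `residues`
#'   (per-residue areas, deltas, class flags), `total_delta`,
#'   `hydrophobic_area_native`, `hydrophobic_area_analog`,
#'   `hydrophobic_fraction_native`, `hydrophobic_fraction_analog`,
#'   `hydrophobic_fraction_delta`.
#' @export
compare_surfaces <- function(native_sasa, analog_sasa, set = hydrophobic_set()) {
  stopifnot(inherits(native_sasa, "qty_sasa"), inherits(analog_sasa, "qty_sasa"))
  if (!identical(native_sasa$params, analog_sasa$params)) {
    abort("surface runs were computed with different parameters")
  }
  rn <- native_sasa$residues %>%
    mutate(aa1 = aa_three_to_one(.data$resname),
           hydrophobic = .data$aa1 %in% set)
  ra <- analog_sasa$residues %>%
    mutate(aa1 = aa_three_to_one(.data$resname),
           hydrophobic = .data$aa1 %in% set)
  joined <- inner_join(
    rn, ra,
    by = c("chain", "resno", "icode"),
    suffix = c("_native", "_analog")
  ) %>%
    mutate(
      delta_area = .data$area_analog - .data$area_native,
      class_changed = .data$hydrophobic_native != .data$hydrophobic_analog
    )
  hf_n <- hydrophobic_fraction(native_sasa, set)
  hf_a <- hydrophobic_fraction(analog_sasa, set)
  out <- list(
    residues = joined,
    total_delta = analog_sasa$total_area - native_sasa$total_area,
    hydrophobic_area_native = hf_n * native_sasa$total_area,
    hydrophobic_area_analog = hf_a * analog_sasa$total_area,
    hydrophobic_fraction_native = hf_n,
    hydrophobic_fraction_analog = hf_a,
    hydrophobic_fraction_delta = hf_a - hf_n,
    set = set
  )
  class(out) <- "qty_surface_delta"
  out
}

#' @export
print.qty_surface_delta <- function(x, ...) {
  cat(sprintf(
    paste0("# Surface comparison: hydrophobic fraction %.3f -> %.3f ",
           "(delta %+.3f); %d residue(s) changed class\n"),
    x$hydrophobic_fraction_native, x$hydrophobic_fraction_analog,
    x$hydrophobic_fraction_delta, sum(x$residues$class_changed)
  ))
  invisible(x)
}

#' @describeIn shrake_rupley `tidy()` returns the per-residue area table.
#' @param x A `qty_sasa`.
#' @param ... Unused.
#' @export
tidy.qty_sasa <- function(x, ...) {
  x$residues
}

#' @describeIn shrake_rupley `glance()` returns total area, hydrophobic
#'   area and hydrophobic fraction with the run parameters.
#' @export
glance.qty_sasa <- function(x, ...) {
  hf <- hydrophobic_fraction(x)
  tibble(
    total_area = x$total_area,
    hydrophobic_area = hf * x$total_area,
    hydrophobic_fraction = hf,
    probe = x$params$probe,
    n_points = x$params$n_points,
    radii_set = x$params$radii_set
  )
}
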