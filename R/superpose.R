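#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum_i |R p_i + t - q_i|^2` by SVD of the covariance of the centered
#' coordinate sets, with the reflection corrected by flipping the sign of
#' the smallest singular vector whenever the determinant of the candidate
#' rotation is negative — so a mirror-image target is never "matched" by an
#' improper transform. RMSD is `sqrt(mean(|R p_i + t - q_i|^2))`.
#'
#' For degenerate (e.g. collinear) inputs the returned transform is still a
#' minimizer but is no longer unique.
#'
#' @param p,q N x 3 coordinate matrices (N >= 3), `p` mobile, `q` target.
#' @return An object of class `qty_superposition`: list with `rotation`
#'   (3 x 3, det +1), `translation` (length 3), `rmsd`, `rmsd_all`,
#'   `distances` (per-pair post-fit distances), `n_pairs_used`,
#'   `n_rejected`, `cycles_run`.
#' @export
#' @examples
#' p <- matrix(rnorm(15), 5, 3)
#' kabsch(p, p)$rmsd
kabsch <- function(p, q) {
  p <- as.matrix(p)
  q <- as.matrix(q)
  if (!all(dim(p) == dim(q)) || ncol(p) != 3) {
    abort("p and q must be N x 3 matrices of equal size")
  }
  if (nrow(p) < 3) abort("at least 3 point pairs are required")
  cp <- colMeans(p)
  cq <- colMeans(q)
  pc <- sweep(p, 2, cp)
  qc <- sweep(q, 2, cq)
  h <- crossprod(pc, qc)            # 3x3 covariance
  s <- svd(h)
  d <- sign(det(tcrossprod(s$v, s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- tcrossprod(pc, rot)        # pc %*% t(rot)
  dists <- sqrt(rowSums((fit - qc)^2))
  res <- list(
    rotation = rot,
    translation = as.numeric(cq - rot %*% cp),
    rmsd = sqrt(mean(dists^2)),
    rmsd_all = sqrt(mean(dists^2)),
    distances = dists,
    n_pairs_used = nrow(p),
    n_rejected = 0L,
    cycles_run = 0L
  )
  class(res) <- "qty_superposition"
  res
}

#' Superpose two structure models on paired CA atoms
#'
#' CA-only Kabsch superposition over a residue pairing, with optional
#' outlier-rejection cycles: after each fit, pairs whose post-fit distance
#' exceeds `cutoff` are discarded and the fit repeated (the refinement
#' strategy of PyMOL-style `align`). Both the all-pair RMSD (`rmsd_all`,
#' cycle 0 on the full pairing) and the refined RMSD (`rmsd`) are reported
#' so a published value of unknown settings can be bracketed.
#'
#' @param a,b `qty_structure` models.
#' @param pairing A `qty_pairing` from [pair_residues()] (computed with the
#'   `"resnum"` policy when omitted).
#' @param cycles Number of rejection cycles (default 0 = plain Kabsch).
#' @param cutoff Rejection distance in Angstrom (default 2.0).
#' @param atoms `"CA"` (default) or `"all"` (all heavy atoms shared by name
#'   within each paired residue).
#' @return A `qty_superposition`; `n_rejected` counts dropped pairs.
#' @export
superpose_structures <- function(a, b, pairing = NULL, cycles = 0,
                                 cutoff = 2.0, atoms = c("CA", "all")) {
  atoms <- match.arg(atoms)
  stopifnot(cycles >= 0, cutoff > 0)
  if (is.null(pairing)) pairing <- pair_residues(a, b)
  pq <- paired_coordinates(a, b, pairing, atoms)
  p <- pq$p
  q <- pq$q
  base <- kabsch(p, q)
  keep <- seq_len(nrow(p))
  fit <- base
  cycles_run <- 0L
  if (cycles > 0) {
    for (i in seq_len(cycles)) {
      bad <- which(fit$distances > cutoff)
      if (length(bad) == 0) break
      keep <- keep[-bad]
      if (length(keep) < 3) {
        abort("fewer than 3 pairs remain after outlier rejection")
      }
      fit <- kabsch(p[keep, , drop = FALSE], q[keep, , drop = FALSE])
      cycles_run <- i
    }
  }
  res <- list(
    rotation = fit$rotation,
    translation = fit$translation,
    rmsd = fit$rmsd,
    rmsd_all = base$rmsd,
    distances = fit$distances,
    n_pairs_used = length(keep),
    n_rejected = nrow(p) - length(keep),
    cycles_run = cycles_run
  )
  class(res) <- "qty_superposition"
  res
}

paired_coordinates <- function(a, b, pairing, atoms = "CA") {
  ta <- as_tibble(a)
  tb <- as_tibble(b)
  key <- function(tab) paste(tab$chain, tab$resno, tab$icode, sep = "\r")
  ka <- key(ta)
  kb <- key(tb)
  pa <- paste(pairing$chain_a, pairing$resno_a, pairing$icode_a, sep = "\r")
  pb <- paste(pairing$chain_b, pairing$resno_b, pairing$icode_b, sep = "\r")
  rows <- purrr::map2(pa, pb, function(ra, rb) {
    sa <- ta[ka == ra & ta$is_polymer, , drop = FALSE]
    sb <- tb[kb == rb & tb$is_polymer, , drop = FALSE]
    if (atoms == "CA") {
      sa <- sa[sa$atom == "CA", , drop = FALSE]
      sb <- sb[sb$atom == "CA", , drop = FALSE]
      if (nrow(sa) < 1 || nrow(sb) < 1) return(NULL)
      list(p = coords(sa)[1, , drop = FALSE], q = coords(sb)[1, , drop = FALSE])
    } else {
      shared <- intersect(sa$atom, sb$atom)
      if (length(shared) == 0) return(NULL)
      sa <- sa[match(shared, sa$atom), , drop = FALSE]
      sb <- sb[match(shared, sb$atom), , drop = FALSE]
      list(p = coords(sa), q = coords(sb))
    }
  })
  rows <- purrr::compact(rows)
  if (length(rows) < 3) abort("insufficient paired atoms (< 3)")
  list(
    p = do.call(rbind, purrr::map(rows, "p")),
    q = do.call(rbind, purrr::map(rows, "q"))
  )
}

#' Apply a superposition transform to a structure
#'
#' @param struct A `qty_structure`.
#' @param sp A `qty_superposition`.
#' @return The transformed structure (`x' = R x + t`) as a new
#'   `qty_structure`; the input is unchanged.
#' @export
apply_transform <- function(struct, sp) {
  stopifnot(inherits(struct, "qty_structure"), inherits(sp, "qty_superposition"))
  xyz <- coords(struct) %*% t(sp$rotation)
  xyz <- sweep(xyz, 2, sp$translation, "+")
  out <- as_tibble(struct)
  out$x <- xyz[, 1]
  out$y <- xyz[, 2]
  out$z <- xyz[, 3]
  new_structure(out)
}

#' Invert a superposition transform
#'
#' @param sp A `qty_superposition`.
#' @return A `qty_superposition` whose transform undoes `sp`'s.
#' @export
invert_transform <- function(sp) {
  stopifnot(inherits(sp, "qty_superposition"))
  inv <- sp
  inv$rotation <- t(sp$rotation)
  inv$translation <- as.numeric(-t(sp$rotation) %*% sp$translation)
  inv
}

#' @export
print.qty_superposition <- function(x, ...) {
  cat(sprintf(
    "# Superposition: RMSD %.3f A over %d pairs (%d rejected, %d cycle%s); all-pair RMSD %.3f A\n",
    x$rmsd, x$n_pairs_used, x$n_rejected, x$cycles_run,
    if (x$cycles_run == 1) "" else "s", x$rmsd_all
  ))
  invisible(x)
}

#' @describeIn kabsch `tidy()` returns per-pair post-fit distances.
#' @param x A `qty_superposition`.
#' @param ... Unused.
#' @export
tidy.qty_superposition <- function(x, ...) {
  tibble(pair = seq_along(x$distances), distance = x$distances)
}

#' @describeIn kabsch `glance()` returns a one-row fit summary.
#' @export
glance.qty_superposition <- function(x, ...) {
  tibble(
    rmsd = x$rmsd, rmsd_all = x$rmsd_all,
    n_pairs_used = x$n_pairs_used, n_rejected = x$n_rejected,
    cycles_run = x$cycles_run
  )
}
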