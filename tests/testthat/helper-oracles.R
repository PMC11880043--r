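# Independent oracles and fixture builders used across the suite.

# --- random protein records -------------------------------------------------

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_record <- function(seed, min_len = 30, max_len = 120) {
  withr::with_seed(seed, {
    n <- sample(min_len:max_len, 1)
    sequence <- paste(sample(AA20, n, replace = TRUE), collapse = "")
    n_seg <- sample(1:3, 1)
    bounds <- sort(sample(seq_len(n), 2 * n_seg))
    seg <- tibble::tibble(
      start = bounds[seq(1, 2 * n_seg, by = 2)],
      end = bounds[seq(2, 2 * n_seg, by = 2)]
    )
    # drop touching segments that would overlap after sorting
    keep <- c(TRUE, seg$start[-1] > seg$end[-nrow(seg)])
    protein_record(paste0("rnd", seed), sequence, seg[keep, , drop = FALSE])
  })
}

# --- pI: dense grid-scan root finder (independent of bisection) -------------

grid_pi <- function(sequence, pka = pka_table(), step = 1e-4) {
  chars <- strsplit(sequence, "")[[1]]
  nt <- chars[1]
  nt_pka <- if (nt %in% names(pka$nterm_by_residue)) {
    pka$nterm_by_residue[[nt]]
  } else {
    pka$nterm
  }
  side <- chars[chars %in% names(pka$side)]
  pos_pka <- c(nt_pka, unname(pka$side[side[side %in% c("K", "R", "H")]]))
  neg_pka <- c(pka$cterm, unname(pka$side[side[side %in% c("D", "E", "C", "Y")]]))
  ph <- seq(step, 14 - step, by = step)
  charge <- rep(0, length(ph))
  for (p in pos_pka) charge <- charge + 1 / (1 + 10^(ph - p))
  for (p in neg_pka) charge <- charge - 1 / (1 + 10^(p - ph))
  i <- which(charge <= 0)[1]
  if (is.na(i)) return(ph[length(ph)])
  if (i == 1) return(ph[1])
  mean(ph[c(i - 1, i)])
}

# --- superposition: Horn closed-form quaternion solver ----------------------

horn_rmsd <- function(p, q) {
  pc <- sweep(p, 2, colMeans(p))
  qc <- sweep(q, 2, colMeans(q))
  m <- crossprod(pc, qc)
  n4 <- matrix(c(
    m[1, 1] + m[2, 2] + m[3, 3], m[2, 3] - m[3, 2], m[3, 1] - m[1, 3], m[1, 2] - m[2, 1],
    m[2, 3] - m[3, 2], m[1, 1] - m[2, 2] - m[3, 3], m[1, 2] + m[2, 1], m[3, 1] + m[1, 3],
    m[3, 1] - m[1, 3], m[1, 2] + m[2, 1], -m[1, 1] + m[2, 2] - m[3, 3], m[2, 3] + m[3, 2],
    m[1, 2] - m[2, 1], m[3, 1] + m[1, 3], m[2, 3] + m[3, 2], -m[1, 1] - m[2, 2] + m[3, 3]
  ), 4, 4, byrow = TRUE)
  ev <- eigen(n4, symmetric = TRUE)
  qv <- ev$vectors[, 1]
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  rot <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
  fit <- pc %*% t(rot)
  sqrt(mean(rowSums((fit - qc)^2)))
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation <- function() {
  qr_r <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(qr_r)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# minimum RMSD over a coarse Euler-angle grid (brute-force lower-quality
# minimizer: its minimum can never beat the true optimum by more than the
# grid resolution allows)
grid_search_rmsd <- function(p, q, step_deg = 10) {
  pc <- sweep(p, 2, colMeans(p))
  qc <- sweep(q, 2, colMeans(q))
  ang <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  half <- seq(0, 180, by = step_deg) * pi / 180
  best <- Inf
  for (a in ang) {
    ca <- cos(a); sa <- sin(a)
    rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    for (b in half) {
      cb <- cos(b); sb <- sin(b)
      ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
      for (g in ang) {
        cg <- cos(g); sg <- sin(g)
        rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
        r <- rz1 %*% ry %*% rz2
        v <- sqrt(mean(rowSums((pc %*% t(r) - qc)^2)))
        if (v < best) best <- v
      }
    }
  }
  best
}

# --- SASA: analytic two-sphere areas ----------------------------------------

# accessible areas of two spheres (expanded radii r1, r2) at center
# distance d, each losing a spherical cap to the other
two_sphere_areas <- function(r1, r2, d) {
  stopifnot(d < r1 + r2, d > abs(r1 - r2))
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  h1 <- r1 - x1
  h2 <- r2 - (d - x1)
  c(4 * pi * r1^2 - 2 * pi * r1 * h1,
    4 * pi * r2^2 - 2 * pi * r2 * h2)
}

# --- structure fixtures -----------------------------------------------------

pdb_atom_line <- function(type, serial, name, alt, resname, chain, resno,
                          icode, x, y, z, occ = 1, b = 0, element = NULL) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  nm <- if (nchar(name) >= 4 || grepl("^[0-9]", name)) name else paste0(" ", name)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, nm, alt, resname, chain, resno, icode,
          x, y, z, occ, b, element)
}

write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a 3-residue, 2-chain mini structure with a heme iron near chain A
mini_complex_pdb <- function() {
  write_mini_pdb(c(
    pdb_atom_line("ATOM", 1, "CA", " ", "ALA", "A", 1, " ", 0, 0, 0),
    pdb_atom_line("ATOM", 2, "CA", " ", "LEU", "A", 2, " ", 3.8, 0, 0),
    pdb_atom_line("ATOM", 3, "CA", " ", "GLY", "A", 3, " ", 7.6, 0, 0),
    pdb_atom_line("ATOM", 4, "CA", " ", "SER", "B", 1, " ", 0, 20, 0),
    pdb_atom_line("ATOM", 5, "CA", " ", "LYS", "B", 2, " ", 3.8, 20, 0),
    pdb_atom_line("ATOM", 6, "CA", " ", "THR", "B", 3, " ", 7.6, 20, 0),
    pdb_atom_line("HETATM", 7, "FE", " ", "HEM", "A", 201, " ", 0, 3, 0,
                  element = "FE")
  ))
}

# qty_structure with a single carbon atom at the origin
single_carbon <- function() {
  as_structure(data.frame(resno = 1, resname = "GLY", atom = "C",
                          element = "C", x = 0, y = 0, z = 0))
}
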