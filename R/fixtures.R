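#' Ideal alpha-helix CA trace
#'
#' CA coordinates of an ideal alpha helix: residue `i` (0-based) sits at
#' `(radius cos(i twist), radius sin(i twist), i rise)`. The defaults
#' (rise 1.5 A per residue, twist 100 degrees, radius 2.3 A) give the
#' conventional 3.6-residues-per-turn helix with consecutive CA-CA
#' distances of ~3.8 A.
#'
#' @param n Number of residues (>= 1).
#' @param rise Rise per residue in Angstrom.
#' @param twist Twist per residue in degrees.
#' @param radius Helix radius in Angstrom.
#' @return An `n` x 3 coordinate matrix.
#' @export
ideal_helix <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  if (n < 1) abort("n must be >= 1")
  i <- seq_len(n) - 1
  ang <- i * twist * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), i * rise)
}

POLAR_LOOP_SET <- c("G", "S", "N", "Q", "D", "E", "K", "R", "P", "H", "T")

#' Generate a synthetic transmembrane protein with known ground truth
#'
#' Emulates the sequence and CA-trace geometry of a helical-bundle membrane
#' protein: transmembrane segments enriched in hydrophobic residues
#' (L, I, V, F, M, W, A) connected by polar loops, packed as an
#' antiparallel bundle of ideal helices on a 10 A grid. Everything is a
#' pure function of the parameters and seed, and the returned `truth`
#' records the planted segments, the composition rule and an
#' exposed/buried label per residue (CA distance from the bundle axis),
#' so downstream statistics can be checked against known answers.
#'
#' @param n_helices Number of transmembrane helices (>= 1).
#' @param helix_len Residues per helix (>= 1).
#' @param loop_len Residues per connecting loop (>= 1).
#' @param hydrophobic_bias Probability that a TM residue is drawn from the
#'   hydrophobic set (1.0 = TM segments are purely hydrophobic).
#' @param seed Integer seed; same seed, same protein.
#' @return A list of class `qty_synthetic`: `record` (one-row record tibble
#'   with segments attached), `model` (`qty_structure` CA trace), `truth`
#'   (list: segments, seed, hydrophobic_bias, sigma, exposure).
#' @export
#' @examples
#' fx <- synthetic_tm_protein(n_helices = 2, helix_len = 12, seed = 1)
#' fx$record
synthetic_tm_protein <- function(n_helices = 4, helix_len = 24, loop_len = 6,
                                 hydrophobic_bias = 0.8, seed = 1) {
  stopifnot(n_helices >= 1, helix_len >= 1, loop_len >= 1,
            hydrophobic_bias >= 0, hydrophobic_bias <= 1)
  hydro <- hydrophobic_set()
  withr::with_seed(seed, {
    seq_parts <- list()
    seg_rows <- list()
    xyz_parts <- list()
    pos <- 0L
    for (h in seq_len(n_helices)) {
      n_tm <- helix_len
      tm_seq <- vapply(seq_len(n_tm), function(i) {
        if (stats::runif(1) < hydrophobic_bias) {
          sample(hydro, 1)
        } else {
          sample(POLAR_LOOP_SET, 1)
        }
      }, character(1))
      seg_rows[[h]] <- tibble(start = pos + 1L, end = pos + n_tm,
                              kind = "helix")
      seq_parts[[length(seq_parts) + 1]] <- tm_seq
      hel <- ideal_helix(n_tm)
      if (h %% 2 == 0) hel[, 3] <- max(hel[, 3]) - hel[, 3]  # antiparallel
      hel[, 1] <- hel[, 1] + 10 * (h - 1)
      xyz_parts[[length(xyz_parts) + 1]] <- hel
      pos <- pos + n_tm
      if (h < n_helices) {
        loop_seq <- sample(POLAR_LOOP_SET, loop_len, replace = TRUE)
        seq_parts[[length(seq_parts) + 1]] <- loop_seq
        pos <- pos + loop_len
        # straight loop trace between helix end and next helix start
        from <- hel[nrow(hel), ]
        ang0 <- 0
        next_start <- c(2.3 * cos(ang0) + 10 * h, 2.3 * sin(ang0),
                        if ((h + 1) %% 2 == 0) (helix_len - 1) * 1.5 else 0)
        frac <- seq_len(loop_len) / (loop_len + 1)
        xyz_parts[[length(xyz_parts) + 1]] <-
          cbind(from[1] + frac * (next_start[1] - from[1]),
                from[2] + frac * (next_start[2] - from[2]),
                from[3] + frac * (next_start[3] - from[3]))
      }
    }
    sequence <- paste(unlist(seq_parts), collapse = "")
    xyz <- do.call(rbind, xyz_parts)
    segments <- bind_rows(seg_rows)
    record <- protein_record(paste0("synthetic_tm_", seed), sequence, segments)
    model <- ca_trace_structure(sequence, xyz)
    axis_xy <- colMeans(xyz[segment_positions(segments), 1:2, drop = FALSE])
    d_axis <- sqrt((xyz[, 1] - axis_xy[1])^2 + (xyz[, 2] - axis_xy[2])^2)
    exposure <- ifelse(d_axis >= stats::median(d_axis), "exposed", "buried")
    out <- list(
      record = record,
      model = model,
      truth = list(
        segments = segments, seed = seed,
        hydrophobic_bias = hydrophobic_bias, sigma = 0,
        exposure = exposure
      )
    )
    class(out) <- "qty_synthetic"
    out
  })
}

# CA-only qty_structure from a sequence and an n x 3 coordinate matrix
ca_trace_structure <- function(sequence, xyz, chain = "A") {
  chars <- seq_chars(sequence)
  stopifnot(length(chars) == nrow(xyz))
  new_structure(tibble(
    chain = chain,
    resno = seq_along(chars),
    icode = "",
    resname = aa_one_to_three(chars),
    atom = "CA",
    element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = 1, b = 0,
    is_polymer = TRUE
  ))
}

#' Rename a structure's residues to their QTY analogs
#'
#' Threads the analog sequence of a [qty_apply()] result onto the native
#' coordinates (residue names change, coordinates do not) — the idealized
#' setting in which surface-hydrophobicity changes are attributable purely
#' to the substitution chemistry.
#'
#' @param struct A `qty_structure` whose polymer residues are numbered
#'   1..n in sequence order (as produced by [synthetic_tm_protein()]).
#' @param qty A one-row `qty_tbl`.
#' @return The renamed `qty_structure`.
#' @export
thread_analog <- function(struct, qty) {
  stopifnot(inherits(struct, "qty_structure"), inherits(qty, "qty_tbl"),
            nrow(qty) == 1)
  chars <- seq_chars(qty$analog[1])
  out <- as_tibble(struct)
  poly <- out$is_polymer
  if (max(out$resno[poly]) > length(chars)) {
    abort("structure residue numbers exceed analog sequence length")
  }
  out$resname[poly] <- aa_one_to_three(chars[out$resno[poly]])
  new_structure(out)
}

#' Perturb a structure with Gaussian coordinate noise
#'
#' Adds i.i.d. Gaussian noise (s.d. `sigma` per axis) to every atom,
#' deterministically per seed. After optimal superposition onto the
#' original, the expected RMSD is slightly below `sigma * sqrt(3)` (the
#' fitted rigid transform absorbs 6 of the `3N` noise degrees of freedom).
#'
#' @param struct A `qty_structure`.
#' @param sigma Noise s.d. per coordinate in Angstrom (>= 0).
#' @param seed Integer seed.
#' @return The perturbed `qty_structure`.
#' @export
perturb_structure <- function(struct, sigma, seed = 1) {
  stopifnot(inherits(struct, "qty_structure"), sigma >= 0)
  n <- nrow(struct)
  withr::with_seed(seed, {
    out <- as_tibble(struct)
    out$x <- out$x + rnorm(n, 0, sigma)
    out$y <- out$y + rnorm(n, 0, sigma)
    out$z <- out$z + rnorm(n, 0, sigma)
    new_structure(out)
  })
}

#' Write a structure to a PDB file
#'
#' @param struct A `qty_structure`.
#' @param path Output path.
#' @return `path`, invisibly. Round-trips through [read_structure()].
#' @export
write_structure <- function(struct, path) {
  stopifnot(inherits(struct, "qty_structure"))
  tab <- as_tibble(struct)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(coords(tab))),
    type = ifelse(tab$is_polymer, "ATOM", "HETATM"),
    resno = tab$resno,
    resid = tab$resname,
    chain = tab$chain,
    insert = ifelse(nzchar(tab$icode), tab$icode, ""),
    elety = tab$atom,
    o = tab$occ,
    b = tab$b,
    elesy = tab$element
  )
  invisible(path)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the FASTA sequence, the TM-segment TSV and the CA-trace PDB of a
#' synthetic protein, exercising the package's real I/O paths.
#'
#' @param fixture A `qty_synthetic` from [synthetic_tm_protein()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three file paths.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "qty_synthetic"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- fixture$record$id[1]
  paths <- c(
    fasta = file.path(dir, paste0(id, ".fa")),
    tm = file.path(dir, paste0(id, ".tm.tsv")),
    pdb = file.path(dir, paste0(id, ".pdb"))
  )
  write_fasta(fixture$record, paths[["fasta"]])
  seg <- fixture$record$segments[[1]]
  readr::write_tsv(
    tibble(id = id, start = seg$start, end = seg$end, kind = seg$kind),
    paths[["tm"]]
  )
  write_structure(fixture$model, paths[["pdb"]])
  paths
}
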