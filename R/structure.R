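#' Read a protein structure (PDB or mmCIF) into an atom tibble
#'
#' Parses a structure file into a flat heavy-atom table, the container used
#' by all downstream geometry (superposition, surface area, contacts).
#' Only the first model of multi-model files is kept; alternate locations
#' are resolved to the highest-occupancy conformer (ties and missing
#' occupancies fall back to altloc `"A"`/first); hydrogens are dropped
#' (cryo-EM depositions lack them and all geometry here is heavy-atom);
#' hetero residues are retained and flagged non-polymer. Residue numbers
#' are author numbering.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param format `"auto"` (default, by extension then content sniff),
#'   `"pdb"` or `"cif"`.
#' @return A tibble of class `qty_structure` with columns `chain`, `resno`,
#'   `icode`, `resname`, `atom`, `element`, `x`, `y`, `z`, `occ`, `b`,
#'   `is_polymer`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("structure file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) {
      "cif"
    } else if (ext %in% c("pdb", "ent")) {
      "pdb"
    } else if (any(grepl("_atom_site\\.", readLines(path, n = 200, warn = FALSE)))) {
      "cif"
    } else {
      "pdb"
    }
  }
  raw <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    },
    error = function(e) abort(paste0("could not parse structure file ", path,
                                     ": ", conditionMessage(e)))
  )
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0) abort(paste0("no atoms in ", path))
  element <- toupper(trimws(at$elesy))
  miss <- is.na(element) | !nzchar(element)
  element[miss] <- guess_element(at$elety[miss])
  out <- tibble(
    chain = ifelse(is.na(at$chain), "A", as.character(at$chain)),
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resname = as.character(at$resid),
    atom = as.character(at$elety),
    altloc = ifelse(is.na(at$alt), "", as.character(at$alt)),
    element = element,
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    is_polymer = at$type == "ATOM"
  )
  out <- out[out$element != "H" & out$element != "D", , drop = FALSE]
  if (nrow(out) == 0) abort(paste0("no heavy atoms in ", path))
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    abort(paste0("non-finite coordinates in ", path))
  }
  out <- resolve_altloc(out)
  out$altloc <- NULL
  new_structure(out)
}

guess_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Z]", "", toupper(atom_name)))
  two <- substr(nm, 1, 2)
  known2 <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "SE", "CA", "NI", "CO")
  ifelse(two %in% known2 & nchar(nm) == 2, two, substr(nm, 1, 1))
}

resolve_altloc <- function(at) {
  key <- paste(at$chain, at$resno, at$icode, at$atom, sep = "\r")
  if (!anyDuplicated(key)) return(at)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    occ <- at$occ[idx]
    best <- idx[occ == max(occ)]
    if (length(best) > 1) {
      a <- best[at$altloc[best] == "A"]
      best <- if (length(a) > 0) a[1] else best[1]
    }
    best
  }), use.names = FALSE)
  at[sort(keep), , drop = FALSE]
}

new_structure <- function(tab) {
  tab <- as_tibble(tab)
  class(tab) <- c("qty_structure", setdiff(class(tab), "qty_structure"))
  tab
}

#' Build a structure model from an atom table
#'
#' Constructor for assembling models in code (fixtures, toy geometries).
#' Required columns: `resno`, `resname`, `atom`, `element`, `x`, `y`, `z`;
#' `chain` defaults to `"A"`, `icode` to `""`, `occ` to 1, `b` to 0 and
#' `is_polymer` to `TRUE`.
#'
#' @param atoms A data frame of atoms.
#' @return A `qty_structure`.
#' @export
#' @examples
#' as_structure(data.frame(resno = 1, resname = "GLY", atom = "CA",
#'                         element = "C", x = 0, y = 0, z = 0))
as_structure <- function(atoms) {
  atoms <- as_tibble(atoms)
  need <- c("resno", "resname", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("missing atom columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!("chain" %in% names(atoms))) atoms$chain <- "A"
  if (!("icode" %in% names(atoms))) atoms$icode <- ""
  if (!("occ" %in% names(atoms))) atoms$occ <- 1
  if (!("b" %in% names(atoms))) atoms$b <- 0
  if (!("is_polymer" %in% names(atoms))) atoms$is_polymer <- TRUE
  atoms$resno <- as.integer(atoms$resno)
  atoms$element <- toupper(atoms$element)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("coordinates must be finite")
  }
  new_structure(atoms[, c("chain", "resno", "icode", "resname", "atom",
                          "element", "x", "y", "z", "occ", "b", "is_polymer")])
}

#' @export
print.qty_structure <- function(x, ...) {
  res <- residue_keys(x)
  cat(sprintf(
    "# Structure: %d atoms, %d residues, chain(s) %s\n",
    nrow(x), nrow(res), paste(unique(x$chain), collapse = ", ")
  ))
  NextMethod()
}

residue_keys <- function(struct) {
  distinct(as_tibble(struct)[, c("chain", "resno", "icode", "resname",
                                 "is_polymer")])
}

coords <- function(struct) {
  cbind(struct$x, struct$y, struct$z)
}

#' Extract one protomer from a multimeric structure
#'
#' Keeps the polymer residues of a single chain together with every hetero
#' residue (ligand, cofactor, ion) whose nearest polymer atom belongs to
#' that chain. This reproduces the common characterization step of cutting
#' a single monomer out of a dimeric membrane-enzyme structure before
#' superposition.
#'
#' @param struct A `qty_structure`.
#' @param chain Chain identifier to keep.
#' @return A `qty_structure` containing one chain plus its ligands.
#' @export
extract_protomer <- function(struct, chain) {
  stopifnot(inherits(struct, "qty_structure"))
  poly <- struct[struct$is_polymer, , drop = FALSE]
  if (!(chain %in% poly$chain)) {
    abort(paste0("chain '", chain, "' not found among polymer chains"))
  }
  keep_poly <- struct$is_polymer & struct$chain == chain
  het <- struct[!struct$is_polymer, , drop = FALSE]
  keep_het <- rep(FALSE, nrow(struct))
  if (nrow(het) > 0) {
    pxyz <- coords(poly)
    hkey <- paste(het$chain, het$resno, het$icode, sep = "\r")
    for (k in unique(hkey)) {
      sub <- het[hkey == k, , drop = FALSE]
      d2 <- crossdist2(coords(sub), pxyz)
      nearest <- arrayInd(which.min(d2), dim(d2))[2]
      if (poly$chain[nearest] == chain) {
        keep_het <- keep_het |
          (!struct$is_polymer &
             paste(struct$chain, struct$resno, struct$icode, sep = "\r") == k)
      }
    }
  }
  new_structure(struct[keep_poly | keep_het, , drop = FALSE])
}

# squared Euclidean cross-distances between two coordinate matrices
crossdist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

ca_table <- function(struct) {
  tab <- as_tibble(struct) %>%
    filter(.data$is_polymer, .data$atom == "CA")
  tab$aa1 <- aa_three_to_one(tab$resname)
  tab
}

#' Pair residues between two structure models
#'
#' Builds the one-to-one residue correspondence used for superposition and
#' pocket-conservation analysis. Both policies require a CA atom on each
#' side and silently drop residues present in only one model — unresolved
#' loops in an experimental structure, extra termini in a prediction — which
#' is exactly the loop-trimming rule applied before computing RMSDs between
#' experimental structures and predicted analogs.
#'
#' @param a,b `qty_structure` models (native and analog, say).
#' @param policy `"resnum"`: pair residues sharing author residue number and
#'   insertion code (chains matched in order of appearance, or via
#'   `chain_map`); `"align"`: pair by global sequence alignment in which the
#'   four QTY substitutions (L:Q, I:T, V:T, F:Y) score as matches — the
#'   fallback when the two models use different numbering.
#' @param offset Constant added to `b`'s residue numbers before `"resnum"`
#'   matching (handles predictions numbered from 1).
#' @param chain_map Optional named character vector mapping chains of `a` to
#'   chains of `b`.
#' @return A tibble of class `qty_pairing` with columns `chain_a`,
#'   `resno_a`, `icode_a`, `resname_a`, `chain_b`, `resno_b`, `icode_b`,
#'   `resname_b`; attribute `policy`.
#' @export
pair_residues <- function(a, b, policy = c("resnum", "align"), offset = 0L,
                          chain_map = NULL) {
  policy <- match.arg(policy)
  ca_a <- ca_table(a)
  ca_b <- ca_table(b)
  if (nrow(ca_a) < 3 || nrow(ca_b) < 3) {
    abort("both models need at least 3 CA atoms")
  }
  if (is.null(chain_map)) {
    cha <- unique(ca_a$chain)
    chb <- unique(ca_b$chain)
    k <- min(length(cha), length(chb))
    chain_map <- setNames(chb[seq_len(k)], cha[seq_len(k)])
  }
  pairs <- purrr::map(names(chain_map), function(ca) {
    cb <- chain_map[[ca]]
    ta <- ca_a[ca_a$chain == ca, , drop = FALSE]
    tb <- ca_b[ca_b$chain == cb, , drop = FALSE]
    if (nrow(ta) == 0 || nrow(tb) == 0) return(NULL)
    if (policy == "resnum") {
      m <- inner_join(
        ta %>% mutate(key = paste(.data$resno, .data$icode)),
        tb %>% mutate(key = paste(.data$resno + as.integer(offset), .data$icode)),
        by = "key", suffix = c("_a", "_b")
      )
      tibble(
        chain_a = m$chain_a, resno_a = m$resno_a, icode_a = m$icode_a,
        resname_a = m$resname_a,
        chain_b = m$chain_b, resno_b = m$resno_b, icode_b = m$icode_b,
        resname_b = m$resname_b
      )
    } else {
      align_pair_chains(ta, tb)
    }
  })
  out <- bind_rows(pairs)
  if (nrow(out) < 3) abort("insufficient common residues (< 3 pairs)")
  class(out) <- c("qty_pairing", class(out))
  attr(out, "policy") <- policy
  out
}

# QTY-aware substitution matrix: identities and the four QTY pairs score
# as matches, everything else as a mismatch
qty_aware_matrix <- function(match = 2L, mismatch = -1L, qty_pairs = qty_map()) {
  letters <- c(AA1, "X")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  for (src in names(qty_pairs)) {
    tgt <- qty_pairs[[src]]
    m[src, tgt] <- match
    m[tgt, src] <- match
  }
  m
}

align_pair_chains <- function(ta, tb) {
  sa <- paste(ta$aa1, collapse = "")
  sb <- paste(tb$aa1, collapse = "")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    type = "global",
    substitutionMatrix = qty_aware_matrix(),
    gapOpening = 5, gapExtension = 1
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L
  ib <- 0L
  rows <- vector("list", length(pa))
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (pb[k] != "-") ib <- ib + 1L
    if (pa[k] != "-" && pb[k] != "-") {
      rows[[k]] <- tibble(
        chain_a = ta$chain[ia], resno_a = ta$resno[ia], icode_a = ta$icode[ia],
        resname_a = ta$resname[ia],
        chain_b = tb$chain[ib], resno_b = tb$resno[ib], icode_b = tb$icode[ib],
        resname_b = tb$resname[ib]
      )
    }
  }
  bind_rows(rows)
}
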