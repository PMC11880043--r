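#' Select atoms with a simple selection string
#'
#' Supports the clauses `chain <id>`, `resn <name>` and `resi <spec>`
#' (where `<spec>` is a comma list of numbers and `a-b` ranges), combined
#' with `and`, e.g. `"chain A and resn FAD"`.
#'
#' @param struct A `qty_structure`.
#' @param selection Selection string.
#' @return A `qty_structure` subset (possibly empty).
#' @export
#' @examples
#' \dontrun{select_atoms(model, "resn HEM")}
select_atoms <- function(struct, selection) {
  stopifnot(inherits(struct, "qty_structure"), is.character(selection))
  clauses <- strsplit(trimws(selection), "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(struct))
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    if (length(tok) != 2) {
      abort(paste0("cannot parse selection clause: '", cl, "'"))
    }
    keep <- keep & switch(
      tok[1],
      chain = struct$chain %in% strsplit(tok[2], ",")[[1]],
      resn = struct$resname %in% strsplit(toupper(tok[2]), ",")[[1]],
      resi = struct$resno %in% parse_resi(tok[2]),
      abort(paste0("unknown selection keyword: '", tok[1], "'"))
    )
  }
  new_structure(as_tibble(struct)[keep, , drop = FALSE])
}

parse_resi <- function(spec) {
  parts <- strsplit(spec, ",")[[1]]
  unlist(lapply(parts, function(p) {
    if (grepl("-", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      seq(ab[1], ab[2])
    } else {
      as.integer(p)
    }
  }))
}

#' Contact residues around a ligand
#'
#' Lists every polymer residue with at least one heavy atom within `cutoff`
#' of any atom matched by the ligand selection (minimum heavy-atom distance
#' convention, the standard way binding-pocket residues such as "within
#' 4 A of the cofactor" are defined). The ligand's own residues are
#' excluded; results are sorted by distance.
#'
#' @param struct A `qty_structure`.
#' @param ligand Selection string (see [select_atoms()]) or a
#'   `qty_structure` of ligand atoms.
#' @param cutoff Contact cutoff in Angstrom (default 4.0).
#' @return A tibble of class `qty_contacts` with columns `chain`, `resno`,
#'   `icode`, `resname`, `distance`; attributes `cutoff` and `selection`.
#' @export
contact_residues <- function(struct, ligand, cutoff = 4.0) {
  stopifnot(inherits(struct, "qty_structure"), cutoff > 0)
  sel_label <- if (is.character(ligand)) ligand else "<structure subset>"
  lig <- if (is.character(ligand)) select_atoms(struct, ligand) else ligand
  if (nrow(lig) == 0) abort("ligand selection matched no atoms")
  ligkey <- unique(paste(lig$chain, lig$resno, lig$icode, sep = "\r"))
  tab <- as_tibble(struct)
  cand <- tab[tab$is_polymer &
                !(paste(tab$chain, tab$resno, tab$icode, sep = "\r") %in% ligkey),
              , drop = FALSE]
  out <- empty_contacts()
  if (nrow(cand) > 0) {
    d2 <- crossdist2(coords(cand), coords(lig))
    mind <- sqrt(pmax(0, apply(d2, 1, min)))
    cand$distance <- mind
    out <- cand %>%
      group_by(.data$chain, .data$resno, .data$icode, .data$resname) %>%
      summarise(distance = min(.data$distance), .groups = "drop") %>%
      filter(.data$distance <= cutoff) %>%
      arrange(.data$distance)
  }
  class(out) <- c("qty_contacts", class(out))
  attr(out, "cutoff") <- cutoff
  attr(out, "selection") <- sel_label
  out
}

empty_contacts <- function() {
  tibble(chain = character(), resno = integer(), icode = character(),
         resname = character(), distance = numeric())
}

#' Minimum distance between two atom selections
#'
#' Minimum heavy-atom pairwise distance (default) or the distance between
#' the two selection centroids — both conventions are useful when comparing
#' against a published inter-cofactor figure whose convention is unstated.
#'
#' @param struct A `qty_structure`.
#' @param sel_a,sel_b Selection strings (see [select_atoms()]).
#' @param convention `"heavy"` (minimum heavy-atom pair, default) or
#'   `"centroid"`.
#' @return A one-row tibble: `distance`, `convention`, and for `"heavy"`
#'   the achieving atom pair (`atom_a`, `resname_a`, `atom_b`,
#'   `resname_b`).
#' @export
min_distance <- function(struct, sel_a, sel_b,
                         convention = c("heavy", "centroid")) {
  convention <- match.arg(convention)
  a <- select_atoms(struct, sel_a)
  b <- select_atoms(struct, sel_b)
  if (nrow(a) == 0 || nrow(b) == 0) abort("empty selection")
  akey <- paste(a$chain, a$resno, a$icode, a$atom, sep = "\r")
  bkey <- paste(b$chain, b$resno, b$icode, b$atom, sep = "\r")
  if (length(intersect(akey, bkey)) > 0) {
    abort("selections overlap: they share at least one atom")
  }
  if (convention == "centroid") {
    d <- sqrt(sum((colMeans(coords(a)) - colMeans(coords(b)))^2))
    return(tibble(distance = d, convention = convention,
                  atom_a = NA_character_, resname_a = NA_character_,
                  atom_b = NA_character_, resname_b = NA_character_))
  }
  d2 <- crossdist2(coords(a), coords(b))
  ij <- arrayInd(which.min(d2), dim(d2))
  tibble(
    distance = sqrt(max(0, d2[ij])),
    convention = convention,
    atom_a = a$atom[ij[1]], resname_a = a$resname[ij[1]],
    atom_b = b$atom[ij[2]], resname_b = b$resname[ij[2]]
  )
}

#' Binding-pocket conservation between native and analog models
#'
#' Maps the analog's contact residues back onto the native model through a
#' residue pairing and scores how much of the pocket is preserved: the
#' Jaccard index of the two (mapped) contact-residue sets, plus a
#' per-residue table marking each residue `kept`, `lost` or `gained`, with
#' an `identity_changed` flag when a kept position changed amino acid
#' (QTY substitutions, or pocket shifts such as a leucine contact replaced
#' by an asparagine one). Analog contacts that have no counterpart in the
#' pairing are reported with status `unpaired`, never dropped silently.
#'
#' @param native_contacts,analog_contacts `qty_contacts` reports from the
#'   native and analog models.
#' @param pairing A `qty_pairing` between the native (side a) and analog
#'   (side b) models.
#' @return An object of class `qty_conservation`: list with `jaccard` and
#'   `table`.
#' @export
pocket_conservation <- function(native_contacts, analog_contacts, pairing) {
  stopifnot(inherits(native_contacts, "qty_contacts"),
            inherits(analog_contacts, "qty_contacts"),
            inherits(pairing, "qty_pairing"))
  key <- function(ch, no, ic) paste(ch, no, ic, sep = "\r")
  nat_keys <- key(native_contacts$chain, native_contacts$resno,
                  native_contacts$icode)
  pk_a <- key(pairing$chain_a, pairing$resno_a, pairing$icode_a)
  pk_b <- key(pairing$chain_b, pairing$resno_b, pairing$icode_b)
  ana_keys_b <- key(analog_contacts$chain, analog_contacts$resno,
                    analog_contacts$icode)
  idx <- match(ana_keys_b, pk_b)
  ana_mapped <- pk_a[idx]            # NA for unpaired analog contacts
  mapped <- ana_mapped[!is.na(ana_mapped)]
  union_keys <- union(nat_keys, mapped)
  inter_keys <- intersect(nat_keys, mapped)
  jac <- if (length(union_keys) == 0) 1 else length(inter_keys) / length(union_keys)
  rows <- list()
  for (k in union_keys) {
    in_nat <- k %in% nat_keys
    in_ana <- k %in% mapped
    i_nat <- match(k, nat_keys)
    i_pair <- match(k, pk_a)
    rows[[k]] <- tibble(
      chain = if (!is.na(i_pair)) pairing$chain_a[i_pair] else native_contacts$chain[i_nat],
      resno = if (!is.na(i_pair)) pairing$resno_a[i_pair] else native_contacts$resno[i_nat],
      icode = if (!is.na(i_pair)) pairing$icode_a[i_pair] else native_contacts$icode[i_nat],
      resname_native = if (!is.na(i_pair)) pairing$resname_a[i_pair] else native_contacts$resname[i_nat],
      resname_analog = if (!is.na(i_pair)) pairing$resname_b[i_pair] else NA_character_,
      status = if (in_nat && in_ana) "kept" else if (in_nat) "lost" else "gained",
      identity_changed = if (!is.na(i_pair)) {
        pairing$resname_a[i_pair] != pairing$resname_b[i_pair]
      } else NA
    )
  }
  unpaired <- which(is.na(ana_mapped))
  for (u in unpaired) {
    rows[[paste0("unpaired", u)]] <- tibble(
      chain = analog_contacts$chain[u],
      resno = analog_contacts$resno[u],
      icode = analog_contacts$icode[u],
      resname_native = NA_character_,
      resname_analog = analog_contacts$resname[u],
      status = "unpaired",
      identity_changed = NA
    )
  }
  tab <- bind_rows(rows) %>% arrange(.data$chain, .data$resno)
  out <- list(jaccard = jac, table = tab)
  class(out) <- "qty_conservation"
  out
}

#' @export
print.qty_conservation <- function(x, ...) {
  cat(sprintf(
    "# Pocket conservation: Jaccard %.3f (%d kept, %d lost, %d gained, %d unpaired)\n",
    x$jaccard,
    sum(x$table$status == "kept"), sum(x$table$status == "lost"),
    sum(x$table$status == "gained"), sum(x$table$status == "unpaired")
  ))
  invisible(x)
}
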