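# a chain with residues at controlled distances from a heme iron at origin
site_fixture <- function() {
  as_structure(tibble::tibble(
    chain = "A",
    resno = c(283L, 332L, 359L, 438L, 500L, 900L),
    icode = "",
    resname = c("LEU", "VAL", "PHE", "LEU", "GLY", "HEM"),
    atom = c(rep("CA", 5), "FE"),
    element = c(rep("C", 5), "FE"),
    x = c(3.5, 3.9, 2.0, 4.5, 8.0, 0),
    y = 0, z = 0,
    occ = 1, b = 0,
    is_polymer = c(rep(TRUE, 5), FALSE)
  ))
}

test_that("contact residues are those within the cutoff, sorted by distance", {
  s <- site_fixture()
  ct <- contact_residues(s, "resn HEM", cutoff = 4.0)
  expect_equal(ct$resno, c(359L, 283L, 332L))
  expect_equal(ct$distance, c(2.0, 3.5, 3.9))
  expect_false(438L %in% ct$resno)                 # at 4.5 A
  expect_false(900L %in% ct$resno)                 # the ligand itself

  none <- contact_residues(s, "resn HEM", cutoff = 1.0)
  expect_equal(nrow(none), 0)
  expect_error(contact_residues(s, "resn XYZ"), "no atoms")

  # cutoff monotonicity
  small <- contact_residues(s, "resn HEM", cutoff = 3.0)
  expect_true(all(small$resno %in% ct$resno))
})

test_that("contact search equals an exhaustive pairwise scan on random models", {
  for (seed in 1:5) {
    withr::local_seed(seed)
    n <- 30
    tab <- tibble::tibble(
      chain = "A", resno = seq_len(n), icode = "",
      resname = sample(c("LEU", "SER", "PHE"), n, TRUE),
      atom = "CA", element = "C",
      x = stats::runif(n, 0, 20), y = stats::runif(n, 0, 20),
      z = stats::runif(n, 0, 20),
      occ = 1, b = 0, is_polymer = TRUE
    )
    lig <- tibble::tibble(
      chain = "A", resno = 999L, icode = "", resname = "FAD",
      atom = paste0("C", 1:4), element = "C",
      x = stats::runif(4, 5, 15), y = stats::runif(4, 5, 15),
      z = stats::runif(4, 5, 15), occ = 1, b = 0, is_polymer = FALSE
    )
    s <- as_structure(dplyr::bind_rows(tab, lig))
    got <- contact_residues(s, "resn FAD", cutoff = 6.0)
    # brute force double loop
    want <- vapply(seq_len(n), function(i) {
      min(sqrt((tab$x[i] - lig$x)^2 + (tab$y[i] - lig$y)^2 +
                 (tab$z[i] - lig$z)^2))
    }, numeric(1))
    keep <- which(want <= 6.0)
    expect_setequal(got$resno, keep)
    expect_equal(sort(got$distance), sort(want[keep]), tolerance = 1e-12)
  }
})

test_that("minimum distances honor both conventions and reject overlap", {
  s <- as_structure(tibble::tibble(
    chain = "A", resno = c(1L, 2L), icode = "",
    resname = c("FAD", "HEM"), atom = c("C1", "FE"),
    element = c("C", "FE"),
    x = 0, y = 0, z = c(0, 9.3), occ = 1, b = 0, is_polymer = FALSE
  ))
  d <- min_distance(s, "resn FAD", "resn HEM")
  expect_equal(d$distance, 9.3)
  expect_equal(d$atom_a, "C1")
  expect_equal(d$atom_b, "FE")
  dc <- min_distance(s, "resn FAD", "resn HEM", convention = "centroid")
  expect_equal(dc$distance, 9.3)                   # single-atom selections

  expect_error(min_distance(s, "resn FAD", "resn FAD"), "overlap")
  expect_error(min_distance(s, "resn FAD", "resn XXX"), "empty")
})

test_that("minimum distance equals the brute-force double loop on random clouds", {
  for (seed in 1:5) {
    withr::local_seed(100 + seed)
    mk <- function(resname, resno) tibble::tibble(
      chain = "A", resno = resno, icode = "", resname = resname,
      atom = paste0("C", 1:10), element = "C",
      x = stats::rnorm(10, sd = 5), y = stats::rnorm(10, sd = 5),
      z = stats::rnorm(10, sd = 5), occ = 1, b = 0, is_polymer = FALSE
    )
    a <- mk("AAA", 1L)
    b <- mk("BBB", 2L)
    s <- as_structure(dplyr::bind_rows(a, b))
    got <- min_distance(s, "resn AAA", "resn BBB")$distance
    want <- Inf
    for (i in 1:10) for (j in 1:10) {
      want <- min(want, sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                               (a$z[i] - b$z[j])^2))
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("selection strings compose with 'and' and parse ranges", {
  s <- read_structure(mini_complex_pdb())
  expect_equal(nrow(select_atoms(s, "chain B")), 3)
  expect_equal(nrow(select_atoms(s, "resn HEM")), 1)
  expect_equal(nrow(select_atoms(s, "chain A and resi 1-2")), 2)
  expect_equal(nrow(select_atoms(s, "resi 1,3")), 4)
  expect_error(select_atoms(s, "foo bar"), "unknown selection keyword")
  expect_error(select_atoms(s, "chain"), "cannot parse")
})

test_that("pocket conservation scores kept, lost and gained residues", {
  # native pocket {283, 332, 438}; analog pocket {283, 332, 442}
  mk_model <- function(resnos, names) as_structure(tibble::tibble(
    chain = "A", resno = resnos, icode = "", resname = names,
    atom = "CA", element = "C",
    x = resnos * 3.8, y = 0, z = 0, occ = 1, b = 0, is_polymer = TRUE
  ))
  resnos <- c(283L, 332L, 438L, 442L, 500L)
  native <- mk_model(resnos, c("LEU", "VAL", "LEU", "ASN", "GLY"))
  analog <- mk_model(resnos, c("GLN", "THR", "LEU", "ASN", "GLY"))
  pairing <- pair_residues(native, analog)

  contact_at <- function(model, resnos_in) {
    ct <- tibble::as_tibble(model) %>%
      dplyr::filter(resno %in% resnos_in) %>%
      dplyr::select(chain, resno, icode, resname) %>%
      dplyr::mutate(distance = 3.5)
    class(ct) <- c("qty_contacts", class(ct))
    attr(ct, "cutoff") <- 4.0
    ct
  }
  nat_ct <- contact_at(native, c(283, 332, 438))
  ana_ct <- contact_at(analog, c(283, 332, 442))
  pc <- pocket_conservation(nat_ct, ana_ct, pairing)
  expect_equal(pc$jaccard, 0.5)
  expect_equal(pc$table$status[pc$table$resno == 438], "lost")
  expect_equal(pc$table$status[pc$table$resno == 442], "gained")
  expect_equal(sort(pc$table$resno[pc$table$status == "kept"]), c(283L, 332L))
  # kept pocket positions that changed identity under QTY are flagged
  expect_true(all(pc$table$identity_changed[pc$table$resno %in% c(283, 332)]))

  expect_equal(pocket_conservation(nat_ct, nat_ct, pairing)$jaccard, 1.0)
  disjoint <- pocket_conservation(nat_ct, contact_at(analog, 500), pairing)
  expect_equal(disjoint$jaccard, 0.0)

  # analog contacts missing from the pairing are reported, not dropped
  short_pairing <- pairing[pairing$resno_a != 442L, ]
  class(short_pairing) <- class(pairing)
  pc2 <- pocket_conservation(nat_ct, ana_ct, short_pairing)
  expect_true("unpaired" %in% pc2$table$status)
})
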