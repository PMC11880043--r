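test_that("free amino-acid masses implied by the residue table match printed values", {
  m <- residue_masses()
  water <- attr(m, "water")
  free <- c(L = 131.17, Q = 146.14, I = 131.17, V = 117.15,
            T = 119.12, F = 165.19, Y = 181.19)
  for (aa in names(free)) {
    expect_lt(abs(m[[aa]] + water - free[[aa]]), 0.01)
  }
})

test_that("molecular weight is additive and flags unknown residues", {
  m <- residue_masses()
  water <- attr(m, "water")
  expect_equal(molecular_weight("G"), m[["G"]] + water)
  expect_equal(molecular_weight("GG"), 2 * m[["G"]] + water)
  # additivity: MW(a + b) = MW(a) + MW(b) - water
  expect_equal(molecular_weight("MKLIV"),
               molecular_weight("MK") + molecular_weight("LIV") - water)
  # one L -> Q substitution adds the difference of the free masses
  expect_equal(molecular_weight("AQA") - molecular_weight("ALA"),
               m[["Q"]] - m[["L"]])
  expect_lt(abs((molecular_weight("AQA") - molecular_weight("ALA")) - 14.97),
            0.01)
  expect_error(molecular_weight("MXK"), "position 2")
})

test_that("net charge follows the Henderson-Hasselbalch sum and is monotone", {
  pka <- pka_table()
  # brute-force re-evaluation for GDG: N-term (G), C-term, one D side chain
  ph <- c(2, 4.05, 7, 10)
  manual <- 1 / (1 + 10^(ph - pka$nterm)) -
    1 / (1 + 10^(pka$cterm - ph)) -
    1 / (1 + 10^(pka$side[["D"]] - ph))
  expect_equal(net_charge("GDG", ph), manual)
  # half-titration: at pH == pKa(D) the aspartate contributes exactly -0.5
  # GG has the same two terminal groups, so the difference isolates the D
  expect_equal(net_charge("GDG", 4.05) - net_charge("GG", 4.05),
               -0.5, tolerance = 1e-12)

  for (seed in 1:10) {
    seq <- random_record(seed)$sequence
    expect_gt(net_charge(seq, 0.5), 0)
    expect_lt(net_charge(seq, 13.5), 0)
    grid <- net_charge(seq, seq(0.5, 13.5, by = 0.25))
    expect_true(all(diff(grid) < 0))
  }
})

test_that("bisection pI matches a dense grid-scan oracle", {
  expect_equal(isoelectric_point("GG"), grid_pi("GG"), tolerance = 2e-4)
  for (seed in 1:20) {
    seq <- random_record(seed)$sequence
    expect_equal(isoelectric_point(seq), grid_pi(seq), tolerance = 2e-4)
  }
  # EMBOSS set gives a different but nearby root
  expect_equal(isoelectric_point("GG", pka = pka_table("emboss")),
               grid_pi("GG", pka = pka_table("emboss")), tolerance = 2e-4)
  expect_lt(abs(net_charge("MKLLIVFAGW", isoelectric_point("MKLLIVFAGW"))),
            1e-3)
})

test_that("acidic residues lower the pI and QTY shifts are bounded", {
  for (seed in 1:10) {
    seq <- random_record(seed)$sequence
    expect_lt(isoelectric_point(paste0(seq, "D")), isoelectric_point(seq))
    q <- qty_apply(random_record(seed))
    expect_lt(abs(isoelectric_point(q$analog) - isoelectric_point(q$native)), 1)
  }
})

test_that("hydropathy profiles are windowed means and drop after QTY", {
  homo <- strrep("I", 30)
  prof <- hydropathy_profile(homo, window = 9)
  expect_true(all(abs(prof$score - kyte_doolittle()[["I"]]) < 1e-12))
  expect_equal(nrow(prof), 30 - 9 + 1)
  expect_equal(prof$position, 5:26)

  one <- hydropathy_profile("MKLLIVFAG", window = 9)
  expect_equal(nrow(one), 1)
  expect_equal(one$score,
               mean(kyte_doolittle()[strsplit("MKLLIVFAG", "")[[1]]]))

  expect_error(hydropathy_profile("MKLLIV", window = 4), "odd")
  expect_error(hydropathy_profile("MKL", window = 19), "exceeds")

  q <- qty_apply(protein_record("toy", "MKLLIVFAGW",
                                tibble::tibble(start = 3, end = 8)))
  pn <- hydropathy_profile(q$native, window = 5)
  pa <- hydropathy_profile(q$analog, window = 5)
  expect_true(all(pa$score <= pn$score + 1e-12))
})

test_that("residue composition is exact and QTY changes only map residues", {
  comp <- residue_composition("MKQ")
  expect_equal(sum(comp$count), 3)
  expect_equal(comp$count[comp$residue %in% c("M", "K", "Q")], c(1L, 1L, 1L))
  expect_error(residue_composition("MBK"), "illegal residue")

  q <- qty_apply(random_record(3))
  cn <- residue_composition(q$native)
  ca <- residue_composition(q$analog)
  changed <- cn$residue[cn$count != ca$count]
  expect_true(all(changed %in% c("L", "I", "V", "F", "Q", "T", "Y")))
})

test_that("characterization table reports near-invariant MW and pI", {
  q <- qty_apply(protein_record("toy", "MKLLIVFAGW",
                                tibble::tibble(start = 3, end = 8)))
  ch <- qty_characterize(q)
  expect_equal(names(ch), c("id", "mw_native", "mw_analog", "pi_native",
                            "pi_analog", "tm_pct", "overall_pct"))
  expect_gt(ch$mw_analog, ch$mw_native)          # Q, T, Y are heavier
  expect_lt(ch$mw_analog - ch$mw_native, 100)
  expect_lt(abs(ch$pi_analog - ch$pi_native), 0.5)
})
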