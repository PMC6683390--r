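neg_table <- function(values, bead = "B", donor = "D1") {
  mfi_table(data.frame(sample_id = sprintf("N%02d", seq_along(values)),
                       donor_id = donor, bead_id = bead, mfi = values,
                       role = "negative_control"))
}

test_that("compute_cutoffs applies mean + 3 sample SD per bead", {
  cs <- compute_cutoffs(neg_table(c(10, 20, 30)))
  expect_equal(cs$neg_mean, 20)
  expect_equal(cs$neg_sd, 10)        # n-1 denominator
  expect_equal(cs$cutoff, 50)
  expect_equal(cs$n_controls, 3L)
  # constant controls: sd 0, cutoff = the constant
  expect_equal(compute_cutoffs(neg_table(rep(75.1, 8)))$cutoff, 75.1)
  # fewer than 2 controls is undefined
  expect_error(compute_cutoffs(neg_table(75.1)), "B", class = "hpadeconv_schema_error")
})

test_that("population sd mode uses the n denominator", {
  cs <- compute_cutoffs(neg_table(c(10, 20, 30)), sd_mode = "population")
  expect_equal(cs$neg_sd, sqrt(200 / 3))
  expect_equal(cs$cutoff, 20 + 3 * sqrt(200 / 3))
})

test_that("compute_cutoffs is permutation-invariant in control ordering", {
  set.seed(7)
  v <- rlnorm(8, 4, 0.3)
  base <- compute_cutoffs(neg_table(v))
  for (i in 1:5) {
    expect_equal(compute_cutoffs(neg_table(sample(v)))$cutoff, base$cutoff)
  }
})

test_that("call_reactivity applies inclusive per-bead cutoffs", {
  pat <- ref_pattern()
  t10 <- reactive_donors(pat, "T10", "GPIa/IIa")
  expect_equal(t10$R, "G4")                     # 1979.27 >= 132.29
  expect_setequal(t10$N, c("G1", "G2", "G3"))
  t8 <- reactive_donors(pat, "T8", "GPIIb/IIIa")
  expect_false("G3" %in% t8$R)                  # 92.82 < 163.46
  # exact equality is reactive (>= is inclusive)
  m <- mfi_table(data.frame(sample_id = "S", donor_id = "D1", bead_id = "B",
                            mfi = 50, role = "test"))
  cs <- cutoff_set(data.frame(bead_id = "B", cutoff = 50))
  pat1 <- call_reactivity(m, cs)
  expect_true(reactive_donors(pat1, "S", "B")$R == "D1")
})

test_that("R and N partition the measured donors; missing cells flagged", {
  pat <- ref_pattern()
  for (s in c("S2", "T8")) {
    for (b in c("GPIa/IIa", "HLA")) {
      rd <- reactive_donors(pat, s, b)
      expect_setequal(c(rd$R, rd$N), c("G1", "G2", "G3", "G4"))
      expect_length(intersect(rd$R, rd$N), 0L)
    }
  }
  m <- ref_mfi()
  m2 <- mfi_table(m[!(m$sample_id == "S2" & m$donor_id == "G4" & m$bead_id == "HLA"), ])
  pat2 <- call_reactivity(m2, ref_cutoffs(), beads = ref_beads())
  rd <- reactive_donors(pat2, "S2", "HLA")
  expect_equal(rd$missing, "G4")
  expect_false("G4" %in% c(rd$R, rd$N))
})

test_that("raising a cutoff never moves a donor from N to R (monotonicity)", {
  m <- ref_mfi()
  base <- ref_cutoffs()
  set.seed(3)
  for (i in 1:10) {
    higher <- base
    higher$cutoff <- higher$cutoff * runif(4, 1, 3)
    r_base <- call_reactivity(m, base, beads = ref_beads())
    r_high <- call_reactivity(m, cutoff_set(higher), beads = ref_beads())
    expect_true(all(!r_base$reactive | is.na(r_base$reactive) |
                      r_high$reactive <= r_base$reactive))
    expect_false(any(r_high$reactive & !r_base$reactive, na.rm = TRUE))
  }
})

test_that("grey zone marks reactive values below grey_factor * cutoff", {
  pat <- ref_pattern()
  s2 <- reactive_donors(pat, "S2", "GPIIb/IIIa")
  expect_equal(s2$R, "G3")          # 186.68 >= 163.46 ...
  expect_equal(s2$borderline, "G3") # ... but < 1.25 * 163.46 = 204.3
  t5 <- reactive_donors(pat, "T5", "GPIIb/IIIa")
  expect_length(t5$borderline, 0L)  # all well above the grey zone
})

test_that("cutoff CSV round-trips", {
  cs <- compute_cutoffs(neg_table(c(40, 55, 62, 70, 48, 52, 58, 61)))
  path <- tempfile(fileext = ".csv")
  write_cutoffs(cs, path)
  back <- read_cutoffs(path)
  expect_equal(back$cutoff, cs$cutoff, tolerance = 1e-12)
  expect_equal(back$n_controls, cs$n_controls)
})

test_that("MFI schema violations are rejected", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,donor_id,bead_id,mfi",
               "S,D1,B,\"1,979.27\""), f)  # thousands separator
  expect_error(read_mfi(f), "thousands", class = "hpadeconv_schema_error")
  writeLines(c("sample_id,donor_id,bead_id,mfi",
               "S,D1,B,10", "S,D1,B,20"), f)  # duplicate triple
  expect_error(read_mfi(f), "duplicate", class = "hpadeconv_schema_error")
  expect_error(
    mfi_table(data.frame(sample_id = "S", donor_id = "D1", bead_id = "B", mfi = -5)),
    ">= 0", class = "hpadeconv_schema_error")
})
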