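test_that("consistent() is the carrier-coverage / non-carrier-exclusion predicate", {
  d <- ref_donors(); b <- ref_beads()
  expect_true(consistent("anti-HPA-3a", "GPIIb/IIIa",
                         R = c("G1", "G2", "G4"), N = "G3", d, b))
  # G3 carries HPA-1a yet is non-reactive: anti-HPA-1a is falsified
  expect_false(consistent("anti-HPA-1a", "GPIIb/IIIa",
                          R = c("G1", "G2", "G4"), N = "G3", d, b))
  # empty pattern, empty explanation
  expect_true(consistent(character(0), "GPIIb/IIIa",
                         R = character(0), N = c("G1", "G2", "G3", "G4"), d, b))
  expect_false(consistent(character(0), "GPIIb/IIIa",
                          R = "G1", N = c("G2", "G3", "G4"), d, b))
  expect_error(consistent("anti-HPA-5a", "GPIIb/IIIa", R = "G1", N = "G2", d, b),
               "subset")
})

test_that("infer_bead finds ranked minimal consistent sets", {
  d <- ref_donors(); b <- ref_beads()
  # sole HPA-5 ab carrier reactive on the GPIa/IIa bead
  sets <- infer_bead("GPIa/IIa", R = "G4", N = c("G1", "G2", "G3"), d, b)
  expect_length(sets, 1L)
  expect_equal(sets[[1]]$specificities, "anti-HPA-5b")
  # all-reactive GPIIb/IIIa on an all-1aa/4aa panel: 1a vs 4a ambiguity,
  # resolved by priors; the 3a+3b mixture survives as a larger explanation
  sets <- infer_bead("GPIIb/IIIa", R = c("G1", "G2", "G3", "G4"), N = character(0), d, b)
  expect_equal(sets[[1]]$specificities, "anti-HPA-1a")
  expect_equal(sets[[2]]$specificities, "anti-HPA-4a")
  expect_gt(sets[[1]]$prior_score, sets[[2]]$prior_score)
  expect_equal(sets[[1]]$cardinality, 1L)
  # borderline lone G3 reactor: no candidate allele separates G3 from the
  # non-reactive HPA-3ab donors -> nothing consistent
  sets <- infer_bead("GPIIb/IIIa", R = "G3", N = c("G1", "G2", "G4"), d, b)
  expect_length(sets, 0L)
  # no reactivity -> no explanation sets
  expect_length(infer_bead("GPIa/IIa", R = character(0),
                           N = c("G1", "G2", "G3", "G4"), d, b), 0L)
  expect_error(infer_bead("GPIa/IIa", R = "G4", N = character(0), d, b,
                          max_set_size = 0), "max_set_size")
})

test_that("every reported set is consistent and minimal (soundness)", {
  d <- ref_donors(); b <- ref_beads()
  donors <- d$donor_id
  for (bead in c("GPIa/IIa", "GPIba/IX", "GPIIb/IIIa")) {
    for (mask in 0:15) {
      R <- donors[bitwAnd(mask, 2^(0:3)) > 0L]
      N <- setdiff(donors, R)
      sets <- infer_bead(bead, R, N, d, b, max_set_size = 3)
      for (s in sets) {
        expect_true(consistent(s$specificities, bead, R, N, d, b))
        if (s$cardinality > 1L) {
          subs <- utils::combn(s$specificities, s$cardinality - 1L, simplify = FALSE)
          expect_false(any(vapply(subs, consistent, logical(1),
                                  bead_id = bead, R = R, N = N,
                                  donors = d, beads = b)))
        }
      }
    }
  }
})

test_that("infer_bead with uncapped size equals the exhaustive oracle", {
  set.seed(202)
  for (rep in 1:200) {
    n <- sample(4:6, 1)
    d <- random_donors(n)
    b <- gp3_beads()
    donors <- d$donor_id
    R <- donors[runif(n) < 0.5]
    N <- setdiff(donors, R)
    got <- infer_bead("GP", R, N, d, b, max_set_size = 6)
    want <- oracle_infer("GP", R, N, d, b)
    expect_same_sets(got, want)
  }
})

test_that("removing a donor never shrinks the consistent-set family", {
  set.seed(99)
  b <- gp3_beads()
  all_subsets <- unlist(lapply(1:6, function(k) {
    utils::combn(candidate_specificities(b, "GP"), k, simplify = FALSE)
  }), recursive = FALSE)
  for (rep in 1:30) {
    d <- random_donors(5)
    R <- d$donor_id[runif(5) < 0.5]
    N <- setdiff(d$donor_id, R)
    keep_full <- vapply(all_subsets, consistent, logical(1),
                        bead_id = "GP", R = R, N = N, donors = d, beads = b)
    drop <- sample(d$donor_id, 1)
    keep_red <- vapply(all_subsets, consistent, logical(1),
                       bead_id = "GP", R = setdiff(R, drop),
                       N = setdiff(N, drop), donors = d, beads = b)
    expect_true(all(keep_red[keep_full]))
  }
})

test_that("infer_hla calls sample-level HLA positivity from any reactive donor", {
  pat <- ref_pattern(); b <- ref_beads()
  t8 <- infer_hla(pat, "T8", b)
  expect_true(t8$positive)
  expect_setequal(t8$reactive_donors, c("G2", "G3", "G4"))  # 3 of 4
  expect_false(infer_hla(pat, "T5", b)$positive)
  zero <- mfi_table(data.frame(sample_id = "Z", donor_id = rep(c("G1", "G2"), 1),
                               bead_id = "HLA", mfi = 0, role = "test"))
  patz <- call_reactivity(zero, ref_cutoffs())
  expect_false(infer_hla(patz, "Z", b)$positive)
})

test_that("call_sample assembles whole-row interpretations", {
  pat <- ref_pattern(); d <- ref_donors(); b <- ref_beads()
  s9 <- call_sample("S9", pat, d, b)
  expect_setequal(s9$final_call, c("anti-HLA", "anti-HPA-3b"))
  s7 <- call_sample("S7", pat, d, b)
  expect_setequal(s7$final_call, c("anti-HPA-5a", "anti-HPA-1a"))
  expect_false(isTRUE(s7$hla_positive))
  # all-zero sample is a clean negative
  zeros <- mfi_table(expand.grid(sample_id = "Z", donor_id = ref_donors()$donor_id,
                                 bead_id = active_beads(b)$bead_id, mfi = 0,
                                 role = "test", stringsAsFactors = FALSE))
  patz <- call_reactivity(zeros, ref_cutoffs(), beads = b)
  z <- call_sample("Z", patz, d, b)
  expect_true(z$negative)
  expect_length(z$final_call, 0L)
  expect_length(grep("uninformative", z$flags, invert = TRUE, value = TRUE), 0L)
})

test_that("borderline-only reactivity is flagged, reported, and kept out of the call", {
  pat <- ref_pattern(); d <- ref_donors(); b <- ref_beads()
  s2 <- call_sample("S2", pat, d, b)
  expect_setequal(s2$final_call, c("anti-HLA", "anti-HPA-2b"))
  expect_true(any(grepl("^borderline_only:GPIIb/IIIa$", s2$flags)))
  expect_true(any(grepl("^unexplained_reactivity:GPIIb/IIIa:G3$", s2$flags)))
})

test_that("concordance compares final calls as sets against a reference", {
  res <- run_reference_fixture()
  expect_equal(res$concordance$n_agree, 9L)
  expect_equal(res$concordance$percent_agreement, 100)

  ref <- read.csv(hpa_fixture("maipa_reference.csv"))
  ref$reference_call[ref$sample_id == "T10"] <- "Anti-HPA-5a"  # deliberate flip
  conc <- concordance(res$calls, ref)
  expect_equal(conc$n_agree, 8L)
  expect_equal(conc$discordant$sample_id, "T10")

  ref2 <- ref[ref$sample_id != "S12", ]  # missing reference sample excluded
  conc2 <- concordance(res$calls, ref2)
  expect_equal(conc2$n_compared, 8L)
  expect_equal(conc2$missing_reference, "S12")

  ref3 <- data.frame(sample_id = "X1", reference_call = "Negative")
  expect_error(concordance(res$calls, ref3), "overlap",
               class = "hpadeconv_schema_error")
})
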