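test_that("carries() follows the allele-carriage relation", {
  d <- ref_donors()
  expect_true(carries(d, "G4", "HPA-5", "b"))    # heterozygote carries b
  expect_false(carries(d, "G3", "HPA-3", "a"))   # bb homozygote lacks a
  expect_true(carries(d, "G1", "HPA-1", "a"))    # aa homozygote carries own allele
  expect_equal(carries(d, c("G1", "G2", "G3", "G4"), "HPA-3", "b"),
               c(TRUE, FALSE, TRUE, TRUE))
  expect_error(carries(d, "G1", "HPA-99", "a"), "HPA-99")
  expect_error(carries(d, "G9", "HPA-1", "a"), "G9")
})

test_that("every donor carries a or b at every system (no null genotype)", {
  set.seed(42)
  for (rep in 1:20) {
    d <- random_donors(5, systems = c("HPA-1", "HPA-2", "HPA-15"))
    for (s in panel_systems(d)) {
      expect_true(all(carries(d, d$donor_id, s, "a") | carries(d, d$donor_id, s, "b")))
    }
  }
})

test_that("candidate_specificities enumerates per bead role", {
  b <- ref_beads()
  expect_setequal(candidate_specificities(b, "GPIa/IIa"),
                  c("anti-HPA-5a", "anti-HPA-5b"))
  expect_equal(candidate_specificities(b, "HLA"), "anti-HLA")
  gp <- candidate_specificities(b, "GPIIb/IIIa")
  expect_length(gp, 6L)  # 2 alleles x 3 systems
  expect_setequal(gp, c("anti-HPA-1a", "anti-HPA-1b", "anti-HPA-3a",
                        "anti-HPA-3b", "anti-HPA-4a", "anti-HPA-4b"))
  expect_error(candidate_specificities(b, "IgG-control"), "positive-control")
  # deterministic and order-independent
  expect_identical(gp, candidate_specificities(b, "GPIIb/IIIa"))
})

test_that("load_panel validates and reports structural limitations", {
  expect_warning(
    panels <- load_panel(hpa_fixture("genotypes_reference.csv")),
    "uninformative"
  )
  expect_equal(nrow(panels$donors), 4L)
  expect_length(panel_systems(panels$donors), 6L)
  act <- active_beads(panels$beads)
  expect_equal(nrow(act), 4L)  # CD109 shipped disabled
  expect_false(panels$beads$enabled[panels$beads$bead_id == "CD109"])
  # the all-HPA-1aa panel makes anti-HPA-1b structurally undetectable
  uninf <- uninformative_specificities(panels$donors, panels$beads)
  expect_true(all(c("anti-HPA-1a", "anti-HPA-1b", "anti-HPA-4a",
                    "anti-HPA-4b", "anti-HPA-5a") %in% uninf))
  expect_false("anti-HPA-2b" %in% uninf)
})

test_that("panel loading rejects malformed inputs", {
  empty <- tempfile(fileext = ".csv")
  writeLines("donor_id,HPA-1", empty)
  expect_error(read_genotypes(empty), class = "hpadeconv_schema_error")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("donor_id,HPA-1", "D1,aa", "D1,ab"), dup)
  expect_error(read_genotypes(dup), "duplicate donor_id")

  badtok <- tempfile(fileext = ".csv")
  writeLines(c("donor_id,HPA-1", "D1,ac"), badtok)
  expect_error(read_genotypes(badtok), "zygosity")

  badbead <- tempfile(fileext = ".yml")
  writeLines(c("beads:",
               "  - bead_id: X", "    code: C", "    target: T",
               "    systems: [HPA-7]", "    role: hpa_capture",
               "    enabled: true"), badbead)
  expect_error(load_panel(hpa_fixture("genotypes_reference.csv"), badbead),
               "not genotyped")
})

test_that("genotype tokens are normalised across dialects", {
  df <- data.frame(donor_id = c("D1", "D2", "D3"),
                   `HPA-1` = c("A/B", "AB", "bb"), check.names = FALSE)
  d <- donor_panel(df)
  expect_equal(d$`HPA-1`, c("ab", "ab", "bb"))
})

test_that("panel round-trips through write/read identically", {
  d <- ref_donors()
  path <- tempfile(fileext = ".csv")
  write_genotypes(d, path)
  expect_identical(read_genotypes(path), d)
})

test_that("resolvable_specificities reports the panel's effective repertoire", {
  rs <- resolvable_specificities(ref_donors(), ref_beads())
  expect_setequal(rs, c("anti-HLA", "anti-HPA-1a", "anti-HPA-2a", "anti-HPA-2b",
                        "anti-HPA-3a", "anti-HPA-3b", "anti-HPA-5a", "anti-HPA-5b"))
  # no carrier on the panel => not resolvable
  expect_false("anti-HPA-1b" %in% rs)
  # shadowed by the higher-prior anti-HPA-1a on an all-reactive bead
  expect_false("anti-HPA-4a" %in% rs)
})

test_that("call strings parse and format round-trip", {
  expect_equal(parse_call_string("Anti-HLA + anti-HPA-2b"),
               c("anti-HLA", "anti-HPA-2b"))
  expect_equal(parse_call_string("negative"), character(0))
  expect_equal(parse_call_string("ANTI-HPA-21WB"), "anti-HPA-21wb")
  expect_error(parse_call_string("anti-GPIIb"), class = "hpadeconv_schema_error")
  b <- ref_beads()
  expect_equal(format_call(c("anti-HPA-1a", "anti-HPA-5a"), b),
               "Anti-HPA-5a + anti-HPA-1a")  # bead-panel order, GPIa bead first
  expect_equal(format_call(c("anti-HPA-3a", "anti-HLA"), b),
               "Anti-HLA + anti-HPA-3a")
  expect_equal(format_call(character(0)), "Negative")
  for (s in c("Anti-HLA + anti-HPA-2b", "Anti-HPA-5a + anti-HPA-1a", "Negative")) {
    expect_equal(format_call(parse_call_string(s), b), s)
  }
})
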