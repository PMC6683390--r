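# Shared fixtures, built in code or loaded from the packaged plain-text data.

ref_donors <- function() reference_donor_panel()
ref_beads <- function() reference_bead_panel()
ref_mfi <- function() read_mfi(hpa_fixture("mfi_reference.csv"))
ref_cutoffs <- function() read_cutoffs(hpa_fixture("cutoffs_reference.csv"))

ref_pattern <- function() {
  call_reactivity(ref_mfi(), ref_cutoffs(), beads = ref_beads())
}

# a random donor panel over the given systems, for property-style tests
random_donors <- function(n_donors, systems = c("HPA-1", "HPA-3", "HPA-4")) {
  df <- data.frame(donor_id = sprintf("D%02d", seq_len(n_donors)))
  for (s in systems) df[[s]] <- sample(c("aa", "ab", "bb"), n_donors, replace = TRUE)
  donor_panel(df)
}

# minimal one-GP-bead panel used by deconvolution property tests
gp3_beads <- function(systems = c("HPA-1", "HPA-3", "HPA-4")) {
  bead_panel(data.frame(
    bead_id = "GP", code = "X-01", target = "GPIIb/IIIa",
    systems = I(list(systems)), role = "hpa_capture", enabled = TRUE,
    stringsAsFactors = FALSE))
}

expect_same_sets <- function(got, want) {
  norm <- function(sets) {
    keys <- vapply(sets, function(s) paste(sort(s$specificities), collapse = "+"),
                   character(1))
    sets[order(keys)]
  }
  got <- norm(got); want <- norm(want)
  expect_equal(length(got), length(want))
  for (i in seq_along(got)) {
    expect_equal(got[[i]]$specificities, want[[i]]$specificities)
  }
  # rank orders must agree too
  expect_equal(vapply(got, `[[`, integer(1), "rank"),
               vapply(want, `[[`, integer(1), "rank"))
}
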