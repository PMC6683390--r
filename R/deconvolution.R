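#' Prior plausibility weights for specificities
#'
#' Same-cardinality candidate explanations of a reactivity pattern are ranked
#' by prior plausibility (product of per-specificity weights in `[0,1]`).
#' The shipped defaults encode relative population polymorphism and
#' reported-antibody frequency — in particular, HPA-4, HPA-6 and HPA-21w
#' alloantibodies get very low weight, so an all-reactive GPIIb/IIIa bead on
#' an all-`HPA-1aa/4aa` panel resolves to anti-HPA-1a over anti-HPA-4a in an
#' auditable, configurable way rather than by a hard-coded rule.
#'
#' @return Data frame `specificity, weight` of class `prior_table`.
#' @export
default_priors <- function() {
  read_priors(hpa_fixture("priors.csv"))
}

#' @rdname default_priors
#' @param path CSV path with columns `specificity, weight`.
#' @export
read_priors <- function(path) {
  df <- read_csv_checked(path, required = c("specificity", "weight"))
  df$specificity <- as.character(df$specificity)
  df$weight <- as.numeric(df$weight)
  spec_fields(df$specificity)  # validates labels
  if (anyDuplicated(df$specificity)) stop_schema("duplicate specificity in priors")
  if (any(!is.finite(df$weight)) || any(df$weight < 0 | df$weight > 1)) {
    stop_schema("prior weights must lie in [0, 1]")
  }
  class(df) <- c("prior_table", "data.frame")
  df
}

prior_weight <- function(priors, specs) {
  if (length(specs) == 0L) return(numeric(0))
  w <- priors$weight[match(specs, priors$specificity)]
  if (anyNA(w)) {
    stop_schema("no prior weight for specificity(ies): ",
                paste(specs[is.na(w)], collapse = ", "))
  }
  w
}

#' Consistency of a specificity set with a reactivity pattern
#'
#' A set of candidate specificities explains one bead's reactivity pattern
#' when (i) every reactive donor carries at least one of the implicated
#' alleles — so the antibody has an antigen to bind on that donor's captured
#' glycoprotein — and (ii) no non-reactive donor carries any of them — a
#' carrier that failed to react would falsify the hypothesis. This is the
#' formal version of reading an assay plate against the donor genotype table.
#'
#' @param spec_set Character vector of anti-HPA specificity labels (subset of
#'   the bead's candidates).
#' @param bead_id Glycoprotein-capture bead identifier.
#' @param R,N Character vectors of reactive / non-reactive donor ids
#'   (disjoint; together the measured donors).
#' @param donors A [donor_panel].
#' @param beads A [bead_panel].
#' @return `TRUE` or `FALSE` (pure predicate; no side effects).
#' @examples
#' d <- reference_donor_panel(); b <- reference_bead_panel()
#' consistent("anti-HPA-3a", "GPIIb/IIIa", R = c("G1", "G2", "G4"), N = "G3", d, b)
#' @export
consistent <- function(spec_set, bead_id, R, N, donors, beads) {
  stopifnot(length(intersect(R, N)) == 0L)
  cands <- candidate_specificities(beads, bead_id)
  if (!all(spec_set %in% cands)) {
    stop("specificity set is not a subset of bead '", bead_id, "' candidates")
  }
  if (length(spec_set) == 0L) return(length(R) == 0L)
  fl <- spec_fields(spec_set)
  covered <- rep(FALSE, length(R))
  hit_N <- rep(FALSE, length(N))
  for (i in seq_len(nrow(fl))) {
    if (length(R) > 0L) covered <- covered | carries(donors, R, fl$system[i], fl$allele[i])
    if (length(N) > 0L) hit_N <- hit_N | carries(donors, N, fl$system[i], fl$allele[i])
  }
  all(covered) && !any(hit_N)
}

rank_sets <- function(sets, priors) {
  if (length(sets) == 0L) return(list())
  card <- vapply(sets, length, integer(1))
  score <- vapply(sets, function(s) prod(prior_weight(priors, s)), numeric(1))
  key <- vapply(sets, function(s) paste(sort(s), collapse = "+"), character(1))
  ord <- order(card, -score, key)
  lapply(seq_along(ord), function(r) {
    i <- ord[r]
    list(specificities = sort(sets[[i]]), cardinality = card[i],
         prior_score = score[i], rank = r)
  })
}

#' Minimal consistent specificity sets for one bead
#'
#' Enumerates subsets of the bead's candidate specificities in cardinality
#' order up to `max_set_size`, keeps those consistent with the observed
#' reactive/non-reactive donor partition, discards non-minimal sets (a set is
#' reported only if no proper subset already explains the pattern), and ranks
#' the survivors: fewest specificities first (parsimony), then higher prior
#' score, then lexicographically. An empty result for a non-empty reactive
#' set means no candidate combination explains the pattern — callers raise an
#' `unexplained_reactivity` flag.
#'
#' @inheritParams consistent
#' @param priors A [default_priors()]-style table.
#' @param max_set_size Largest explanation considered (default 2; one
#'   antibody per glycoprotein is the overwhelmingly common case, two covers
#'   every mixture reported for this assay class).
#' @return List of ranked explanations, each
#'   `list(specificities, cardinality, prior_score, rank)`; empty when
#'   `R` is empty or nothing is consistent.
#' @export
infer_bead <- function(bead_id, R, N, donors, beads,
                       priors = default_priors(), max_set_size = 2) {
  if (max_set_size < 1) stop("max_set_size must be >= 1")
  if (length(R) == 0L) return(list())
  cands <- candidate_specificities(beads, bead_id)
  kept <- list()
  for (k in seq_len(min(max_set_size, length(cands)))) {
    idx <- utils::combn(length(cands), k)
    for (j in seq_len(ncol(idx))) {
      s <- cands[idx[, j]]
      # enumeration is in cardinality order, so any kept subset proves s non-minimal
      if (any(vapply(kept, function(m) all(m %in% s), logical(1)))) next
      if (consistent(s, bead_id, R, N, donors, beads)) kept <- c(kept, list(s))
    }
  }
  rank_sets(kept, priors)
}

#' Exhaustive-enumeration oracle for [infer_bead()]
#'
#' Brute force over all `2^k` candidate subsets with minimality established
#' by pairwise subset tests. Independent of the incremental search in
#' [infer_bead()]; intended for validation, hence the hard bound on
#' candidate count.
#'
#' @inheritParams infer_bead
#' @return Same structure as [infer_bead()].
#' @export
oracle_infer <- function(bead_id, R, N, donors, beads, priors = default_priors()) {
  cands <- candidate_specificities(beads, bead_id)
  if (length(cands) > 12L) stop("oracle_infer supports at most 12 candidates")
  if (length(R) == 0L) return(list())
  subsets <- list()
  for (mask in seq_len(2^length(cands)) - 1L) {
    s <- cands[bitwAnd(mask, 2^(seq_along(cands) - 1L)) > 0L]
    if (length(s) > 0L && consistent(s, bead_id, R, N, donors, beads)) {
      subsets <- c(subsets, list(s))
    }
  }
  minimal <- Filter(function(s) {
    !any(vapply(subsets, function(t) length(t) < length(s) && all(t %in% s), logical(1)))
  }, subsets)
  rank_sets(minimal, priors)
}

#' Sample-level HLA antibody positivity
#'
#' A sample is anti-HLA positive when at least one panel donor reacts on the
#' HLA-capture bead. Partial patterns are expected — reactivity depends on
#' the (untyped) HLA phenotype of each donor — so the per-donor pattern is
#' reported but not interpreted further.
#'
#' @param pattern A [call_reactivity()] result.
#' @param sample_id Sample identifier.
#' @param beads A [bead_panel] with an active `hla_capture` bead.
#' @return List `positive` (logical), `reactive_donors`, `bead_id`; or
#'   `positive = NA` when no HLA bead is active.
#' @export
infer_hla <- function(pattern, sample_id, beads) {
  hla <- active_beads(beads, "hla_capture")
  if (nrow(hla) == 0L) {
    return(list(positive = NA, reactive_donors = character(0), bead_id = NA_character_))
  }
  rd <- reactive_donors(pattern, sample_id, hla$bead_id[1])
  list(positive = length(rd$R) > 0L, reactive_donors = rd$R, bead_id = hla$bead_id[1])
}

#' Deconvolve one sample's antibody specificities
#'
#' Combines the per-bead minimal consistent sets into a sample-level call:
#' the final call is the union of each glycoprotein bead's rank-1 explanation
#' plus `anti-HLA` when the HLA bead is positive. Beads whose reactive donors
#' are all in the borderline grey zone contribute their candidate sets to the
#' report but are excluded from the final call (`borderline_only` flag);
#' reactive beads with no consistent explanation raise
#' `unexplained_reactivity`. Structurally uninformative specificities of the
#' panel are attached to every call so a negative result is never over-read.
#'
#' @inheritParams infer_hla
#' @param donors A [donor_panel].
#' @param priors Prior table for ranking.
#' @param max_set_size Passed to [infer_bead()].
#' @return Object of class `specificity_call`.
#' @export
call_sample <- function(sample_id, pattern, donors, beads,
                        priors = default_priors(), max_set_size = 2) {
  gp <- active_beads(beads, "hpa_capture")
  flags <- character(0)
  per_bead <- list()
  final <- character(0)
  any_reactive <- FALSE
  for (b in gp$bead_id) {
    rd <- reactive_donors(pattern, sample_id, b)
    if (length(rd$missing) > 0L) {
      flags <- c(flags, paste0("missing_measurement:", b, ":",
                               paste(rd$missing, collapse = ",")))
    }
    sets <- infer_bead(b, rd$R, rd$N, donors, beads, priors, max_set_size)
    per_bead[[b]] <- list(R = rd$R, N = rd$N, borderline = rd$borderline, sets = sets)
    if (length(rd$R) == 0L) next
    any_reactive <- TRUE
    borderline_only <- length(setdiff(rd$R, rd$borderline)) == 0L
    if (length(sets) == 0L) {
      flags <- c(flags, paste0("unexplained_reactivity:", b, ":",
                               paste(rd$R, collapse = ",")))
    }
    if (borderline_only) {
      flags <- c(flags, paste0("borderline_only:", b))
      next  # reported above, but never promoted to the final call
    }
    if (length(sets) > 0L) {
      final <- union(final, sets[[1]]$specificities)
    }
  }
  hla <- infer_hla(pattern, sample_id, beads)
  if (isTRUE(hla$positive)) {
    any_reactive <- TRUE
    final <- union(final, spec_hla())
  }
  uninf <- uninformative_specificities(donors, beads)
  for (u in uninf) flags <- c(flags, paste0("uninformative:", u))
  structure(list(sample_id = sample_id,
                 per_bead = per_bead,
                 hla_positive = hla$positive,
                 hla_reactive_donors = hla$reactive_donors,
                 final_call = sort(final),
                 negative = !any_reactive,
                 flags = flags),
            class = "specificity_call")
}

#' @export
format.specificity_call <- function(x, beads = NULL, ...) {
  format_call(x$final_call, beads)
}

#' @export
print.specificity_call <- function(x, ...) {
  cat(x$sample_id, ": ", format(x), "\n", sep = "")
  op <- Filter(function(f) !startsWith(f, "uninformative:"), x$flags)
  if (length(op) > 0L) cat("  flags: ", paste(op, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Deconvolve every test sample in a reactivity pattern
#'
#' @inheritParams call_sample
#' @return Named list of [call_sample()] results, class
#'   `specificity_call_set`, in first-appearance sample order.
#' @export
call_samples <- function(pattern, donors, beads,
                         priors = default_priors(), max_set_size = 2) {
  samples <- unique(pattern$sample_id)
  calls <- lapply(samples, call_sample, pattern = pattern, donors = donors,
                  beads = beads, priors = priors, max_set_size = max_set_size)
  structure(stats::setNames(calls, samples), class = "specificity_call_set")
}

#' @export
print.specificity_call_set <- function(x, ...) {
  for (cl in x) print(cl)
  invisible(x)
}

#' Flatten calls to a summary table
#'
#' @param x A `specificity_call_set`.
#' @param beads Optional bead panel for display ordering of call strings.
#' @param ... Unused.
#' @return Data frame `sample_id, final_call, flags`.
#' @export
as.data.frame.specificity_call_set <- function(x, beads = NULL, ...) {
  data.frame(
    sample_id = vapply(x, `[[`, character(1), "sample_id"),
    final_call = vapply(x, function(cl) format_call(cl$final_call, beads), character(1)),
    flags = vapply(x, function(cl) paste(cl$flags, collapse = ";"), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Concordance against a reference method
#'
#' Compares final calls with a reference-method (e.g. MAIPA) call table by
#' set equality of the parsed specificity sets. Samples absent from the
#' reference are listed and excluded from the denominator; an empty overlap
#' of sample ids is an error.
#'
#' @param calls A `specificity_call_set`.
#' @param reference Data frame `sample_id, reference_call` (call strings in
#'   the `"Anti-HLA + anti-HPA-2b"` dialect, `"Negative"` allowed), or a CSV
#'   path to one.
#' @return List of class `concordance_report`: `n_compared`, `n_agree`,
#'   `percent_agreement`, `discordant` (data frame), `missing_reference`
#'   (sample ids without a reference call).
#' @export
concordance <- function(calls, reference) {
  if (is.character(reference) && length(reference) == 1L) {
    reference <- read_csv_checked(reference, required = c("sample_id", "reference_call"))
  }
  if (!all(c("sample_id", "reference_call") %in% names(reference))) {
    stop_schema("reference table needs columns sample_id, reference_call")
  }
  reference$sample_id <- as.character(reference$sample_id)
  sample_ids <- vapply(calls, `[[`, character(1), "sample_id")
  shared <- intersect(sample_ids, reference$sample_id)
  if (length(shared) == 0L) {
    stop_schema("no overlap between called samples and reference sample ids")
  }
  missing_ref <- setdiff(sample_ids, reference$sample_id)
  rows <- lapply(shared, function(s) {
    ours <- calls[[which(sample_ids == s)]]$final_call
    theirs <- parse_call_string(reference$reference_call[match(s, reference$sample_id)])
    data.frame(sample_id = s,
               call = format_call(ours),
               reference_call = format_call(theirs),
               agree = setequal(ours, theirs),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(n_compared = nrow(tab),
                 n_agree = sum(tab$agree),
                 percent_agreement = 100 * mean(tab$agree),
                 discordant = tab[!tab$agree, , drop = FALSE],
                 missing_reference = missing_ref,
                 table = tab),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance: %d/%d samples agree (%.1f%%)\n",
              x$n_agree, x$n_compared, x$percent_agreement))
  if (nrow(x$discordant) > 0L) {
    cat("Discordant:\n")
    print.data.frame(x$discordant, row.names = FALSE)
  }
  if (length(x$missing_reference) > 0L) {
    cat("No reference call (excluded):", paste(x$missing_reference, collapse = ", "), "\n")
  }
  invisible(x)
}
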