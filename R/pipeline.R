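#' Run the full interpretation pipeline
#'
#' End-to-end, deterministic execution of the assay's interpretation stages:
#' load panels, obtain per-bead cutoffs (either supplied directly or computed
#' from the negative-control sera in the MFI table — exactly one of the two),
#' call bead-by-donor reactivity, deconvolve specificities per sample, and
#' optionally compare against a reference-method call table.
#'
#' @param mfi An [mfi_table] or CSV path.
#' @param donors A [donor_panel] or genotype CSV path.
#' @param beads A [bead_panel] or YAML config path (default: packaged panel).
#' @param cutoffs A [cutoff_set], a cutoff CSV path, or `NULL` to compute
#'   cutoffs from rows with role `negative_control` in `mfi`. Supplying both
#'   a cutoff set and negative controls (or neither) is an error.
#' @param priors Prior table or CSV path (default shipped priors).
#' @param reference Optional reference-call data frame or CSV path for
#'   [concordance()].
#' @param grey_factor,max_set_size,sd_mode Tuning knobs passed through to
#'   [call_reactivity()], [call_samples()] and [compute_cutoffs()].
#' @param out_dir Optional directory; when given, the JSON report, the flat
#'   CSV call summary and the cutoffs used are written there with stable
#'   ordering (same inputs, same bytes).
#' @param verbose Log each stage and every tie-break / flag decision to
#'   `message()` in `key=value` form.
#' @return List of class `pipeline_result`: `cutoffs`, `pattern`, `calls`,
#'   `summary` (data frame), `concordance` (or `NULL`), `n_positive`,
#'   `n_dual_positive`.
#' @export
run_pipeline <- function(mfi, donors, beads = hpa_fixture("bead_panel.yml"),
                         cutoffs = NULL, priors = default_priors(),
                         reference = NULL, grey_factor = 1.25,
                         max_set_size = 2, sd_mode = "sample",
                         out_dir = NULL, verbose = FALSE) {
  log_info <- function(...) if (verbose) message("pipeline ", ...)
  if (is.character(donors)) donors <- read_genotypes(donors)
  if (is.character(beads)) beads <- read_bead_config(beads)
  if (is.character(priors)) priors <- read_priors(priors)
  if (is.character(mfi)) mfi <- read_mfi(mfi, donors = donors, beads = beads)
  mfi <- mfi_table(as.data.frame(mfi), donors = donors, beads = beads)
  has_controls <- any(mfi$role == "negative_control")
  if (is.null(cutoffs) && !has_controls) {
    stop_schema("no cutoff source: supply a cutoff set or negative_control samples")
  }
  if (!is.null(cutoffs) && has_controls) {
    stop_schema("ambiguous cutoff source: both a cutoff set and negative_control ",
                "samples supplied; use exactly one")
  }
  if (is.null(cutoffs)) {
    cutoffs <- compute_cutoffs(mfi, beads = beads, sd_mode = sd_mode)
    log_info("stage=cutoffs source=negative_controls n_beads=", nrow(cutoffs))
  } else {
    if (is.character(cutoffs)) cutoffs <- read_cutoffs(cutoffs)
    log_info("stage=cutoffs source=supplied n_beads=", nrow(cutoffs))
  }
  pattern <- call_reactivity(mfi, cutoffs, beads = beads, grey_factor = grey_factor)
  calls <- call_samples(pattern, donors, beads, priors = priors,
                        max_set_size = max_set_size)
  if (verbose) {
    for (cl in calls) {
      log_info("stage=call sample=", cl$sample_id,
               " final=\"", format_call(cl$final_call, beads), "\"",
               if (length(cl$flags) > 0L)
                 paste0(" flags=\"", paste(cl$flags, collapse = ";"), "\"") else "")
      for (b in names(cl$per_bead)) {
        sets <- cl$per_bead[[b]]$sets
        if (length(sets) > 1L) {
          log_info("stage=tiebreak sample=", cl$sample_id, " bead=", b,
                   " rank1=", paste(sets[[1]]$specificities, collapse = "+"),
                   " rank2=", paste(sets[[2]]$specificities, collapse = "+"),
                   " by=", if (sets[[1]]$cardinality < sets[[2]]$cardinality)
                     "parsimony" else "prior")
        }
      }
    }
  }
  conc <- if (!is.null(reference)) concordance(calls, reference) else NULL
  summary_df <- as.data.frame(calls, beads = beads)
  positive <- !vapply(calls, `[[`, logical(1), "negative")
  dual <- vapply(calls, function(cl) {
    isTRUE(cl$hla_positive) && any(!spec_is_hla(cl$final_call))
  }, logical(1))
  res <- structure(list(cutoffs = cutoffs, pattern = pattern, calls = calls,
                        summary = summary_df, concordance = conc,
                        n_positive = sum(positive),
                        n_dual_positive = sum(dual)),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(res, file.path(out_dir, "report.json"))
    utils::write.csv(summary_df, file.path(out_dir, "calls.csv"),
                     row.names = FALSE, quote = TRUE)
    write_cutoffs(cutoffs, file.path(out_dir, "cutoffs.csv"))
    log_info("stage=write out_dir=", out_dir)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", length(x$calls), "samples,",
      x$n_positive, "antibody-positive,",
      x$n_dual_positive, "HPA+HLA dual-positive\n")
  print.data.frame(x$summary, row.names = FALSE)
  if (!is.null(x$concordance)) print(x$concordance)
  invisible(x)
}

#' Write the machine-readable run report
#'
#' JSON with schema version, cutoffs, per-sample final calls, ranked
#' per-bead candidate sets and flags. Ordering is stable so identical inputs
#' give byte-identical reports.
#'
#' @param result A [run_pipeline()] result.
#' @param path Output path.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  samples <- lapply(result$calls, function(cl) {
    list(sample_id = cl$sample_id,
         final_call = format_call(cl$final_call),
         specificities = as.list(cl$final_call),
         negative = cl$negative,
         hla_positive = cl$hla_positive,
         hla_reactive_donors = as.list(cl$hla_reactive_donors),
         flags = as.list(cl$flags),
         beads = lapply(cl$per_bead, function(pb) {
           list(reactive = as.list(pb$R), non_reactive = as.list(pb$N),
                borderline = as.list(pb$borderline),
                candidate_sets = lapply(pb$sets, function(s) {
                  list(specificities = as.list(s$specificities),
                       cardinality = s$cardinality,
                       prior_score = s$prior_score, rank = s$rank)
                }))
         }))
  })
  report <- list(schema = "hpadeconv-report/1",
                 cutoffs = as.data.frame(result$cutoffs),
                 n_positive = result$n_positive,
                 n_dual_positive = result$n_dual_positive,
                 samples = unname(samples))
  if (!is.null(result$concordance)) {
    report$concordance <- list(
      n_compared = result$concordance$n_compared,
      n_agree = result$concordance$n_agree,
      percent_agreement = result$concordance$percent_agreement,
      discordant = result$concordance$discordant)
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the packaged reference fixture end to end
#'
#' Applies the published per-bead cutoffs to the packaged nine-sample panel
#' (four genotyped donors, four active beads), deconvolves every sample, and
#' compares against the packaged reference-method calls. This is the
#' package's primary validation surface.
#'
#' @param verbose Passed to [run_pipeline()].
#' @return A [run_pipeline()] result (with `concordance` filled in).
#' @examples
#' res <- run_reference_fixture()
#' res$summary
#' @export
run_reference_fixture <- function(verbose = FALSE) {
  panels <- load_panel(hpa_fixture("genotypes_reference.csv"),
                       hpa_fixture("bead_panel.yml"), quiet = TRUE)
  run_pipeline(mfi = hpa_fixture("mfi_reference.csv"),
               donors = panels$donors, beads = panels$beads,
               cutoffs = hpa_fixture("cutoffs_reference.csv"),
               reference = hpa_fixture("maipa_reference.csv"),
               verbose = verbose)
}
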