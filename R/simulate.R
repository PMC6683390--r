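#' Configuration of the synthetic assay generator
#'
#' The simulator emulates the statistical structure of the bead assay's
#' output: positive (antibody-bound) cells draw log-normal MFIs around
#' `10^signal_log10_mean` (defaults: 10^3 with log10-sd 0.3, i.e. positives
#' 1-2 decades above background, as in real plates), negative cells draw
#' from a normal truncated at zero (defaults: mean 60, sd 25, matching
#' typical negative wells), HLA-bead reactivity of a donor for an anti-HLA
#' sample is Bernoulli (default 0.75 — partial patterns are the norm because
#' donor HLA types differ), and dilution series decay geometrically with
#' per-doubling retention `rho` (default 0.65, the step ratio of real
#' standard-serum series).
#'
#' @param truth Named list: `sample_id -> character vector` of true
#'   specificity labels (empty vector = antibody-negative sample).
#' @param donors A [donor_panel].
#' @param beads A [bead_panel]. Truth specificities must resolve against its
#'   *enabled* beads; a specificity whose system lives only on a disabled
#'   bead is an error.
#' @param signal_log10_mean,signal_log10_sd Log10 location / scale of
#'   positive MFIs.
#' @param background_mean,background_sd Location / scale of the truncated
#'   normal background (sd 0 gives a deterministic background).
#' @param hla_reactive_fraction Per-donor Bernoulli probability that an
#'   anti-HLA sample reacts on the HLA bead.
#' @param dilution_rho Per-doubling signal retention in (0, 1).
#' @param n_negative_controls Number of negative-control sera to simulate
#'   (default 8, the usual validation panel size).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(truth, donors, beads,
                              signal_log10_mean = 3, signal_log10_sd = 0.3,
                              background_mean = 60, background_sd = 25,
                              hla_reactive_fraction = 0.75,
                              dilution_rho = 0.65,
                              n_negative_controls = 8, seed = 1L) {
  stopifnot(inherits(donors, "donor_panel"), inherits(beads, "bead_panel"),
            is.list(truth), length(truth) > 0L, !is.null(names(truth)),
            signal_log10_sd >= 0, background_sd >= 0,
            hla_reactive_fraction >= 0, hla_reactive_fraction <= 1,
            dilution_rho > 0, dilution_rho < 1, n_negative_controls >= 0)
  act <- active_beads(beads)
  gp <- act[act$role == "hpa_capture", ]
  enabled_systems <- unique(unlist(gp$systems))
  has_hla <- any(act$role == "hla_capture")
  for (s in names(truth)) {
    specs <- truth[[s]]
    if (length(specs) == 0L) next
    fl <- spec_fields(specs)
    if (any(fl$kind == "anti-HLA") && !has_hla) {
      stop_schema("truth for sample '", s, "' needs an active HLA bead")
    }
    off <- setdiff(fl$system[fl$kind == "anti-HPA"], enabled_systems)
    if (length(off) > 0L) {
      stop_schema("truth for sample '", s, "' references system(s) with no ",
                  "enabled bead: ", paste(off, collapse = ", "))
    }
  }
  structure(list(truth = truth, donors = donors, beads = beads,
                 signal_log10_mean = signal_log10_mean,
                 signal_log10_sd = signal_log10_sd,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 hla_reactive_fraction = hla_reactive_fraction,
                 dilution_rho = dilution_rho,
                 n_negative_controls = n_negative_controls,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# normal truncated at 0 by inverse-CDF; degenerates cleanly at sd = 0
rtrunc0 <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Simulate an assay plate
#'
#' For every (sample, donor, active bead) cell the expected reactivity is
#' derived from the truth via the antigen-carriage relation (glycoprotein
#' beads) or a per-donor Bernoulli draw (HLA bead); reactive cells then draw
#' from the signal model, all others from the background model.
#' Negative-control sera draw background everywhere. Fully reproducible from
#' the config seed.
#'
#' @param config A [simulation_config].
#' @return List: `mfi` (an [mfi_table] with roles `test` /
#'   `negative_control`), `truth` (data frame `sample_id, truth_call` with
#'   canonical call strings), `expected` (logical expected-reactivity column
#'   bound to the test grid, for diagnostics).
#' @export
simulate_assay <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  act <- active_beads(config$beads)
  donors <- config$donors
  grid <- expand.grid(donor_id = donors$donor_id, bead_id = act$bead_id,
                      sample_id = names(config$truth),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("sample_id", "bead_id", "donor_id")]
  role <- stats::setNames(act$role, act$bead_id)
  systems <- stats::setNames(act$systems, act$bead_id)
  expected <- logical(nrow(grid))
  for (s in names(config$truth)) {
    specs <- config$truth[[s]]
    if (length(specs) == 0L) next
    fl <- spec_fields(specs)
    for (b in act$bead_id) {
      sel <- grid$sample_id == s & grid$bead_id == b
      if (role[[b]] == "hla_capture") {
        if (any(fl$kind == "anti-HLA")) {
          expected[sel] <- stats::runif(sum(sel)) < config$hla_reactive_fraction
        }
      } else {
        hpa <- fl[fl$kind == "anti-HPA" & fl$system %in% systems[[b]], , drop = FALSE]
        if (nrow(hpa) > 0L) {
          hit <- rep(FALSE, sum(sel))
          for (i in seq_len(nrow(hpa))) {
            hit <- hit | carries(donors, grid$donor_id[sel], hpa$system[i], hpa$allele[i])
          }
          expected[sel] <- hit
        }
      }
    }
  }
  mfi <- numeric(nrow(grid))
  n_pos <- sum(expected)
  mfi[expected] <- 10^stats::rnorm(n_pos, config$signal_log10_mean, config$signal_log10_sd)
  mfi[!expected] <- rtrunc0(nrow(grid) - n_pos, config$background_mean, config$background_sd)
  grid$mfi <- mfi
  grid$role <- "test"
  if (config$n_negative_controls > 0L) {
    nc_ids <- sprintf("NC%02d", seq_len(config$n_negative_controls))
    nc <- expand.grid(donor_id = donors$donor_id, bead_id = act$bead_id,
                      sample_id = nc_ids, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
    nc <- nc[, c("sample_id", "bead_id", "donor_id")]
    nc$mfi <- rtrunc0(nrow(nc), config$background_mean, config$background_sd)
    nc$role <- "negative_control"
    grid <- rbind(grid, nc)
  }
  truth_df <- data.frame(
    sample_id = names(config$truth),
    truth_call = vapply(config$truth, format_call, character(1), beads = config$beads),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(mfi = mfi_table(grid[, c("sample_id", "donor_id", "bead_id", "mfi", "role")],
                       donors = donors, beads = config$beads),
       truth = truth_df,
       expected = cbind(grid[grid$role == "test", c("sample_id", "bead_id", "donor_id")],
                        expected = expected))
}

#' Simulate a two-fold dilution series
#'
#' MFI at dilution factor `f` is `background_mean + amplitude * rho^log2(f)`
#' plus optional Gaussian noise — geometric decay of the specific signal on
#' top of a constant background, the shape real standard-serum titrations
#' follow. Factors must be powers of two (the standard doubling scheme);
#' anything else is an error.
#'
#' @param config A [simulation_config] (supplies background, `dilution_rho`).
#' @param bead_id Target bead label for the series.
#' @param amplitude Neat specific signal above background (> 0; the base
#'   sample must be reactive on the target bead).
#' @param factors Dilution factors, powers of two starting at 1.
#' @param noise_sd Gaussian noise sd (default 0 = noise-free).
#' @param sample_id Label for the series.
#' @return A [dilution_series].
#' @export
simulate_dilution <- function(config, bead_id, amplitude, factors,
                              noise_sd = 0, sample_id = "dilution_std") {
  stopifnot(inherits(config, "simulation_config"))
  if (amplitude <= 0) stop_schema("base sample must be reactive: amplitude must be > 0")
  k <- log2(factors)
  if (any(factors < 1) || any(abs(k - round(k)) > 1e-9)) {
    stop_schema("dilution factors must be powers of two starting at 1 (doubling scheme)")
  }
  set.seed(config$seed)
  mu <- config$background_mean + amplitude * config$dilution_rho^k
  mfi <- pmax(0, mu + stats::rnorm(length(mu), 0, noise_sd))
  dilution_series(sample_id, bead_id, factors, mfi)
}

#' Analytic endpoint of a noise-free decay series
#'
#' Closed-form counterpart of [endpoint_titer()] under the
#' [simulate_dilution()] model: the largest power-of-two factor `f = 2^k`
#' with `background + amplitude * rho^k >= cutoff`, restricted to the
#' measured factors; 0 when even the neat point is below the cutoff.
#'
#' @param amplitude,rho,background Decay-model parameters.
#' @param cutoff Positivity cutoff.
#' @param factors Measured dilution factors (powers of two).
#' @return List `titer`, `censored` (mirrors [endpoint_titer()] semantics).
#' @export
analytic_titer <- function(amplitude, rho, background, cutoff, factors) {
  stopifnot(amplitude > 0, rho > 0, rho < 1)
  k <- log2(factors)
  if (background >= cutoff) {
    return(list(titer = max(factors), censored = TRUE))
  }
  # rho^k >= (cutoff - background) / amplitude  <=>  k <= log(ratio)/log(rho)
  ratio <- (cutoff - background) / amplitude
  if (ratio > 1) {
    return(list(titer = 0L, censored = FALSE))
  }
  k_max <- floor(log(ratio) / log(rho) + 1e-12)
  pos <- factors[k <= k_max]
  if (length(pos) == 0L) {
    return(list(titer = 0L, censored = FALSE))
  }
  list(titer = max(pos), censored = max(pos) == max(factors))
}

#' Draw a random truth table from the panel's resolvable repertoire
#'
#' Convenience truth sampler for validation studies: each sample is
#' antibody-negative with probability `p_negative`; otherwise it carries an
#' anti-HLA component with probability `p_hla` and zero, one or two HPA
#' specificities drawn from [resolvable_specificities()] (two only from
#' different beads — two specificities on one glycoprotein collapse into a
#' single parsimonious explanation and are not recoverable by design).
#'
#' @param n Number of test samples.
#' @param donors,beads Panels.
#' @param seed Integer seed.
#' @param p_negative,p_hla,p_second_hpa Mixture probabilities.
#' @return Named list suitable as the `truth` of [simulation_config()].
#' @export
simulate_truth_table <- function(n, donors, beads, seed = 1L,
                                 p_negative = 0.15, p_hla = 0.35,
                                 p_second_hpa = 0.15) {
  set.seed(seed)
  repertoire <- resolvable_specificities(donors, beads)
  hpa_specs <- repertoire[!spec_is_hla(repertoire)]
  has_hla <- any(spec_is_hla(repertoire))
  if (length(hpa_specs) == 0L) stop("panel resolves no HPA specificity")
  fl <- spec_fields(hpa_specs)
  bead_of <- vapply(fl$system, function(s) {
    gp <- active_beads(beads, "hpa_capture")
    gp$bead_id[which(vapply(gp$systems, function(sys) s %in% sys, logical(1)))[1]]
  }, character(1))
  truth <- vector("list", n)
  names(truth) <- sprintf("SIM%03d", seq_len(n))
  for (i in seq_len(n)) {
    if (stats::runif(1) < p_negative) {
      truth[[i]] <- character(0)
      next
    }
    hla <- has_hla && stats::runif(1) < p_hla
    n_hpa <- if (hla) sample(0:2, 1, prob = c(0.25, 0.60, 0.15)) else
      sample(1:2, 1, prob = c(0.85, 0.15))
    specs <- if (hla) spec_hla() else character(0)
    if (n_hpa >= 1L) {
      first <- sample(hpa_specs, 1)
      specs <- c(specs, first)
      if (n_hpa == 2L) {
        other <- hpa_specs[bead_of != bead_of[match(first, hpa_specs)]]
        if (length(other) > 0L) specs <- c(specs, sample(other, 1))
      }
    }
    truth[[i]] <- specs
  }
  truth
}
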