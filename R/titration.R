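#' Serial dilution series
#'
#' An ordered set of (dilution factor, MFI) points for one sample on one
#' bead. Factors are reciprocals of the dilution (1 = neat, 2 = 1:2, ...);
#' they must be strictly increasing positive integers and, when a neat point
#' is present, it must come first.
#'
#' @param sample_id,bead_id Identifiers.
#' @param factors Integer vector of dilution factors, strictly increasing.
#' @param mfi Numeric vector of MFI values (same length, all >= 0).
#' @return Object of class `dilution_series`.
#' @examples
#' dilution_series("std", "GPIIb/IIIa", c(1, 2, 4), c(16878.5, 12786.5, 9112))
#' @export
dilution_series <- function(sample_id, bead_id, factors, mfi) {
  factors <- as.numeric(factors)
  if (length(factors) == 0L || length(factors) != length(mfi)) {
    stop_schema("dilution series needs matching, non-empty factors and mfi")
  }
  if (any(factors < 1) || any(factors != round(factors))) {
    stop_schema("dilution factors must be positive integers (1 = neat)")
  }
  if (any(diff(factors) <= 0)) {
    stop_schema("dilution factors must be strictly increasing")
  }
  if (any(!is.finite(mfi)) || any(mfi < 0)) stop_schema("MFI must be finite and >= 0")
  structure(list(sample_id = as.character(sample_id),
                 bead_id = as.character(bead_id),
                 factors = as.integer(factors), mfi = as.numeric(mfi)),
            class = "dilution_series")
}

#' @rdname dilution_series
#' @param path CSV path with columns `sample_id,bead_id,dilution_factor,mfi`.
#' @return `read_dilution_series`: a list of `dilution_series`, one per
#'   (sample, bead) pair, in file order.
#' @export
read_dilution_series <- function(path) {
  df <- read_csv_checked(path, required = c("sample_id", "bead_id", "dilution_factor", "mfi"))
  key <- paste(df$sample_id, df$bead_id, sep = "\r")
  lapply(unique(key), function(k) {
    rows <- df[key == k, ]
    dilution_series(rows$sample_id[1], rows$bead_id[1], rows$dilution_factor, rows$mfi)
  })
}

#' Endpoint titer of a dilution series
#'
#' The titer is the reciprocal of the highest dilution still testing positive
#' (MFI >= cutoff), i.e. the largest measured dilution factor above the
#' cutoff; 0 when no point is positive. When the last measured point is
#' still positive the titer is right-censored — the true endpoint lies
#' beyond the measured range. Non-monotone MFI across dilutions (prozone /
#' hook effects) does not change the endpoint definition but triggers a
#' warning.
#'
#' @param series A [dilution_series].
#' @param cutoff Positivity cutoff in MFI units (> 0).
#' @param potency Optional standard potency in IU/mL; when supplied the
#'   titer is converted via [to_concentration()].
#' @return Object of class `titer_result`: `titer` (integer), `censored`
#'   (logical), `concentration` (IU/mL or `NA`).
#' @examples
#' s <- dilution_series("std", "B", c(1, 2, 4), c(100, 60, 30))
#' endpoint_titer(s, cutoff = 50)
#' @export
endpoint_titer <- function(series, cutoff, potency = NULL) {
  stopifnot(inherits(series, "dilution_series"), is.numeric(cutoff), cutoff > 0)
  if (any(diff(series$mfi) > 0)) {
    warning("non-monotone MFI across dilutions (hook effect?) in sample '",
            series$sample_id, "'; endpoint definition unchanged", call. = FALSE)
  }
  pos <- series$mfi >= cutoff
  if (!any(pos)) {
    res <- list(titer = 0L, censored = FALSE, concentration = NA_real_)
  } else {
    last_pos <- max(which(pos))
    titer <- series$factors[last_pos]
    res <- list(titer = titer,
                censored = last_pos == length(series$factors),
                concentration = if (is.null(potency)) NA_real_ else
                  to_concentration(titer, potency)$concentration)
  }
  structure(res, class = "titer_result")
}

#' @export
print.titer_result <- function(x, ...) {
  if (x$titer == 0L) {
    cat("Titer: negative at all dilutions\n")
  } else {
    cat(sprintf("Titer: 1:%d%s", x$titer, if (x$censored) " (censored: last point still positive)" else ""))
    if (!is.na(x$concentration)) cat(sprintf(", %.3g IU/mL", x$concentration))
    cat("\n")
  }
  invisible(x)
}

#' Convert an endpoint titer to a concentration
#'
#' Against a reference standard of known potency, the analyte concentration
#' detectable at the endpoint is `potency / titer`. The default potency of
#' 100 IU/mL corresponds to the NIBSC anti-HPA-1a reference standard
#' (03/152); it is a default, not a constant.
#'
#' @param titer Endpoint titer (reciprocal dilution, >= 1; a titer of 0 has
#'   no defined concentration and returns `NA` rather than an error).
#' @param potency Standard potency in IU/mL (> 0).
#' @return List `concentration` (full precision), `concentration_3sf`
#'   (rounded to 3 significant figures, the conventional reporting
#'   precision).
#' @examples
#' to_concentration(512, 100)  # 0.195 IU/mL
#' @export
to_concentration <- function(titer, potency = 100) {
  stopifnot(is.numeric(titer), length(titer) == 1L, is.numeric(potency), potency > 0)
  if (titer == 0) {
    return(list(concentration = NA_real_, concentration_3sf = NA_real_))
  }
  if (titer < 1) stop("titer must be 0 or >= 1")
  conc <- potency / titer
  list(concentration = conc, concentration_3sf = signif(conc, 3))
}

#' Fold difference between two assay sensitivities
#'
#' Ratio of two endpoint titers (a higher titer = the assay detects the
#' antibody at greater dilution = higher sensitivity). Censoring propagates:
#' a censored numerator makes the ratio a lower bound, a censored
#' denominator an upper bound.
#'
#' @param a,b [endpoint_titer()] results with `titer >= 1`.
#' @return List `fold` (a over b), `lower_bound`, `upper_bound` (logicals
#'   from censoring).
#' @examples
#' a <- structure(list(titer = 512L, censored = FALSE), class = "titer_result")
#' b <- structure(list(titer = 64L, censored = FALSE), class = "titer_result")
#' compare_sensitivity(a, b)$fold  # 8
#' @export
compare_sensitivity <- function(a, b) {
  stopifnot(inherits(a, "titer_result"), inherits(b, "titer_result"))
  if (a$titer < 1 || b$titer < 1) {
    stop("sensitivity comparison needs both titers >= 1")
  }
  list(fold = a$titer / b$titer,
       lower_bound = isTRUE(a$censored),
       upper_bound = isTRUE(b$censored))
}
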