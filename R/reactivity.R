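#' Read / write an MFI table
#'
#' Long-format CSV with header `sample_id,donor_id,bead_id,mfi` and an
#' optional `role` column (`test`, `negative_control`, `dilution`,
#' `positive_control`; defaults to `test`). MFI values must be plain
#' non-negative decimal numbers — thousands separators are rejected, the
#' decimal point is locale-independent — and each (sample, donor, bead)
#' triple may appear at most once.
#'
#' @param path File path.
#' @param donors,beads Optional panels; when supplied, donor and bead ids are
#'   checked against them (unknown ids are a schema error).
#' @return Data frame of class `mfi_table`.
#' @export
read_mfi <- function(path, donors = NULL, beads = NULL) {
  df <- read_csv_checked(path, required = c("sample_id", "donor_id", "bead_id", "mfi"),
                         colClasses = "character")
  if (!"role" %in% names(df)) df$role <- "test"
  mfi_table(df, donors = donors, beads = beads)
}

#' @rdname read_mfi
#' @param df Data frame with the columns above (`mfi` may be character, in
#'   which case the strict numeric dialect is enforced).
#' @export
mfi_table <- function(df, donors = NULL, beads = NULL) {
  req <- c("sample_id", "donor_id", "bead_id", "mfi")
  if (!all(req %in% names(df))) {
    stop_schema("MFI table needs columns: ", paste(req, collapse = ", "))
  }
  if (!"role" %in% names(df)) df$role <- "test"
  for (col in c("sample_id", "donor_id", "bead_id", "role")) {
    df[[col]] <- as.character(df[[col]])
  }
  if (is.character(df$mfi)) {
    bad <- !grepl("^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$", trimws(df$mfi))
    if (any(bad)) {
      stop_schema("non-numeric MFI value(s) (thousands separators are rejected): ",
                  paste(utils::head(unique(df$mfi[bad]), 5), collapse = ", "))
    }
    df$mfi <- as.numeric(df$mfi)
  }
  if (any(!is.finite(df$mfi)) || any(df$mfi < 0)) {
    stop_schema("MFI values must be finite and >= 0 (corrupt input?)")
  }
  key <- paste(df$sample_id, df$donor_id, df$bead_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_schema("duplicate (sample, donor, bead) triple(s): ",
                paste(utils::head(gsub("\r", "/", unique(key[duplicated(key)])), 3),
                      collapse = "; "))
  }
  bad_role <- setdiff(unique(df$role),
                      c("test", "negative_control", "dilution", "positive_control"))
  if (length(bad_role) > 0L) {
    stop_schema("unknown sample role(s): ", paste(bad_role, collapse = ", "))
  }
  if (!is.null(donors)) {
    unk <- setdiff(unique(df$donor_id), donors$donor_id)
    if (length(unk) > 0L) stop_schema("MFI table has unknown donor id(s): ",
                                      paste(unk, collapse = ", "))
  }
  if (!is.null(beads)) {
    unk <- setdiff(unique(df$bead_id), beads$bead_id)
    if (length(unk) > 0L) stop_schema("MFI table has unknown bead id(s): ",
                                      paste(unk, collapse = ", "))
  }
  df <- df[, c("sample_id", "donor_id", "bead_id", "mfi", "role")]
  class(df) <- c("mfi_table", "data.frame")
  df
}

#' @rdname read_mfi
#' @param mfi An `mfi_table` to write. Rows are written in canonical order
#'   (sample, then bead, then donor) so that write-then-read is the identity
#'   on canonical form.
#' @export
write_mfi <- function(mfi, path) {
  mfi <- mfi_table(as.data.frame(mfi))
  mfi <- mfi[order(mfi$sample_id, mfi$bead_id, mfi$donor_id), ]
  utils::write.csv(mfi, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-bead positivity cutoffs from negative controls
#'
#' The positivity cutoff of a bead is the mean negative-control MFI plus
#' three standard deviations; an MFI greater than or equal to the cutoff is
#' positive. Controls are pooled across panel donors (one cutoff per bead).
#'
#' @param neg_mfi An [mfi_table]. Rows with `role == "negative_control"` are
#'   used; if no row carries that role the whole table is treated as
#'   controls.
#' @param beads Optional [bead_panel]; cutoffs are computed for its active
#'   beads (any bead with fewer than 2 control values is an error). Without
#'   it, every bead present in the control data gets a cutoff.
#' @param sd_mode `"sample"` (n-1 denominator, the conservative clinical
#'   default) or `"population"` (n denominator).
#' @param n_sd Number of standard deviations above the mean (default 3).
#' @return A `cutoff_set`: data frame `bead_id, neg_mean, neg_sd, cutoff,
#'   n_controls` with `cutoff = neg_mean + n_sd * neg_sd`.
#' @examples
#' m <- mfi_table(data.frame(sample_id = c("N1", "N2", "N3"), donor_id = "D1",
#'                           bead_id = "B", mfi = c(10, 20, 30),
#'                           role = "negative_control"))
#' compute_cutoffs(m)
#' @export
compute_cutoffs <- function(neg_mfi, beads = NULL,
                            sd_mode = c("sample", "population"), n_sd = 3) {
  sd_mode <- match.arg(sd_mode)
  neg_mfi <- mfi_table(as.data.frame(neg_mfi))
  if (any(neg_mfi$role == "negative_control")) {
    neg_mfi <- neg_mfi[neg_mfi$role == "negative_control", ]
  }
  target_beads <- if (is.null(beads)) {
    sort(unique(neg_mfi$bead_id))
  } else {
    active_beads(beads)$bead_id
  }
  rows <- lapply(target_beads, function(b) {
    v <- neg_mfi$mfi[neg_mfi$bead_id == b]
    if (length(v) < 2L) {
      stop_schema("bead '", b, "' has ", length(v),
                  " negative-control value(s); >= 2 required for a cutoff")
    }
    m <- mean(v)
    s <- stats::sd(v)
    if (sd_mode == "population") s <- s * sqrt((length(v) - 1) / length(v))
    data.frame(bead_id = b, neg_mean = m, neg_sd = s,
               cutoff = m + n_sd * s, n_controls = length(v),
               stringsAsFactors = FALSE)
  })
  cutoff_set(do.call(rbind, rows))
}

#' @rdname compute_cutoffs
#' @param df Data frame with at least `bead_id` and `cutoff`; `neg_mean`,
#'   `neg_sd` and `n_controls` may be `NA` when cutoffs are supplied directly
#'   (e.g. published values) rather than computed.
#' @export
cutoff_set <- function(df) {
  if (!all(c("bead_id", "cutoff") %in% names(df))) {
    stop_schema("cutoff set needs columns bead_id and cutoff")
  }
  for (col in c("neg_mean", "neg_sd", "n_controls")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  df$bead_id <- as.character(df$bead_id)
  df$cutoff <- as.numeric(df$cutoff)
  if (anyDuplicated(df$bead_id)) stop_schema("duplicate bead_id in cutoff set")
  if (any(!is.finite(df$cutoff)) || any(df$cutoff < 0)) {
    stop_schema("cutoffs must be finite and >= 0")
  }
  df <- df[, c("bead_id", "neg_mean", "neg_sd", "cutoff", "n_controls")]
  class(df) <- c("cutoff_set", "data.frame")
  df
}

#' @rdname compute_cutoffs
#' @param path CSV path (`bead_id,neg_mean,neg_sd,cutoff,n_controls`).
#' @export
read_cutoffs <- function(path) {
  cutoff_set(read_csv_checked(path, required = c("bead_id", "cutoff")))
}

#' @rdname compute_cutoffs
#' @param cutoffs A `cutoff_set` to write.
#' @export
write_cutoffs <- function(cutoffs, path) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  utils::write.csv(as.data.frame(cutoffs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

bead_cutoff <- function(cutoffs, bead_id) {
  i <- match(bead_id, cutoffs$bead_id)
  if (is.na(i)) stop_schema("no cutoff for bead '", bead_id, "'")
  cutoffs$cutoff[i]
}

#' Call bead-by-donor reactivity
#'
#' Applies the per-bead cutoffs to every measured (sample, donor, bead) cell:
#' a donor is reactive for a sample on a bead when the MFI is greater than or
#' equal to the bead's cutoff (inclusive). Reactive values below
#' `grey_factor * cutoff` additionally carry a `borderline` flag, which the
#' deconvolution consumes. Cells absent from the input (relative to the full
#' sample x donor x bead grid) are reported with `measured = FALSE` and
#' belong to neither the reactive nor the non-reactive donor set.
#'
#' @param mfi An [mfi_table]; rows with role `negative_control` are excluded
#'   from pattern construction.
#' @param cutoffs A [cutoff_set] covering every bead present.
#' @param beads Optional [bead_panel]; restricts calling to its active
#'   (non-control) beads.
#' @param grey_factor Upper bound (as a multiple of the cutoff) of the
#'   borderline zone `[cutoff, grey_factor * cutoff)`; default 1.25.
#' @return A `reactivity_pattern`: data frame `sample_id, bead_id, donor_id,
#'   mfi, measured, reactive, borderline` covering the complete grid.
#' @export
call_reactivity <- function(mfi, cutoffs, beads = NULL, grey_factor = 1.25) {
  stopifnot(grey_factor >= 1)
  mfi <- mfi_table(as.data.frame(mfi))
  mfi <- mfi[mfi$role != "negative_control", ]
  if (!is.null(beads)) {
    keep <- active_beads(beads)$bead_id
    mfi <- mfi[mfi$bead_id %in% keep, ]
    bead_ids <- keep
  } else {
    bead_ids <- sort(unique(mfi$bead_id))
  }
  if (nrow(mfi) == 0L) stop_schema("no test measurements to call")
  samples <- unique(mfi$sample_id)
  donor_ids <- sort(unique(mfi$donor_id))
  grid <- expand.grid(donor_id = donor_ids, bead_id = bead_ids,
                      sample_id = samples, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("sample_id", "bead_id", "donor_id")]
  idx <- match(paste(grid$sample_id, grid$donor_id, grid$bead_id, sep = "\r"),
               paste(mfi$sample_id, mfi$donor_id, mfi$bead_id, sep = "\r"))
  grid$mfi <- mfi$mfi[idx]
  grid$measured <- !is.na(idx)
  co <- vapply(grid$bead_id, bead_cutoff, numeric(1), cutoffs = cutoffs)
  grid$reactive <- ifelse(grid$measured, grid$mfi >= co, NA)
  grid$borderline <- ifelse(grid$measured,
                            grid$reactive & grid$mfi < grey_factor * co, NA)
  structure(grid, cutoffs = cutoffs, grey_factor = grey_factor,
            class = c("reactivity_pattern", "data.frame"))
}

#' Reactive / non-reactive donor sets for one sample on one bead
#'
#' @param pattern A [call_reactivity()] result.
#' @param sample_id,bead_id Cell coordinates.
#' @return List with `R` (reactive donors), `N` (non-reactive donors),
#'   `borderline` (subset of `R` in the grey zone), `missing` (unmeasured
#'   donors) and `mfi` (named MFI vector).
#' @export
reactive_donors <- function(pattern, sample_id, bead_id) {
  stopifnot(inherits(pattern, "reactivity_pattern"))
  rows <- pattern[pattern$sample_id == sample_id & pattern$bead_id == bead_id, ]
  if (nrow(rows) == 0L) stop("no pattern rows for sample '", sample_id,
                             "', bead '", bead_id, "'")
  measured <- rows[rows$measured, ]
  list(R = measured$donor_id[measured$reactive],
       N = measured$donor_id[!measured$reactive],
       borderline = measured$donor_id[measured$reactive & measured$borderline],
       missing = rows$donor_id[!rows$measured],
       mfi = stats::setNames(measured$mfi, measured$donor_id))
}

# strict CSV reader shared by all tabular inputs: UTF-8, header required,
# '#' comment lines tolerated, locale-independent decimal point
read_csv_checked <- function(path, required = NULL, colClasses = NA) {
  if (!file.exists(path)) stop_schema("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, comment.char = "#",
                    colClasses = colClasses, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) stop_schema("cannot parse ", path, ": ", conditionMessage(e))
  )
  if (nrow(df) == 0L) stop_schema(path, " contains no data rows")
  if (!is.null(required) && !all(required %in% names(df))) {
    stop_schema(path, " is missing required column(s): ",
                paste(setdiff(required, names(df)), collapse = ", "))
  }
  df
}
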