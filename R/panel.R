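#' Donor panel: HPA-genotyped platelet donors
#'
#' A donor panel is the combinatorial backbone of specificity inference: each
#' panel donor is genotyped at every configured HPA system, and a sample's
#' reactivity pattern over the donors is interpreted against those genotypes.
#'
#' @param df Data frame with a `donor_id` column and one column per HPA
#'   system (e.g. `HPA-1` ... `HPA-15`), cells holding a zygosity token.
#'   Tokens are normalised case-insensitively; both `ab` and `a/b` dialects
#'   are accepted.
#' @return An object of class `donor_panel` (a validated data frame with a
#'   `systems` attribute).
#' @examples
#' donor_panel(data.frame(donor_id = c("D1", "D2"),
#'                        `HPA-1` = c("aa", "ab"), check.names = FALSE))
#' @export
donor_panel <- function(df) {
  if (!is.data.frame(df) || nrow(df) == 0L) {
    stop_schema("donor panel must be a non-empty data frame")
  }
  if (!"donor_id" %in% names(df)) {
    stop_schema("donor panel is missing the 'donor_id' column")
  }
  systems <- setdiff(names(df), "donor_id")
  if (length(systems) == 0L) {
    stop_schema("donor panel has no HPA system columns")
  }
  bad_sys <- systems[!is_hpa_system(systems)]
  if (length(bad_sys) > 0L) {
    stop_schema("unrecognised HPA system column(s): ", paste(bad_sys, collapse = ", "))
  }
  df$donor_id <- as.character(df$donor_id)
  if (anyDuplicated(df$donor_id)) {
    stop_schema("duplicate donor_id: ",
                paste(unique(df$donor_id[duplicated(df$donor_id)]), collapse = ", "))
  }
  for (s in systems) {
    df[[s]] <- normalize_zygosity(df[[s]], s)
  }
  structure(df, systems = systems, class = c("donor_panel", "data.frame"))
}

normalize_zygosity <- function(x, system) {
  x <- gsub("/", "", tolower(trimws(as.character(x))))
  x[x == "ba"] <- "ab"
  bad <- !(x %in% c("aa", "ab", "bb"))
  if (any(bad)) {
    stop_schema("invalid zygosity token(s) at ", system, ": ",
                paste(unique(x[bad]), collapse = ", "),
                " (expected aa, ab or bb)")
  }
  x
}

#' @export
print.donor_panel <- function(x, ...) {
  cat("Donor panel:", nrow(x), "donors x", length(attr(x, "systems")), "HPA systems\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @rdname donor_panel
#' @param panel A `donor_panel`.
#' @export
panel_systems <- function(panel) attr(panel, "systems")

#' Does a donor carry an HPA allele?
#'
#' A donor carries allele `a` (resp. `b`) of a system when their zygosity at
#' that system contains the letter: `aa` and `ab` carry `a`; `ab` and `bb`
#' carry `b`. Heterozygous and homozygous carriers are treated identically
#' (antigen dosage is ignored for reactivity prediction).
#'
#' @param panel A [donor_panel].
#' @param donor_id Donor identifier(s); vectorised.
#' @param system HPA system identifier, e.g. `"HPA-5"`.
#' @param allele `"a"` or `"b"`.
#' @return Logical vector along `donor_id`.
#' @examples
#' p <- reference_donor_panel()
#' carries(p, "G4", "HPA-5", "b")
#' @export
carries <- function(panel, donor_id, system, allele) {
  stopifnot(inherits(panel, "donor_panel"), allele %in% c("a", "b"))
  if (!(system %in% panel_systems(panel))) {
    stop("unknown HPA system '", system, "' (panel has: ",
         paste(panel_systems(panel), collapse = ", "), ")")
  }
  idx <- match(donor_id, panel$donor_id)
  if (anyNA(idx)) {
    stop("unknown donor_id: ", paste(donor_id[is.na(idx)], collapse = ", "))
  }
  grepl(allele, panel[[system]][idx], fixed = TRUE)
}

#' Bead panel: capture beads and the HPA systems they interrogate
#'
#' Each bead captures one platelet membrane glycoprotein (or HLA class I, or
#' coupled IgG for the conjugate control). The HPA systems resident on the
#' captured glycoprotein determine which antibody specificities the bead can
#' report.
#'
#' @param df Data frame with columns `bead_id`, `code` (vendor bead code),
#'   `target` (glycoprotein name), `systems` (list column of HPA system ids;
#'   empty for HLA and control beads), `role` (one of `hpa_capture`,
#'   `hla_capture`, `positive_control`) and `enabled` (logical).
#' @param registry Character vector of admissible system identifiers; bead
#'   systems outside it are an error. Defaults to the systems that match the
#'   `HPA-<n>[w]` grammar (open registry).
#' @return An object of class `bead_panel`.
#' @export
bead_panel <- function(df, registry = NULL) {
  req <- c("bead_id", "code", "target", "systems", "role", "enabled")
  if (!is.data.frame(df) || !all(req %in% names(df))) {
    stop_schema("bead panel needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(df) == 0L) stop_schema("bead panel must be non-empty")
  df$bead_id <- as.character(df$bead_id)
  if (anyDuplicated(df$bead_id)) stop_schema("duplicate bead_id in bead panel")
  if (!all(df$role %in% c("hpa_capture", "hla_capture", "positive_control"))) {
    stop_schema("bead role must be hpa_capture, hla_capture or positive_control")
  }
  if (!is.list(df$systems)) df$systems <- as.list(df$systems)
  df$systems <- lapply(df$systems, function(s) {
    s <- as.character(unlist(s))
    s[nzchar(s)]
  })
  all_sys <- unique(unlist(df$systems))
  bad <- all_sys[!is_hpa_system(all_sys)]
  if (!is.null(registry)) bad <- union(bad, setdiff(all_sys, registry))
  if (length(bad) > 0L) {
    stop_schema("bead panel references unregistered system(s): ",
                paste(bad, collapse = ", "))
  }
  n_sys <- lengths(df$systems)
  if (any(df$role != "hpa_capture" & n_sys > 0L)) {
    stop_schema("only hpa_capture beads may list HPA systems")
  }
  df$enabled <- as.logical(df$enabled)
  structure(df, class = c("bead_panel", "data.frame"))
}

#' @export
print.bead_panel <- function(x, ...) {
  cat("Bead panel:", nrow(x), "beads (", sum(x$enabled), "enabled )\n")
  show <- x
  show$systems <- vapply(x$systems, paste, character(1), collapse = ",")
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}

#' @rdname bead_panel
#' @param beads A `bead_panel`.
#' @param roles Bead roles to keep.
#' @export
active_beads <- function(beads, roles = c("hpa_capture", "hla_capture")) {
  stopifnot(inherits(beads, "bead_panel"))
  beads[beads$enabled & beads$role %in% roles, , drop = FALSE]
}

bead_row <- function(beads, bead_id) {
  i <- match(bead_id, beads$bead_id)
  if (is.na(i)) stop("unknown bead_id '", bead_id, "'")
  beads[i, , drop = FALSE]
}

#' Candidate antibody specificities of a bead
#'
#' An HLA-capture bead can only report anti-HLA; a glycoprotein-capture bead
#' can report either allele of every HPA system resident on its target
#' glycoprotein. The conjugate (positive-control) bead reports nothing and is
#' excluded from inference.
#'
#' @param beads A [bead_panel].
#' @param bead_id Bead identifier.
#' @return Character vector of canonical specificity labels.
#' @examples
#' candidate_specificities(reference_bead_panel(), "GPIIb/IIIa")
#' @export
candidate_specificities <- function(beads, bead_id) {
  b <- bead_row(beads, bead_id)
  if (b$role == "positive_control") {
    stop("bead '", bead_id, "' is a positive-control bead and has no candidate specificities")
  }
  if (b$role == "hla_capture") {
    return(spec_hla())
  }
  systems <- b$systems[[1]]
  if (length(systems) == 0L) return(character(0))
  as.vector(vapply(systems, function(s) spec_hpa(s, c("a", "b")), character(2)))
}

#' Read a donor genotype table
#'
#' CSV with header `donor_id,<system>,<system>,...`, zygosity cells in
#' `{aa, ab, bb}` (case-insensitive; `a/b` dialect accepted).
#'
#' @param path File path.
#' @return A [donor_panel].
#' @export
read_genotypes <- function(path) {
  df <- read_csv_checked(path)
  donor_panel(df)
}

#' @rdname read_genotypes
#' @param panel A [donor_panel] to write.
#' @export
write_genotypes <- function(panel, path) {
  stopifnot(inherits(panel, "donor_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bead panel configuration
#'
#' YAML file with a top-level `beads:` list; each entry carries `bead_id`,
#' `code`, `target`, `systems`, `role` and `enabled`.
#'
#' @param path YAML file path.
#' @return A [bead_panel].
#' @export
read_bead_config <- function(path) {
  if (!file.exists(path)) stop_schema("bead config not found: ", path)
  y <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_schema("cannot parse bead config ", path, ": ", conditionMessage(e))
  })
  if (is.null(y$beads) || length(y$beads) == 0L) {
    stop_schema("bead config ", path, " has no 'beads' entries")
  }
  rows <- lapply(y$beads, function(b) {
    for (f in c("bead_id", "code", "target", "role")) {
      if (is.null(b[[f]])) stop_schema("bead entry missing field '", f, "' in ", path)
    }
    data.frame(bead_id = b$bead_id, code = b$code, target = b$target,
               systems = I(list(as.character(unlist(b$systems)))),
               role = b$role,
               enabled = if (is.null(b$enabled)) TRUE else isTRUE(b$enabled),
               stringsAsFactors = FALSE)
  })
  bead_panel(do.call(rbind, rows))
}

#' Load and cross-validate donor and bead panels
#'
#' Reads both tables, checks that every HPA system a bead interrogates is
#' genotyped in the donor table, and warns (once, with the full list) about
#' structurally uninformative specificities — candidates for which the panel
#' lacks a carrier or a non-carrier, so reactivity can never confirm or
#' exclude them.
#'
#' @param genotype_path CSV path for [read_genotypes()].
#' @param bead_config_path YAML path for [read_bead_config()]; default is the
#'   packaged bead panel.
#' @param quiet Suppress the uninformative-specificity warning.
#' @return List with elements `donors` ([donor_panel]) and `beads`
#'   ([bead_panel]).
#' @export
load_panel <- function(genotype_path,
                       bead_config_path = hpa_fixture("bead_panel.yml"),
                       quiet = FALSE) {
  donors <- read_genotypes(genotype_path)
  beads <- read_bead_config(bead_config_path)
  missing_sys <- setdiff(unlist(active_beads(beads)$systems), panel_systems(donors))
  if (length(missing_sys) > 0L) {
    stop_schema("bead panel interrogates system(s) not genotyped in the donor table: ",
                paste(missing_sys, collapse = ", "))
  }
  uninf <- uninformative_specificities(donors, beads)
  if (length(uninf) > 0L && !quiet) {
    warning("structurally uninformative on this donor panel (no carrier or no ",
            "non-carrier): ", paste(uninf, collapse = ", "), call. = FALSE)
  }
  list(donors = donors, beads = beads)
}

#' Structurally uninformative specificities
#'
#' A candidate anti-HPA specificity is informative only when the donor panel
#' contains at least one carrier and at least one non-carrier of the allele;
#' otherwise reactivity attributable to it can never be separated from the
#' alternatives (e.g. anti-HPA-1b on an all-`HPA-1aa` panel).
#'
#' @param donors A [donor_panel].
#' @param beads A [bead_panel].
#' @return Character vector of uninformative specificity labels.
#' @export
uninformative_specificities <- function(donors, beads) {
  gp <- active_beads(beads, "hpa_capture")
  cands <- unique(unlist(lapply(gp$bead_id, candidate_specificities, beads = beads)))
  if (length(cands) == 0L) return(character(0))
  fl <- spec_fields(cands)
  keep <- vapply(seq_len(nrow(fl)), function(i) {
    cc <- carries(donors, donors$donor_id, fl$system[i], fl$allele[i])
    !any(cc) || all(cc)
  }, logical(1))
  sort(cands[keep])
}

#' Specificities the panel can resolve end to end
#'
#' Runs the noise-free assay forward model for each single candidate
#' specificity (every carrier reactive on the relevant bead, everything else
#' at background) through the deconvolution and keeps those whose final call
#' equals the simulated truth. This is the panel's effective repertoire: a
#' laboratory can only trust calls for specificities in this set. Anti-HLA is
#' always resolvable when an HLA bead is active.
#'
#' @inheritParams uninformative_specificities
#' @param priors A priors table (see [default_priors()]) used for tie-breaks,
#'   as in the production pipeline.
#' @return Character vector of specificity labels.
#' @examples
#' resolvable_specificities(reference_donor_panel(), reference_bead_panel())
#' @export
resolvable_specificities <- function(donors, beads, priors = default_priors()) {
  gp <- active_beads(beads, "hpa_capture")
  out <- character(0)
  for (b in gp$bead_id) {
    for (cand in candidate_specificities(beads, b)) {
      fl <- spec_fields(cand)
      R <- donors$donor_id[carries(donors, donors$donor_id, fl$system, fl$allele)]
      N <- setdiff(donors$donor_id, R)
      sets <- infer_bead(b, R, N, donors, beads, priors = priors)
      if (length(sets) > 0L && identical(sets[[1]]$specificities, cand)) {
        out <- c(out, cand)
      }
    }
  }
  hla <- nrow(active_beads(beads, "hla_capture")) > 0L
  sort(unique(c(out, if (hla) spec_hla())))
}

#' Packaged reference fixtures
#'
#' Convenience accessors for the fixtures shipped with the package: the
#' four-donor genotyped panel, the default bead configuration, the nine
#' positive clinical/workshop samples with their published per-bead cutoffs,
#' and the reference-method (MAIPA) calls.
#'
#' @param name File name under the package's `extdata/`.
#' @return `hpa_fixture`: a file path. `reference_donor_panel` /
#'   `reference_bead_panel`: the parsed panel objects.
#' @export
hpa_fixture <- function(name) {
  p <- system.file("extdata", name, package = "hpadeconv", mustWork = FALSE)
  if (!nzchar(p)) stop("no packaged fixture named '", name, "'")
  p
}

#' @rdname hpa_fixture
#' @export
reference_donor_panel <- function() read_genotypes(hpa_fixture("genotypes_reference.csv"))

#' @rdname hpa_fixture
#' @export
reference_bead_panel <- function() read_bead_config(hpa_fixture("bead_panel.yml"))
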