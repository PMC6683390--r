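#' Registered HPA system identifiers
#'
#' The biallelic (a/b) human platelet antigen systems the package knows about
#' by default. Any identifier matching `HPA-<number>` with an optional
#' workshop `w` suffix (e.g. `HPA-21w`) is accepted by the validators, so the
#' registry is extensible through the genotype table and bead configuration.
#'
#' @return Character vector of system identifiers.
#' @export
hpa_systems <- function() {
  c("HPA-1", "HPA-2", "HPA-3", "HPA-4", "HPA-5", "HPA-6", "HPA-15", "HPA-21w")
}

# identifier grammar for a biallelic HPA system
.system_regex <- "^HPA-[0-9]+w?$"

is_hpa_system <- function(x) grepl(.system_regex, x)

#' Construct specificity labels
#'
#' Antibody specificities are represented throughout the package as canonical
#' character labels: `"anti-HLA"` for HLA class I reactivity and
#' `"anti-HPA-<system><allele>"` (e.g. `"anti-HPA-5b"`) for a platelet
#' alloantibody against one allele of a biallelic HPA system.
#'
#' @param system HPA system identifier, e.g. `"HPA-5"`.
#' @param allele `"a"` or `"b"`.
#' @return Canonical specificity label (character scalar).
#' @examples
#' spec_hpa("HPA-5", "b")
#' @export
spec_hpa <- function(system, allele) {
  stopifnot(all(is_hpa_system(system)), all(allele %in% c("a", "b")))
  paste0("anti-", system, allele)
}

#' @rdname spec_hpa
#' @export
spec_hla <- function() "anti-HLA"

spec_is_hla <- function(spec) spec == "anti-HLA"

#' Decompose a specificity label
#'
#' @param spec Specificity label(s) as produced by [spec_hpa()] / [spec_hla()].
#' @return Data frame with columns `spec`, `kind` (`anti-HPA` / `anti-HLA`),
#'   `system` and `allele` (`NA` for anti-HLA).
#' @export
spec_fields <- function(spec) {
  ok <- grepl("^anti-HLA$", spec) | grepl("^anti-HPA-[0-9]+w?[ab]$", spec)
  if (!all(ok)) {
    stop_schema("invalid specificity label(s): ", paste(spec[!ok], collapse = ", "))
  }
  hla <- spec_is_hla(spec)
  data.frame(
    spec = spec,
    kind = ifelse(hla, "anti-HLA", "anti-HPA"),
    system = ifelse(hla, NA_character_, sub("^anti-(HPA-[0-9]+w?)[ab]$", "\\1", spec)),
    allele = ifelse(hla, NA_character_, sub("^.*([ab])$", "\\1", spec)),
    stringsAsFactors = FALSE
  )
}

#' Parse a human-readable antibody call string
#'
#' Parses the reporting dialect used on serology worksheets, e.g.
#' `"Anti-HLA + anti-HPA-2b"` or `"Negative"`, into a canonical set of
#' specificity labels. Parsing is strict: components must be `anti-HLA` or
#' `anti-HPA-<system><a|b>` (case-insensitive), joined by `+`.
#'
#' @param x Call string (character scalar).
#' @return Character vector of canonical specificity labels (length 0 for a
#'   negative call).
#' @examples
#' parse_call_string("Anti-HLA + anti-HPA-2b")
#' @export
parse_call_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (nchar(x) == 0L || tolower(x) %in% c("negative", "neg", "none")) {
    return(character(0))
  }
  parts <- trimws(strsplit(x, "+", fixed = TRUE)[[1]])
  canon <- vapply(parts, function(p) {
    pl <- tolower(p)
    m <- regmatches(pl, regexec("^anti-(hla|hpa-([0-9]+w?)([ab]))$", pl))[[1]]
    if (length(m) == 0L) {
      stop_schema("cannot parse antibody call component: '", p, "'")
    }
    if (m[2] == "hla") "anti-HLA" else paste0("anti-HPA-", m[3], m[4])
  }, character(1), USE.NAMES = FALSE)
  unique(canon)
}

#' Format a specificity set as a call string
#'
#' Inverse of [parse_call_string()]. Anti-HLA is reported first, then HPA
#' specificities in bead-panel order (the order glycoprotein beads appear in
#' the configuration), alleles `a` before `b` within a bead. The first
#' component is capitalised (`"Anti-..."`), matching worksheet convention; an
#' empty set formats as `"Negative"`.
#'
#' @param specs Character vector of canonical specificity labels.
#' @param beads Optional [bead_panel] used to order HPA components; without it
#'   components sort lexicographically.
#' @return Character scalar.
#' @export
format_call <- function(specs, beads = NULL) {
  specs <- unique(specs)
  if (length(specs) == 0L) {
    return("Negative")
  }
  hla <- specs[spec_is_hla(specs)]
  hpa <- sort(specs[!spec_is_hla(specs)])
  if (!is.null(beads) && length(hpa) > 0L) {
    fl <- spec_fields(hpa)
    bead_rank <- vapply(fl$system, function(s) {
      hit <- which(vapply(beads$systems, function(sys) s %in% sys, logical(1)))
      if (length(hit) == 0L) Inf else min(hit)
    }, numeric(1))
    hpa <- hpa[order(bead_rank, fl$system, fl$allele)]
  }
  out <- paste(c(hla, hpa), collapse = " + ")
  sub("^anti-", "Anti-", out)
}

# classed error so the CLI can map schema violations to exit code 2
stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("hpadeconv_schema_error", "error")))
}
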