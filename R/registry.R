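# The 12-term polynomial basis shared by all four (race, sex) groups:
# {1, F, A, H, F*A, F*H, F^2, F^2*A, F^3, F^4, F^2*H, F^3*H}
# with F = fat mass (kg), A = age (y), H = height (cm).

#' Basis term names of the FFM polynomial class
#'
#' @return character vector of the 12 term names, in canonical column order.
#' @export
ffm_basis_terms <- function() {
  c("1", "F", "A", "H", "FA", "FH", "F2", "F2A", "F3", "F4", "F2H", "F3H")
}

# Evaluate the 12 basis monomials at (F, A, H); vectorised over F.
basis_monomials <- function(fm, age, height) {
  cbind(`1` = rep(1, length(fm)), F = fm, A = rep(age, length(fm)),
        H = rep(height, length(fm)), FA = fm * age, FH = fm * height,
        F2 = fm^2, F2A = fm^2 * age, F3 = fm^3, F4 = fm^4,
        F2H = fm^2 * height, F3H = fm^3 * height)
}

REGISTRY_VARIANTS <- c("normalized", "printed", "corrected")

registry_cache <- new.env(parent = emptyenv())

#' Coefficient registry of the FFM polynomial class
#'
#' Returns the coefficient table for one registry variant: a named list
#' mapping group keys `"AA.F"`, `"AA.M"`, `"NAA.F"`, `"NAA.M"` to named
#' 12-element coefficient vectors over [ffm_basis_terms()].
#'
#' Three variants are shipped:
#' \describe{
#'   \item{`printed`}{a literal transcription of the published coefficient
#'     table, including its two typographical anomalies (an `A` term where
#'     the row pattern has `F*A`, and a trailing `F*H` term where the
#'     pattern has `F^3*H`), read literally.}
#'   \item{`normalized`}{the two anomalous terms replaced by their
#'     pattern-consistent `F*A` and `F^3*H` forms; the default.}
#'   \item{`corrected`}{the normalized table with the AA-female row
#'     repaired: its height coefficient set to the pattern-consistent 0.7
#'     (also required for a non-negative zero-fat intercept at short
#'     stature) and its intercept and linear-F coefficients recalibrated so
#'     the row interpolates the two published reference compositions
#'     FFM(27.75) = 47.25 kg and FFM(20.74) = 44.26 kg at age 34 y, height
#'     165 cm. Use this variant when reproducing the published worked
#'     example; see the package vignette.}
#' }
#'
#' @param variant one of `"normalized"` (default), `"printed"`,
#'   `"corrected"`.
#' @return object of class `ffm_registry`: list of four named coefficient
#'   vectors, with attributes `variant` and `version`.
#' @export
ffm_registry <- function(variant = "normalized") {
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% REGISTRY_VARIANTS) {
    stop_config(sprintf("unknown registry variant %s (expected one of %s)",
                        dQuote(variant),
                        paste(dQuote(REGISTRY_VARIANTS), collapse = ", ")))
  }
  if (!is.null(registry_cache[[variant]])) return(registry_cache[[variant]])
  if (is.null(registry_cache$tab)) {
    path <- system.file("extdata", "ffm_coefficients.tsv", package = "bodycomp")
    if (path == "") path <- file.path("inst", "extdata", "ffm_coefficients.tsv")
    registry_cache$tab <- read_ffm_registry_table(path)
  }
  tab <- registry_cache$tab[registry_cache$tab$variant == variant, ]
  groups <- c("AA.F", "AA.M", "NAA.F", "NAA.M")
  reg <- lapply(groups, function(g) {
    sub <- tab[paste(tab$race, tab$sex, sep = ".") == g, ]
    co <- stats::setNames(sub$value[match(ffm_basis_terms(), sub$term)],
                          ffm_basis_terms())
    if (anyNA(co)) stop_config(sprintf("registry group %s is missing terms", g))
    co
  })
  names(reg) <- groups
  registry_cache[[variant]] <- structure(
    reg, variant = variant, version = attr(registry_cache$tab, "version"),
    class = "ffm_registry")
  registry_cache[[variant]]
}

# Parse the shipped plain-text coefficient table.
read_ffm_registry_table <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("registry file not found: %s", path))
  first <- readLines(path, n = 1L)
  version <- sub("^#\\s*version:\\s*", "", first)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "character", "character", "numeric"))
  needed <- c("variant", "race", "sex", "term", "value")
  if (!identical(names(tab), needed))
    stop_config(sprintf("registry table must have columns %s",
                        paste(needed, collapse = ", ")))
  attr(tab, "version") <- version
  tab
}

#' Read / write a coefficient registry file
#'
#' The registry is serialised as a versioned tab-separated table with
#' columns `variant`, `race`, `sex`, `term`, `value`. Values are written
#' with full double precision (17 significant digits) so a write/read cycle
#' is bit-exact.
#'
#' @param path file path.
#' @rdname registry-io
#' @return `read_ffm_registry()` returns the registry data frame;
#'   `write_ffm_registry()` returns `path` invisibly.
#' @export
read_ffm_registry <- function(path) {
  read_ffm_registry_table(path)
}

#' @param tab registry data frame as returned by [read_ffm_registry()].
#' @param version version string recorded in the file header.
#' @rdname registry-io
#' @export
write_ffm_registry <- function(tab, path, version = attr(tab, "version")) {
  if (is.null(version)) version <- "1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# version: %s", version), con)
  writeLines(paste(c("variant", "race", "sex", "term", "value"), collapse = "\t"), con)
  writeLines(sprintf("%s\t%s\t%s\t%s\t%.17g", tab$variant, tab$race, tab$sex,
                     tab$term, tab$value),
             con)
  invisible(path)
}

#' @export
print.ffm_registry <- function(x, ...) {
  cat(sprintf("FFM polynomial coefficient registry (variant %s, version %s)\n",
              dQuote(attr(x, "variant")), attr(x, "version")))
  m <- do.call(rbind, x)
  print(signif(m, 6))
  invisible(x)
}

group_key <- function(cov) paste(cov$race, cov$sex, sep = ".")
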