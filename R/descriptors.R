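# Structural identity of a fatty acid: chain length, branching class,
# unsaturation count, and 3-hydroxylation. Branching follows the standard
# nomenclature: iso = methyl on the penultimate carbon, anteiso = methyl on
# the antepenultimate carbon, normal = straight chain.

fa_branching_levels <- c("normal", "iso", "anteiso")

#' Create a fatty-acid descriptor
#'
#' A descriptor captures the structural identity of one fatty acid: carbon
#' number, branching class (`normal`, `iso`, `anteiso`), number of double
#' bonds and whether the acid is hydroxylated at carbon 3 (a 3-OH FA,
#' characteristic of the lipopolysaccharide lipid A of Gram-negative
#' bacteria). Equality is structural: two descriptors with identical fields
#' denote the same compound.
#'
#' @param carbon_number Integer chain length (2--40).
#' @param branching One of `"normal"`, `"iso"`, `"anteiso"`. `iso` requires at
#'   least 4 carbons, `anteiso` at least 5.
#' @param n_unsaturations Non-negative integer number of double bonds,
#'   strictly less than `carbon_number`.
#' @param hydroxylated_3 Logical; `TRUE` for a 3-hydroxy fatty acid.
#' @return An object of class `fa_descriptor`.
#' @seealso [parse_fa_name()], [format_fa_name()], [fa_key()]
#' @examples
#' fa_descriptor(15, "anteiso", 0, hydroxylated_3 = TRUE)
#' @export
fa_descriptor <- function(carbon_number, branching = "normal",
                          n_unsaturations = 0L, hydroxylated_3 = FALSE) {
  carbon_number <- as.integer(carbon_number)
  n_unsaturations <- as.integer(n_unsaturations)
  branching <- match.arg(branching, fa_branching_levels)
  if (length(carbon_number) != 1L || is.na(carbon_number) ||
      carbon_number < 2L || carbon_number > 40L) {
    stop("carbon number out of range [2, 40]: ", carbon_number, call. = FALSE)
  }
  if (branching == "iso" && carbon_number < 4L) {
    stop("iso branching requires at least 4 carbons", call. = FALSE)
  }
  if (branching == "anteiso" && carbon_number < 5L) {
    stop("anteiso branching requires at least 5 carbons", call. = FALSE)
  }
  if (length(n_unsaturations) != 1L || is.na(n_unsaturations) ||
      n_unsaturations < 0L || n_unsaturations >= carbon_number) {
    stop("number of unsaturations must lie in [0, carbon_number)", call. = FALSE)
  }
  structure(
    list(carbon_number = carbon_number,
         branching = branching,
         n_unsaturations = n_unsaturations,
         hydroxylated_3 = isTRUE(hydroxylated_3)),
    class = "fa_descriptor"
  )
}

#' Canonical key of a fatty-acid descriptor
#'
#' Returns an unambiguous text key, e.g. `"3OH-ai-C15:0"` or `"n-C16:1"`,
#' used to identify compounds in measurement tables. Two descriptors are the
#' same compound if and only if their keys are equal.
#'
#' @param x An `fa_descriptor`.
#' @return Character scalar.
#' @export
fa_key <- function(x) {
  stopifnot(inherits(x, "fa_descriptor"))
  abbr <- c(normal = "n", iso = "i", anteiso = "ai")[[x$branching]]
  sprintf("%s%s-C%d:%d", if (x$hydroxylated_3) "3OH-" else "",
          abbr, x$carbon_number, x$n_unsaturations)
}

#' @export
print.fa_descriptor <- function(x, ...) {
  cat("<fa_descriptor>", fa_key(x), "\n")
  invisible(x)
}

#' @export
format.fa_descriptor <- function(x, ...) format_fa_name(x)

# ---- parsing -----------------------------------------------------------

#' Parse a fatty-acid label
#'
#' Understands the naming dialects found in culture-study tables:
#' `"iso C_15"`, `"anteiso 15:0"`, `"16:1"`, `"i-C15"`, `"ai-C17"`,
#' `"n-C16"`, `"3-OH ai-C17"`, case-insensitively. A `"3-OH"` prefix marks
#' the compound as 3-hydroxylated; a bare label takes `default_3oh`, so that
#' tables printed "vs. total 3-OH FAs" can be parsed with
#' `default_3oh = TRUE`.
#'
#' @param label Character scalar, non-empty.
#' @param default_3oh Logical used when the label itself carries no 3-OH
#'   marker.
#' @return An [fa_descriptor()].
#' @examples
#' parse_fa_name("anteiso 15:0")
#' parse_fa_name("iso C_17", default_3oh = TRUE)
#' parse_fa_name("16:1")
#' @export
parse_fa_name <- function(label, default_3oh = FALSE) {
  if (!is.character(label) || length(label) != 1L || is.na(label)) {
    stop("fatty-acid label must be a single character string", call. = FALSE)
  }
  raw <- label
  s <- tolower(trimws(label))
  if (!nzchar(s)) stop("empty fatty-acid label", call. = FALSE)

  hydroxy <- isTRUE(default_3oh)
  if (grepl("^3[- ]?oh[-_ ]*", s)) {
    hydroxy <- TRUE
    s <- sub("^3[- ]?oh[-_ ]*", "", s)
  }

  take <- function(pat) {
    if (grepl(pat, s, perl = TRUE)) {
      s <<- sub(pat, "", s, perl = TRUE)
      TRUE
    } else FALSE
  }
  branching <- "normal"
  if (take("^anteiso(?=[-_ c0-9])[-_ ]*") || take("^ai(?=[-_ c])[-_ ]*")) {
    branching <- "anteiso"
  } else if (take("^iso(?=[-_ c0-9])[-_ ]*") || take("^i(?=[-_ c])[-_ ]*")) {
    branching <- "iso"
  } else if (take("^normal(?=[-_ c0-9])[-_ ]*") || take("^n(?=[-_ c])[-_ ]*")) {
    branching <- "normal"
  }

  m <- regmatches(s, regexec("^c?[_ ]?([0-9]+)(:([0-9]+))?$", s))[[1L]]
  if (length(m) == 0L) {
    stop(sprintf("cannot parse fatty-acid label '%s': unrecognized token '%s'",
                 raw, s), call. = FALSE)
  }
  carbon <- as.integer(m[2L])
  if (carbon < 2L || carbon > 40L) {
    stop(sprintf("carbon number %d in label '%s' out of range [2, 40]",
                 carbon, raw), call. = FALSE)
  }
  unsat <- if (nzchar(m[4L])) as.integer(m[4L]) else 0L
  fa_descriptor(carbon, branching, unsat, hydroxy)
}

#' Parse a vector of fatty-acid labels into a descriptor table
#'
#' @param labels Character vector of labels.
#' @inheritParams parse_fa_name
#' @return A data frame with one row per label: `fa_key`, `carbon_number`,
#'   `branching`, `n_unsaturations`, `hydroxylated_3`.
#' @export
parse_fa_names <- function(labels, default_3oh = FALSE) {
  ds <- lapply(labels, parse_fa_name, default_3oh = default_3oh)
  data.frame(
    fa_key = vapply(ds, fa_key, character(1)),
    carbon_number = vapply(ds, function(d) d$carbon_number, integer(1)),
    branching = vapply(ds, function(d) d$branching, character(1)),
    n_unsaturations = vapply(ds, function(d) d$n_unsaturations, integer(1)),
    hydroxylated_3 = vapply(ds, function(d) d$hydroxylated_3, logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Format a fatty-acid descriptor in a given naming dialect
#'
#' The inverse of [parse_fa_name()]: `parse_fa_name(format_fa_name(d, dl))`
#' returns a descriptor equal to `d` for every dialect `dl`.
#'
#' @param x An [fa_descriptor()].
#' @param dialect `"short"` (`"i-C15"`), `"long"` (`"iso C_15"`) or
#'   `"colon"` (`"iso 15:0"`).
#' @return Character scalar.
#' @export
format_fa_name <- function(x, dialect = c("short", "long", "colon")) {
  stopifnot(inherits(x, "fa_descriptor"))
  dialect <- match.arg(dialect)
  pre <- if (x$hydroxylated_3) "3-OH " else ""
  u <- x$n_unsaturations
  out <- switch(dialect,
    short = {
      abbr <- c(normal = "n", iso = "i", anteiso = "ai")[[x$branching]]
      sprintf("%s-C%d%s", abbr, x$carbon_number,
              if (u > 0L) paste0(":", u) else "")
    },
    long = sprintf("%s C_%d%s",
                   x$branching, x$carbon_number,
                   if (u > 0L) paste0(":", u) else ""),
    colon = sprintf("%s%d:%d",
                    if (x$branching == "normal") "" else paste0(x$branching, " "),
                    x$carbon_number, u)
  )
  paste0(pre, out)
}
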