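#' Compound registry
#'
#' A compound registry is a data frame with one row per chemical species at
#' its dominant protonation state at pH 7 (so acetate is C2H3O2 with charge
#' -1, caproate C6H11O2 with charge -1, and protons are balanced explicitly
#' through the `H+` species). Columns:
#'
#' * `id` — unique short key (e.g. `"glucose"`, `"H+"`).
#' * `name` — free-text name.
#' * `formula` — Hill-style elemental formula string, e.g. `"C6H12O6"`.
#' * `charge` — signed integer charge of the species.
#' * `dfg_prime` — transformed standard formation energy (kJ/mol) at pH 7.0,
#'   ionic strength 0.25 M, 298.15 K.
#' * `dfg_uncertainty` — standard error of `dfg_prime` (kJ/mol; 0 if unknown).
#'
#' The packaged default table covers the ten species of the glucose and
#' lactate caproate fermentations. Aqueous CO2 and H2 are used and the proton
#' carries the pH-7 activity term RT ln(1e-7), so summing coefficient-weighted
#' entries over a balanced equation directly yields its transformed standard
#' reaction energy.
#'
#' @param path TSV file to read; defaults to the packaged table.
#' @return Registry data frame with an added `elements` list-column of named
#'   integer element counts.
#' @examples
#' reg <- default_compounds()
#' reg[reg$id == "caproate", c("formula", "charge", "dfg_prime")]
#' @export
read_compounds <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "formula", "charge", "dfg_prime", "dfg_uncertainty")
  if (!all(need %in% names(tab))) {
    stop("compound table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate compound id(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  tab$elements <- lapply(tab$formula, parse_formula)
  tab
}

#' @rdname read_compounds
#' @export
default_compounds <- function() {
  if (is.null(.registry_cache$tab)) {
    path <- system.file("extdata", "formation_energies.tsv",
                        package = "caproscope", mustWork = TRUE)
    .registry_cache$tab <- read_compounds(path)
  }
  .registry_cache$tab
}

.registry_cache <- new.env(parent = emptyenv())

#' Parse an elemental formula string
#'
#' Accepts element symbols followed by optional counts, e.g. `"C6H12O6"`,
#' `"H1"`, `"CO2"`. No parentheses or hydrates.
#'
#' @param formula formula string.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1 || is.na(formula)) {
    stop("formula must be a single string")
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (length(toks) == 0 || sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Za-z]+", "", paste0(toks, "")))
  n[is.na(n)] <- 1L
  counts <- tapply(n, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

registry_lookup <- function(ids, registry = default_compounds()) {
  idx <- match(ids, registry$id)
  if (anyNA(idx)) {
    stop("unknown compound id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         " (not in the registry)")
  }
  idx
}
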