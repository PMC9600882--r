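#' Construct a fermentation reaction
#'
#' A reaction is a signed stoichiometric map over registered compounds:
#' negative coefficients are consumed, positive produced. Coefficients are
#' exact rationals; duplicate ids are summed and zero net coefficients are
#' dropped.
#'
#' @param stoich named numeric or `rational` vector of coefficients, names
#'   being compound ids.
#' @param basis optional compound id used for per-mole normalization.
#' @param registry compound registry (see [default_compounds()]).
#' @return An object of class `reaction` with fields `ids`, `coef`
#'   (rational), and `basis`.
#' @examples
#' reaction(c(glucose = -1, CO2 = 6), basis = "glucose")
#' @export
reaction <- function(stoich, basis = NULL, registry = default_compounds()) {
  if (length(stoich) && is.null(names(stoich))) {
    stop("stoich must be a named vector of coefficients")
  }
  coef <- as_rational(unname(stoich))
  ids <- names(stoich)
  registry_lookup(unique(ids), registry)
  # sum duplicates, drop exact zeros
  uid <- unique(ids)
  merged <- rational(numeric(0))
  for (u in uid) {
    merged <- c(merged, sum(coef[ids == u]))
  }
  keep <- merged$num != 0
  uid <- uid[keep]
  merged <- merged[keep]
  if (!is.null(basis)) {
    registry_lookup(basis, registry)
  }
  structure(list(ids = uid, coef = merged, basis = basis),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  if (length(x$ids) == 0) {
    cat("<empty reaction>\n")
    return(invisible(x))
  }
  neg <- as.numeric(x$coef) < 0
  side <- function(i, flip) {
    co <- if (flip) -x$coef[i] else x$coef[i]
    paste(ifelse(format(co) == "1", x$ids[i],
                 paste(format(co), x$ids[i])), collapse = " + ")
  }
  cat(side(which(neg), TRUE), "->", side(which(!neg), FALSE), "\n")
  if (!is.null(x$basis)) cat("basis:", x$basis, "\n")
  invisible(x)
}

#' Stoichiometric coefficient lookup
#'
#' @param rxn a `reaction`.
#' @param id compound id.
#' @return The coefficient as a `rational` (zero if absent).
#' @export
reaction_coef <- function(rxn, id) {
  i <- match(id, rxn$ids)
  if (is.na(i)) rational(0) else rxn$coef[i]
}

#' Balance a fermentation equation over elements and charge
#'
#' Given fixed (measured) coefficients for some species and a list of free
#' species, solves the linear system with one conservation equation per
#' element plus one for charge, using exact rational elimination. The
#' returned reaction is exactly balanced.
#'
#' For the caproate fermentations the fixed species are the measured
#' substrates and products (glucose or lactate, acetate, caproate, butyrate)
#' and the free species are `H+`, `H2O`, `CO2` and `H2`; the system is then
#' square (C, H, O, charge) and has a unique solution whenever the fixed
#' species contain carbon.
#'
#' Non-integer fixed coefficients (noisy measured spectra) are snapped to a
#' common decimal denominator of `10^digits` before solving, which keeps the
#' exact elimination within the representable integer range; integer and
#' `rational` input is used as given.
#'
#' @param fixed named numeric/rational vector of fixed coefficients
#'   (negative = consumed).
#' @param free character vector of compound ids whose coefficients are to be
#'   solved.
#' @param basis optional basis compound id stored on the result.
#' @param digits decimal places retained for non-integer fixed coefficients.
#' @param registry compound registry.
#' @return A balanced `reaction` containing both fixed and solved
#'   coefficients.
#' @examples
#' balance_fermentation(
#'   c(glucose = -6, acetate = -2, caproate = 4, butyrate = 1),
#'   free = c("H+", "H2O", "CO2", "H2"))
#' @export
balance_fermentation <- function(fixed, free,
                                 basis = NULL,
                                 digits = 6,
                                 registry = default_compounds()) {
  if (length(intersect(names(fixed), free))) {
    stop("fixed and free species must be disjoint: ",
         paste(intersect(names(fixed), free), collapse = ", "))
  }
  idx_fixed <- registry_lookup(names(fixed), registry)
  idx_free <- registry_lookup(free, registry)
  fixed_r <- if (is.rational(fixed)) fixed else {
    v <- unname(fixed)
    if (all(v == round(v))) rational(v)
    else rational(round(v * 10^digits), 10^digits)
  }

  elements <- sort(unique(unlist(lapply(
    registry$elements[c(idx_fixed, idx_free)], names))))
  rows <- c(elements, "charge")

  count_of <- function(idx, el) {
    if (el == "charge") return(registry$charge[idx])
    v <- registry$elements[[idx]][el]
    if (is.na(v)) 0 else unname(v)
  }
  A <- matrix(0, length(rows), length(free),
              dimnames = list(rows, free))
  for (j in seq_along(free)) {
    for (r in seq_along(rows)) A[r, j] <- count_of(idx_free[j], rows[r])
  }
  # rhs: minus the fixed-side totals, kept rational
  b <- rational(rep(0, length(rows)))
  for (r in seq_along(rows)) {
    tot <- rational(0)
    for (k in seq_along(idx_fixed)) {
      tot <- tot + fixed_r[k] * rational(count_of(idx_fixed[k], rows[r]))
    }
    b[r] <- rational(0) - tot
  }
  sol <- tryCatch(rat_solve(A, b), caproscope_unbalanceable = function(e) {
    off <- conditionMessage(e)
    stop(errorCondition(
      paste0("unbalanceable fermentation specification: ", off),
      class = c("caproscope_unbalanceable", "error"),
      offending = attr(e, "offending")))
  })
  stoich <- c(fixed_r, sol)
  names_all <- c(names(fixed), free)
  rxn <- reaction_from_parts(names_all, stoich, basis, registry)
  res <- check_balance(rxn, registry)
  if (any(res != 0)) {
    stop("internal error: solved reaction fails the balance check")
  }
  rxn
}

reaction_from_parts <- function(ids, coef, basis, registry) {
  uid <- unique(ids)
  merged <- rational(numeric(0))
  for (u in uid) merged <- c(merged, sum(coef[ids == u]))
  keep <- merged$num != 0
  structure(list(ids = uid[keep], coef = merged[keep], basis = basis),
            class = "reaction")
}

#' Element and charge residuals of a reaction
#'
#' Sums coefficient-weighted element counts and charge over the reaction.
#' All residuals are zero exactly when the reaction is balanced. Residuals
#' are computed in exact rational arithmetic and returned as numeric.
#'
#' @param rxn a `reaction`.
#' @param registry compound registry.
#' @return Named numeric vector over the elements present plus `"charge"`;
#'   empty reaction gives an all-zero residual over no elements.
#' @examples
#' check_balance(fermentation_equation("eq1"))
#' @export
check_balance <- function(rxn, registry = default_compounds()) {
  idx <- registry_lookup(rxn$ids, registry)
  elements <- sort(unique(unlist(lapply(registry$elements[idx], names))))
  rows <- c(elements, "charge")
  if (length(idx) == 0) return(stats::setNames(numeric(1), "charge"))
  out <- numeric(length(rows))
  names(out) <- rows
  for (r in seq_along(rows)) {
    tot <- rational(0)
    for (k in seq_along(idx)) {
      cnt <- if (rows[r] == "charge") registry$charge[idx[k]] else {
        v <- registry$elements[[idx[k]]][rows[r]]
        if (is.na(v)) 0 else unname(v)
      }
      tot <- tot + rxn$coef[k] * rational(cnt)
    }
    out[r] <- as.numeric(tot)
  }
  out
}

#' Built-in caproate fermentation equations
#'
#' The two balanced fermentation equations of *C. lactatifermentans* grown at
#' a reducing-substrate:acetate ratio of 5:1, as printed:
#'
#' * `"eq1"` (glucose): 6 glucose + 2 acetate -> 4 caproate + butyrate +
#'   3 H+ + 6 H2O + 12 CO2 + 6 H2, basis glucose.
#' * `"eq2"` (lactate): 21 lactate + 2 acetate + 15 H+ -> 7 caproate +
#'   butyrate + 9 H2O + 21 CO2 + 12 H2, basis lactate.
#'
#' @param which `"eq1"`/`"glucose"` or `"eq2"`/`"lactate"`.
#' @return A balanced `reaction`.
#' @export
fermentation_equation <- function(which = c("eq1", "eq2", "glucose", "lactate")) {
  which <- match.arg(which)
  if (which %in% c("eq1", "glucose")) {
    reaction(c(glucose = -6, acetate = -2, caproate = 4, butyrate = 1,
               `H+` = 3, H2O = 6, CO2 = 12, H2 = 6), basis = "glucose")
  } else {
    reaction(c(lactate = -21, acetate = -2, `H+` = -15, caproate = 7,
               butyrate = 1, H2O = 9, CO2 = 21, H2 = 12), basis = "lactate")
  }
}

#' Transformed standard reaction Gibbs energy
#'
#' Computes the transformed standard reaction energy of a balanced reaction
#' from the packaged formation-energy table (pH 7.0, ionic strength 0.25 M,
#' 298.15 K), normalized per mole of a basis compound. Uncertainty is the
#' root-sum-square of coefficient-weighted per-compound standard errors
#' (covariances between compound estimates are not available, so this
#' approximates the uncertainty of the difference).
#'
#' @param rxn a balanced `reaction`.
#' @param basis compound id to normalize by; defaults to `rxn$basis`.
#' @param registry compound registry carrying `dfg_prime`.
#' @return An object of class `thermo_result`: list with `drg_prime` (kJ per
#'   mole of basis), `uncertainty` (kJ/mol), `basis`.
#' @examples
#' delta_r_g_prime(fermentation_equation("eq1"), basis = "glucose")
#' @export
delta_r_g_prime <- function(rxn, basis = rxn$basis,
                            registry = default_compounds()) {
  if (length(rxn$ids) == 0) {
    stop("empty reaction: no basis compound present")
  }
  if (is.null(basis)) stop("a basis compound id is required")
  res <- check_balance(rxn, registry)
  if (any(res != 0)) {
    stop("reaction is not balanced (residuals in ",
         paste(names(res)[res != 0], collapse = ", "),
         "); refusing to compute a reaction energy")
  }
  idx <- registry_lookup(rxn$ids, registry)
  if (anyNA(registry$dfg_prime[idx])) {
    stop("no thermodynamic data for: ",
         paste(rxn$ids[is.na(registry$dfg_prime[idx])], collapse = ", "))
  }
  bcoef <- reaction_coef(rxn, basis)
  if (bcoef$num == 0) {
    stop("basis compound '", basis, "' does not appear in the reaction")
  }
  coef <- as.numeric(rxn$coef)
  scale <- abs(as.numeric(bcoef))
  drg <- sum(coef * registry$dfg_prime[idx]) / scale
  u <- sqrt(sum((coef * registry$dfg_uncertainty[idx])^2)) / scale
  structure(list(drg_prime = drg, uncertainty = u, basis = basis),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("deltaG'0 = %.1f +- %.1f kJ per mol %s\n",
              x$drg_prime, x$uncertainty, x$basis))
  invisible(x)
}

#' JSON report for a reaction
#'
#' Serializes a reaction (and optionally its thermodynamics) in the report
#' schema `{stoich: {id: "num/den"}, balanced, basis, drg_prime,
#' uncertainty}`.
#'
#' @param rxn a `reaction`.
#' @param thermo optional `thermo_result` for the same reaction.
#' @param path optional file to write; if `NULL` the JSON string is returned.
#' @param registry compound registry.
#' @return JSON string (invisibly when written to file).
#' @export
reaction_report <- function(rxn, thermo = NULL, path = NULL,
                            registry = default_compounds()) {
  res <- check_balance(rxn, registry)
  obj <- list(
    stoich = stats::setNames(as.list(format(rxn$coef)), rxn$ids),
    balanced = all(res == 0),
    basis = if (is.null(rxn$basis)) NA else rxn$basis)
  if (!is.null(thermo)) {
    obj$drg_prime <- thermo$drg_prime
    obj$uncertainty <- thermo$uncertainty
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
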