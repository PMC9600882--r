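#' Ledger configuration
#'
#' Chemiosmotic constants of the cofactor-ledger model of chain-elongation
#' bioenergetics.
#'
#' @param rnf_protons_per_2e protons translocated by the Rnf complex per
#'   reduced ferredoxin (2 e-) oxidized. Default 2, the small-integer
#'   stoichiometry that reproduces both published ATP yields together with
#'   the 4 H+/ATP ATPase.
#' @param atpase_protons_per_atp protons consumed per ATP by the V-type
#'   ATPase. Default exactly 4 (value adopted for *C. lactatifermentans*
#'   from the *T. thermophilus* enzyme).
#' @param hydrogenase_donor carrier whose surplus reducing equivalents are
#'   vented as H2: `"nadh"` (default; all ferredoxin is first routed through
#'   Rnf and the NADH surplus is vented at 1 NADH : 1 H2) or `"fd"` (only
#'   the ferredoxin needed to cover the NADH demand passes Rnf, the rest is
#'   vented directly). The default is the routing that simultaneously closes
#'   the NADH ledger and the printed H2 coefficients of the two fermentation
#'   equations.
#' @return A `ledger_config` list.
#' @export
ledger_config <- function(rnf_protons_per_2e = 2,
                          atpase_protons_per_atp = 4,
                          hydrogenase_donor = c("nadh", "fd")) {
  hydrogenase_donor <- match.arg(hydrogenase_donor)
  if (as.numeric(as_rational(rnf_protons_per_2e)) <= 0 ||
      as.numeric(as_rational(atpase_protons_per_atp)) <= 0) {
    stop("ledger constants must be positive")
  }
  structure(list(rnf_protons_per_2e = as_rational(rnf_protons_per_2e),
                 atpase_protons_per_atp = as_rational(atpase_protons_per_atp),
                 hydrogenase_donor = hydrogenase_donor),
            class = "ledger_config")
}

# per-mole substrate oxidation stoichiometries (acetyl-CoA, NADH, reduced
# ferredoxin, substrate-level ATP):
#  - glucose: PTS uptake + glycolysis (net 2 ATP) + 2 Pfor
#  - lactate: confurcating Ldh/EtfAB (consumes 1 Fd2-) + Pfor (restores it)
#  - pyruvate: Pfor only
.oxidation_table <- list(
  glucose  = c(acetyl_coa = 2, nadh = 2, fd = 2, atp_slp = 2),
  lactate  = c(acetyl_coa = 1, nadh = 2, fd = 0, atp_slp = 0),
  pyruvate = c(acetyl_coa = 1, nadh = 0, fd = 1, atp_slp = 0))

#' Substrate oxidation ledger
#'
#' Per-mole cofactor yields of oxidizing a reducing substrate to acetyl-CoA:
#' glucose via PTS/glycolysis and pyruvate:ferredoxin oxidoreductase,
#' lactate via the electron-confurcating Ldh/EtfAB complex plus Pfor
#' (lactate's net ferredoxin is zero: Ldh consumes the Fd2- that Pfor
#' restores), pyruvate via Pfor alone.
#'
#' @param substrate `"glucose"`, `"lactate"` or `"pyruvate"`.
#' @param moles moles oxidized (rational or numeric).
#' @return List of rationals: `acetyl_coa`, `nadh`, `fd`, `atp_slp`.
#' @examples
#' oxidize_substrate("glucose", 1)
#' @export
oxidize_substrate <- function(substrate, moles = 1) {
  if (!substrate %in% names(.oxidation_table)) {
    stop("unknown reducing substrate: ", substrate,
         " (expected glucose, lactate or pyruvate)")
  }
  m <- as_rational(moles)
  per <- .oxidation_table[[substrate]]
  list(acetyl_coa = m * rational(per[["acetyl_coa"]]),
       nadh = m * rational(per[["nadh"]]),
       fd = m * rational(per[["fd"]]),
       atp_slp = m * rational(per[["atp_slp"]]))
}

#' Reducing-equivalent pairs per mole of substrate
#'
#' Counts (NADH + reduced ferredoxin) pairs released by complete oxidation
#' of one mole of substrate to acetyl-CoA: 4 for glucose, 2 for lactate,
#' 1 for pyruvate — hence pyruvate provides one quarter of glucose's and one
#' half of lactate's reducing power.
#'
#' @param substrate `"glucose"`, `"lactate"` or `"pyruvate"`.
#' @return A `rational` count.
#' @export
reducing_equivalent_pairs <- function(substrate) {
  ox <- oxidize_substrate(substrate, 1)
  ox$nadh + ox$fd
}

#' Fermentation product spectrum
#'
#' The per-basis product spectrum of a chain-elongation fermentation:
#' reducing substrate consumed, acetate consumed (negative = net produced),
#' caproate and butyrate produced. Two-carbon units are conserved:
#' `3*caproate + 2*butyrate = acetyl-CoA yield * substrate +
#' acetate_consumed`; when `acetate_consumed` is omitted it is inferred from
#' that closure.
#'
#' @param substrate reducing substrate id.
#' @param substrate_moles moles of substrate consumed (>= 0).
#' @param caproate,butyrate moles produced.
#' @param acetate_consumed moles of acetate consumed (negative for net
#'   production); inferred from C2 closure when `NULL`.
#' @param basis free-text label of the normalization basis.
#' @return A `fermentation_spectrum`.
#' @examples
#' fermentation_spectrum("glucose", 1, caproate = 2/3, butyrate = 1/6)
#' @export
fermentation_spectrum <- function(substrate, substrate_moles,
                                  caproate = 0, butyrate = 0,
                                  acetate_consumed = NULL,
                                  basis = "per mole substrate") {
  s <- as_rational(substrate_moles)
  if (as.numeric(s) < 0) stop("substrate moles must be nonnegative")
  cap <- as_rational(caproate) ; but <- as_rational(butyrate)
  yield <- oxidize_substrate(substrate, 1)$acetyl_coa
  implied <- rational(3) * cap + rational(2) * but - yield * s
  if (is.null(acetate_consumed)) {
    a <- implied
  } else {
    a <- as_rational(acetate_consumed)
    if (!(a == implied)) {
      stop("spectrum violates C2-unit conservation: acetate_consumed should ",
           "be ", format(implied), " given the other moles")
    }
  }
  structure(list(substrate = substrate, substrate_moles = s,
                 acetate_consumed = a, caproate = cap, butyrate = but,
                 basis = basis),
            class = "fermentation_spectrum")
}

#' @export
print.fermentation_spectrum <- function(x, ...) {
  cat(sprintf("fermentation spectrum (%s):\n", x$basis))
  cat(sprintf("  %s consumed: %s\n", x$substrate, format(x$substrate_moles)))
  cat(sprintf("  acetate %s: %s\n",
              if (as.numeric(x$acetate_consumed) >= 0) "consumed" else "produced",
              format(abs(x$acetate_consumed))))
  cat(sprintf("  caproate: %s, butyrate: %s\n",
              format(x$caproate), format(x$butyrate)))
  invisible(x)
}

#' Derive a product spectrum from a balanced fermentation equation
#'
#' Reads the single reducing substrate (glucose, lactate or pyruvate),
#' acetate, caproate and butyrate coefficients off a balanced reaction and
#' normalizes them to the requested basis: per mole of substrate, per the
#' equation as printed, or per glucose-equivalent (one mole of glucose is
#' equivalent to two moles of lactate).
#'
#' @param rxn a balanced `reaction`.
#' @param per `"substrate"`, `"equation"` or `"glucose_equivalent"`.
#' @param registry compound registry.
#' @return A `fermentation_spectrum`.
#' @examples
#' spectrum_from_equation(fermentation_equation("eq1"))
#' @export
spectrum_from_equation <- function(rxn,
                                   per = c("substrate", "equation",
                                           "glucose_equivalent"),
                                   registry = default_compounds()) {
  per <- match.arg(per)
  subs <- intersect(rxn$ids, names(.oxidation_table))
  subs <- subs[vapply(subs, function(s) as.numeric(reaction_coef(rxn, s)) < 0,
                      logical(1))]
  if (length(subs) != 1) {
    stop("expected exactly one consumed reducing substrate, found: ",
         if (length(subs)) paste(subs, collapse = ", ") else "none")
  }
  s <- rational(0) - reaction_coef(rxn, subs)
  scale <- switch(per,
    equation = rational(1),
    substrate = rational(1) / s,
    glucose_equivalent = {
      eq <- if (subs == "glucose") rational(1) else rational(2)
      eq / s
    })
  fermentation_spectrum(
    substrate = subs,
    substrate_moles = s * scale,
    caproate = reaction_coef(rxn, "caproate") * scale,
    butyrate = reaction_coef(rxn, "butyrate") * scale,
    acetate_consumed = (rational(0) - reaction_coef(rxn, "acetate")) * scale,
    basis = switch(per,
      equation = "per equation as printed",
      substrate = paste("per mole", subs),
      glucose_equivalent = "per glucose-equivalent"))
}

#' Reverse beta-oxidation demand of a product spectrum
#'
#' Each elongation cycle (thiolase condensation, Hbd, Crt, bifurcating
#' Bcd/EtfAB) consumes one acetyl-CoA and three NADH (one at Hbd, two at the
#' bifurcating Bcd) and regenerates one reduced ferredoxin. Caproate takes
#' two cycles from its acetate primer, butyrate one.
#'
#' @param spectrum a `fermentation_spectrum`.
#' @return List of rationals: `steps`, `nadh_required`, `fd_generated`.
#' @examples
#' elongation_demand(spectrum_from_equation(fermentation_equation("eq1")))
#' @export
elongation_demand <- function(spectrum) {
  steps <- rational(2) * spectrum$caproate + spectrum$butyrate
  if (as.numeric(steps) < 0) stop("malformed spectrum: negative elongation")
  list(steps = steps,
       nadh_required = rational(3) * steps,
       fd_generated = steps)
}

#' Redox feasibility of a product spectrum
#'
#' Checks whether the NADH obtainable from substrate oxidation plus Rnf
#' turnover of all reduced ferredoxin covers the reverse beta-oxidation NADH
#' demand. When infeasible, also reports the maximal elongation the redox
#' budget supports, with the remaining acetyl-CoA discharged as acetate via
#' Ack-Pta (earning 1 ATP each) — the situation observed when pyruvate is
#' the reducing substrate and acetate, not caproate, dominates the products.
#'
#' @param spectrum a `fermentation_spectrum`.
#' @param config a `ledger_config`.
#' @return List: `feasible`, `nadh_deficit` (rational), and when infeasible
#'   `max_spectrum` (caproate-only spectrum at the maximal feasible
#'   elongation) plus `acetate_produced` under that spectrum.
#' @export
redox_feasibility <- function(spectrum, config = ledger_config()) {
  ox <- oxidize_substrate(spectrum$substrate, spectrum$substrate_moles)
  el <- elongation_demand(spectrum)
  supply <- ox$nadh + ox$fd + el$fd_generated  # each Fd2- yields 1 NADH via Rnf
  deficit <- el$nadh_required - supply
  if (as.numeric(deficit) <= 0) deficit <- rational(0)
  out <- list(feasible = deficit == rational(0), nadh_deficit = deficit)
  if (!out$feasible) {
    # 3*steps <= ox_nadh + ox_fd + steps  =>  steps <= (ox_nadh + ox_fd)/2
    max_steps <- (ox$nadh + ox$fd) / rational(2)
    cap <- max_steps / rational(2)
    acetate_out <- ox$acetyl_coa - max_steps
    out$max_spectrum <- fermentation_spectrum(
      spectrum$substrate, spectrum$substrate_moles,
      caproate = cap, butyrate = 0,
      basis = spectrum$basis)
    out$acetate_produced <- acetate_out
  }
  out
}

#' Run the cofactor ledger
#'
#' Converts a feasible fermentation product spectrum into a closed cofactor
#' ledger: all reduced ferredoxin (substrate oxidation + elongation) passes
#' the Rnf complex, translocating `rnf_protons_per_2e` protons and yielding
#' one NADH each; the NADH surplus over the elongation demand is vented as
#' H2 (1:1); net acetate production earns one substrate-level ATP per mole
#' via Ack-Pta; chemiosmotic ATP is translocated protons divided by the
#' ATPase H+/ATP ratio. All arithmetic is exact.
#'
#' @param spectrum a `fermentation_spectrum`.
#' @param config a `ledger_config`.
#' @return A `cofactor_ledger`: rationals `atp_slp`, `nadh_produced`,
#'   `nadh_consumed`, `fd_reduced`, `protons_translocated`,
#'   `atp_chemiosmotic`, `h2`, `atp_total`, plus the `config` and the
#'   spectrum `basis`.
#' @examples
#' run_ledger(spectrum_from_equation(fermentation_equation("eq1")))
#' @export
run_ledger <- function(spectrum, config = ledger_config()) {
  ox <- oxidize_substrate(spectrum$substrate, spectrum$substrate_moles)
  el <- elongation_demand(spectrum)
  fd_total <- ox$fd + el$fd_generated

  if (config$hydrogenase_donor == "nadh") {
    fd_rnf <- fd_total
    fd_vented <- rational(0)
  } else {
    need <- el$nadh_required - ox$nadh
    if (as.numeric(need) < 0) need <- rational(0)
    fd_rnf <- if (need <= fd_total) need else fd_total
    fd_vented <- fd_total - fd_rnf
  }
  nadh_rnf <- fd_rnf
  nadh_avail <- ox$nadh + nadh_rnf
  surplus <- nadh_avail - el$nadh_required
  if (as.numeric(surplus) < 0) {
    stop(errorCondition(
      paste0("redox-infeasible spectrum: NADH deficit of ",
             format(rational(0) - surplus), " after Rnf routing"),
      class = c("caproscope_redox_infeasible", "error"),
      deficit = as.numeric(rational(0) - surplus)))
  }
  h2 <- surplus + fd_vented
  acetate_produced <- rational(0) - spectrum$acetate_consumed
  if (as.numeric(acetate_produced) < 0) acetate_produced <- rational(0)
  atp_slp <- ox$atp_slp + acetate_produced
  protons <- config$rnf_protons_per_2e * fd_rnf
  atp_chemi <- protons / config$atpase_protons_per_atp
  structure(list(
    atp_slp = atp_slp,
    nadh_produced = nadh_avail,
    nadh_consumed = el$nadh_required + surplus,
    fd_reduced = fd_total,
    protons_translocated = protons,
    atp_chemiosmotic = atp_chemi,
    h2 = h2,
    atp_total = atp_slp + atp_chemi,
    basis = spectrum$basis,
    config = config), class = "cofactor_ledger")
}

#' @export
print.cofactor_ledger <- function(x, ...) {
  cat(sprintf("cofactor ledger (%s):\n", x$basis))
  num <- function(r) sprintf("%.2f", as.numeric(r))
  cat("  ATP (substrate-level):", num(x$atp_slp), "\n")
  cat("  ATP (chemiosmotic):   ", num(x$atp_chemiosmotic), "\n")
  cat("  ATP total:            ", num(x$atp_total), "\n")
  cat("  NADH produced/consumed:", num(x$nadh_produced), "/",
      num(x$nadh_consumed), "\n")
  cat("  Fd2- through Rnf:     ", num(x$fd_reduced), "\n")
  cat("  H+ translocated:      ", num(x$protons_translocated), "\n")
  cat("  H2 vented:            ", num(x$h2), "\n")
  invisible(x)
}

#' JSON report of a cofactor ledger
#'
#' @param ledger a `cofactor_ledger`.
#' @param path optional output file.
#' @return JSON string (invisibly when written).
#' @export
ledger_report <- function(ledger, path = NULL) {
  num <- function(r) round(as.numeric(r), 2)
  obj <- list(basis = ledger$basis,
              atp_slp = num(ledger$atp_slp),
              atp_chemiosmotic = num(ledger$atp_chemiosmotic),
              atp_total = num(ledger$atp_total),
              nadh_produced = num(ledger$nadh_produced),
              nadh_consumed = num(ledger$nadh_consumed),
              fd_reduced = num(ledger$fd_reduced),
              protons_translocated = num(ledger$protons_translocated),
              h2 = num(ledger$h2),
              config = list(
                rnf_protons_per_2e =
                  as.numeric(ledger$config$rnf_protons_per_2e),
                atpase_protons_per_atp =
                  as.numeric(ledger$config$atpase_protons_per_atp),
                hydrogenase_donor = ledger$config$hydrogenase_donor))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Free energy dissipated per mole of ATP
#'
#' @param drg_per_basis transformed reaction energy on some basis (kJ/mol;
#'   sign ignored).
#' @param atp_per_basis ATP yield on the same basis (mol; must be positive).
#' @return kJ per mole of ATP (numeric).
#' @examples
#' free_energy_per_atp(-254.2, 3.75)  # ~68
#' @export
free_energy_per_atp <- function(drg_per_basis, atp_per_basis) {
  atp <- as.numeric(as_rational(atp_per_basis))
  if (atp <= 0) {
    stop("ATP yield must be positive: cannot express energy per mole of ",
         "ATP for a pathway with no net ATP synthesis")
  }
  abs(as.numeric(drg_per_basis)) / atp
}
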