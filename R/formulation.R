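# Sprayable-ink formulation arithmetic: surfactant blend HLB and emulsion
# phase composition.

#' Reference HLB values for common sorbitan/polysorbate surfactants
#'
#' Standard hydrophilic/lipophilic balance constants from surfactant
#' supplier tables; the blend used for the sprayable silicone ink combines
#' Span 85 and Tween 40.
#'
#' @format Data frame with columns `name` and `hlb`.
#' @export
surfactant_hlb <- data.frame(
  name = c("Span 85", "Span 80", "Span 60", "Span 20",
           "Tween 20", "Tween 40", "Tween 60", "Tween 80"),
  hlb = c(1.8, 4.3, 4.7, 8.6, 16.7, 15.6, 14.9, 15.0))

#' Blend HLB of a surfactant mixture
#'
#' The HLB of a surfactant blend is the weight-fraction-weighted arithmetic
#' mean of the component HLB values. Weights are normalized internally.
#'
#' @param weights Numeric vector of blend weights (parts or fractions). If
#'   named with surfactant names present in [surfactant_hlb], `hlb` may be
#'   omitted.
#' @param hlb Component HLB values (same length as `weights`).
#' @return Blend HLB (dimensionless), bounded by the component range.
#' @examples
#' blend_hlb(c("Span 85" = 3, "Tween 40" = 7)) # 11.46, i.e. 11.5
#' @export
blend_hlb <- function(weights, hlb = NULL) {
  if (length(weights) == 0) stop_invalid("empty surfactant list")
  if (is.null(hlb)) {
    if (is.null(names(weights)))
      stop_invalid("provide hlb values or name the weights after known surfactants")
    idx <- match(names(weights), surfactant_hlb$name)
    if (anyNA(idx))
      stop_invalid("unknown surfactant(s): ",
                   paste(names(weights)[is.na(idx)], collapse = ", "))
    hlb <- surfactant_hlb$hlb[idx]
  }
  if (length(hlb) != length(weights))
    stop_invalid("weights and hlb must have the same length")
  if (any(weights < 0) || sum(weights) == 0)
    stop_invalid("weights must be non-negative with positive sum")
  if (any(hlb < 0 | hlb > 20)) stop_invalid("HLB values must be in [0, 20]")
  sum(weights * hlb) / sum(weights)
}

#' Sprayable-ink recipe
#'
#' The emulsion ink is built from a saturated salt solution (40 wt% NaCl)
#' blended 3:1 with a 20 wt% PEG solution to form the aqueous (porogen)
#' phase; silicone diluted in n-heptane forms the continuous phase; the two
#' are combined at a 1:3 aqueous:silicone-solution ratio and a surfactant
#' blend is added at 3 wt% of the overall liquid.
#'
#' The heptane dilution "1:3 by weight" is read as 1 part silicone : 3
#' parts heptane by default; the opposite reading is selectable.
#'
#' @param salt_wt Salt mass fraction of the salt solution (default 0.40).
#' @param peg_wt PEG mass fraction of the PEG solution (default 0.20).
#' @param aqueous_parts Parts salt solution : parts PEG solution (default
#'   `c(3, 1)`).
#' @param dilution_parts Parts silicone : parts heptane (default `c(1, 3)`).
#' @param phase_parts Parts aqueous : parts silicone solution (default
#'   `c(1, 3)`).
#' @param surfactant_wt Surfactant fraction of the total liquid (default
#'   0.03).
#' @return An object of class `ink_recipe`.
#' @export
ink_recipe <- function(salt_wt = 0.40, peg_wt = 0.20,
                       aqueous_parts = c(3, 1), dilution_parts = c(1, 3),
                       phase_parts = c(1, 3), surfactant_wt = 0.03) {
  for (f in c(salt_wt, peg_wt, surfactant_wt))
    if (f < 0 || f >= 1) stop_invalid("mass fractions must lie in [0, 1)")
  for (p in list(aqueous_parts, dilution_parts, phase_parts))
    if (length(p) != 2 || any(p < 0)) stop_invalid("part ratios must be two non-negative numbers")
  structure(list(salt_wt = salt_wt, peg_wt = peg_wt,
                 aqueous_parts = aqueous_parts,
                 dilution_parts = dilution_parts,
                 phase_parts = phase_parts,
                 surfactant_wt = surfactant_wt),
            class = "ink_recipe")
}

#' Ink composition report
#'
#' Resolves a recipe into overall mass fractions (water, salt, PEG,
#' silicone solids, heptane, surfactant) and reports the
#' aqueous-phase : silicone-solids ratio alongside the stated 2:1
#' (salt solution : solid silicone) process target. Straightforward
#' arithmetic on the recipe ratios gives approximately 1.33:1, not 2:1;
#' the disagreement is surfaced in the report rather than hidden.
#'
#' @param recipe An [ink_recipe()].
#' @param target_ratio Stated process target for aqueous : solids
#'   (default 2).
#' @return An object of class `composition_report`: list with `fractions`
#'   (named, summing to 1), `aqueous_to_solids`, `target_ratio`,
#'   `matches_target`.
#' @export
ink_composition <- function(recipe = ink_recipe(), target_ratio = 2) {
  stopifnot(inherits(recipe, "ink_recipe"))
  aq <- recipe$phase_parts[1] / sum(recipe$phase_parts)
  sil_sol <- recipe$phase_parts[2] / sum(recipe$phase_parts)
  salt_solution <- aq * recipe$aqueous_parts[1] / sum(recipe$aqueous_parts)
  peg_solution <- aq * recipe$aqueous_parts[2] / sum(recipe$aqueous_parts)
  solids <- sil_sol * recipe$dilution_parts[1] / sum(recipe$dilution_parts)
  heptane <- sil_sol * recipe$dilution_parts[2] / sum(recipe$dilution_parts)
  base <- c(
    salt = salt_solution * recipe$salt_wt,
    peg = peg_solution * recipe$peg_wt,
    water = salt_solution * (1 - recipe$salt_wt) +
      peg_solution * (1 - recipe$peg_wt),
    silicone_solids = solids,
    heptane = heptane)
  # surfactant is added at surfactant_wt of the overall liquid
  s <- recipe$surfactant_wt
  fractions <- c(base * (1 - s), surfactant = s)
  ratio <- if (solids > 0) aq / solids else 0
  structure(list(fractions = fractions,
                 aqueous_to_solids = ratio,
                 target_ratio = target_ratio,
                 matches_target = isTRUE(abs(ratio - target_ratio) < 0.05)),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat("ink composition (mass fractions):\n")
  print(round(x$fractions, 4))
  cat(sprintf("aqueous : silicone solids = %.2f : 1 (stated target %.1f : 1)%s\n",
              x$aqueous_to_solids, x$target_ratio,
              if (x$matches_target) "" else "  [DISAGREES]"))
  invisible(x)
}
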