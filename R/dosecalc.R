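# Chow-equivalent nutrient-intake arithmetic for supplement cocktails.
#
# A mouse eating ~3 g chow and drinking ~4.8 ml supplemented water per day
# receives, per nutrient, chow_conc * 3 g + water_conc * 4.8 ml of mass
# (taking water density as 1 g/ml so % w/v mass = conc x ml). Expressing
# that combined intake as a chow concentration gives
#   effective = chow_conc + water_conc * water_ml / chow_g,
# identical algebra for % w/w and for ppm.

#' Drinking-water cocktail presets
#'
#' Named water concentrations of the branched-chain amino acids
#' (Leu:Ile:Val = 2:1:1), L-serine (%) and zinc (ppm) for the half,
#' quarter and eighth cocktails. The half-cocktail Ile and Val entries
#' are stored as 0.225% — half of the 0.45% full BCAA dose — rather than
#' a value rounded to 0.25%, since 0.225 is what reproduces the published
#' effective chow concentrations (Ile 1.1%, Val 1.23%).
#'
#' @param name `"half"`, `"quarter"` or `"eighth"`.
#' @return Named numeric vector (Ile, Leu, Val, Ser in %; Zn in ppm).
#' @examples
#' cocktailPreset("quarter")
#' @export
cocktailPreset <- function(name = c("half", "quarter", "eighth")) {
  name <- match.arg(name)
  switch(name,
    half    = c(Ile = 0.225,  Leu = 0.45,   Val = 0.225,  Ser = 1.0, Zn = 20),
    quarter = c(Ile = 0.1125, Leu = 0.225,  Val = 0.1125, Ser = 1.0, Zn = 20),
    eighth  = c(Ile = 0.056,  Leu = 0.1125, Val = 0.056,  Ser = 0.5, Zn = 20))
}

#' Chow-equivalent concentration of one nutrient
#'
#' Combined daily intake from chow plus supplemented drinking water,
#' expressed as a concentration in chow (same units in and out: % stays
#' %, ppm stays ppm). Linear in the water concentration and never below
#' the chow baseline.
#'
#' @param diet a [dietSpec()].
#' @param nutrient nutrient key present in the chow concentrations.
#' @return A single number (full precision; round for display with
#'   `roundHalfUp`-style rounding as in [cocktailTable()]).
#' @examples
#' effectiveConcentration(dietSpec(cocktailPreset("half")), "Leu")  # 2.21
#' @export
effectiveConcentration <- function(diet, nutrient) {
  stopifnot(is(diet, "DietSpec"))
  if (diet@chowIntakeG == 0) stop("chow intake must be positive")
  if (!nutrient %in% names(diet@chowConc))
    stop("unknown nutrient: ", nutrient)
  w <- if (nutrient %in% names(diet@waterConc)) diet@waterConc[[nutrient]] else 0
  diet@chowConc[[nutrient]] + w * diet@waterIntakeMl / diet@chowIntakeG
}

#' Effective dietary concentrations for a supplement cocktail
#'
#' Chow-equivalent concentration of each of the five supplemented
#' nutrients (Ile, Leu, Val, Ser, Zn) for a cocktail preset or custom
#' water concentrations, against the LabDiet 5K54 chow baseline by
#' default. The `display` column rounds half-up to the printed precision
#' (two decimals for percentages, whole ppm for zinc); `effective` keeps
#' full precision.
#'
#' @param preset preset name (see [cocktailPreset()]) or a named numeric
#'   vector of water concentrations.
#' @param diet optional [dietSpec()] overriding the chow baseline and
#'   intakes (its water concentrations are replaced by `preset`).
#' @return A data.frame with `nutrient`, `unit`, `chow`, `water`,
#'   `effective`, `display`.
#' @examples
#' cocktailTable("quarter")
#' @export
cocktailTable <- function(preset = "quarter", diet = NULL) {
  water <- if (is.character(preset)) cocktailPreset(preset) else preset
  if (is.null(names(water))) stop("water concentrations must be named")
  if (is.null(diet)) {
    diet <- dietSpec(water)
  } else {
    diet <- dietSpec(water, chowConc = diet@chowConc,
                     chowIntakeG = diet@chowIntakeG,
                     waterIntakeMl = diet@waterIntakeMl)
  }
  nutrients <- names(diet@chowConc)
  missing <- setdiff(names(water), nutrients)
  if (length(missing))
    stop("chow baseline lacks nutrient(s): ", paste(missing, collapse = ", "))
  eff <- vapply(nutrients, effectiveConcentration, numeric(1), diet = diet)
  unit <- ifelse(nutrients == "Zn", "ppm", "%")
  data.frame(
    nutrient = nutrients, unit = unit,
    chow = unname(diet@chowConc),
    water = unname(vapply(nutrients, function(nm)
      if (nm %in% names(water)) water[[nm]] else 0, numeric(1))),
    effective = unname(eff),
    display = unname(ifelse(unit == "ppm", roundHalfUp(eff, 0),
                            roundHalfUp(eff, 2))),
    row.names = NULL)
}
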