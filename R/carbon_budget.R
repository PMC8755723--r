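# Molar masses (g/mol) for the carbon fraction of the dissolved species.
.MM_C <- 12.011
.MM_CO2 <- 44.009
.MM_HCO3 <- 61.016

#' Volume of a cylindrical geyser tubing system
#'
#' @param radius_m Inner radius in metres.
#' @param length_m Tubing length in metres.
#' @return Volume in cubic metres (`pi * r^2 * L`).
#' @export
tubing_volume <- function(radius_m, length_m) {
  check_number(radius_m, "radius_m", min = .Machine$double.eps)
  check_number(length_m, "length_m", min = .Machine$double.eps)
  pi * radius_m^2 * length_m
}

#' Eruptions per year over an observation season
#'
#' @param season_days Days per year the geyser is driven/observed
#'   (default 210, an April-October season).
#' @param eruptions_per_day Eruptions per day (12 for an eruption roughly
#'   every two hours).
#' @return Eruption count per year (real-valued).
#' @export
annual_eruptions <- function(season_days = 210, eruptions_per_day = 12) {
  check_number(season_days, "season_days", min = 0)
  check_number(eruptions_per_day, "eruptions_per_day", min = 0)
  season_days * eruptions_per_day
}

#' Annual cell-bound carbon erupted by the geyser
#'
#' Converts a cell density to grams of biomass carbon per year:
#' `cells/ml * 1e6 ml/m3 * volume * eruptions * fg C per cell * 1e-15 g/fg`.
#'
#' @param cells_per_ml Cell density of the erupted fluid.
#' @param fg_c_per_cell Intracellular carbon per cell in femtograms
#'   (default 14).
#' @param eruption_volume_m3 Fluid volume per eruption in cubic metres.
#' @param eruptions_per_year Eruption count per year.
#' @return Grams of carbon per year.
#' @export
cell_carbon <- function(cells_per_ml, fg_c_per_cell = 14,
                        eruption_volume_m3, eruptions_per_year) {
  check_number(cells_per_ml, "cells_per_ml", min = 0)
  check_number(fg_c_per_cell, "fg_c_per_cell", min = 0)
  check_number(eruption_volume_m3, "eruption_volume_m3", min = 0)
  check_number(eruptions_per_year, "eruptions_per_year", min = 0)
  cells_per_ml * 1e6 * eruption_volume_m3 * eruptions_per_year *
    fg_c_per_cell * 1e-15
}

#' Annual inorganic carbon erupted as dissolved CO2 and bicarbonate
#'
#' Concentrations in mg/L convert to kg/m3 one-to-one in value (1 mg/L =
#' 1 g/m3 = 1e-3 kg/m3); the carbon mass fraction of each species is its
#' molar carbon share (12.011/44.009 for CO2, 12.011/61.016 for HCO3-).
#'
#' @param co2_mg_per_l Dissolved CO2 concentration (mg/L).
#' @param hco3_mg_per_l Bicarbonate concentration (mg/L).
#' @param eruption_volume_m3 Fluid volume per eruption (m3).
#' @param eruptions_per_year Eruption count per year.
#' @return Kilograms of carbon per year.
#' @export
erupted_carbon <- function(co2_mg_per_l, hco3_mg_per_l,
                           eruption_volume_m3, eruptions_per_year) {
  check_number(co2_mg_per_l, "co2_mg_per_l", min = 0)
  check_number(hco3_mg_per_l, "hco3_mg_per_l", min = 0)
  check_number(eruption_volume_m3, "eruption_volume_m3", min = 0)
  check_number(eruptions_per_year, "eruptions_per_year", min = 0)
  kg_c_per_m3 <- (co2_mg_per_l * .MM_C / .MM_CO2 +
                  hco3_mg_per_l * .MM_C / .MM_HCO3) * 1e-3
  eruption_volume_m3 * eruptions_per_year * kg_c_per_m3
}

#' Fraction of erupted carbon fixed into biomass
#'
#' @param cell_c_g_per_yr Cell-bound carbon, grams per year.
#' @param erupted_c_kg_per_yr Total erupted inorganic carbon, kilograms per
#'   year (> 0).
#' @return Percent of the erupted carbon bound in cells.
#' @export
fixed_fraction <- function(cell_c_g_per_yr, erupted_c_kg_per_yr) {
  check_number(cell_c_g_per_yr, "cell_c_g_per_yr", min = 0)
  check_number(erupted_c_kg_per_yr, "erupted_c_kg_per_yr",
               min = .Machine$double.eps)
  cell_c_g_per_yr / (erupted_c_kg_per_yr * 1000) * 100
}

#' Full geyser carbon mass balance
#'
#' Chains the budget operations: tubing volume (unless an eruption volume
#' is given directly), annual eruption count, erupted inorganic carbon,
#' cell-bound carbon and the fixed fraction. Every intermediate term is
#' returned so the report is auditable.
#'
#' @param co2_mg_per_l,hco3_mg_per_l Dissolved inorganic species (mg/L).
#' @param cells_per_ml Cell density of the erupted fluid.
#' @param fg_c_per_cell Carbon per cell (fg, default 14).
#' @param eruption_volume_m3 Volume per eruption; defaults to the tubing
#'   volume from `radius_m`/`length_m`.
#' @param radius_m,length_m Tubing geometry used when `eruption_volume_m3`
#'   is not supplied (defaults: 0.075 m, 351.5 m).
#' @param season_days,eruptions_per_day Eruption regime (defaults 210 days,
#'   12/day).
#' @return A `carbon_budget` list with all inputs, intermediates, and the
#'   headline `fixed_percent`.
#' @export
carbon_budget <- function(co2_mg_per_l, hco3_mg_per_l, cells_per_ml,
                          fg_c_per_cell = 14, eruption_volume_m3 = NULL,
                          radius_m = 0.075, length_m = 351.5,
                          season_days = 210, eruptions_per_day = 12) {
  vol <- eruption_volume_m3 %||% tubing_volume(radius_m, length_m)
  n_eruptions <- annual_eruptions(season_days, eruptions_per_day)
  erupted_kg <- erupted_carbon(co2_mg_per_l, hco3_mg_per_l, vol, n_eruptions)
  cell_g <- cell_carbon(cells_per_ml, fg_c_per_cell, vol, n_eruptions)
  structure(
    list(inputs = list(co2_mg_per_l = co2_mg_per_l,
                       hco3_mg_per_l = hco3_mg_per_l,
                       cells_per_ml = cells_per_ml,
                       fg_c_per_cell = fg_c_per_cell,
                       season_days = season_days,
                       eruptions_per_day = eruptions_per_day),
         eruption_volume_m3 = vol,
         eruptions_per_year = n_eruptions,
         erupted_c_kg_per_yr = erupted_kg,
         cell_c_g_per_yr = cell_g,
         fixed_percent = fixed_fraction(cell_g, erupted_kg)),
    class = "carbon_budget"
  )
}

#' @export
print.carbon_budget <- function(x, ...) {
  cat(sprintf(paste0(
    "<carbon_budget>\n",
    "  eruption volume: %.2f m3, %.0f eruptions/yr\n",
    "  erupted inorganic C: %.1f kg/yr\n",
    "  cell-bound C: %.2f g/yr\n",
    "  fixed into biomass: %.4g%%\n"),
    x$eruption_volume_m3, x$eruptions_per_year, x$erupted_c_kg_per_yr,
    x$cell_c_g_per_yr, x$fixed_percent))
  invisible(x)
}
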