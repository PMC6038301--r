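# The yield ledger: convert published growth measurements into
# Biomass/NH4+ and ATP/NH4+ yields, compare them with the theoretical
# pathway yields, and extrapolate to the global carbon-fixation rate.

#' Constants used by the yield ledger
#'
#' @param biomass_mw Molecular weight of one C-mol of biomass
#'   (g mol^-1; default 26).
#' @param fg_per_cell Dry weight per cell for *N. maritimus*-like cells
#'   (fg; default 20).
#' @param protons_per_atp Protons translocated per ATP by the F0F1
#'   synthase (default 4).
#' @param carbon_g_per_cmol Grams of carbon per C-mol of biomass
#'   (default 12).
#' @param n_molar_mass Molar mass of nitrogen (g mol^-1; default 14) -
#'   the remineralized ammonium flux is interpreted on a nitrogen-mass
#'   basis.
#' @return A `ledger_config` list.
#' @export
ledger_config <- function(biomass_mw = 26, fg_per_cell = 20,
                          protons_per_atp = 4, carbon_g_per_cmol = 12,
                          n_molar_mass = 14) {
  cfg <- list(biomass_mw = biomass_mw, fg_per_cell = fg_per_cell,
              protons_per_atp = protons_per_atp,
              carbon_g_per_cmol = carbon_g_per_cmol,
              n_molar_mass = n_molar_mass)
  if (any(unlist(cfg) <= 0)) abort("all ledger constants must be > 0")
  structure(cfg, class = "ledger_config")
}

#' Round to significant figures, half away from zero
#'
#' Display rounding used throughout the ledger (3 significant figures,
#' half-up), matching how the derived yield cells are printed.
#'
#' @param x Numeric vector.
#' @param digits Significant figures.
#' @return Rounded numeric vector.
#' @export
signif_half_up <- function(x, digits = 3) {
  out <- x
  nz <- !is.na(x) & x != 0
  e <- floor(log10(abs(x[nz]))) - digits + 1
  out[nz] <- sign(x[nz]) * floor(abs(x[nz]) / 10^e + 0.5) * 10^e
  out
}

#' Convert a cell yield to a dry-weight yield
#'
#' @param cells_per_mol Cells produced per mol NH4+ oxidized.
#' @param fg_per_cell Dry weight per cell (fg).
#' @return Biomass yield in gDW per mol NH4+ (full precision;
#'   displayed cells use [signif_half_up()]).
#' @export
cells_to_gdw <- function(cells_per_mol, fg_per_cell = 20) {
  cells_per_mol * fg_per_cell * 1e-15
}

#' Dry weight per cell from protein content
#'
#' @param fg_protein Protein mass per cell (fg).
#' @param protein_fraction Protein fraction of dry weight (0-1].
#' @return Dry weight per cell (fg).
#' @export
protein_to_dw <- function(fg_protein, protein_fraction) {
  if (any(protein_fraction <= 0 | protein_fraction > 1))
    abort("protein_fraction must be in (0, 1]")
  fg_protein / protein_fraction
}

#' Molar biomass yield as a "1:N" ratio
#'
#' @param gdw_per_mol Biomass yield, gDW per mol NH4+.
#' @param biomass_mw C-mol biomass molecular weight (g mol^-1).
#' @return Character "1:N" with `N = round(biomass_mw / gdw_per_mol)`.
#' @export
gdw_to_molar_ratio <- function(gdw_per_mol, biomass_mw = 26) {
  sprintf("1:%d", as.integer(floor(biomass_mw / gdw_per_mol + 0.5)))
}

#' Biomass yield from growth rate and uptake rate
#'
#' @param mu Specific growth rate (h^-1).
#' @param q Ammonium uptake rate (mmol NH4+ gDW^-1 h^-1).
#' @return Biomass yield, gDW per mol NH4+ (`1000 * mu / q`).
#' @export
rate_ratio_to_gdw <- function(mu, q) 1000 * mu / q

#' ATP required per mol ammonium oxidized
#'
#' The respiratory-chain efficiency estimate: the product of the
#' ATP/Biomass yield (mol ATP-equivalent per gDW) and the Biomass/NH4+
#' yield (gDW per mol).
#'
#' @param atp_per_gdw ATP/Biomass yield (mol gDW^-1).
#' @param gdw_per_mol Biomass/NH4+ yield (gDW mol^-1).
#' @return ATP/NH4+ yield (mol mol^-1).
#' @export
atp_per_nh4 <- function(atp_per_gdw, gdw_per_mol) atp_per_gdw * gdw_per_mol

#' Convert an H+/O ratio to an ATP/NH4+ yield
#'
#' @param h_per_o Measured H+/O ratio.
#' @param protons_per_atp Protons per ATP (default 4).
#' @return ATP/NH4+ yield.
#' @export
h_per_o_to_atp <- function(h_per_o, protons_per_atp = 4) h_per_o / protons_per_atp

#' Global carbon fixation by ammonia-oxidizing archaea
#'
#' Scales the remineralized ammonium flux of the dark ocean by the
#' molar biomass yield: `nh4_gt_per_yr / n_molar_mass * molar_yield *
#' carbon_g_per_cmol`. The ammonium flux is taken on a nitrogen-mass
#' basis (Gt N yr^-1).
#'
#' @param nh4_gt_per_yr Ammonium flux, Gt (N) per year (default 4.62).
#' @param molar_yield Biomass yield, mol biomass per mol NH4+
#'   (default 1/25, the ledger average).
#' @param carbon_g_per_cmol Grams of carbon per C-mol biomass.
#' @param n_molar_mass Molar mass of nitrogen (g mol^-1).
#' @return Carbon fixation rate, Gt C per year.
#' @export
global_c_fixation <- function(nh4_gt_per_yr = 4.62, molar_yield = 1 / 25,
                              carbon_g_per_cmol = 12, n_molar_mass = 14) {
  nh4_gt_per_yr / n_molar_mass * molar_yield * carbon_g_per_cmol
}

#' Published yield measurements for ammonia-oxidizing strains
#'
#' The raw measurements behind the ledger: cell yields, a direct
#' dry-weight yield, a growth-rate/uptake-rate pair for
#' *N. maritimus* SCM1 and related strains, and a directly measured
#' ATP/NH4+ yield (with its own literature ATP/Biomass figure) for the
#' ammonia-oxidizing bacterium *N. europaea*.
#'
#' @return Tibble with one row per measurement: `strain`, `type`
#'   (`"cells_per_mol"`, `"gdw_per_mol"`, `"rate_ratio"`,
#'   `"atp_per_nh4_direct"`), the raw values, and `source`.
#' @export
aoa_yield_measurements <- function() {
  tribble(
    ~strain, ~type, ~cells_per_mol, ~gdw_per_mol, ~mu, ~q, ~atp_direct, ~atp_per_gdw_lit, ~source,
    "Nitrosopumilus maritimus SCM1", "cells_per_mol", 3.49e13, NA, NA, NA, NA, NA, "Loscher et al. 2012",
    "Nitrosopumilus maritimus SCM1", "cells_per_mol", 5e13, NA, NA, NA, NA, NA, "Konneke et al. 2005",
    "Nitrosopumilus maritimus SCM1", "gdw_per_mol", NA, 1.3, NA, NA, NA, NA, "Konneke et al. 2014",
    "Nitrosopumilus maritimus SCM1", "rate_ratio", NA, NA, 0.027, 26.5, NA, NA, "Martens-Habbena et al. 2009",
    "Strain PS0", "cells_per_mol", 5.31e13, NA, NA, NA, NA, NA, "Qin et al. 2014",
    "Strain HCA1", "cells_per_mol", 5.50e13, NA, NA, NA, NA, NA, "Qin et al. 2014",
    "Nitrosopumilus piranensis D3C / adriaticus NF5", "cells_per_mol", 6e13, NA, NA, NA, NA, NA, "Bayer et al. 2016",
    "Nitrosomonas europaea ATCC 19718", "atp_per_nh4_direct", NA, NA, NA, NA, 0.171, 0.238, "Poughon et al. 2001"
  )
}

#' Build the yield ledger
#'
#' Converts each raw measurement into a Biomass/NH4+ yield, derives the
#' molar ratio and the ATP/NH4+ yield, and (optionally) compares the
#' estimates against theoretical pathway yields. Derived display cells
#' are chained from the 3-significant-figure displayed biomass yield -
#' the convention the printed table follows - while `gdw_per_mol_full`
#' keeps full precision.
#'
#' @param rows Measurement tibble as from [aoa_yield_measurements()].
#' @param cost An `energy_cost` (or a single ATP-equivalent number,
#'   mol gDW^-1) giving the ATP/Biomass yield used for rows without
#'   their own literature figure.
#' @param config A [ledger_config()].
#' @param theoretical Named numeric vector of theoretical ATP/NH4+
#'   yields (mol mol^-1) to compare against, e.g.
#'   `c(pathway1 = 1.5, pathway2 = 1.75, pathway3 = 1.625)`.
#' @return An `aoa_ledger` tibble: `strain`, `gdw_per_mol_full`,
#'   `gdw_per_mol` (displayed), `molar_ratio`, `atp_per_gdw`,
#'   `atp_per_nh4`, `source`; the theoretical comparison, when
#'   requested, is in `attr(, "comparison")`.
#' @export
build_ledger <- function(rows, cost, config = ledger_config(),
                         theoretical = NULL) {
  atp_per_gdw_model <- if (inherits(cost, "energy_cost")) atp_equivalent(cost) else cost
  if (!nrow(rows)) {
    out <- tibble(strain = character(), gdw_per_mol_full = numeric(),
                  gdw_per_mol = numeric(), molar_ratio = character(),
                  atp_per_gdw = numeric(), atp_per_nh4 = numeric(),
                  source = character())
    return(structure(out, class = c("aoa_ledger", class(out))))
  }
  gdw_full <- pmap(list(rows$type, rows$cells_per_mol, rows$gdw_per_mol,
                        rows$mu, rows$q, rows$atp_direct, rows$atp_per_gdw_lit),
                   function(type, cells, gdw, mu, q, atp_d, atp_lit) {
                     switch(type,
                       cells_per_mol = cells_to_gdw(cells, config$fg_per_cell),
                       gdw_per_mol = gdw,
                       rate_ratio = rate_ratio_to_gdw(mu, q),
                       atp_per_nh4_direct = atp_d / atp_lit,
                       abort(sprintf("unknown measurement type '%s'", type)))
                   })
  gdw_full <- unlist(gdw_full)
  gdw_disp <- signif_half_up(gdw_full, 3)
  atp_gdw <- ifelse(is.na(rows$atp_per_gdw_lit), atp_per_gdw_model, rows$atp_per_gdw_lit)
  atp_nh4 <- ifelse(is.na(rows$atp_direct),
                    signif_half_up(atp_per_nh4(atp_gdw, gdw_disp), 3),
                    rows$atp_direct)
  out <- tibble(
    strain = rows$strain,
    gdw_per_mol_full = gdw_full,
    gdw_per_mol = gdw_disp,
    molar_ratio = gdw_to_molar_ratio(gdw_disp, config$biomass_mw),
    atp_per_gdw = atp_gdw,
    atp_per_nh4 = atp_nh4,
    source = rows$source
  )
  out <- structure(out, class = c("aoa_ledger", class(tibble())))
  if (!is.null(theoretical)) {
    comparison <- tidyr::expand_grid(
      pathway = names(theoretical),
      tibble(strain = out$strain, estimated = out$atp_per_nh4)
    )
    comparison$theoretical <- theoretical[comparison$pathway]
    comparison$ratio <- comparison$theoretical / comparison$estimated
    attr(out, "comparison") <- as_tibble(comparison)
  }
  out
}

#' @export
glance.aoa_ledger <- function(x, ...) {
  tibble(
    n_rows = nrow(x),
    mean_gdw_per_mol = mean(x$gdw_per_mol),
    mean_atp_per_nh4 = mean(x$atp_per_nh4)
  )
}

#' Plot estimated versus theoretical ATP yields
#'
#' Bar chart of the per-strain estimated ATP/NH4+ yields with the
#' theoretical pathway yields as horizontal reference lines - the
#' roughly ten-fold gap between available and used energy is the
#' headline feature.
#'
#' @param object An `aoa_ledger` built with `theoretical` yields.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aoa_ledger <- function(object, ...) {
  comparison <- attr(object, "comparison")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$strain, y = .data$atp_per_nh4)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ATP per NH4+ oxidized (mol/mol)",
                  title = "Estimated vs theoretical ATP yield") +
    ggplot2::theme_minimal()
  if (!is.null(comparison)) {
    ref <- dplyr::distinct(comparison, .data$pathway, .data$theoretical)
    p <- p + ggplot2::geom_hline(data = ref,
      ggplot2::aes(yintercept = .data$theoretical, linetype = .data$pathway),
      colour = "grey30")
  }
  p
}
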