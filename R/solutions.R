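#' Nernst equilibrium potential
#'
#' `E = (RT/zF) * ln(c_out/c_in)` in mV. For the standard FLS recording
#' solutions (141 mM internal potassium from K-gluconate + KCl, 5 mM
#' external) this gives about -84.6 mV at 294 K.
#'
#' @param c_in,c_out intra/extracellular concentrations (mM), > 0.
#' @param z ionic valence (non-zero integer).
#' @param temp_K absolute temperature (K).
#' @return potential in mV.
#' @examples
#' nernst(141, 5, z = 1, temp_K = 294)
#' @export
nernst <- function(c_in, c_out, z = 1, temp_K = 294) {
  if (any(c(c_in, c_out) <= 0)) stopf("concentrations must be > 0")
  if (z == 0) stopf("valence must be non-zero")
  1000 * .GAS_R * temp_K / (z * .FARADAY) * log(c_out / c_in)
}

#' Limiting-mobility table for junction-potential calculations
#'
#' Relative ionic mobilities `u = lambda0 / (z^2 * lambda0_K)` (limiting
#' molar conductivity scaled by the squared valence, relative to
#' potassium), the parameterisation in which the Henderson equation is
#' written with `z*u` and `z^2*u` weights. Values follow the standard
#' electrophysiology junction-potential tables.
#'
#' @return data.frame with columns `species`, `z`, `mobility`.
#' @export
ion_mobility_table <- function() {
  data.frame(
    species = c("K", "Na", "Li", "Cs", "Cl", "Ca", "Mg", "Gluconate",
                "HEPES", "EGTA", "F", "Br"),
    z = c(1, 1, 1, 1, -1, 2, 2, -1, -1, -2, -1, -1),
    mobility = c(1, 0.682, 0.526, 1.05, 1.0388, 0.4048, 0.361, 0.33,
                 0.30, 0.24, 0.753, 1.063),
    stringsAsFactors = FALSE)
}

#' Define an electrolyte solution
#'
#' A named list of ionic species with concentrations; valences and
#' relative mobilities are looked up in [ion_mobility_table()] unless
#' supplied. Species without a mobility entry raise an explicit error --
#' a silent default would corrupt the junction potential. Departures from
#' electroneutrality beyond `charge_tol` mM of charge produce a warning
#' only, since real recipes are balanced by pH titration with ions that
#' are not always listed.
#'
#' @param concentrations_mM named numeric vector, names are species, all
#'   values >= 0 (zero-concentration species are dropped).
#' @param z,mobility optional named overrides for valence and relative
#'   mobility.
#' @param charge_tol electroneutrality warning threshold (mM of charge).
#' @return An object of class `solution_composition`: data.frame with
#'   columns `species`, `conc_mM`, `z`, `mobility`.
#' @export
solution_composition <- function(concentrations_mM, z = NULL,
                                 mobility = NULL, charge_tol = 15) {
  if (is.null(names(concentrations_mM)) ||
      any(!nzchar(names(concentrations_mM))))
    stopf("concentrations must be a named vector")
  if (any(concentrations_mM < 0)) stopf("concentrations must be >= 0")
  concentrations_mM <- concentrations_mM[concentrations_mM > 0]
  tab <- ion_mobility_table()
  sp <- names(concentrations_mM)
  zz <- uu <- numeric(length(sp))
  for (i in seq_along(sp)) {
    if (!is.null(z) && sp[i] %in% names(z)) zz[i] <- z[[sp[i]]]
    else {
      j <- match(sp[i], tab$species)
      if (is.na(j)) stopf("no valence known for species '%s'", sp[i])
      zz[i] <- tab$z[j]
    }
    if (!is.null(mobility) && sp[i] %in% names(mobility))
      uu[i] <- mobility[[sp[i]]]
    else {
      j <- match(sp[i], tab$species)
      if (is.na(j))
        stopf("no limiting mobility known for species '%s'; supply one explicitly",
              sp[i])
      uu[i] <- tab$mobility[j]
    }
  }
  charge <- sum(zz * concentrations_mM)
  if (abs(charge) > charge_tol)
    warning(sprintf("solution is not electroneutral (net charge %+.1f mM)",
                    charge), call. = FALSE)
  structure(
    data.frame(species = sp, conc_mM = as.numeric(concentrations_mM),
               z = zz, mobility = uu, stringsAsFactors = FALSE),
    class = c("solution_composition", "data.frame"))
}

#' Standard FLS pipette (intracellular) solution
#'
#' 115 mM K-gluconate, 26 mM KCl, 1 mM MgCl2, 5 mM EGTA, 10 mM HEPES
#' (pH 7.2), decomposed into ionic species: K+ 141, gluconate- 115,
#' Cl- 28, Mg2+ 1, EGTA(2-) 5, HEPES(-) 10.
#' @return a [solution_composition()].
#' @export
fls_pipette_solution <- function() {
  suppressWarnings(solution_composition(c(
    K = 141, Gluconate = 115, Cl = 28, Mg = 1, EGTA = 5, HEPES = 10)))
}

#' Standard FLS bath (extracellular) solution
#'
#' 140 mM NaCl, 5 mM KCl, 2 mM CaCl2, 1 mM MgCl2, 10 mM HEPES, 5 mM
#' glucose (pH 7.4), decomposed into ionic species: Na+ 140, K+ 5,
#' Cl- 151, Ca2+ 2, Mg2+ 1, HEPES(-) 10. Glucose is uncharged and
#' omitted.
#' @return a [solution_composition()].
#' @export
fls_bath_solution <- function() {
  suppressWarnings(solution_composition(c(
    Na = 140, K = 5, Cl = 151, Ca = 2, Mg = 1, HEPES = 10)))
}

#' Henderson liquid junction potential
#'
#' Computes the liquid junction potential between pipette and bath
#' solutions from the Henderson equation,
#' \deqn{V_{LJP} = \frac{RT}{F}\,
#'   \frac{\sum_i z_i u_i (c_i^{bath} - c_i^{pip})}
#'        {\sum_i z_i^2 u_i (c_i^{bath} - c_i^{pip})}\,
#'   \ln \frac{\sum_i z_i^2 u_i c_i^{bath}}{\sum_i z_i^2 u_i c_i^{pip}}}
#' with relative mobilities `u`. The sign convention is that of the
#' correction added to measured potentials: a K-gluconate pipette in a
#' NaCl bath gives a negative value (about -14 mV), making corrected
#' potentials more negative.
#'
#' @param pipette,bath [solution_composition()] objects.
#' @param temp_K absolute temperature (K).
#' @return junction potential in mV.
#' @examples
#' henderson_ljp(fls_pipette_solution(), fls_bath_solution(), temp_K = 294)
#' @export
henderson_ljp <- function(pipette, bath, temp_K = 294) {
  for (s in list(pipette, bath))
    if (!inherits(s, "solution_composition") || nrow(s) < 1)
      stopf("pipette and bath must be non-empty solution_composition objects")
  sp <- union(pipette$species, bath$species)
  get <- function(sol, what) {
    v <- structure(sol[[what]], names = sol$species)[sp]
    v[is.na(v)] <- 0
    v
  }
  cp <- get(pipette, "conc_mM"); cb <- get(bath, "conc_mM")
  zp <- get(pipette, "z"); zb <- get(bath, "z")
  up <- get(pipette, "mobility"); ub <- get(bath, "mobility")
  z <- ifelse(cp > 0, zp, zb)
  u <- ifelse(cp > 0, up, ub)
  if (any(cp > 0 & cb > 0 & (zp != zb | abs(up - ub) > 1e-12)))
    stopf("species present in both solutions must share valence and mobility")
  d1 <- sum(z * u * (cb - cp))
  d2 <- sum(z^2 * u * (cb - cp))
  s_pip <- sum(z^2 * u * cp)
  s_bath <- sum(z^2 * u * cb)
  if (s_pip <= 0 || s_bath <= 0) stopf("each solution needs charged species")
  if (abs(d2) < 1e-12) return(0)           # identical ionic strengths/profiles
  1000 * .GAS_R * temp_K / .FARADAY * (d1 / d2) * log(s_bath / s_pip)
}
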