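# Unit conventions: user-facing flows in ml/s, pressures in mmHg, resistances
# in mmHg.s/ml, compliances in ml/mmHg. SI appears only inside the Darcy
# porous-zone law and the volumetric source terms; conversions live here so
# there is exactly one definition of each factor.

#' Unit conversion constants
#'
#' Named constants used throughout the package: `mmHg_Pa` (1 mmHg in Pa),
#' `mmHg_s_ml_SI` (1 mmHg.s/ml in Pa.s/m^3) and `ml_m3` (1 ml in m^3).
#'
#' @format A named numeric vector of length 3.
#' @examples
#' csf_units["mmHg_Pa"]
#' @export
csf_units <- c(
  mmHg_Pa      = 133.322,
  mmHg_s_ml_SI = 133.322 / 1e-6, # = 1.33322e8 Pa.s/m^3
  ml_m3        = 1e-6
)

.mmHg_Pa <- 133.322
.mmHg_s_ml_SI <- 1.33322e8
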