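#' Physical constants for quantal charge arithmetic
#'
#' Fixed CODATA values used to convert integrated spike charge into molecule
#' counts. Dopamine oxidation at the electrode transfers two electrons per
#' molecule, so a spike of charge `Q` corresponds to `Q / (2 q_e)` molecules.
#'
#' @param electrons_per_molecule Electrons transferred per analyte molecule
#'   (2 for dopamine and other catecholamines).
#' @return A list with `elementary_charge` (C), `avogadro` (mol^-1) and
#'   `electrons_per_molecule`.
#' @export
physical_constants <- function(electrons_per_molecule = 2) {
  stopifnot(electrons_per_molecule >= 1)
  list(
    elementary_charge = 1.602176634e-19,
    avogadro = 6.02214076e23,
    electrons_per_molecule = electrons_per_molecule
  )
}

# fC of oxidation charge produced by one attomole of analyte
.charge_per_attomole_fC <- function(constants = physical_constants()) {
  constants$avogadro * 1e-18 *
    constants$electrons_per_molecule * constants$elementary_charge / 1e-15
}
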