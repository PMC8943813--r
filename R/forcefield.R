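#' Coarse-grained chromatin force field
#'
#' All energies are expressed in kT at the reference temperature (293 K);
#' replica temperatures are dimensionless multipliers of it.
#'
#' @param stretch_modulus Stretching stiffness scale, kT/nm; per-segment
#'   spring constant is `stretch_modulus / rest_length` (kT/nm^2).
#' @param bend_persistence DNA bending persistence length, nm.
#' @param torsion_persistence DNA torsional persistence length, nm.
#' @param debye_length Debye screening length, nm (0.96 nm at 100 mM
#'   monovalent salt).
#' @param linear_charge Linker DNA linear charge density after Manning
#'   counterion condensation, e/nm.
#' @param bjerrum_length Bjerrum length of water, nm.
#' @param charge_spacing Target spacing of discrete charge points along
#'   linker segments, nm.
#' @param e_max Maximum attractive internucleosomal energy, kT (>= 0;
#'   0 switches the attraction off).
#' @param nucleosome_diameter,nucleosome_height Spherocylinder dimensions of
#'   the nucleosome body, nm.
#' @param cutoff Internucleosomal interaction cutoff, nm (energy is exactly 0
#'   beyond it).
#' @param taper_from Distance from which the internucleosomal potential is
#'   smoothly tapered to 0 at `cutoff`, nm.
#' @param well_width Width parameter of the internucleosomal well, nm.
#' @param ev_radius_dna Excluded-volume radius of linker DNA, nm.
#' @param ev_radius_nuc Effective excluded-volume radius used for
#'   DNA-nucleosome contacts, nm.
#' @param ev_strength Prefactor of the capped quartic overlap penalty, kT.
#' @param ev_cap Upper cap of any single repulsive penalty, kT.
#' @param es_cutoff Electrostatic cutoff, nm.
#' @param electrostatics,excluded_volume Logical switches for the two terms
#'   (useful for ideal-chain validation runs).
#' @return An object of class `force_field`.
#' @export
force_field <- function(stretch_modulus = 500,
                        bend_persistence = 50,
                        torsion_persistence = 75,
                        debye_length = 0.96,
                        linear_charge = 1.41,
                        bjerrum_length = 0.7,
                        charge_spacing = 2,
                        e_max = 4,
                        nucleosome_diameter = 11,
                        nucleosome_height = 5.5,
                        cutoff = 20,
                        taper_from = 15,
                        well_width = 3.5,
                        ev_radius_dna = 1.2,
                        ev_radius_nuc = 4,
                        ev_strength = 4000,
                        ev_cap = 1000,
                        es_cutoff = 6 * debye_length,
                        electrostatics = TRUE,
                        excluded_volume = TRUE) {
  ff <- list(stretch_modulus = stretch_modulus,
             bend_persistence = bend_persistence,
             torsion_persistence = torsion_persistence,
             debye_length = debye_length,
             linear_charge = linear_charge,
             bjerrum_length = bjerrum_length,
             charge_spacing = charge_spacing,
             e_max = e_max,
             nucleosome_diameter = nucleosome_diameter,
             nucleosome_height = nucleosome_height,
             cutoff = cutoff,
             taper_from = taper_from,
             well_width = well_width,
             ev_radius_dna = ev_radius_dna,
             ev_radius_nuc = ev_radius_nuc,
             ev_strength = ev_strength,
             ev_cap = ev_cap,
             es_cutoff = es_cutoff,
             electrostatics = isTRUE(electrostatics),
             excluded_volume = isTRUE(excluded_volume))
  stopifnot(ff$e_max >= 0, ff$cutoff >= ff$nucleosome_diameter,
            ff$bend_persistence > 0, ff$debye_length > 0,
            ff$taper_from < ff$cutoff)
  structure(ff, class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  describe_forcefield(x)
  invisible(x)
}

#' Print every force-field parameter (provenance record)
#' @param ff A `force_field`.
#' @return `ff`, invisibly.
#' @export
describe_forcefield <- function(ff) {
  cat("<force_field> (energies in kT at 293 K)\n")
  for (nm in names(unclass(ff)))
    cat(sprintf("  %-20s %s\n", nm, format(ff[[nm]])))
  invisible(ff)
}
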