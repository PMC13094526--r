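#' Construct an energy table
#'
#' Holds named electronic-structure total energies (eV) plus optional
#' frontier-orbital entries, for the bookkeeping formulas below. This module
#' performs no electronic-structure computation; it makes post-processing of
#' supplied DFT energies reproducible.
#'
#' @param entries named numeric vector (or list) of total energies in eV.
#' @param orbitals optional named list of `list(E_HOMO =, E_LUMO =)` entries
#'   (eV, with `E_LUMO >= E_HOMO`).
#' @return object of class `energy_table`.
#' @export
energy_table <- function(entries = c(), orbitals = list()) {
  entries <- unlist(entries)
  if (length(entries) && is.null(names(entries)))
    stop("entries must be named")
  for (nm in names(orbitals)) {
    o <- orbitals[[nm]]
    if (is.null(o$E_HOMO) || is.null(o$E_LUMO))
      stop("orbital entry ", nm, " needs E_HOMO and E_LUMO")
    if (o$E_LUMO < o$E_HOMO)
      stop("orbital entry ", nm, ": E_LUMO must be >= E_HOMO")
  }
  structure(list(entries = entries, orbitals = orbitals),
            class = "energy_table")
}

lookup_energy <- function(table, name) {
  stopifnot(inherits(table, "energy_table"))
  if (!name %in% names(table$entries))
    stop("no energy entry named '", name, "'")
  unname(table$entries[[name]])
}

#' Defect formation energy
#'
#' `dE = E_defect - E_perfect + E_removed - E_added`: the energy of replacing
#' one host atom (removed, e.g. Au) by a dopant (added, e.g. Ra) in the
#' cluster. Negative values mean doping is energetically favorable.
#'
#' @param table an [energy_table()].
#' @param defect_name,perfect_name names of the doped and pristine cluster
#'   total energies.
#' @param removed_atom,added_atom names of the single-atom reference
#'   energies for the displaced host atom and the dopant.
#' @return formation energy in eV.
#' @examples
#' tab <- energy_table(c(RaAu9 = -11.16, Au10 = -10, Au = -3, Ra = -3))
#' formation_energy(tab, "RaAu9", "Au10", "Au", "Ra")  # -1.16
#' @export
formation_energy <- function(table, defect_name, perfect_name,
                             removed_atom, added_atom) {
  lookup_energy(table, defect_name) - lookup_energy(table, perfect_name) +
    lookup_energy(table, removed_atom) - lookup_energy(table, added_atom)
}

#' Relative energy of a doped cluster
#'
#' `dE = E_doped - (E_perfect + E_dopant - E_host)`, with the single-atom
#' references taken in the ground-state elemental structures. Algebraically
#' this is the same linear combination as [formation_energy()] with the roles
#' of the atomic references fixed; it is provided as a separately named
#' operation because the two conventions differ only in which atomic
#' reference energies are supplied.
#'
#' @param table an [energy_table()].
#' @param doped_name,perfect_name cluster total-energy names.
#' @param dopant_atom,host_atom elemental reference-energy names.
#' @return relative energy in eV.
#' @export
relative_energy <- function(table, doped_name, perfect_name,
                            dopant_atom, host_atom) {
  formation_energy(table, doped_name, perfect_name,
                   removed_atom = host_atom, added_atom = dopant_atom)
}

#' Binding energy of a dopant to the cluster frame
#'
#' `E_b = E_frame + E_atom - E_doped`: larger values mean a more stable
#' doped cluster. Note the sign convention is opposite to
#' [formation_energy()]: binding energies are positive for bound systems.
#'
#' @param table an [energy_table()].
#' @param frame_name name of the bare frame energy (e.g. Au9).
#' @param atom_name name of the dopant atom energy.
#' @param doped_name name of the doped-cluster energy.
#' @return binding energy in eV.
#' @examples
#' tab <- energy_table(c(Au9 = -5, Ra = -1, RaAu9 = -8.86))
#' binding_energy(tab, "Au9", "Ra", "RaAu9")  # 2.86
#' @export
binding_energy <- function(table, frame_name, atom_name, doped_name) {
  lookup_energy(table, frame_name) + lookup_energy(table, atom_name) -
    lookup_energy(table, doped_name)
}

#' HOMO-LUMO gap
#'
#' `E_gap = E_LUMO - E_HOMO` for a stored orbital entry; always >= 0 by the
#' table's validity invariant, and invariant under a uniform shift of both
#' orbital energies.
#'
#' @param table an [energy_table()].
#' @param name orbital entry name.
#' @return gap in eV.
#' @examples
#' tab <- energy_table(orbitals = list(RaAu9 = list(E_HOMO = -4.42,
#'                                                  E_LUMO = -1.00)))
#' homo_lumo_gap(tab, "RaAu9")  # 3.42
#' @export
homo_lumo_gap <- function(table, name) {
  stopifnot(inherits(table, "energy_table"))
  o <- table$orbitals[[name]]
  if (is.null(o)) stop("no orbital entry named '", name, "'")
  o$E_LUMO - o$E_HOMO
}
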