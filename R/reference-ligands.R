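#' Reference drug ligands
#'
#' Literature SMILES for two approved/clinical drugs used as dominance
#' references in case studies: Tropifexor, an FXR agonist (the ligand of
#' PDB entry 7D42), and Copanlisib, a PI3K inhibitor (the ligand of PDB
#' entry 5G2N). Strings are stereo-free connection tables as in PDB
#' chemical-component dictionaries.
#'
#' @return Tibble with columns `name`, `pdb`, `smiles`.
#' @examples
#' \dontrun{
#' score_properties(reference_ligands()$smiles)
#' }
#' @export
reference_ligands <- function() {
  tibble::tibble(
    name = c("Tropifexor", "Copanlisib"),
    pdb = c("7D42", "5G2N"),
    smiles = c(
      "OC(=O)c1cc2sc(nc2c(F)c1)N1C2CCC1CC(C2)OCc1c(onc1-c1ccccc1OC(F)(F)F)C1CC1",
      "COc1cc2c(c(OCCCN3CCOCC3)c1)C1=NCCN1C(=N2)NC(=O)c1cnc(N)nc1"
    )
  )
}
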