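# Deposited coordinate set (user-supplied)

The published-value acceptance tests measure structural observables on the
study's deposited coordinate ensemble of the amyloid-beta(20-34) double
layer (Open Science Framework, DOI 10.17605/OSF.IO/WTYA5). Those
coordinates are not redistributable with this package.

To enable the measurements, download the deposit and place the files here
(single-model PDB for structures, multi-model PDB for pathways), then
reinstall the package:

    flat.pdb               optimised flat conformation (dimer)
    twisted_psi_E22.pdb    optimised twisted conformation, psi torsion of E22
    twisted_phi_D23.pdb    optimised twisted conformation, phi torsion of D23
    path_psi_G25.pdb       minimum-energy-path ensemble, psi torsion of G25
                           (flat first, twisted local minimum last)

XYZ-trajectory input is also supported through readPath(format = "xyz")
with a topology template.
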