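# van der Waals radii (A), force-field flavoured set: Lennard-Jones R_min/2
# values typical of Amber-family force fields (aromatic H/C/N types, TIP3P
# water oxygen, halide and alkali ion radii from hydration-free-energy fits).
# This is the set under which the fused-sphere solute volume reproduces the
# excluded-solvent bookkeeping of MD-based differential scattering workflows.
# element radius
H  1.459
C  1.908
N  1.824
O  1.768
Na 1.369
P  2.10
S  2.00
Cl 2.29
K  1.705
Fe 1.456
Ru 2.05
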