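# van der Waals radii (A), Bondi (1964) set; Ru is not in Bondi's compilation
# and takes a commonly used transition-metal default of 2.05 A.
# element radius
H  1.20
C  1.70
N  1.55
O  1.52
Na 2.27
P  1.80
S  1.80
Cl 1.75
K  2.75
Fe 2.05
Ru 2.05
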