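# X-ray atomic form factors, neutral atoms, independent atom approximation.
# Four-Gaussian-plus-constant parameterization (International Tables for
# Crystallography Vol. C, Table 6.1.1.4; Cromer-Mann analytic coefficients),
# valid to sin(theta)/lambda = 2 A^-1, i.e. Q ~ 25 A^-1.
#   f(Q) = sum_k a_k exp(-b_k (Q/4pi)^2) + c      [electrons; b_k in A^2]
# element a1 a2 a3 a4 b1 b2 b3 b4 c
H  0.493002 0.322912 0.140191 0.04081  10.5109 26.1257 3.14236 57.7997 0.003038
C  2.31     1.02     1.5886   0.865    20.8439 10.2075 0.5687  51.6512 0.2156
N  12.2126  3.1322   2.0125   1.1663   0.0057  9.8933  28.9975 0.5826  -11.529
O  3.0485   2.2868   1.5463   0.867    13.2771 5.7011  0.3239  32.9089 0.2508
Na 4.7626   3.1736   1.2674   1.1128   3.285   8.8422  0.3136  129.424 0.676
P  6.4345   4.1791   1.78     1.4908   1.9067  27.157  0.526   68.1645 1.1149
S  6.9053   5.2034   1.4379   1.5863   1.4679  22.2151 0.2536  56.172  0.8669
Cl 11.4604  7.1964   6.2556   1.6455   0.0104  1.1662  18.5194 47.7784 -9.5574
K  8.2186   7.4398   1.0519   0.8659   12.7949 0.7748  213.187 41.6841 1.4228
Fe 11.7695  7.3573   3.5222   2.3045   4.7611  0.3072  15.3535 76.8805 1.0369
Ru 19.2674  12.9182  4.86337  1.56756  0.80852 8.43467 24.7997 94.2928 5.37874
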