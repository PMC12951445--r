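# Synthetic OpenDX fixture in the dialect emitted by Poisson-Boltzmann
# solvers (comments, gridpositions counts, z-fastest data, 3 per line).
# Values are v(ix,iy,iz) = 0.01 * (9*(ix-1) + 3*(iy-1) + (iz-1)).
object 1 class gridpositions counts 3 3 3
origin -1.000000e+00 -1.000000e+00 -1.000000e+00
delta 1.000000e+00 0.000000e+00 0.000000e+00
delta 0.000000e+00 1.000000e+00 0.000000e+00
delta 0.000000e+00 0.000000e+00 1.000000e+00
object 2 class gridconnections counts 3 3 3
object 3 class array type double rank 0 items 27 data follows
0.000000e+00 1.000000e-02 2.000000e-02
3.000000e-02 4.000000e-02 5.000000e-02
6.000000e-02 7.000000e-02 8.000000e-02
9.000000e-02 1.000000e-01 1.100000e-01
1.200000e-01 1.300000e-01 1.400000e-01
1.500000e-01 1.600000e-01 1.700000e-01
1.800000e-01 1.900000e-01 2.000000e-01
2.100000e-01 2.200000e-01 2.300000e-01
2.400000e-01 2.500000e-01 2.600000e-01
attribute "dep" string "positions"
object "regular positions regular connections" class field
component "positions" value 1
component "connections" value 2
component "data" value 3
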