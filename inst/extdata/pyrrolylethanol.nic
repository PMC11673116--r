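# 1-(1H-pyrrol-3-yl)ethanol natural internal coordinates (45 = 3N-6).
# Pyrrole ring atoms 1-5 (N = atom 2, ring sequence 1-2-3-4-5-1); C6 carries
# the ethanol fragment: C7 = methyl carbon (H13, H14, H16), O8-H17 hydroxyl,
# H15 on C6; ring hydrogens H9(C1), H10(N2), H11(C3), H12(C4).
# Five-membered-ring combination constants (standard ring-symmetry values):
#   A = cos(144 deg) = -0.809016994374947
#   B = cos(72 deg)  =  0.309016994374947
#   C = sin(144 deg) =  0.587785252292473
#   D = sin(72 deg)  =  0.951056516295154

[coordinate]
name = ring breathing
bond 5 4  1
bond 1 5  1
bond 4 3  1
bond 2 1  1
bond 2 3  1

[coordinate]
name = ring stretching def. 1
bond 5 4  1
bond 1 5  0.309016994374947
bond 4 3  0.309016994374947
bond 2 1  -0.809016994374947
bond 2 3  -0.809016994374947

[coordinate]
name = ring stretching def. 2
bond 1 5  0.951056516295154
bond 4 3  -0.951056516295154
bond 2 1  0.587785252292473
bond 2 3  -0.587785252292473

[coordinate]
name = ring stretching def. 3
bond 5 4  1
bond 1 5  -0.809016994374947
bond 4 3  -0.809016994374947
bond 2 1  0.309016994374947
bond 2 3  0.309016994374947

[coordinate]
name = ring stretching def. 4
bond 1 5  0.587785252292473
bond 4 3  -0.587785252292473
bond 2 1  -0.951056516295154
bond 2 3  0.951056516295154

[coordinate]
name = C5-C6 stretch
bond 5 6  1

[coordinate]
name = C6-C7 stretch
bond 6 7  1

[coordinate]
name = C-O stretch
bond 6 8  1

[coordinate]
name = C1-H9 stretch
bond 1 9  1

[coordinate]
name = N-H stretch
bond 2 10  1

[coordinate]
name = C3-H11 stretch
bond 3 11  1

[coordinate]
name = C4-H12 stretch
bond 4 12  1

[coordinate]
name = C6-H15 stretch
bond 6 15  1

[coordinate]
name = O-H stretch
bond 8 17  1

[coordinate]
name = CH3 sym. stretch
bond 7 13  1
bond 7 14  1
bond 7 16  1

[coordinate]
name = CH3 sym. stretch 2
bond 7 13  2
bond 7 14  -1
bond 7 16  -1

[coordinate]
name = CH3 antisym. stretch
bond 7 14  1
bond 7 16  -1

[coordinate]
name = ring bending
angle 1 2 3  1
angle 2 1 5  -0.809016994374947
angle 2 3 4  -0.809016994374947
angle 1 5 4  0.309016994374947
angle 3 4 5  0.309016994374947

[coordinate]
name = ring shearing
angle 2 1 5  -1.118033988749895
angle 2 3 4  1.118033988749895
angle 1 5 4  1.809016994374947
angle 3 4 5  -1.809016994374947

[coordinate]
name = C6-C5 P rock
angle 6 5 4  1
angle 6 5 1  -1

[coordinate]
name = C7-C6-O bend
angle 8 6 7  1

[coordinate]
name = C5-C6 E wag
angle 5 6 7  1
angle 5 6 8  1

[coordinate]
name = C5-C6 E rock
angle 5 6 7  1
angle 5 6 8  -1

[coordinate]
name = C-H rock (C1)
angle 9 1 2  1
angle 9 1 5  -1

[coordinate]
name = N-H rock
angle 10 2 3  1
angle 10 2 1  -1

[coordinate]
name = C-H rock (C3)
angle 11 3 4  1
angle 11 3 2  -1

[coordinate]
name = C-H rock (C4)
angle 12 4 5  1
angle 12 4 3  -1

[coordinate]
name = C-O-H bend
angle 17 8 6  1

[coordinate]
name = H-C-C rock
angle 15 6 7  1
angle 15 6 8  1

[coordinate]
name = H-C-C wag
angle 15 6 7  1
angle 15 6 8  -1

[coordinate]
name = CH3 umbrella
angle 13 7 6  1
angle 14 7 6  1
angle 16 7 6  1
angle 14 7 16  -1
angle 13 7 14  -1
angle 13 7 16  -1

[coordinate]
name = CH3 rock
angle 13 7 6  2
angle 14 7 6  -1
angle 16 7 6  -1

[coordinate]
name = CH3 wag
angle 14 7 6  1
angle 16 7 6  -1

[coordinate]
name = CH3 scissor
angle 14 7 16  2
angle 13 7 14  -1
angle 13 7 16  -1

[coordinate]
name = CH3 def.
angle 13 7 14  1
angle 13 7 16  -1

[coordinate]
name = ring twisting
torsion 1 5 4 3  1
torsion 4 3 2 1  0.309016994374947
torsion 3 2 1 5  0.309016994374947
torsion 5 4 3 2  -0.809016994374947
torsion 2 1 5 4  -0.809016994374947

[coordinate]
name = ring puckering
torsion 4 3 2 1  1.809016994374947
torsion 3 2 1 5  -1.809016994374947
torsion 5 4 3 2  -1.118033988749895
torsion 2 1 5 4  1.118033988749895

[coordinate]
name = CH3 torsion
torsion 13 7 6 8  1
torsion 14 7 6 8  1
torsion 16 7 6 8  1

[coordinate]
name = O-H torsion
torsion 17 8 6 7  1

[coordinate]
name = P-E torsion
torsion 1 5 6 7  1
torsion 1 5 6 8  1
torsion 4 5 6 7  1
torsion 4 5 6 8  1

[coordinate]
name = C6-C5 P wag
out_of_plane 6 5 1 4  1

[coordinate]
name = C-H wag (C1)
out_of_plane 9 1 2 5  1

[coordinate]
name = N-H wag
out_of_plane 10 2 3 1  1

[coordinate]
name = C-H wag (C3)
out_of_plane 11 3 4 2  1

[coordinate]
name = C-H wag (C4)
out_of_plane 12 4 5 3  1
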