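# Pyridine natural internal coordinates (27 = 3N-6 for C5H5N).
# Ring atoms 1-5 are carbons (ring sequence 5-3-1-2-4-6), atom 6 is N;
# hydrogens 7-11 sit on carbons 1-5 respectively.
# Coefficients are the unnormalized ring-symmetry combinations; rows are
# normalized to unit Euclidean norm on load.

[coordinate]
name = ring breathing
irrep = a1
bond 5 3  1
bond 3 1  1
bond 1 2  1
bond 2 4  1
bond 4 6  1
bond 6 5  1

[coordinate]
name = ring stretching def. 1
irrep = b2
bond 5 3  1
bond 3 1  -1
bond 1 2  1
bond 2 4  -1
bond 4 6  1
bond 6 5  -1

[coordinate]
name = ring stretching def. 2
irrep = a1
bond 5 3  2
bond 3 1  -1
bond 1 2  -1
bond 2 4  2
bond 4 6  -1
bond 6 5  -1

[coordinate]
name = ring stretching def. 3
irrep = b2
bond 5 3  2
bond 3 1  1
bond 1 2  -1
bond 2 4  -2
bond 4 6  -1
bond 6 5  1

[coordinate]
name = ring stretching def. 4
irrep = a1
bond 3 1  1
bond 1 2  1
bond 4 6  -1
bond 6 5  -1

[coordinate]
name = ring stretching def. 5
irrep = b2
bond 3 1  1
bond 1 2  -1
bond 4 6  1
bond 6 5  -1

[coordinate]
name = sym. CH stretch (5,4)
irrep = a1
bond 5 11  1
bond 4 10  1

[coordinate]
name = antisym. CH stretch (5,4)
irrep = b2
bond 5 11  1
bond 4 10  -1

[coordinate]
name = sym. CH stretch (3,2)
irrep = a1
bond 3 9  1
bond 2 8  1

[coordinate]
name = antisym. CH stretch (3,2)
irrep = b2
bond 3 9  1
bond 2 8  -1

[coordinate]
name = CH stretch (1)
irrep = a1
bond 1 7  1

[coordinate]
name = ring stellation
irrep = a1
angle 4 6 5  1
angle 6 5 3  -1
angle 5 3 1  1
angle 3 1 2  -1
angle 1 2 4  1
angle 2 4 6  -1

[coordinate]
name = ring rectangulation
irrep = a1
angle 4 6 5  2
angle 6 5 3  -1
angle 5 3 1  -1
angle 3 1 2  2
angle 1 2 4  -1
angle 2 4 6  -1

[coordinate]
name = ring shearing
irrep = b2
angle 6 5 3  1
angle 5 3 1  -1
angle 1 2 4  1
angle 2 4 6  -1

[coordinate]
name = sym. i.p. CH rock (5,4)
irrep = a1
angle 11 5 6  1
angle 11 5 3  -1
angle 10 4 6  1
angle 10 4 2  -1

[coordinate]
name = antisym. i.p. CH rock (5,4)
irrep = b2
angle 11 5 6  1
angle 11 5 3  -1
angle 10 4 6  -1
angle 10 4 2  1

[coordinate]
name = sym. i.p. CH rock (3,2)
irrep = a1
angle 9 3 5  1
angle 9 3 1  -1
angle 8 2 4  1
angle 8 2 1  -1

[coordinate]
name = antisym. i.p. CH rock (3,2)
irrep = b2
angle 9 3 5  1
angle 9 3 1  -1
angle 8 2 4  -1
angle 8 2 1  1

[coordinate]
name = i.p. CH rock (1)
irrep = b2
angle 7 1 2  1
angle 7 1 3  -1

[coordinate]
name = chair ring pucker
irrep = b1
torsion 6 5 3 1  1
torsion 3 1 2 4  1
torsion 5 3 1 2  -1
torsion 1 2 4 6  -1
torsion 2 4 6 5  1
torsion 4 6 5 3  -1

[coordinate]
name = boat ring pucker
irrep = b1
torsion 3 1 2 4  1
torsion 5 3 1 2  -1
torsion 2 4 6 5  -1
torsion 4 6 5 3  1

[coordinate]
name = ring twist
irrep = a2
torsion 6 5 3 1  2
torsion 5 3 1 2  -1
torsion 3 1 2 4  -1
torsion 1 2 4 6  2
torsion 2 4 6 5  -1
torsion 4 6 5 3  -1

[coordinate]
name = sym. o.o.p. CH wag (5,4)
irrep = b1
out_of_plane 11 5 3 6  1
out_of_plane 10 4 6 2  1

[coordinate]
name = antisym. o.o.p. CH wag (5,4)
irrep = a2
out_of_plane 11 5 3 6  1
out_of_plane 10 4 6 2  -1

[coordinate]
name = sym. o.o.p. CH wag (3,2)
irrep = b1
out_of_plane 9 3 1 5  1
out_of_plane 8 2 4 1  1

[coordinate]
name = antisym. o.o.p. CH wag (3,2)
irrep = a2
out_of_plane 9 3 1 5  1
out_of_plane 8 2 4 1  -1

[coordinate]
name = o.o.p. CH wag (1)
irrep = b1
out_of_plane 7 1 2 3  1
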