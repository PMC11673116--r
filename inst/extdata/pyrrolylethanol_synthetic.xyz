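17
1-(1H-pyrrol-3-yl)ethanol, idealized synthetic geometry, not a reference structure
C       0.000000000000     1.190911131693     0.000000000000
N      -1.132623792125     0.368011778483     0.000000000000
C      -0.700000000000    -0.963467344330     0.000000000000
C       0.700000000000    -0.963467344330     0.000000000000
C       1.132623792125     0.368011778483     0.000000000000
C       2.568719131731     0.834627439990     0.000000000000
C       2.083709535548     0.677038269328     1.442508698380
O       1.754601604925     1.797790762053    -0.674113542053
H       0.000000000000     2.270911131693     0.000000000000
H      -2.093190873583     0.680118942802     0.000000000000
H      -1.334808072476    -1.837205698255     0.000000000000
H       1.334808072476    -1.837205698255     0.000000000000
H       2.935684319355     0.024171078709     1.252763081384
H       1.289239546302     0.418899321756     0.742307498770
H       2.498210828935    -0.124070833618    -0.513834797789
H       2.389225908075     1.705997134856     1.252763081384
H       1.175669321810     1.128650125483    -0.301704868607
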