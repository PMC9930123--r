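6
hydrogen-bonded water dimer, acceptor then donor, O-O 2.97 A
O        0.0000000000       0.0000000000       0.0000000000
H       -0.5858822766       0.0000000000       0.7569503273
H       -0.5858822766       0.0000000000      -0.7569503273
O        2.9700000000       0.0000000000       0.0000000000
H        2.0128000000       0.0000000000       0.0000000000
H        3.2099872084       0.9266272065       0.0000000000
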