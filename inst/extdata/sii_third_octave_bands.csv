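center_hz,importance,internal_noise_db
160,0.0083,0.6
200,0.0095,-1.7
250,0.0150,-3.9
315,0.0289,-6.1
400,0.0440,-8.2
500,0.0578,-9.7
630,0.0653,-10.8
800,0.0711,-11.9
1000,0.0818,-12.5
1250,0.0844,-13.5
1600,0.0882,-15.4
2000,0.0898,-17.7
2500,0.0868,-21.2
3150,0.0844,-24.2
4000,0.0771,-25.9
5000,0.0527,-23.6
6300,0.0364,-15.8
8000,0.0185,-7.1
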