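center_hz,importance,internal_noise_db
250,0.0617,1.0
500,0.1671,-4.9
1000,0.2373,-7.7
2000,0.2648,-12.9
4000,0.2142,-21.1
8000,0.0549,-2.2
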