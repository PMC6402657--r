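subject,D1,D2,D3,D4,D5,D6
S1,29.6,39.0,41.3,41.4,52.8,36.5
S2,30.5,33.6,45.8,47.1,41.1,44.1
S3,18.4,18.7,32.3,27.9,16.5,19.5
S4,41.8,50.0,50.2,48.0,40.6,31.5
S5,56.4,54.1,67.0,45.5,44.9,41.3
S6,21.5,27.4,35.7,42.8,21.5,50.7
S7,31.1,21.4,37.9,63.8,46.4,42.8
S8,10.2,14.3,27.2,36.1,13.4,11.4
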