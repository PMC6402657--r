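subject,D1,D2,D3,D4,D5,D6
S1,42.5,46.4,49.7,49.6,58.9,55.8
S2,37.5,45.5,54.2,50.1,47.6,52.1
S3,31.8,32.3,32.0,34.8,32.9,36.8
S4,52.0,59.0,58.5,55.1,54.4,54.6
S5,68.6,70.6,73.4,65.8,61.5,61.9
S6,34.1,34.0,42.5,48.3,33.0,58.1
S7,48.4,52.2,53.3,64.9,51.2,63.6
S8,34.7,30.6,43.7,42.6,36.9,30.7
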