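L_mm,flow_lpm,ptrans_pa,fo_hz,fr1_hz
200,124,4208,151.3,527
240,120,4100,152.9,433
300,123,4188,151.3,337
340,120,4122,150.5,293
400,107,3791,225.7,244
500,99,3617,158.6,190
600,58,2659,158.6,156
700,55,2527,136.8,132
800,46,2266,119.0,114
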