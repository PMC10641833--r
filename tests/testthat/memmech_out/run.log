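2026-09-10 04:09:42 memmech 0.1.0
2026-09-10 04:09:42 stage load start
2026-09-10 04:09:42 stage load FAILED: cannot open the connection
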