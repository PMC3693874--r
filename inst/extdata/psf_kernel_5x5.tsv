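0.0074	0.2584	0.8439	0.2584	0.0074
0.2584	8.9997	29.3891	8.9997	0.2584
0.8439	29.3891	95.9719	29.3891	0.8439
0.2584	8.9997	29.3891	8.9997	0.2584
0.0074	0.2584	0.8439	0.2584	0.0074
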