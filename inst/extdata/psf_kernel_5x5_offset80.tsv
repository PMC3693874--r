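80.0074	80.2584	80.8439	80.2584	80.0074
80.2584	88.9997	109.3891	88.9997	80.2584
80.8439	109.3891	175.9719	109.3891	80.8439
80.2584	88.9997	109.3891	88.9997	80.2584
80.0074	80.2584	80.8439	80.2584	80.0074
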