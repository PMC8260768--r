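dose	tested	responding
2e6	5	5
2e5	5	5
2e4	5	5
2e3	5	4
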