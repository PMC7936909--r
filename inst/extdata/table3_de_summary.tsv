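comparison	total_genes	differential	up	down
CGT vs. CG	29049	613	324	289
MG vs. CG	29049	766	314	452
MGT vs. MG	29049	583	308	275
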