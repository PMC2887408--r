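group,gsi,proxy_for
hima,0.10,
euha,0.13,
cloa,0.18,
acan,0.21,
prob,0.24,
stic,0.27,
renc,0.12,renicolid relative
smcy,0.11,
male,0.146,
female,0.149,
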