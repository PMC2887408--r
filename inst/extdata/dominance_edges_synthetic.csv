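killer,victim
hima,euha
hima,cloa
hima,acan
hima,prob
hima,stic
hima,renc
hima,smcy
euha,cloa
euha,acan
euha,prob
euha,stic
euha,smcy
cloa,acan
cloa,prob
cloa,stic
cloa,smcy
acan,prob
acan,stic
acan,smcy
prob,stic
prob,smcy
stic,smcy
renc,smcy
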