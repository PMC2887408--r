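(((hima:1,euha:1):1,((cloa:1,acan:1):1,(prob:1,stic:1):1):1):1,((renc:1,smcy:1):1,(male:1,female:1):1):1);
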