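(((sp01:1,sp02:1):2,(sp03:2,(sp04:1,sp05:1):1):1):3,((sp06:2,(sp07:1,sp08:1):1):2,((sp09:1,sp10:1):2,(sp11:2,sp12:2):1):1):2);
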