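((P04:1.839470589,P01:0.4375033762):0.5338348006,((P06:0.187451933,P05:0.01352713117):0.2910880172,(P02:0.009825887624,P03:0.2620997019):3.073499277):0.5621648468);
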