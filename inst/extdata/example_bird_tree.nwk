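(H01:0.1795679624,((H03:0.3411924606,H04:0.4974624431):0.1881986307,H02:0.788183363):0.1422189141);
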