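species,bill_length,body_mass,tail_length,wing_chord,tarsus_length
H01,15.0907305266065,3.29309959864841,77.073471114249,49.4785776790969,6.16645668128078
H02,25.4608924546786,7.7615754911234,50.7321313726011,56.8611078785458,7.14525522591553
H03,17.8266952795017,5.07283561878035,58.7537538247206,52.2682164502218,6.55864086867594
H04,18.8798217908708,8.86280284538213,76.9711173437689,58.785172640062,5.24876342017433
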