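site,month,plant,bird,visits,recording_hours
site1,1,P02,H01,3,61.5782699966803
site1,1,P02,H03,3,61.5782699966803
site1,1,P02,H04,1,61.5782699966803
site1,1,P05,H01,6,66.7973370999098
site1,1,P05,H02,4,66.7973370999098
site1,1,P05,H03,17,66.7973370999098
site1,1,P05,H04,10,66.7973370999098
site1,1,P06,,0,69.2865736512467
site1,2,P02,H03,1,70.9321589078754
site1,2,P02,H04,2,70.9321589078754
site1,2,P05,H02,11,60.8966135736555
site1,2,P05,H03,3,60.8966135736555
site1,2,P05,H04,6,60.8966135736555
site1,2,P06,,0,62.3818589346483
site1,3,P02,H01,1,61.4871241869405
site1,3,P02,H03,1,61.4871241869405
site1,3,P02,H04,4,61.4871241869405
site1,3,P05,H01,5,66.064707278274
site1,3,P05,H02,9,66.064707278274
site1,3,P05,H03,8,66.064707278274
site1,3,P05,H04,9,66.064707278274
site1,3,P06,,0,71.2120790714398
site1,4,P01,H02,6,60.3010192522779
site1,4,P02,H01,3,63.2497889650986
site1,4,P02,H04,1,63.2497889650986
site1,4,P04,H04,4,71.1564477402717
site1,4,P05,H01,4,67.556517158635
site1,4,P05,H04,1,67.556517158635
site1,4,P06,,0,63.8092180956155
site1,5,P01,H02,14,71.5585832269862
site1,5,P02,H01,4,64.9188815848902
site1,5,P02,H03,1,64.9188815848902
site1,5,P04,H03,4,68.9775594156235
site1,5,P04,H04,7,68.9775594156235
site1,5,P05,H01,9,61.5977348098531
site1,5,P05,H03,1,61.5977348098531
site1,5,P05,H04,1,61.5977348098531
site1,5,P06,,0,71.6318599786609
site1,6,P01,H02,11,65.0536275180057
site1,6,P02,H01,9,62.4407435562462
site1,6,P03,H01,1,64.6705444827676
site1,6,P03,H02,1,64.6705444827676
site1,6,P03,H04,2,64.6705444827676
site1,6,P04,H01,1,65.9585800459608
site1,6,P04,H04,2,65.9585800459608
site1,6,P05,H01,5,70.5502295158803
site1,6,P06,H01,1,68.6610929081216
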