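"sex","age_lo","age_hi","mean","sd"
"M",5,6,16.4,2
"M",6,7,17.3,2.1
"M",7,8,18.1,2.2
"M",8,9,18.8,2.3
"M",9,10,19.4,2.4
"M",10,11,19.9,2.5
"M",11,12,20.4,2.6
"M",12,13,20.7,2.7
"M",13,14,21.1,2.8
"M",14,15,21.4,2.9
"M",15,16,21.6,3
"M",16,17,21.9,3
"M",17,18,22.1,3.1
"M",18,25,22.2,3.2
"M",25,35,22.9,3.2
"M",35,50,23.2,3.2
"F",5,6,16,2
"F",6,7,16.9,2
"F",7,8,17.6,2.1
"F",8,9,18.3,2.2
"F",9,10,18.9,2.3
"F",10,11,19.4,2.4
"F",11,12,19.8,2.5
"F",12,13,20.2,2.6
"F",13,14,20.5,2.7
"F",14,15,20.8,2.8
"F",15,16,21,2.8
"F",16,17,21.2,2.9
"F",17,18,21.4,3
"F",18,25,21.6,3.1
"F",25,35,22.2,3.1
"F",35,50,22.5,3.1
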