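"process","sp_mean","sp_sd","o18_mean","o18_sd"
"bD",-1.9,2.8,19.2,1.65
"fD",33.5,3.18,47.2,3.28
"Ni",35,1.68,23.5,3
"nD",-5.9,3.88,16.8,1.25
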