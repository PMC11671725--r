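sp_mean,sp_sd,o18_mean,o18_sd,spc_mean,spc_sd,r_mean,r_sd,ratio_unit
5.7658264753291286,0.10000000000000001,33.394679425987384,0.5,0.97089999999999999,0.0067000000000000002,0.41570000000000001,0.049399999999999999,fraction
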