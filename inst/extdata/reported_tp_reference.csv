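quantity,item,reported,tolerance,digits
fish_tp_single,fish_1,2.53,0.01,2
fish_tp_single,fish_2,2.63,0.01,2
fish_tp_single,fish_3,2.76,0.01,2
fish_tp_single_mean,all,2.64,0.01,2
fish_corrected_tp,all,2.38,0.01,2
squid_tp,all,2.67,0.01,2
bird_tp_single,bird_1,2.54,0.01,2
bird_tp_single,bird_2,2.83,0.01,2
bird_tp_single,bird_3,2.75,0.01,2
bird_tp_single,bird_4,2.51,0.01,2
bird_tp_single,bird_5,2.84,0.01,2
bird_tp_single,bird_6,2.66,0.01,2
bird_tp_single,bird_7,2.6,0.01,2
bird_tp_multi,bird_1,3.14,0.06,2
bird_tp_multi,bird_2,3.78,0.06,2
bird_tp_multi,bird_3,3.61,0.06,2
bird_tp_multi,bird_4,3.07,0.06,2
bird_tp_multi,bird_5,3.8,0.06,2
bird_tp_multi,bird_6,3.4,0.06,2
bird_tp_multi,bird_7,3.27,0.06,2
bird_tp_single_mean,all,2.68,0.01,2
bird_tp_multi_mean,all,3.44,0.06,2
spacing_mean,fish,15.9,0.05,1
spacing_sd,fish,0.9,0.05,1
bulk_offset_15N,bird_minus_fish,6.2,0.05,1
period_tp_single,MWP,2.63,0.01,2
period_tp_single,LIA,2.7,0.01,2
period_tp_single,all,2.68,0.01,2
period_tp_multi,MWP,3.34,0.06,2
period_tp_multi,LIA,3.4,0.06,2
period_tp_multi,all,3.44,0.06,2
period_tp_diet,MWP,3.41,0.01,2
period_tp_diet,LIA,3.56,0.01,2
period_tp_diet,all,3.44,0.01,2
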