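well,role,group,condition,density
A1,sample,motor_neuron,rest,50000
A2,sample,motor_neuron,stimulated,50000
A3,dye_only_background,,rest,
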