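participant_id,max_force,ami_ba,ami_es,ami_sm,ami_total
p001,69.2836718721501,1.6923836546492066,1.2072675272035545,1.2909147267728769,1.3968553028752126
p002,60.71626023589366,2.5074128450334996,1.6186869429911146,1.5385519400921988,1.8882172427056043
p003,56.19512560651706,2.118062185299655,1.1025356370663562,0.9176483276594584,1.379415383341823
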