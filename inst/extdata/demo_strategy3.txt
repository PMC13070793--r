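solitary_lung_mass
inferior_mediastinal_mass
superior_mediastinal_mass
diffuse_upper_airspace_opacity
diffuse_airspace_opacity
pleural_effusion
loculated_pleural_effusion
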