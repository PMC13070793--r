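finding,priority_class
pneumothorax,CRITICAL
tension_pneumothorax,CRITICAL
pneumomediastinum,CRITICAL
solitary_lung_mass,HIGH
inferior_mediastinal_mass,HIGH
superior_mediastinal_mass,HIGH
diffuse_upper_airspace_opacity,HIGH
diffuse_airspace_opacity,HIGH
pleural_effusion,HIGH
loculated_pleural_effusion,HIGH
interstitial_thickening,HIGH
illustrative_standard_finding_01,STANDARD
illustrative_standard_finding_02,STANDARD
illustrative_standard_finding_03,STANDARD
illustrative_standard_finding_04,STANDARD
illustrative_standard_finding_05,STANDARD
illustrative_standard_finding_06,STANDARD
illustrative_standard_finding_07,STANDARD
illustrative_standard_finding_08,STANDARD
illustrative_standard_finding_09,STANDARD
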