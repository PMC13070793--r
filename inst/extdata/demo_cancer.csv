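study_id,pneumothorax,tension_pneumothorax,pneumomediastinum,solitary_lung_mass,inferior_mediastinal_mass,superior_mediastinal_mass,diffuse_upper_airspace_opacity,diffuse_airspace_opacity,pleural_effusion,loculated_pleural_effusion,interstitial_thickening,illustrative_standard_finding_01,illustrative_standard_finding_02,illustrative_standard_finding_03,illustrative_standard_finding_04,illustrative_standard_finding_05,illustrative_standard_finding_06,illustrative_standard_finding_07,illustrative_standard_finding_08,illustrative_standard_finding_09
c1_00001,0,0,0,0,1,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0
c1_00002,0,0,1,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0
c1_00003,0,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,0,0,1,0
c1_00004,0,0,1,0,0,1,0,1,0,0,0,0,1,0,0,0,0,0,0,1
c1_00005,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,1,0,0,0
c1_00006,0,0,0,0,1,1,1,1,1,1,0,0,0,0,0,1,0,0,0,1
c1_00007,0,1,0,1,0,1,1,0,1,1,0,0,0,0,1,1,0,1,1,1
c1_00008,0,0,0,0,0,0,1,0,0,0,0,1,0,0,0,0,0,0,0,0
c1_00009,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0
c1_00010,0,0,0,0,1,0,0,1,0,0,0,0,0,0,0,1,0,0,0,0
c1_00011,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
c1_00012,0,0,0,0,1,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0
c1_00013,0,0,0,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1
c1_00014,0,0,0,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00015,0,0,0,0,1,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0
c1_00016,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00017,0,0,0,1,0,0,0,0,0,0,0,0,0,0,1,0,0,1,0,0
c1_00018,0,0,0,1,1,0,0,1,0,0,0,0,0,1,1,1,0,0,0,0
c1_00019,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00020,0,0,0,1,0,0,0,1,1,0,0,0,0,0,0,0,0,0,0,0
c1_00021,1,0,0,0,0,1,1,0,0,0,1,0,1,1,0,0,1,0,1,0
c1_00022,1,0,0,0,1,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0
c1_00023,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
c1_00024,0,0,0,0,1,0,0,1,0,0,0,1,0,0,0,0,1,0,0,1
c1_00025,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00026,0,0,0,0,0,1,0,1,0,0,0,0,0,1,0,0,0,0,0,0
c1_00027,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00028,0,0,0,1,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0
c1_00029,0,0,0,1,1,0,0,0,1,0,1,1,0,0,0,0,0,0,0,0
c1_00030,0,0,0,0,1,0,0,1,0,0,0,0,0,1,0,1,0,1,0,0
c1_00031,0,0,0,1,0,0,1,1,0,0,0,1,0,0,1,0,0,0,0,1
c1_00032,1,0,0,0,0,1,0,0,0,0,0,0,0,0,0,1,0,0,0,0
c1_00033,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,1,0,0,0
c1_00034,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,1,0
c1_00035,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00036,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0
c1_00037,0,0,0,1,0,0,0,1,0,0,0,0,0,1,0,0,0,1,0,0
c1_00038,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00039,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00040,0,0,0,1,0,1,0,1,0,0,0,1,0,1,0,0,0,0,0,0
c1_00041,0,0,0,0,1,1,1,0,0,0,0,0,0,0,0,1,1,0,0,0
c1_00042,0,0,0,0,0,0,0,1,0,0,1,0,0,0,0,1,0,0,0,0
c1_00043,1,0,0,1,1,0,1,0,0,1,0,0,1,0,0,0,0,0,0,0
c1_00044,0,0,1,0,0,1,0,1,0,1,0,0,1,1,0,1,0,1,0,0
c1_00045,0,0,0,0,0,1,1,1,0,0,1,0,0,0,1,0,0,0,0,0
c1_00046,0,0,1,1,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0
c1_00047,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00048,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00049,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,1,0,0
c1_00050,0,0,0,1,1,1,1,0,0,0,0,0,0,0,0,0,0,0,0,1
c1_00051,0,0,0,0,1,0,0,0,0,0,0,0,0,1,0,0,0,0,0,1
c1_00052,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00053,0,0,0,0,0,0,0,1,1,0,0,0,0,0,0,0,0,0,0,0
c1_00054,0,0,0,0,1,1,1,0,0,0,0,0,0,0,0,0,0,0,1,0
c1_00055,0,0,0,0,1,1,0,1,0,0,0,0,0,1,1,0,0,0,0,0
c1_00056,0,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,1,1,0,1
c1_00057,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00058,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0
c1_00059,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00060,0,0,0,1,1,0,0,1,0,0,0,0,0,0,1,0,0,1,0,0
c1_00061,0,0,0,1,1,0,0,1,1,0,0,0,0,0,0,0,0,0,0,0
c1_00062,0,0,0,1,1,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0
c1_00063,0,0,1,0,0,1,0,0,0,1,0,0,0,0,1,1,0,0,0,1
c1_00064,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0
c1_00065,0,0,0,0,1,1,1,0,0,0,0,0,0,0,0,1,0,1,0,0
c1_00066,0,0,0,1,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00067,0,0,0,1,0,1,0,1,1,0,1,0,0,0,0,0,0,0,0,1
c1_00068,0,0,0,1,1,0,0,0,1,0,0,0,0,0,0,1,0,0,0,0
c1_00069,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00070,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0
c1_00071,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00072,0,0,1,0,0,0,1,1,1,0,0,0,0,0,1,1,0,0,0,0
c1_00073,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0
c1_00074,0,0,0,1,1,1,0,0,0,0,0,0,0,0,0,0,0,0,1,1
c1_00075,1,0,0,0,1,1,0,0,0,0,1,1,0,0,1,0,1,1,0,0
c1_00076,0,0,0,0,0,0,0,0,0,1,1,0,1,0,0,0,0,0,0,0
c1_00077,1,0,0,0,0,0,1,1,0,0,0,0,0,0,0,0,0,1,0,0
c1_00078,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00079,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00080,0,0,0,1,0,0,0,0,0,0,0,1,0,0,0,0,0,1,0,0
c1_00081,1,0,0,0,0,0,1,1,0,0,1,0,0,0,1,0,0,0,0,0
c1_00082,0,1,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0,1
c1_00083,0,0,0,0,1,0,0,1,0,0,0,0,0,0,0,1,0,0,0,0
c1_00084,0,0,1,1,1,1,0,0,0,0,0,0,0,1,1,0,0,1,0,0
c1_00085,0,0,0,0,0,1,0,0,1,1,0,1,0,1,0,0,0,0,0,0
c1_00086,0,0,0,1,1,0,0,0,1,0,0,0,0,0,1,0,0,0,0,0
c1_00087,0,0,0,0,0,0,1,1,0,0,0,1,0,0,0,0,0,0,0,0
c1_00088,0,0,0,0,1,0,1,1,1,1,0,0,0,0,0,0,0,0,1,0
c1_00089,0,0,0,0,1,0,1,1,0,0,1,0,0,0,0,0,0,0,0,0
c1_00090,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,1,0,0,0
c1_00091,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0
c1_00092,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00093,0,0,0,0,0,1,1,0,0,0,0,0,0,0,0,0,0,0,0,1
c1_00094,0,0,0,1,1,0,0,0,1,0,0,0,0,1,0,0,0,0,0,0
c1_00095,0,0,0,0,1,0,1,0,0,1,0,0,0,0,0,0,1,1,0,1
c1_00096,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0,0
c1_00097,0,0,0,0,0,1,0,0,1,1,1,0,0,0,0,0,0,0,0,0
c1_00098,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00099,0,0,0,1,0,1,1,1,0,1,0,0,0,0,0,0,0,0,1,0
c1_00100,0,1,0,1,1,0,0,0,1,1,0,0,0,0,0,0,0,0,0,1
c1_00101,0,0,1,1,0,1,1,0,0,0,0,0,0,0,1,0,0,1,0,0
c1_00102,0,0,0,1,0,0,1,0,1,0,0,0,0,0,1,1,0,0,0,0
c1_00103,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00104,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1
c1_00105,0,0,1,1,1,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0
c1_00106,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,1,0,0,0,1
c1_00107,0,0,0,1,0,1,0,1,0,1,0,0,0,0,0,0,0,0,1,0
c1_00108,0,0,0,0,0,1,1,0,1,0,1,0,1,0,0,1,0,0,0,1
c1_00109,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00110,0,0,0,0,1,1,1,1,1,0,0,0,0,0,0,0,0,0,0,1
c1_00111,0,0,0,0,0,0,0,1,0,0,1,0,0,0,0,0,0,0,0,0
c1_00112,1,0,0,0,1,1,1,0,0,0,1,1,0,0,1,0,0,0,0,0
c1_00113,0,0,0,1,1,1,1,1,1,0,0,0,0,0,0,1,1,0,0,0
c1_00114,1,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,1,0,0,0
c1_00115,0,0,0,0,0,0,0,0,0,1,0,0,1,0,0,1,0,0,0,0
c1_00116,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00117,0,0,0,0,1,1,0,0,0,0,0,0,0,1,0,0,0,0,0,0
c1_00118,0,0,0,0,0,1,0,1,0,0,1,0,0,0,0,0,0,0,0,0
c1_00119,1,0,0,0,0,0,1,1,0,0,0,0,0,0,1,0,0,0,0,0
c1_00120,0,0,0,0,1,0,0,0,0,0,1,0,0,1,0,1,0,0,0,0
c1_00121,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0
c1_00122,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,1,0,0
c1_00123,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
c1_00124,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0,0
c1_00125,0,0,0,1,1,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00126,0,0,0,0,0,0,0,1,0,0,0,0,1,0,1,0,1,0,0,0
c1_00127,0,0,0,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00128,0,0,0,1,0,0,1,1,0,0,0,1,0,1,0,0,0,0,0,0
c1_00129,0,0,1,0,0,1,0,0,1,0,0,0,0,0,0,0,0,0,0,0
c1_00130,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00131,0,0,0,0,0,0,0,0,0,0,1,0,1,0,1,1,1,0,0,0
c1_00132,0,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0
c1_00133,1,0,0,1,1,1,0,0,0,0,1,0,0,1,0,0,0,1,1,0
c1_00134,0,0,0,0,0,1,0,1,0,1,0,0,0,0,0,0,0,0,0,0
c1_00135,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,1,0
c1_00136,0,0,0,1,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1,0
c1_00137,0,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
c1_00138,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0
c1_00139,0,0,0,0,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00140,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
c1_00141,0,1,0,0,0,0,0,0,0,0,0,0,1,1,0,0,0,0,0,0
c1_00142,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0
c1_00143,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0
c1_00144,0,0,0,0,0,0,0,1,0,0,0,0,1,1,0,0,0,0,0,0
c1_00145,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0,0
c1_00146,0,0,0,0,1,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1
c1_00147,0,0,0,0,0,1,0,1,1,0,0,0,0,1,0,1,0,0,0,0
c1_00148,0,0,0,1,1,1,0,0,0,0,1,0,0,0,0,0,0,0,0,0
c1_00149,0,0,0,1,1,1,0,1,0,0,0,1,0,0,1,0,0,0,1,0
c1_00150,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0
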