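archival_tag_id,acoustic_tag_id,days_detected,archived_days,distance_km,sigma,distance_km_no_acoustic,sigma_no_acoustic,sensitivity_mean_km,sensitivity_min_km,sensitivity_max_km
A19124,22060372,1,12,85.1,2.26,80.3,2.38,1.28,0,7.71
A19230,22060608,0,29,184,1.43,,,,,
A18831,22060633,1,58,133,0.84,115,0.65,4.98,0,22.8
A18844,22060642,0,41,112,0.97,,,,,
A18832,22060511,20,79,250,0.57,263,1.13,56.5,0,91.8
A19051,22060504,1,60,120,0.67,122,0.67,2.36,0,11.1
A18857,22060471,2,341,1055,1.36,914,1.98,12.6,0,103
A18828,22060378,10,372,1828,1.66,1034,0.97,19.2,0,78
A19056,22060500,4,435,1570,1.14,2125,1.57,23.5,0,198
A19226,22060612,0,447,1165,1.21,,,,,
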