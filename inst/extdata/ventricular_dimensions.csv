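structure,measured_ex_vivo_mm,predicted_diastolic_mm,predicted_systolic_mm
interventricular_septum,3.0,1.0,1.7
lv_posterior_wall,3.5,1.3,1.8
lv_diameter,3.7,6.2,3.5
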