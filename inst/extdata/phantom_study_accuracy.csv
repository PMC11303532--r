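table,angle_deg,condyle,mean_error_mm,sd_error_mm,mae_mm,sd_mae_mm
mjsw,0,medial,-0.01,0.15,0.11,0.09
mjsw,0,lateral,-0.22,0.08,0.22,0.08
mjsw,30,medial,-0.21,0.14,0.21,0.14
mjsw,30,lateral,-0.05,0.07,0.06,0.06
mjsw,60,medial,0.02,0.10,0.08,0.05
mjsw,60,lateral,0.14,0.12,0.15,0.12
wear,0,both,-0.02,0.10,0.07,0.06
wear,30,both,0.00,0.06,0.05,0.04
wear,60,both,0.03,0.12,0.09,0.09
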