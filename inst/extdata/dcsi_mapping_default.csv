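prefix,category,severity
E08.31,retinopathy,1
E09.31,retinopathy,1
E10.31,retinopathy,1
E11.31,retinopathy,1
E13.31,retinopathy,1
E08.32,retinopathy,1
E09.32,retinopathy,1
E10.32,retinopathy,1
E11.32,retinopathy,1
E13.32,retinopathy,1
E08.33,retinopathy,1
E09.33,retinopathy,1
E10.33,retinopathy,1
E11.33,retinopathy,1
E13.33,retinopathy,1
E08.34,retinopathy,1
E09.34,retinopathy,1
E10.34,retinopathy,1
E11.34,retinopathy,1
E13.34,retinopathy,1
E08.36,retinopathy,1
E09.36,retinopathy,1
E10.36,retinopathy,1
E11.36,retinopathy,1
E13.36,retinopathy,1
H28.0,retinopathy,1
H35.0,retinopathy,1
E08.35,retinopathy,2
E09.35,retinopathy,2
E10.35,retinopathy,2
E11.35,retinopathy,2
E13.35,retinopathy,2
H33,retinopathy,2
H43.1,retinopathy,2
H54,retinopathy,2
E08.21,nephropathy,1
E09.21,nephropathy,1
E10.21,nephropathy,1
E11.21,nephropathy,1
E13.21,nephropathy,1
E08.22,nephropathy,1
E09.22,nephropathy,1
E10.22,nephropathy,1
E11.22,nephropathy,1
E13.22,nephropathy,1
E08.29,nephropathy,1
E09.29,nephropathy,1
E10.29,nephropathy,1
E11.29,nephropathy,1
E13.29,nephropathy,1
N08,nephropathy,1
N18.1,nephropathy,1
N18.2,nephropathy,1
N18.3,nephropathy,1
N18.4,nephropathy,1
N18.5,nephropathy,2
N18.6,nephropathy,2
N19,nephropathy,2
I12.0,nephropathy,2
Z49,nephropathy,2
Z99.2,nephropathy,2
E08.4,neuropathy,1
E09.4,neuropathy,1
E10.4,neuropathy,1
E11.4,neuropathy,1
E13.4,neuropathy,1
G62.9,neuropathy,1
G63.2,neuropathy,1
G90.9,neuropathy,1
G99.0,neuropathy,1
G45,cerebrovascular,1
I60,cerebrovascular,2
I61,cerebrovascular,2
I62,cerebrovascular,2
I63,cerebrovascular,2
I69,cerebrovascular,2
I20,cardiovascular,1
I24,cardiovascular,1
I25,cardiovascular,1
I21,cardiovascular,2
I22,cardiovascular,2
I46,cardiovascular,2
I49.0,cardiovascular,2
I50,cardiovascular,2
E08.51,peripheral_vascular,1
E09.51,peripheral_vascular,1
E10.51,peripheral_vascular,1
E11.51,peripheral_vascular,1
E13.51,peripheral_vascular,1
I70,peripheral_vascular,1
I73.9,peripheral_vascular,1
E08.52,peripheral_vascular,2
E09.52,peripheral_vascular,2
E10.52,peripheral_vascular,2
E11.52,peripheral_vascular,2
E13.52,peripheral_vascular,2
I74,peripheral_vascular,2
R02,peripheral_vascular,2
Z89,peripheral_vascular,2
E08.64,metabolic,1
E09.64,metabolic,1
E10.64,metabolic,1
E11.64,metabolic,1
E13.64,metabolic,1
E08.0,metabolic,2
E09.0,metabolic,2
E10.0,metabolic,2
E11.0,metabolic,2
E13.0,metabolic,2
E08.1,metabolic,2
E09.1,metabolic,2
E10.1,metabolic,2
E11.1,metabolic,2
E13.1,metabolic,2
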