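drug,endpoint,a,b,c,d,prr,prr_lo,prr_hi,chi2,ror,ror_lo,ror_hi,ic,ic025,ic975,bold_prr,bold_ror,bold_ic
citalopram,qt_prolongation_tdp,381,2290,49824,694012,2.31,2.07,2.57,241.669,2.32,2.08,2.58,1.08,0.91,1.21,1,1,1
escitalopram,qt_prolongation_tdp,299,2372,50299,693537,1.73,1.54,1.95,82.044,1.74,1.54,1.96,0.72,0.53,0.86,0,1,1
sertraline,qt_prolongation_tdp,272,2399,81996,661840,0.92,0.81,1.04,1.83,0.92,0.81,1.04,-0.11,-0.31,0.03,0,0,0
venlafaxine,qt_prolongation_tdp,250,2421,78129,665707,0.88,0.77,1,1.418,0.88,0.77,1,-0.17,-0.37,-0.01,0,0,0
fluoxetine,qt_prolongation_tdp,265,2406,50427,693409,1.51,1.33,1.72,41.018,1.51,1.33,1.72,0.55,0.34,0.69,0,1,1
mirtazapine,qt_prolongation_tdp,136,2535,35629,708207,1.07,0.9,1.27,0.467,1.07,0.9,1.27,0.09,-0.2,0.29,0,0,0
duloxetine,qt_prolongation_tdp,60,2701,79205,664541,0.17,0.14,0.24,207.354,0.19,0.14,0.24,-2.28,-2.71,-1.97,0,0,0
quetiapine,qt_prolongation_tdp,120,2551,22643,721193,1.5,1.25,1.8,18.405,1.5,1.25,1.8,0.56,0.25,0.77,0,1,1
citalopram,atrial_fibrillation,80,609,50125,695693,1.82,1.44,2.3,25.468,1.82,1.44,2.3,0.78,0.41,1.05,0,1,1
escitalopram,atrial_fibrillation,61,628,50537,695281,1.34,1.03,1.74,4.378,1.34,1.03,1.74,0.38,-0.04,0.69,0,1,0
sertraline,atrial_fibrillation,97,592,82171,663647,1.32,1.07,1.64,6.268,1.32,1.07,1.64,0.35,0.01,0.59,0,1,1
venlafaxine,atrial_fibrillation,67,622,78312,667506,0.92,0.71,1.81,0.362,0.92,0.71,1.18,-0.11,-0.52,0.18,0,0,0
fluoxetine,atrial_fibrillation,75,614,50617,695201,1.68,1.32,2.13,17.627,1.68,1.32,2.13,0.68,0.29,0.95,0,1,1
mirtazapine,atrial_fibrillation,25,664,35740,710078,0.75,0.5,1.12,1.796,0.75,0.5,1.12,-0.39,-1.06,0.08,0,0,0
duloxetine,atrial_fibrillation,78,611,79187,666631,1.08,0.85,1.36,0.288,1.08,0.85,1.36,0.09,-0.28,0.36,0,0,0
quetiapine,atrial_fibrillation,8,681,22755,723063,0.37,0.19,0.75,7.69,0.37,0.19,0.75,-1.34,-2.55,-0.54,0,0,0
citalopram,heart_block,59,596,50146,695706,1.37,1.05,1.79,5.086,1.37,1.05,1.8,0.42,-0.01,0.73,0,1,0
escitalopram,heart_block,48,607,50550,695302,1.09,0.81,1.46,0.233,1.09,0.81,1.46,0.11,-0.37,0.45,0,0,0
sertraline,heart_block,85,570,82183,663669,1.2,0.96,1.51,2.364,1.2,0.96,1.51,0.23,-0.13,0.49,0,0,0
venlafaxine,heart_block,52,603,78327,667525,0.74,0.55,0.98,4.305,0.73,0.55,0.98,-0.4,-0.86,-0.07,0,0,0
fluoxetine,heart_block,43,612,50649,695203,0.96,0.71,1.31,0.023,0.96,0.71,1.31,-0.05,-0.56,0.31,0,0,0
mirtazapine,heart_block,43,612,35722,710130,1.4,1.03,1.9,4.142,1.4,1.03,1.9,0.45,-0.06,0.81,0,1,0
duloxetine,heart_block,20,635,79245,666607,0.27,0.17,0.41,38.734,0.26,0.17,0.41,-1.77,-2.52,-1.25,0,0,0
quetiapine,heart_block,28,627,22735,723117,1.42,0.97,2.07,2.929,1.42,0.97,2.07,0.48,-0.15,0.92,0,0,0
citalopram,ventricular_arrhythmia,62,554,50150,695741,1.55,1.19,2.02,10.427,1.55,1.19,2.02,0.58,0.15,0.88,0,1,1
escitalopram,ventricular_arrhythmia,61,555,50537,695354,1.51,1.16,1.97,9.038,1.51,1.16,1.97,0.54,0.12,0.85,0,1,1
sertraline,ventricular_arrhythmia,65,551,82203,663688,0.95,0.74,1.23,13.787,0.95,0.74,1.23,-0.06,-0.47,0.23,0,0,0
venlafaxine,ventricular_arrhythmia,71,545,78308,667583,1.11,0.87,1.42,0.586,1.11,0.87,1.42,0.13,-0.26,0.42,0,0,0
fluoxetine,ventricular_arrhythmia,42,574,50650,695241,1.01,0.73,1.37,0.003,1.01,0.73,1.37,-0.01,-0.51,0.37,0,0,0
mirtazapine,ventricular_arrhythmia,25,591,35740,710151,0.84,0.56,1.25,0.573,0.84,0.56,1.25,-0.24,-0.9,0.24,0,0,0
duloxetine,ventricular_arrhythmia,18,598,79247,666644,0.25,0.16,0.41,37.668,0.25,0.16,0.4,-1.83,-2.63,-1.28,0,0,0
quetiapine,ventricular_arrhythmia,43,573,22720,723171,2.39,1.75,3.25,30.912,2.39,1.75,3.26,1.17,0.67,1.54,1,1,1
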