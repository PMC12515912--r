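endpoint,drug_i,drug_j,or,lo,hi
qt_prolongation_tdp,citalopram,escitalopram,1.29,1.11,1.50
qt_prolongation_tdp,citalopram,sertraline,2.31,1.97,2.69
qt_prolongation_tdp,citalopram,venlafaxine,2.39,2.04,2.80
qt_prolongation_tdp,citalopram,fluoxetine,1.46,1.24,1.70
qt_prolongation_tdp,citalopram,mirtazapine,2.00,1.65,2.44
qt_prolongation_tdp,citalopram,quetiapine,1.44,1.18,1.77
qt_prolongation_tdp,citalopram,duloxetine,10.10,7.69,13.26
qt_prolongation_tdp,escitalopram,duloxetine,7.85,5.95,10.36
qt_prolongation_tdp,escitalopram,sertraline,1.79,1.52,2.11
qt_prolongation_tdp,escitalopram,venlafaxine,1.86,1.57,2.20
atrial_fibrillation,citalopram,sertraline,1.35,1.01,1.82
atrial_fibrillation,citalopram,venlafaxine,1.87,1.35,2.58
atrial_fibrillation,citalopram,mirtazapine,2.28,1.46,3.58
atrial_fibrillation,citalopram,duloxetine,1.62,1.19,2.21
atrial_fibrillation,citalopram,quetiapine,4.54,2.19,9.39
heart_block,venlafaxine,duloxetine,2.63,1.57,4.41
ventricular_arrhythmia,citalopram,sertraline,1.56,1.10,2.22
ventricular_arrhythmia,citalopram,fluoxetine,1.49,1.01,2.21
ventricular_arrhythmia,citalopram,mirtazapine,1.77,1.11,2.81
ventricular_arrhythmia,citalopram,duloxetine,5.44,3.22,9.20
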