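drug,endpoint,a,b,c,d
citalopram,qt_prolongation_tdp,381,2290,49824,694012
escitalopram,qt_prolongation_tdp,299,2372,50299,693537
sertraline,qt_prolongation_tdp,272,2399,81996,661840
venlafaxine,qt_prolongation_tdp,250,2421,78129,665707
fluoxetine,qt_prolongation_tdp,265,2406,50427,693409
mirtazapine,qt_prolongation_tdp,136,2535,35629,708207
duloxetine,qt_prolongation_tdp,60,2701,79205,664541
quetiapine,qt_prolongation_tdp,120,2551,22643,721193
citalopram,atrial_fibrillation,80,609,50125,695693
escitalopram,atrial_fibrillation,61,628,50537,695281
sertraline,atrial_fibrillation,97,592,82171,663647
venlafaxine,atrial_fibrillation,67,622,78312,667506
fluoxetine,atrial_fibrillation,75,614,50617,695201
mirtazapine,atrial_fibrillation,25,664,35740,710078
duloxetine,atrial_fibrillation,78,611,79187,666631
quetiapine,atrial_fibrillation,8,681,22755,723063
citalopram,heart_block,59,596,50146,695706
escitalopram,heart_block,48,607,50550,695302
sertraline,heart_block,85,570,82183,663669
venlafaxine,heart_block,52,603,78327,667525
fluoxetine,heart_block,43,612,50649,695203
mirtazapine,heart_block,43,612,35722,710130
duloxetine,heart_block,20,635,79245,666607
quetiapine,heart_block,28,627,22735,723117
citalopram,ventricular_arrhythmia,62,554,50150,695741
escitalopram,ventricular_arrhythmia,61,555,50537,695354
sertraline,ventricular_arrhythmia,65,551,82203,663688
venlafaxine,ventricular_arrhythmia,71,545,78308,667583
fluoxetine,ventricular_arrhythmia,42,574,50650,695241
mirtazapine,ventricular_arrhythmia,25,591,35740,710151
duloxetine,ventricular_arrhythmia,18,598,79247,666644
quetiapine,ventricular_arrhythmia,43,573,22720,723171
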