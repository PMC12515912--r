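# Placeholder preferred-term groups for the four arrhythmia endpoints,
# patterned on the SMQ-narrow style of grouping.  MedDRA SMQ content is
# licensed and is NOT reproduced here: these synthetic lists keep the
# pipeline runnable and testable; substitute licensed SMQ-narrow PT lists
# for production use.  The four groups must stay pairwise disjoint because
# the endpoints are tabulated separately.
qt_prolongation_tdp:
  - Electrocardiogram QT prolonged
  - Electrocardiogram QT interval abnormal
  - Torsade de pointes
  - Long QT syndrome
atrial_fibrillation:
  - Atrial fibrillation
  - Atrial flutter
heart_block:
  - Atrioventricular block
  - Atrioventricular block first degree
  - Atrioventricular block second degree
  - Atrioventricular block complete
  - Bundle branch block left
  - Bundle branch block right
ventricular_arrhythmia:
  - Ventricular arrhythmia
  - Ventricular tachycardia
  - Ventricular fibrillation
  - Ventricular flutter
  - Ventricular extrasystoles
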