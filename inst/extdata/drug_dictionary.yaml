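# Verbatim-name -> generic mapping for the eight study antidepressants.
# Synonyms are matched exactly after normalization (case-fold, trim, dosage
# and salt/formulation suffix stripping), so plain salt forms need no entry.
citalopram:
  - citalopram
  - celexa
  - cipramil
escitalopram:
  - escitalopram
  - lexapro
  - cipralex
sertraline:
  - sertraline
  - zoloft
  - lustral
venlafaxine:
  - venlafaxine
  - effexor
  - effexor xr
fluoxetine:
  - fluoxetine
  - prozac
  - sarafem
mirtazapine:
  - mirtazapine
  - remeron
  - zispin
duloxetine:
  - duloxetine
  - cymbalta
  - yentreve
quetiapine:
  - quetiapine
  - seroquel
  - seroquel xr
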